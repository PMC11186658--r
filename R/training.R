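# The training harness: per-sample min-max normalization, cubic patching,
# Dice / Dice+cross-entropy losses, and a train() loop that plugs the bucket
# controller into any model implementing the trainer contract (fit_step /
# validate_loss / predict_labels). Augmentation touches training patches
# only; validation and test sets always pass through untouched.

#' Training configuration
#'
#' @param n_buckets Number of buckets `N_b` (default 10).
#' @param n_ops Transforms per bucket `N_op` (default 5).
#' @param val_every_k_epochs Run validation (and one controller update) every
#'   `K` epochs (default 2).
#' @param epochs Total training epochs.
#' @param patch_size Cubic patch shape, 3 positive integers. 96^3 matches
#'   full-scale CT practice; tests and the synthetic demo use 16^3.
#' @param batch_size Patches per gradient step (default 2).
#' @param seed Integer seed controlling the whole run.
#' @param augmentation_mode One of `"bucketaugment"` (policy search),
#'   `"trivialaugment"` (one random transform per sample) or `"none"`.
#' @return A `train_config` list.
#' @export
train_config <- function(n_buckets = 10, n_ops = 5, val_every_k_epochs = 2,
                         epochs = 6, patch_size = c(96, 96, 96),
                         batch_size = 2, seed = 1,
                         augmentation_mode = c("bucketaugment",
                                               "trivialaugment", "none")) {
  augmentation_mode <- match.arg(augmentation_mode)
  patch_size <- as.integer(rep_len(patch_size, 3L))
  counts <- c(n_buckets, n_ops, val_every_k_epochs, epochs, batch_size,
              patch_size)
  if (any(is.na(counts)) || any(counts < 1)) {
    stop("all counts in the training configuration must be positive integers",
         call. = FALSE)
  }
  structure(
    list(n_buckets = as.integer(n_buckets), n_ops = as.integer(n_ops),
         val_every_k_epochs = as.integer(val_every_k_epochs),
         epochs = as.integer(epochs), patch_size = patch_size,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         augmentation_mode = augmentation_mode),
    class = "train_config"
  )
}

#' Per-sample min-max intensity normalization
#'
#' Rescales a raw scalar volume (e.g. Hounsfield units) to \[0, 1\] using the
#' minimum and maximum of that sample: `(x - min) / (max - min)`.
#'
#' @param raw_image 3D numeric array in acquisition units.
#' @return 3D array with minimum 0 and maximum 1.
#' @export
normalize_volume <- function(raw_image) {
  if (!is.array(raw_image) || length(dim(raw_image)) != 3L) {
    stop("`raw_image` must be a 3D array", call. = FALSE)
  }
  if (any(!is.finite(raw_image))) {
    stop("`raw_image` contains non-finite values", call. = FALSE)
  }
  lo <- min(raw_image)
  hi <- max(raw_image)
  if (hi == lo) {
    stop("cannot normalize a constant volume (zero dynamic range)",
         call. = FALSE)
  }
  (raw_image - lo) / (hi - lo)
}

#' Split a volume into non-overlapping cubic patches
#'
#' Each axis is zero-padded (background label) up to the next multiple of the
#' patch size, then tiled without overlap; the union of patches covers the
#' padded volume exactly once. [unpatchify()] inverts the operation.
#'
#' @param volume A [volume_patch()].
#' @param patch_size 3 positive integers.
#' @return A list of `volume_patch` objects carrying the tiling geometry in
#'   attributes (`orig_dim`, `padded_dim`, `patch_size`, and per-patch
#'   `offset`).
#' @export
patchify <- function(volume, patch_size) {
  check_patch(volume)
  patch_size <- as.integer(rep_len(patch_size, 3L))
  if (any(is.na(patch_size)) || any(patch_size < 1L)) {
    stop("`patch_size` must be 3 positive integers", call. = FALSE)
  }
  d <- dim(volume$image)
  n_tiles <- ceiling(d / patch_size)
  padded <- n_tiles * patch_size
  img <- array(0, dim = padded)
  lab <- array(0L, dim = padded)
  img[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- volume$image
  lab[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- volume$label

  patches <- list()
  for (k in seq_len(n_tiles[3])) for (j in seq_len(n_tiles[2])) {
    for (i in seq_len(n_tiles[1])) {
      o <- (c(i, j, k) - 1L) * patch_size
      xs <- o[1] + seq_len(patch_size[1])
      ys <- o[2] + seq_len(patch_size[2])
      zs <- o[3] + seq_len(patch_size[3])
      p <- volume_patch(img[xs, ys, zs, drop = FALSE],
                        lab[xs, ys, zs, drop = FALSE], volume$spacing)
      attr(p, "offset") <- o
      patches[[length(patches) + 1L]] <- p
    }
  }
  attr(patches, "orig_dim") <- d
  attr(patches, "padded_dim") <- padded
  attr(patches, "patch_size") <- patch_size
  patches
}

#' Reassemble patches produced by [patchify()]
#'
#' @param patches The list returned by [patchify()].
#' @return The original `volume_patch` (padding cropped away).
#' @export
unpatchify <- function(patches) {
  d <- attr(patches, "orig_dim")
  padded <- attr(patches, "padded_dim")
  if (is.null(d) || is.null(padded)) {
    stop("`patches` must come from patchify()", call. = FALSE)
  }
  ps <- attr(patches, "patch_size")
  img <- array(0, dim = padded)
  lab <- array(0L, dim = padded)
  for (p in patches) {
    o <- attr(p, "offset")
    img[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]), o[3] + seq_len(ps[3])] <-
      p$image
    lab[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]), o[3] + seq_len(ps[3])] <-
      p$label
  }
  volume_patch(img[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE],
               lab[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE],
               patches[[1]]$spacing)
}

#' Sørensen–Dice coefficient between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred,truth Binary (logical or 0/1) arrays of identical shape.
#' @return A number in \[0, 1\].
#' @export
dice_score <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("`pred` and `truth` must have the same shape", call. = FALSE)
  }
  a <- as.logical(pred)
  b <- as.logical(truth)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Combined soft-Dice and cross-entropy loss
#'
#' The unweighted sum of (1 - mean per-class soft Dice) and the voxel-mean
#' cross-entropy of the true class. Class channel `k` of the prediction
#' corresponds to label id `k - 1`, so channel 1 is the background.
#'
#' @param pred_probabilities 4D array (x, y, z, class) of per-voxel class
#'   probabilities; each voxel's probabilities must sum to 1.
#' @param truth 3D integer label array with ids in `0:(n_classes - 1)`.
#' @return A non-negative number.
#' @export
dice_ce_loss <- function(pred_probabilities, truth) {
  dp <- dim(pred_probabilities)
  if (length(dp) != 4L || !identical(dp[1:3], dim(truth))) {
    stop("`pred_probabilities` must be a 4D (x, y, z, class) array over the ",
         "shape of `truth`", call. = FALSE)
  }
  n_class <- dp[4]
  pmat <- matrix(pred_probabilities, ncol = n_class)
  if (any(pmat < -1e-9) ||
      max(abs(rowSums(pmat) - 1)) > 1e-6) {
    stop("per-voxel probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  t_id <- as.integer(truth) + 1L
  if (any(t_id < 1L) || any(t_id > n_class)) {
    stop("`truth` contains label ids outside 0:", n_class - 1L, call. = FALSE)
  }
  onehot <- matrix(0, nrow(pmat), n_class)
  onehot[cbind(seq_len(nrow(pmat)), t_id)] <- 1

  dice_per_class <- vapply(seq_len(n_class), function(k) {
    denom <- sum(pmat[, k]) + sum(onehot[, k])
    if (denom == 0) 1 else 2 * sum(pmat[, k] * onehot[, k]) / denom
  }, numeric(1))
  dice_loss <- 1 - mean(dice_per_class)

  eps <- 1e-12
  ce <- -mean(log(pmax(pmat[cbind(seq_len(nrow(pmat)), t_id)], eps)))
  dice_loss + ce
}

# ---- trainer contract ------------------------------------------------------

#' Trainer contract generics
#'
#' Any model can be plugged into [train()] by implementing three S3 methods:
#' `fit_step(trainer, batch)` consumes a list of training `volume_patch`es
#' and returns `list(trainer = <updated>, loss = <training loss>)`;
#' `validate_loss(trainer, val_set)` returns a scalar validation loss and
#' must be deterministic given the model state and data;
#' `predict_labels(trainer, image)` maps a 3D image array to an integer label
#' array of the same shape.
#'
#' @param trainer A trainer object.
#' @param batch List of `volume_patch` training patches.
#' @param val_set List of `volume_patch` validation volumes.
#' @param image 3D image array.
#' @name trainer_contract
NULL

#' @rdname trainer_contract
#' @export
fit_step <- function(trainer, batch) UseMethod("fit_step")

#' @rdname trainer_contract
#' @export
validate_loss <- function(trainer, val_set) UseMethod("validate_loss")

#' @rdname trainer_contract
#' @export
predict_labels <- function(trainer, image) UseMethod("predict_labels")

# ---- the training loop -----------------------------------------------------

#' Train a segmenter with bucket-based augmentation policy search
#'
#' Runs the training loop of the policy search: in `"bucketaugment"` mode
#' every training patch in every epoch is augmented by the controller's
#' current bucket before the model sees it; every `K` epochs the model is
#' validated and the controller observes the loss (reward, Q update, possible
#' bucket switch). `"trivialaugment"` mode draws one random transform per
#' patch and runs no controller; `"none"` passes patches through. Validation
#' data are never augmented.
#'
#' @param dataset Non-empty list of training `volume_patch`es.
#' @param val_set Non-empty list of validation `volume_patch`es.
#' @param trainer An object implementing the trainer contract
#'   (see [fit_step()]).
#' @param config A [train_config()].
#' @param space Optional pre-built [init_search_space()] (e.g. with range
#'   overrides); by default one is drawn from the run seed.
#' @return A list of class `bucket_train_result`: `trainer` (final state),
#'   `controller` (final `bucket_controller`), `log` (tibble with one row per
#'   validation: `epoch`, `val_loss`, `reward`, `bucket`), `space`, `config`.
#' @export
train <- function(dataset, val_set, trainer, config, space = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset) == 0L) stop("`dataset` must be non-empty", call. = FALSE)
  if (length(val_set) == 0L) stop("`val_set` must be non-empty", call. = FALSE)
  for (p in dataset) check_patch(p)
  for (p in val_set) check_patch(p)

  mode <- config$augmentation_mode
  if (is.null(space) && mode == "bucketaugment") {
    space <- init_search_space(config$n_buckets, config$n_ops,
                               seed = config$seed)
  }
  n_buckets <- if (mode == "bucketaugment") space$n_buckets else config$n_buckets

  withr::with_seed(config$seed, {
    controller <- init_controller(n_buckets)
    log <- tibble::tibble(epoch = integer(), val_loss = double(),
                          reward = integer(), bucket = integer())
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(seq_along(dataset))
      for (start in seq(1L, length(idx), by = config$batch_size)) {
        take <- idx[start:min(start + config$batch_size - 1L, length(idx))]
        batch <- lapply(dataset[take], function(p) {
          switch(mode,
            bucketaugment = apply_bucket(p, space$buckets[[controller$current]]),
            trivialaugment = sample_trivial(p),
            none = p
          )
        })
        res <- fit_step(trainer, batch)
        trainer <- res$trainer
      }
      if (epoch %% config$val_every_k_epochs == 0L) {
        loss <- validate_loss(trainer, val_set)
        if (mode == "bucketaugment") {
          bucket_used <- controller$current
          obs <- observe_validation(controller, loss)
          controller <- obs$state
          log <- dplyr::bind_rows(log, tibble::tibble(
            epoch = epoch, val_loss = loss, reward = obs$reward,
            bucket = bucket_used))
        } else {
          log <- dplyr::bind_rows(log, tibble::tibble(
            epoch = epoch, val_loss = loss, reward = NA_integer_,
            bucket = NA_integer_))
        }
      }
    }
    structure(
      list(trainer = trainer, controller = controller, log = log,
           space = space, config = config),
      class = "bucket_train_result"
    )
  })
}

#' @export
print.bucket_train_result <- function(x, ...) {
  cat("<bucket_train_result> ", x$config$epochs, " epochs, mode '",
      x$config$augmentation_mode, "', ", nrow(x$log), " validations\n",
      sep = "")
  if (x$config$augmentation_mode == "bucketaugment") {
    cat("  best bucket:", best_bucket(x$controller),
        " (q =", max(x$controller$q), ")\n")
  }
  invisible(x)
}

#' Per-class mean Dice of a trained model on a test set
#'
#' For every foreground class present in the ground truth, computes the Dice
#' coefficient between the model's predicted mask and the truth on each
#' volume, then averages over volumes.
#'
#' @param trainer A trained object implementing the trainer contract.
#' @param test_set Non-empty list of `volume_patch`es.
#' @return A tibble with columns `class` and `dice`.
#' @export
evaluate_dice <- function(trainer, test_set) {
  if (length(test_set) == 0L) stop("`test_set` must be non-empty", call. = FALSE)
  for (p in test_set) check_patch(p)
  classes <- sort(setdiff(unique(unlist(lapply(test_set,
                                               function(p) unique(as.integer(p$label))))), 0L))
  if (length(classes) == 0L) {
    stop("test set contains no foreground classes", call. = FALSE)
  }
  rows <- purrr::map_dfr(classes, function(cl) {
    d <- vapply(test_set, function(p) {
      pred <- predict_labels(trainer, p$image)
      dice_score(pred == cl, p$label == cl)
    }, numeric(1))
    tibble::tibble(class = cl, dice = mean(d))
  })
  rows
}

#' Plot a training log
#'
#' @param log The `log` tibble from [train()].
#' @return A ggplot of validation loss over epochs, coloured by the bucket
#'   that was active in the preceding interval (if any).
#' @export
plot_training_log <- function(log) {
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch, y = .data$val_loss))
  if (!all(is.na(log$bucket))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$bucket)),
                                 size = 2) +
      ggplot2::labs(colour = "bucket")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "epoch", y = "validation loss") +
    ggplot2::theme_minimal()
}
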