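# A minimal built-in learner so the whole pipeline runs and is testable
# without any deep-learning stack: a voxelwise multinomial-logistic segmenter
# on four features (bias, intensity, and Gaussian-smoothed intensity at two
# scales), trained by full-batch gradient descent on the cross-entropy.
# It is a deterministic test fixture with just enough capacity to separate
# intensity-coded phantom organs — explicitly not a production architecture;
# real experiments plug any model into the trainer contract.

toy_features <- function(image) {
  cbind(1,
        as.vector(image),
        as.vector(gauss_smooth3(image, 1)),
        as.vector(gauss_smooth3(image, 2)))
}

toy_probs <- function(trainer, image) {
  f <- toy_features(image)
  scores <- f %*% trainer$weights
  scores <- scores - apply(scores, 1, max)
  e <- exp(scores)
  e / rowSums(e)
}

#' Built-in voxelwise softmax segmenter (test fixture)
#'
#' A tiny deterministic learner implementing the trainer contract: per-voxel
#' multinomial logistic regression on intensity and two smoothed-intensity
#' channels, fitted by gradient descent on the cross-entropy. Sufficient to
#' learn intensity-coded synthetic phantoms in a handful of epochs; not a
#' substitute architecture for real segmentation networks.
#'
#' @param n_classes Number of label classes including background.
#' @param lr Gradient-descent learning rate (default 30, stable for the
#'   per-voxel-mean gradients used here).
#' @return An object of class `toy_trainer`.
#' @examples
#' tr <- toy_trainer(n_classes = 3)
#' @export
toy_trainer <- function(n_classes, lr = 30) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) {
    stop("`n_classes` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(weights = matrix(0, 4, n_classes), n_classes = n_classes, lr = lr,
         steps = 0L),
    class = "toy_trainer"
  )
}

#' @export
fit_step.toy_trainer <- function(trainer, batch) {
  grad <- matrix(0, 4, trainer$n_classes)
  loss <- 0
  n_vox <- 0
  for (p in batch) {
    f <- toy_features(p$image)
    probs <- toy_probs(trainer, p$image)
    t_id <- as.integer(p$label) + 1L
    if (any(t_id > trainer$n_classes)) {
      stop("batch contains label ids beyond the trainer's class count",
           call. = FALSE)
    }
    onehot <- matrix(0, nrow(f), trainer$n_classes)
    onehot[cbind(seq_len(nrow(f)), t_id)] <- 1
    grad <- grad + t(f) %*% (probs - onehot) / nrow(f)
    loss <- loss + dice_ce_loss(array(probs, dim = c(dim(p$image),
                                                     trainer$n_classes)),
                                p$label)
    n_vox <- n_vox + nrow(f)
  }
  trainer$weights <- trainer$weights - trainer$lr * grad / length(batch)
  trainer$steps <- trainer$steps + 1L
  list(trainer = trainer, loss = loss / length(batch))
}

#' @export
validate_loss.toy_trainer <- function(trainer, val_set) {
  losses <- vapply(val_set, function(p) {
    probs <- toy_probs(trainer, p$image)
    dice_ce_loss(array(probs, dim = c(dim(p$image), trainer$n_classes)),
                 p$label)
  }, numeric(1))
  mean(losses)
}

#' @export
predict_labels.toy_trainer <- function(trainer, image) {
  probs <- toy_probs(trainer, image)
  array(max.col(probs, ties.method = "first") - 1L, dim = dim(image))
}
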