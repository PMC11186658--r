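# NIfTI input/output, label remapping, flat run configuration files, and the
# functions behind the command-line interface. Volumes are used in index
# space (0-based voxel semantics at the file boundary, 1-based inside R);
# spacing is carried per axis in mm, with no world-coordinate resampling.

#' Read / write a volume (and optional label) as NIfTI
#'
#' `read_volume()` loads a 3D NIfTI image, takes the voxel spacing from the
#' header, and min-max normalizes the intensities to \[0, 1\] unless they
#' already lie there. `write_volume()` writes the image (and the label, if a
#' label path is given) with the patch's spacing in the header; a write/read
#' round-trip preserves data and spacing within float tolerance.
#'
#' @param path Path to the image NIfTI file (.nii or .nii.gz).
#' @param label_path Optional path to an aligned integer label NIfTI.
#' @param normalize Min-max rescale intensities that fall outside \[0, 1\]
#'   (default TRUE).
#' @param patch A [volume_patch()].
#' @return `read_volume()` returns a `volume_patch`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, label_path = NULL, normalize = TRUE) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  img <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(img)) != 3L) {
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(nii)[1:3]
  if (normalize && (min(img) < 0 || max(img) > 1)) {
    img <- normalize_volume(img)
  }
  label <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) {
      stop("label file not found: ", label_path, call. = FALSE)
    }
    lab_nii <- RNifti::readNifti(label_path)
    label <- array(as.integer(round(as.numeric(lab_nii))), dim = dim(lab_nii))
    if (!identical(dim(label), dim(img))) {
      stop("image and label shapes differ: ",
           paste(dim(img), collapse = "x"), " vs ",
           paste(dim(label), collapse = "x"), call. = FALSE)
    }
  }
  volume_patch(img, label, spacing)
}

#' @rdname read_volume
#' @export
write_volume <- function(patch, path, label_path = NULL) {
  check_patch(patch)
  img <- RNifti::asNifti(patch$image)
  RNifti::pixdim(img) <- patch$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(label_path)) {
    lab <- RNifti::asNifti(patch$label)
    RNifti::pixdim(lab) <- patch$spacing
    RNifti::writeNifti(lab, label_path, datatype = "int16")
  }
  invisible(path)
}

#' Remap label ids
#'
#' Rewrites label ids through an explicit old-to-new mapping; any id not in
#' the mapping becomes background (0). The canonical use is merging paired
#' organs — e.g. right and left kidney ids into one kidney class.
#'
#' @param label 3D integer label array.
#' @param mapping Named integer vector or list, names = old ids,
#'   values = new ids (e.g. `c("2" = 1, "3" = 1)`).
#' @return Remapped integer label array of the same shape.
#' @examples
#' lab <- array(c(0L, 2L, 3L, 2L), dim = c(2, 2, 1))
#' remap_labels(lab, c("2" = 1, "3" = 1))
#' @export
remap_labels <- function(label, mapping) {
  if (!is.array(label)) stop("`label` must be an array", call. = FALSE)
  out <- array(0L, dim = dim(label))
  old <- as.integer(names(mapping))
  new <- as.integer(unlist(mapping))
  if (length(old) > 0 && (anyNA(old) || anyNA(new))) {
    stop("`mapping` must have integer-coercible names and values",
         call. = FALSE)
  }
  for (i in seq_along(old)) {
    out[label == old[i]] <- new[i]
  }
  out
}

# ---- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(
    # training / search
    n_buckets = 10L, n_ops = 5L, val_every_k_epochs = 2L, epochs = 6L,
    patch_size = c(16L, 16L, 16L), batch_size = 2L, seed = 1L,
    augmentation_mode = "bucketaugment",
    # synthetic demo data
    shape = c(32L, 32L, 32L), n_source = 8L, n_target = 4L,
    noise_sigma = 0.05, intensity_offset = 0, contrast_gamma = 1,
    spacing = c(1, 1, 1),
    target_intensity_offset = -0.15, target_noise_sigma_delta = 0.1,
    # transform-range overrides, e.g. range_zooming = c(1, 1.5)
    output_dir = "run"
  )
}

#' Read / write a flat run configuration file
#'
#' The run configuration is a flat key-value YAML document covering training
#' parameters, search-space size, the synthetic demo generator, and optional
#' per-transform range overrides (`range_<name>: [min, max]`). Unknown keys
#' are errors, which catches typos in overrides. Values round-trip through
#' `write_run_config()` unchanged.
#'
#' @param path File path.
#' @param config Named list of configuration values (missing keys take
#'   defaults).
#' @return `read_run_config()` returns the complete configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  complete_run_config(raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

complete_run_config <- function(raw) {
  defaults <- run_config_defaults()
  range_keys <- paste0("range_", setdiff(transform_names(), "identity"))
  unknown <- setdiff(names(raw), c(names(defaults), range_keys))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  for (k in intersect(names(cfg), range_keys)) {
    rng <- as.numeric(cfg[[k]])
    if (length(rng) != 2L || rng[1] > rng[2]) {
      stop("range override '", k, "' must be [min, max] with min <= max",
           call. = FALSE)
    }
  }
  cfg
}

# Range-override list (name -> c(min, max)) extracted from a run config.
config_ranges <- function(cfg) {
  keys <- grep("^range_", names(cfg), value = TRUE)
  if (length(keys) == 0) return(NULL)
  out <- lapply(cfg[keys], as.numeric)
  names(out) <- sub("^range_", "", keys)
  out
}

# ---- CLI command backends --------------------------------------------------

#' Generate a synthetic demo dataset on disk
#'
#' Writes `n_source` source-domain and `n_target` target-domain phantoms
#' (image + label NIfTI pairs) under `out_dir/source` and `out_dir/target`,
#' plus a copy of the configuration.
#'
#' @param config A run configuration list (see [read_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a tibble listing the written files.
#' @export
run_demo_synthetic <- function(config = list(), out_dir = NULL) {
  cfg <- complete_run_config(config)
  out_dir <- out_dir %||% cfg$output_dir
  pair <- demo_domain_pair(cfg)
  rows <- list()
  for (domain in c("source", "target")) {
    dir.create(file.path(out_dir, domain), recursive = TRUE,
               showWarnings = FALSE)
    vols <- pair[[domain]]
    for (i in seq_along(vols)) {
      ipath <- file.path(out_dir, domain, sprintf("phantom_%02d.nii.gz", i))
      lpath <- file.path(out_dir, domain, sprintf("phantom_%02d_label.nii.gz", i))
      write_volume(vols[[i]], ipath, lpath)
      rows[[length(rows) + 1L]] <- tibble::tibble(domain = domain,
                                                  image = ipath, label = lpath)
    }
  }
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(dplyr::bind_rows(rows))
}

demo_domain_pair <- function(cfg) {
  src <- phantom_config(shape = cfg$shape, noise_sigma = cfg$noise_sigma,
                        intensity_offset = cfg$intensity_offset,
                        contrast_gamma = cfg$contrast_gamma,
                        spacing = cfg$spacing, seed = cfg$seed)
  make_domain_pair(
    src,
    list(intensity_offset = cfg$target_intensity_offset,
         noise_sigma = cfg$target_noise_sigma_delta),
    n_source = cfg$n_source, n_target = cfg$n_target, seed = cfg$seed
  )
}

#' Run the full demo training pipeline
#'
#' Generates the synthetic source/target pair in memory, patches the source
#' volumes, trains the built-in fixture learner under the configured
#' augmentation mode, and writes the run artifacts into `out_dir`: the
#' configuration copy (`config.yaml`), the training log (`log.csv`), the
#' Q-table with history (`qtable.json`), the discovered best bucket
#' (`best_bucket.json`), and the full search space (`search_space.json`).
#' With the same configuration (and seed) the run is bit-reproducible.
#'
#' @param config A run configuration list.
#' @param out_dir Output directory (created if missing).
#' @param data_dir Optional dataset directory holding `source/` and `target/`
#'   subdirectories of NIfTI image/label pairs (the layout written by
#'   [run_demo_synthetic()]); when `NULL`, phantoms are generated in memory
#'   from the configuration.
#' @return The `bucket_train_result`, invisibly, with the target-domain Dice
#'   table attached as attribute `"target_dice"`.
#' @export
run_training <- function(config = list(), out_dir = NULL, data_dir = NULL) {
  cfg <- complete_run_config(config)
  out_dir <- out_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pair <- if (is.null(data_dir)) {
    demo_domain_pair(cfg)
  } else {
    list(source = read_volume_dir(file.path(data_dir, "source")),
         target = read_volume_dir(file.path(data_dir, "target")))
  }
  n_val <- max(1L, length(pair$source) %/% 4L)
  val_set <- unlist(lapply(pair$source[seq_len(n_val)], patchify,
                           patch_size = cfg$patch_size), recursive = FALSE)
  train_vols <- pair$source[(n_val + 1L):length(pair$source)]
  train_set <- unlist(lapply(train_vols, patchify,
                             patch_size = cfg$patch_size), recursive = FALSE)
  test_set <- unlist(lapply(pair$target, patchify,
                            patch_size = cfg$patch_size), recursive = FALSE)

  tc <- train_config(
    n_buckets = cfg$n_buckets, n_ops = cfg$n_ops,
    val_every_k_epochs = cfg$val_every_k_epochs, epochs = cfg$epochs,
    patch_size = cfg$patch_size, batch_size = cfg$batch_size,
    seed = cfg$seed, augmentation_mode = cfg$augmentation_mode
  )
  ranges <- config_ranges(cfg)
  space <- if (tc$augmentation_mode == "bucketaugment") {
    init_search_space(tc$n_buckets, tc$n_ops, seed = tc$seed,
                      ranges = transform_ranges(ranges))
  } else {
    NULL
  }

  n_classes <- 1L + max(unlist(lapply(train_set,
                                      function(p) max(p$label))))
  result <- train(train_set, val_set, toy_trainer(n_classes), tc,
                  space = space)
  dice <- evaluate_dice(result$trainer, test_set)

  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  utils::write.csv(as.data.frame(result$log),
                   file.path(out_dir, "log.csv"), row.names = FALSE)
  write_controller(result$controller, file.path(out_dir, "qtable.json"))
  if (!is.null(space)) {
    write_search_space(space, file.path(out_dir, "search_space.json"))
    write_bucket(space$buckets[[best_bucket(result$controller)]],
                 file.path(out_dir, "best_bucket.json"))
  }
  utils::write.csv(as.data.frame(dice),
                   file.path(out_dir, "target_dice.csv"), row.names = FALSE)
  attr(result, "target_dice") <- dice
  invisible(result)
}

#' Apply a saved bucket to a volume on disk
#'
#' @param bucket_path Path to a bucket JSON written by [write_bucket()].
#' @param image_path Input NIfTI volume.
#' @param out_path Output NIfTI path.
#' @param label_path,out_label_path Optional aligned label input/output.
#' @param seed Seed for the per-application randomness.
#' @return `out_path`, invisibly.
#' @export
run_apply_bucket <- function(bucket_path, image_path, out_path,
                             label_path = NULL, out_label_path = NULL,
                             seed = 1) {
  bucket <- read_bucket(bucket_path)
  patch <- read_volume(image_path, label_path)
  out <- apply_bucket(patch, bucket, seed = seed)
  write_volume(out, out_path, out_label_path)
  invisible(out_path)
}

#' Inspect the Q-table of a finished run
#'
#' @param run_dir A run directory written by [run_training()].
#' @return A tibble of buckets ranked by Q score (`rank`, `bucket`, `q`),
#'   printed to the console.
#' @export
inspect_qtable <- function(run_dir) {
  path <- file.path(run_dir, "qtable.json")
  if (!file.exists(path)) {
    stop("no Q-table found in '", run_dir,
         "'; run training first (expected ", path, ")", call. = FALSE)
  }
  state <- read_controller(path)
  ranked <- tibble::tibble(bucket = seq_along(state$q), q = state$q) |>
    dplyr::arrange(dplyr::desc(.data$q), .data$bucket) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  print(ranked, n = nrow(ranked))
  invisible(ranked)
}

# All image NIfTIs in a directory, paired with their *_label companions.
read_volume_dir <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir, call. = FALSE)
  imgs <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  imgs <- imgs[!grepl("_label\\.nii", imgs)]
  if (length(imgs) == 0) stop("no NIfTI volumes found in ", dir, call. = FALSE)
  lapply(imgs, function(ip) {
    lp <- sub("\\.nii(\\.gz)?$", "_label.nii\\1", ip)
    read_volume(ip, if (file.exists(lp)) lp else NULL)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
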