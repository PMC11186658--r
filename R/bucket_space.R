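# The search space: N_b buckets, each an ordered stack of N_op transforms
# with magnitudes frozen at initialization. Per-application randomness (axes,
# signs, noise draws, displacement fields) stays live; the policy itself never
# changes after init. A TrivialAugment-style one-transform sampler is the
# comparison baseline.

new_bucket <- function(index, specs) {
  structure(list(index = as.integer(index), specs = specs), class = "bucket")
}

#' @export
print.bucket <- function(x, ...) {
  cat("<bucket ", x$index, "> ", length(x$specs), " transforms:\n", sep = "")
  for (s in x$specs) {
    cat(sprintf("  %-20s bin %2d  magnitude %s\n", s$name, s$bin_index,
                format(s$magnitude, digits = 4)))
  }
  invisible(x)
}

#' Initialize a random bucket search space
#'
#' Draws `n_buckets` buckets, each holding `n_ops` transforms sampled
#' uniformly with replacement from the ten-transform bank, each with a
#' uniformly drawn magnitude bin in 1..15. Magnitudes are frozen here and
#' never resampled during training. The same seed always yields the same
#' space.
#'
#' @param n_buckets Number of buckets `N_b` (>= 1; 10 in typical use).
#' @param n_ops Transforms per bucket `N_op` (>= 1; 5 in typical use).
#' @param seed Integer seed.
#' @param ranges Optional range table from [transform_ranges()].
#' @return An object of class `search_space`.
#' @examples
#' sp <- init_search_space(10, 5, seed = 1)
#' sp$buckets[[1]]
#' @export
init_search_space <- function(n_buckets, n_ops, seed, ranges = NULL) {
  n_buckets <- as.integer(n_buckets)
  n_ops <- as.integer(n_ops)
  if (is.na(n_buckets) || n_buckets < 1L) {
    stop("`n_buckets` must be a positive integer", call. = FALSE)
  }
  if (is.na(n_ops) || n_ops < 1L) {
    stop("`n_ops` must be a positive integer", call. = FALSE)
  }
  nm <- transform_names()
  buckets <- withr::with_seed(seed, {
    lapply(seq_len(n_buckets), function(b) {
      specs <- lapply(seq_len(n_ops), function(i) {
        transform_spec(sample(nm, 1L), sample.int(N_MAGNITUDE_BINS, 1L),
                       ranges = ranges)
      })
      new_bucket(b, specs)
    })
  })
  structure(
    list(buckets = buckets, n_buckets = n_buckets, n_ops = n_ops, seed = seed),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> ", x$n_buckets, " buckets x ", x$n_ops,
      " transforms (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Apply a bucket of transforms to a patch
#'
#' The bucket's transforms are applied sequentially in stored order, each with
#' probability 1, so the result is exactly the left-to-right composition of
#' its [apply_transform()] calls.
#'
#' @param patch A [volume_patch()].
#' @param bucket A bucket from [init_search_space()].
#' @param seed Optional seed for the per-application randomness.
#' @return A new `volume_patch`.
#' @export
apply_bucket <- function(patch, bucket, seed = NULL) {
  check_patch(patch)
  if (!inherits(bucket, "bucket")) {
    stop("expected a `bucket` object", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, apply_bucket(patch, bucket, seed = NULL)))
  }
  for (spec in bucket$specs) {
    patch <- apply_transform(patch, spec)
  }
  patch
}

#' TrivialAugment-style baseline sampler
#'
#' Applies exactly one transform, with the name and the magnitude bin each
#' drawn uniformly at random — the strong parameter-free baseline that
#' bucket search is compared against.
#'
#' @inheritParams apply_bucket
#' @return A new `volume_patch`; the drawn [transform_spec()] is attached as
#'   attribute `"spec"`.
#' @export
sample_trivial <- function(patch, seed = NULL) {
  check_patch(patch)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_trivial(patch, seed = NULL)))
  }
  spec <- transform_spec(sample(transform_names(), 1L),
                         sample.int(N_MAGNITUDE_BINS, 1L))
  out <- apply_transform(patch, spec)
  attr(out, "spec") <- spec
  out
}

# ---- serialization ---------------------------------------------------------

spec_to_list <- function(s) {
  list(name = s$name, bin_index = s$bin_index, magnitude = s$magnitude)
}

spec_from_list <- function(l) {
  row <- transform_row(l$name)
  structure(
    list(name = l$name, bin_index = as.integer(l$bin_index),
         magnitude = as.numeric(l$magnitude), kind = row$kind,
         range = c(row$min, row$max)),
    class = "transform_spec"
  )
}

bucket_to_list <- function(b) {
  list(index = b$index, specs = lapply(b$specs, spec_to_list))
}

bucket_from_list <- function(l) {
  new_bucket(l$index, lapply(l$specs, spec_from_list))
}

#' Write / read a bucket as JSON
#'
#' A discovered policy (one bucket: transform names, bins and frozen
#' magnitudes) serializes to a small JSON document so it can be reused
#' outside the training run that found it.
#'
#' @param bucket A bucket.
#' @param path File path.
#' @return `write_bucket()` returns `path` invisibly; `read_bucket()` returns
#'   a bucket.
#' @export
write_bucket <- function(bucket, path) {
  jsonlite::write_json(bucket_to_list(bucket), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_bucket
#' @export
read_bucket <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  b <- bucket_from_list(l)
  for (s in b$specs) check_spec(s)
  b
}

#' Write / read a whole search space as JSON
#'
#' @param space A `search_space`.
#' @param path File path.
#' @return `write_search_space()` returns `path` invisibly;
#'   `read_search_space()` returns a `search_space`.
#' @export
write_search_space <- function(space, path) {
  doc <- list(n_buckets = space$n_buckets, n_ops = space$n_ops,
              seed = space$seed,
              buckets = lapply(space$buckets, bucket_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_search_space
#' @export
read_search_space <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  buckets <- lapply(doc$buckets, bucket_from_list)
  for (b in buckets) for (s in b$specs) check_spec(s)
  structure(
    list(buckets = buckets, n_buckets = as.integer(doc$n_buckets),
         n_ops = as.integer(doc$n_ops), seed = as.integer(doc$seed)),
    class = "search_space"
  )
}
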