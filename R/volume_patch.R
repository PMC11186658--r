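#' Construct a volume patch
#'
#' A `volume_patch` bundles a 3D image grid of normalized intensities in
#' \[0, 1\], an aligned integer label grid of the same shape (class ids,
#' with 0 the background), and the voxel spacing in millimetres per axis.
#' It is the unit of data every transform, the training harness, and the
#' phantom generator operate on.
#'
#' @param image 3D numeric array with values in \[0, 1\].
#' @param label 3D integer array of the same shape; defaults to all
#'   background (zeros).
#' @param spacing Numeric vector of 3 positive voxel extents in mm.
#' @return An object of class `volume_patch`: a list with elements
#'   `image`, `label` and `spacing`.
#' @examples
#' p <- volume_patch(array(runif(8^3), dim = c(8, 8, 8)))
#' dim(p$image)
#' @export
volume_patch <- function(image, label = NULL, spacing = c(1, 1, 1)) {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("`image` must be a 3D array", call. = FALSE)
  }
  storage.mode(image) <- "double"
  if (is.null(label)) {
    label <- array(0L, dim = dim(image))
  }
  if (!is.array(label) || length(dim(label)) != 3L) {
    stop("`label` must be a 3D array", call. = FALSE)
  }
  storage.mode(label) <- "integer"
  if (!identical(dim(image), dim(label))) {
    stop("`image` and `label` must have identical shape (",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(label), collapse = "x"), ")", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite reals (mm per axis)", call. = FALSE)
  }
  if (anyNA(image) || any(!is.finite(image))) {
    stop("`image` contains non-finite values", call. = FALSE)
  }
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("`image` values must lie in [0, 1]; normalize first ",
         "(see normalize_volume())", call. = FALSE)
  }
  structure(
    list(image = clip01(image), label = label, spacing = spacing),
    class = "volume_patch"
  )
}

#' @export
print.volume_patch <- function(x, ...) {
  cls <- sort(unique(as.integer(x$label)))
  cat("<volume_patch> ", paste(dim(x$image), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n  intensity range [", format(min(x$image), digits = 4), ", ",
      format(max(x$image), digits = 4), "], label classes {",
      paste(cls, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_patch <- function(x) dim(x$image)

is_volume_patch <- function(x) inherits(x, "volume_patch")

check_patch <- function(patch) {
  if (!is_volume_patch(patch)) {
    stop("expected a `volume_patch` object", call. = FALSE)
  }
  invisible(patch)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
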