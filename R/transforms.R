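# The ten-transform augmentation bank. Each transform has a predefined
# magnitude range discretized into 15 uniform bins; spatial transforms warp
# image and label through one shared geometric map, intensity transforms touch
# the image only. Every transform applies with probability 1 when invoked.

.transform_table <- data.frame(
  name = c("identity", "translation", "elastic_deformation", "zooming",
           "rotation", "intensity", "contrast", "sharpening", "smoothing",
           "gaussian_noise"),
  min  = c(NA,   0,  50, 1, 0,    0.1, 1, 10, 0.1, 0.1),
  max  = c(NA,  10, 150, 2, 0.52, 1,   5, 30, 2,   0.3),
  kind = c("intensity_only", "spatial", "spatial", "spatial", "spatial",
           "intensity_only", "intensity_only", "intensity_only",
           "intensity_only", "intensity_only"),
  stringsAsFactors = FALSE
)

N_MAGNITUDE_BINS <- 15L

#' Names of the supported augmentation transforms
#'
#' The bank contains four spatial transforms (translation, rotation, zooming,
#' elastic deformation), five intensity transforms (intensity scaling, gamma
#' contrast, unsharp-mask sharpening, Gaussian smoothing, additive Gaussian
#' noise) and the identity, included as a genuine operation because every
#' transform in a bucket is applied with probability 1.
#'
#' @return Character vector of the ten transform names.
#' @export
transform_names <- function() .transform_table$name

#' Magnitude ranges of the transform bank
#'
#' @param overrides Optional named list of `c(min, max)` pairs replacing the
#'   default range for individual transforms (the identity has no range).
#' @return A tibble with columns `name`, `min`, `max`, `kind`.
#' @export
transform_ranges <- function(overrides = NULL) {
  tab <- .transform_table
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("unknown transform in range override: '", nm, "'",
                         call. = FALSE)
      if (nm == "identity") stop("identity has no magnitude range", call. = FALSE)
      rng <- as.numeric(overrides[[nm]])
      if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] > rng[2]) {
        stop("range override for '", nm, "' must be c(min, max) with min <= max",
             call. = FALSE)
      }
      tab$min[i] <- rng[1]
      tab$max[i] <- rng[2]
    }
  }
  tibble::as_tibble(tab)
}

transform_row <- function(name, ranges = NULL) {
  tab <- if (is.null(ranges)) .transform_table else as.data.frame(ranges)
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown transform '", name, "'; supported transforms are: ",
         paste(.transform_table$name, collapse = ", "), call. = FALSE)
  }
  tab[i, ]
}

#' Magnitude bin grid for a transform
#'
#' Each transform's range is divided into 15 evenly spaced magnitudes with the
#' first bin at the range minimum and the last at the maximum (step
#' `(max - min) / 14`). The identity carries no magnitude and returns 15 zeros.
#'
#' @param name A transform name (see [transform_names()]).
#' @param ranges Optional range table from [transform_ranges()] with overrides.
#' @return Numeric vector of 15 magnitudes.
#' @examples
#' magnitude_bins("zooming")   # 1.0 ... 2.0
#' magnitude_bins("rotation")  # 0 ... 0.52 rad
#' @export
magnitude_bins <- function(name, ranges = NULL) {
  row <- transform_row(name, ranges)
  if (name == "identity") return(rep(0, N_MAGNITUDE_BINS))
  seq(row$min, row$max, length.out = N_MAGNITUDE_BINS)
}

#' Construct a transform specification
#'
#' A `transform_spec` is one concrete augmentation operation: a transform name
#' plus a discrete magnitude bin (1..15) and the magnitude that bin resolves
#' to. Buckets are ordered lists of these specs with magnitudes frozen at
#' search-space initialization.
#'
#' @param name Transform name.
#' @param bin_index Integer bin in `1:15`.
#' @param ranges Optional range table from [transform_ranges()].
#' @return An object of class `transform_spec` with fields `name`,
#'   `bin_index`, `magnitude`, `kind`.
#' @export
transform_spec <- function(name, bin_index, ranges = NULL) {
  row <- transform_row(name, ranges)
  bin_index <- as.integer(bin_index)
  if (length(bin_index) != 1L || is.na(bin_index) ||
      bin_index < 1L || bin_index > N_MAGNITUDE_BINS) {
    stop("`bin_index` must be a single integer in 1..", N_MAGNITUDE_BINS,
         call. = FALSE)
  }
  structure(
    list(name = row$name, bin_index = bin_index,
         magnitude = magnitude_bins(row$name, ranges)[bin_index],
         kind = row$kind, range = c(row$min, row$max)),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec> %s (bin %d/%d, magnitude %s, %s)\n",
              x$name, x$bin_index, N_MAGNITUDE_BINS,
              format(x$magnitude, digits = 4), x$kind))
  invisible(x)
}

check_spec <- function(spec) {
  if (!inherits(spec, "transform_spec")) {
    stop("expected a `transform_spec` object", call. = FALSE)
  }
  row <- transform_row(spec$name)
  rng <- if (!is.null(spec$range) && all(is.finite(spec$range))) {
    spec$range
  } else {
    c(row$min, row$max)
  }
  if (spec$name != "identity") {
    # guards corrupted buckets read back from disk or hand-edited JSON
    if (!is.finite(spec$magnitude) ||
        spec$magnitude < rng[1] - 1e-9 || spec$magnitude > rng[2] + 1e-9) {
      stop("magnitude ", format(spec$magnitude), " for '", spec$name,
           "' is outside its predefined range [", rng[1], ", ", rng[2], "]",
           call. = FALSE)
    }
  }
  invisible(spec)
}

#' Apply one augmentation transform to a volume patch
#'
#' Spatial transforms (translation, rotation, zooming, elastic deformation)
#' warp image and label through the same geometric map — the image with
#' trilinear interpolation, the label with nearest neighbour, so output label
#' values are always a subset of the input's. Intensity transforms modify the
#' image only and leave the label bit-identical. The output image is clipped
#' to \[0, 1\] and the input patch is never mutated.
#'
#' Per-application randomness (translation/rotation axis and sign, noise and
#' displacement-field draws) comes from R's random stream; pass `seed` for a
#' reproducible draw that does not disturb the global stream.
#'
#' Neutral magnitudes (zoom 1, rotation 0, translation 0, elastic amplitude 0)
#' reproduce the input bit-exactly.
#'
#' @param patch A [volume_patch()].
#' @param spec A [transform_spec()].
#' @param seed Optional integer seed for the per-application draws.
#' @return A new `volume_patch`.
#' @export
apply_transform <- function(patch, spec, seed = NULL) {
  check_patch(patch)
  check_spec(spec)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, apply_transform(patch, spec, seed = NULL)))
  }
  m <- spec$magnitude
  switch(spec$name,
    identity = patch,
    translation = tf_translation(patch, m),
    rotation = tf_rotation(patch, m),
    zooming = tf_zooming(patch, m),
    elastic_deformation = tf_elastic(patch, m),
    intensity = tf_intensity(patch, m),
    contrast = tf_contrast(patch, m),
    sharpening = tf_sharpening(patch, m),
    smoothing = tf_smoothing(patch, m),
    gaussian_noise = tf_gaussian_noise(patch, m)
  )
}

# ---- spatial transforms ----------------------------------------------------

# Shift by `m` voxels along a random axis with random sign. The content moves
# in the +/- axis direction; out-of-field voxels fill with 0 / background.
tf_translation <- function(patch, m) {
  axis <- sample.int(3L, 1L)
  sgn <- sample(c(-1, 1), 1L)
  if (m == 0) return(patch)
  offset <- c(0, 0, 0)
  offset[axis] <- sgn * m
  g <- coord_grid(dim(patch$image))
  warp_patch(patch, g$x - offset[1], g$y - offset[2], g$z - offset[3])
}

# Rotate by `m` radians (random sign) about a random principal axis through
# the volume centre.
tf_rotation <- function(patch, m) {
  axis <- sample.int(3L, 1L)
  sgn <- sample(c(-1, 1), 1L)
  if (m == 0) return(patch)
  theta <- sgn * m
  d <- dim(patch$image)
  ctr <- (d + 1) / 2
  g <- coord_grid(d)
  u <- list(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
  plane <- setdiff(1:3, axis)
  a <- u[[plane[1]]]; b <- u[[plane[2]]]
  # inverse map: rotate output coordinates by -theta to find the source
  u[[plane[1]]] <- cos(theta) * a + sin(theta) * b
  u[[plane[2]]] <- -sin(theta) * a + cos(theta) * b
  warp_patch(patch, u[[1]] + ctr[1], u[[2]] + ctr[2], u[[3]] + ctr[3])
}

# Isotropic magnification about the centre by factor m >= 1; the field of view
# implicitly centre-crops back to the original shape.
tf_zooming <- function(patch, m) {
  if (m == 1) return(patch)
  d <- dim(patch$image)
  ctr <- (d + 1) / 2
  g <- coord_grid(d)
  warp_patch(patch,
             ctr[1] + (g$x - ctr[1]) / m,
             ctr[2] + (g$y - ctr[2]) / m,
             ctr[3] + (g$z - ctr[3]) / m)
}

# Random smooth displacement field. The magnitude m is the amplitude knob:
# uniform noise per voxel and axis is smoothed with a fixed Gaussian
# (sigma = 8 voxels), rescaled to unit peak, and scaled to 0.02 * m voxels of
# peak displacement. m = 0 is the identity.
tf_elastic <- function(patch, m, field_sigma = 8, amp_per_unit = 0.02) {
  if (m == 0) return(patch)
  d <- dim(patch$image)
  disp <- lapply(1:3, function(k) {
    u <- gauss_smooth3(array(stats::runif(prod(d), -1, 1), dim = d), field_sigma)
    peak <- max(abs(u))
    if (peak > 0) u <- u / peak
    u * amp_per_unit * m
  })
  g <- coord_grid(d)
  warp_patch(patch,
             g$x - as.vector(disp[[1]]),
             g$y - as.vector(disp[[2]]),
             g$z - as.vector(disp[[3]]))
}

# ---- intensity transforms --------------------------------------------------

with_image <- function(patch, img) {
  volume_patch(clip01(img), patch$label, patch$spacing)
}

# Multiplicative intensity scaling (m in [0.1, 1]: 1 is neutral, smaller darkens).
tf_intensity <- function(patch, m) {
  if (m == 1) return(patch)
  with_image(patch, patch$image * m)
}

# Gamma contrast adjustment on [0, 1]; m = 1 is neutral, larger m deepens shadows.
tf_contrast <- function(patch, m) {
  if (m == 1) return(patch)
  with_image(patch, patch$image^m)
}

# Unsharp masking: img + amount * (img - blur(img, sigma = 1)), amount = m / 10.
tf_sharpening <- function(patch, m) {
  blur <- gauss_smooth3(patch$image, 1)
  with_image(patch, patch$image + (m / 10) * (patch$image - blur))
}

# Gaussian blur with sigma = m voxels; convex weights, so the value range
# never expands.
tf_smoothing <- function(patch, m) {
  with_image(patch, gauss_smooth3(patch$image, m))
}

# Additive zero-mean Gaussian noise with sd = m, then clip.
tf_gaussian_noise <- function(patch, m) {
  d <- dim(patch$image)
  with_image(patch, patch$image + array(stats::rnorm(prod(d), 0, m), dim = d))
}
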