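# Synthetic abdominal-CT-like phantoms: an intensity-coded background, one or
# more large ellipsoids (liver-like, class 1) and paired small ellipsoids
# (kidney-like, class 2). Domain shift between phantom "datasets" is purely
# appearance and spacing — intensity offset, gamma, noise level, voxel size —
# while the label-generating geometry process is shared, i.e. covariate shift
# as produced by different scanners and protocols, not anatomical shift.

#' Phantom generator configuration
#'
#' @param shape Volume shape, 3 positive integers (default 32^3).
#' @param n_large_organs Number of large (liver-like) ellipsoids, class 1.
#' @param n_small_organs Number of small (kidney-like) ellipsoids, class 2;
#'   the default 2 mimics a kidney pair.
#' @param intensity_offset Additive intensity shift applied to the image
#'   (simulates calibration differences).
#' @param contrast_gamma Gamma applied to the image (> 0; 1 is neutral).
#' @param noise_sigma Additive Gaussian noise sd (>= 0; default 0.05).
#' @param spacing Voxel spacing in mm.
#' @param jitter Relative jitter of organ centres and semi-axes (default
#'   0.05), drawn per phantom.
#' @param seed Integer seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32, 32, 32), n_large_organs = 1,
                           n_small_organs = 2, intensity_offset = 0,
                           contrast_gamma = 1, noise_sigma = 0.05,
                           spacing = c(1, 1, 1), jitter = 0.05, seed = 1) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(is.na(shape)) || any(shape < 8L)) {
    stop("`shape` must be 3 integers >= 8", call. = FALSE)
  }
  vals <- c(intensity_offset, contrast_gamma, noise_sigma, spacing, jitter)
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (contrast_gamma <= 0) stop("`contrast_gamma` must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(
    list(shape = shape, n_large_organs = as.integer(n_large_organs),
         n_small_organs = as.integer(n_small_organs),
         intensity_offset = intensity_offset,
         contrast_gamma = contrast_gamma, noise_sigma = noise_sigma,
         spacing = as.numeric(rep_len(spacing, 3L)), jitter = jitter,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Base organ layout as fractions of the volume shape: class-1 ellipsoid in
# the lower half, a symmetric pair (plus extras) of class-2 ellipsoids above.
phantom_layout <- function(config) {
  s <- config$shape
  large <- lapply(seq_len(config$n_large_organs), function(i) {
    list(center = s * c(0.36, 0.42, 0.42 + 0.16 * (i - 1)),
         semi = s * c(0.22, 0.20, 0.18), class = 1L)
  })
  small_pos <- list(c(0.80, 0.25, 0.60), c(0.80, 0.75, 0.60),
                    c(0.25, 0.80, 0.75), c(0.78, 0.50, 0.22))
  small <- lapply(seq_len(config$n_small_organs), function(i) {
    pos <- small_pos[[((i - 1L) %% length(small_pos)) + 1L]]
    list(center = s * pos, semi = s * c(0.085, 0.075, 0.095), class = 2L)
  })
  c(large, small)
}

ellipsoid_mask <- function(shape, center, semi) {
  g <- coord_grid(shape)
  inside <- ((g$x - center[1]) / semi[1])^2 +
            ((g$y - center[2]) / semi[2])^2 +
            ((g$z - center[3]) / semi[3])^2 <= 1
  array(inside, dim = shape)
}

#' Generate one synthetic phantom volume
#'
#' Produces a `volume_patch` with a piecewise-constant base image (background
#' 0.2, class-1 organs 0.6, class-2 organs 0.85), organ geometry jittered per
#' phantom, then transformed by the configured intensity offset, gamma and
#' additive Gaussian noise, and clipped to \[0, 1\]. The label grid is
#' noise-free and unaffected by all appearance parameters. Deterministic
#' under the config seed.
#'
#' @param config A [phantom_config()].
#' @return A `volume_patch`; the drawn ellipsoid geometry is attached as
#'   attribute `"geometry"` (a list of `center`/`semi`/`class` entries).
#' @examples
#' p <- make_phantom(phantom_config(seed = 7))
#' table(p$label)
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, {
    s <- config$shape
    organs <- phantom_layout(config)
    organs <- lapply(organs, function(o) {
      o$center <- o$center * (1 + stats::runif(3, -config$jitter, config$jitter))
      o$semi <- o$semi * (1 + stats::runif(3, -config$jitter, config$jitter))
      o
    })
    for (o in organs) {
      if (any(o$center - o$semi < 1) || any(o$center + o$semi > s)) {
        stop("organ does not fit inside the volume; enlarge `shape` or ",
             "reduce `jitter`", call. = FALSE)
      }
    }
    label <- array(0L, dim = s)
    for (o in organs) {
      m <- ellipsoid_mask(s, o$center, o$semi)
      if (any(label[m] != 0L & label[m] != o$class)) {
        stop("organ ellipsoids overlap across classes; adjust the layout",
             call. = FALSE)
      }
      label[m] <- o$class
    }
    if (!all(c(1L, 2L) %in% label) &&
        (config$n_large_organs > 0 && config$n_small_organs > 0)) {
      stop("a foreground class came out empty; enlarge `shape`", call. = FALSE)
    }
    img <- array(0.2, dim = s)
    img[label == 1L] <- 0.6
    img[label == 2L] <- 0.85
    img <- clip01(img + config$intensity_offset)
    img <- img^config$contrast_gamma
    if (config$noise_sigma > 0) {
      img <- img + array(stats::rnorm(prod(s), 0, config$noise_sigma), dim = s)
    }
    out <- volume_patch(clip01(img), label, config$spacing)
    attr(out, "geometry") <- organs
    out
  })
}

#' Generate paired source/target phantom datasets with domain shift
#'
#' Draws `n_source` phantoms from the source configuration and `n_target`
#' phantoms from the shifted configuration. The geometry (label) process is
#' identical across domains; only image appearance and spacing shift.
#'
#' @param source_config A [phantom_config()].
#' @param target_shift Named list of deltas added to the source parameters:
#'   any of `intensity_offset`, `contrast_gamma`, `noise_sigma`, `spacing`.
#' @param n_source,n_target Positive phantom counts.
#' @param seed Integer seed for the per-volume seeds of both domains.
#' @return A list with elements `source` and `target`, each a list of
#'   `volume_patch`es.
#' @examples
#' pair <- make_domain_pair(phantom_config(), list(noise_sigma = 0.1), 4, 2, 1)
#' length(pair$target)
#' @export
make_domain_pair <- function(source_config, target_shift = list(),
                             n_source, n_target, seed) {
  stopifnot(inherits(source_config, "phantom_config"))
  n_source <- as.integer(n_source)
  n_target <- as.integer(n_target)
  if (is.na(n_source) || n_source < 1L || is.na(n_target) || n_target < 1L) {
    stop("`n_source` and `n_target` must be positive integers", call. = FALSE)
  }
  allowed <- c("intensity_offset", "contrast_gamma", "noise_sigma", "spacing")
  bad <- setdiff(names(target_shift), allowed)
  if (length(bad) > 0) {
    stop("unknown target_shift parameters: ", paste(bad, collapse = ", "),
         "; domain shift is restricted to appearance and spacing",
         call. = FALSE)
  }
  args <- unclass(source_config)
  for (nm in names(target_shift)) {
    args[[nm]] <- args[[nm]] + target_shift[[nm]]
  }
  target_config <- do.call(phantom_config, args)  # re-validates shifted values
  seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, n_source + n_target)
  })
  gen <- function(base, seed_i) {
    cfg <- base
    cfg$seed <- seed_i
    make_phantom(cfg)
  }
  list(
    source = lapply(seeds[seq_len(n_source)], gen, base = source_config),
    target = lapply(seeds[n_source + seq_len(n_target)], gen,
                    base = target_config)
  )
}
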