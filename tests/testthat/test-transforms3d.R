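# The ten-transform bank: bin grids, neutral elements, label handling,
# determinism, and the per-transform geometry/intensity semantics.

test_that("magnitude bins span each predefined range in 15 uniform steps", {
  for (nm in setdiff(transform_names(), "identity")) {
    bins <- magnitude_bins(nm)
    rng <- transform_ranges() |> dplyr::filter(name == nm)
    expect_length(bins, 15)
    expect_equal(bins[1], rng$min)
    expect_equal(bins[15], rng$max)
    expect_equal(diff(bins), rep((rng$max - rng$min) / 14, 14))
  }
  expect_identical(magnitude_bins("identity"), rep(0, 15))
  # midpoint of an endpoints-inclusive uniform grid: min + 7 * (max - min) / 14
  expect_equal(magnitude_bins("translation")[8], 5.0)
  expect_equal(magnitude_bins("zooming")[c(1, 15)], c(1, 2))
  expect_error(magnitude_bins("warp5000"), "unknown transform")
})

test_that("range overrides reshape the bin grid and reject bad input", {
  r <- transform_ranges(list(zooming = c(1, 1.5)))
  expect_equal(magnitude_bins("zooming", r)[15], 1.5)
  expect_error(transform_ranges(list(zooming = c(2, 1))), "min <= max")
  expect_error(transform_ranges(list(identity = c(0, 1))), "no magnitude range")
  expect_error(transform_ranges(list(zoom = c(1, 2))), "unknown transform")
})

test_that("neutral magnitudes reproduce the input bit-exactly", {
  for (seed in 1:20) {
    p <- tiny_phantom(seed)
    neutral <- list(
      transform_spec("identity", 1),
      transform_spec("zooming", 1),       # factor 1
      transform_spec("rotation", 1),      # 0 rad
      transform_spec("translation", 1)    # 0 voxels
    )
    for (sp in neutral) {
      out <- apply_transform(p, sp, seed = seed)
      expect_identical(out$image, p$image)
      expect_identical(out$label, p$label)
    }
  }
})

test_that("elastic deformation with zero amplitude is the identity", {
  p <- tiny_phantom(4)
  sp <- transform_spec("elastic_deformation",
                       ranges = transform_ranges(list(
                         elastic_deformation = c(0, 150))), bin_index = 1)
  expect_patch_equal(apply_transform(p, sp, seed = 1), p)
})

test_that("spatial transforms warp label with the image and never invent classes", {
  max_bin <- 15
  for (seed in 1:20) {
    p <- tiny_phantom(seed)
    for (nm in c("translation", "rotation", "zooming", "elastic_deformation")) {
      out <- apply_transform(p, transform_spec(nm, max_bin), seed = seed)
      expect_true(all(unique(as.vector(out$label)) %in%
                        unique(as.vector(p$label))),
                  label = paste(nm, "label subset"))
      expect_true(min(out$image) >= 0 && max(out$image) <= 1)
    }
  }
})

test_that("intensity transforms leave the label bit-identical", {
  for (seed in 1:20) {
    p <- tiny_phantom(seed)
    for (nm in c("intensity", "contrast", "sharpening", "smoothing",
                 "gaussian_noise")) {
      out <- apply_transform(p, transform_spec(nm, 15), seed = seed)
      expect_identical(out$label, p$label, label = paste(nm, "label"))
    }
  }
})

test_that("translation moves an impulse by the drawn integer offset", {
  p <- impulse_patch(12, at = c(6, 6, 6))
  # pin the range so every bin resolves to exactly 3 voxels
  sp <- transform_spec("translation", 5,
                       ranges = transform_ranges(list(translation = c(3, 3))))
  seed <- 42
  # replicate the per-application draw (axis, then sign) to know the offset
  draw <- withr::with_seed(seed, list(axis = sample.int(3, 1),
                                      sgn = sample(c(-1, 1), 1)))
  out <- apply_transform(p, sp, seed = seed)
  want <- c(6, 6, 6)
  want[draw$axis] <- want[draw$axis] + draw$sgn * 3
  expect_equal(out$image[want[1], want[2], want[3]], 1)
  expect_equal(sum(out$image), 1)
  expect_equal(out$label[want[1], want[2], want[3]], 1L)
})

test_that("gaussian smoothing never expands the image value range", {
  for (seed in 1:5) {
    p <- random_patch(10, seed = seed)
    out <- apply_transform(p, transform_spec("smoothing", 15), seed = seed)
    expect_gte(min(out$image), min(p$image))
    expect_lte(max(out$image), max(p$image))
  }
})

test_that("intensity operators implement their stated arithmetic", {
  p <- random_patch(8, seed = 3)
  half <- transform_spec("intensity",
                         ranges = transform_ranges(list(intensity = c(0.5, 0.5))),
                         bin_index = 1)
  expect_equal(apply_transform(p, half)$image, p$image * 0.5)
  gamma2 <- transform_spec("contrast",
                           ranges = transform_ranges(list(contrast = c(2, 2))),
                           bin_index = 1)
  expect_equal(apply_transform(p, gamma2)$image, p$image^2)
})

test_that("same patch, spec and seed give bit-identical output", {
  p <- tiny_phantom(9)
  for (nm in transform_names()) {
    sp <- transform_spec(nm, 10)
    expect_identical(apply_transform(p, sp, seed = 7),
                     apply_transform(p, sp, seed = 7),
                     label = paste(nm, "determinism"))
  }
})

test_that("transforms never mutate the input patch", {
  p <- tiny_phantom(2)
  snapshot <- list(image = p$image, label = p$label)
  for (nm in transform_names()) {
    invisible(apply_transform(p, transform_spec(nm, 15), seed = 1))
  }
  expect_identical(p$image, snapshot$image)
  expect_identical(p$label, snapshot$label)
})

test_that("out-of-range magnitudes are rejected (corrupted-bucket guard)", {
  p <- tiny_phantom(1)
  bad <- transform_spec("zooming", 15)
  bad$magnitude <- 5   # outside [1, 2]
  expect_error(apply_transform(p, bad), "outside its predefined range")
  expect_error(transform_spec("zooming", 0), "bin_index")
  expect_error(transform_spec("zooming", 16), "bin_index")
})
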