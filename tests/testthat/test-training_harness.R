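# Normalization, patching, metrics, the training loop with the controller in
# it, and Dice evaluation against the trainer contract.

test_that("normalization is an exact per-sample min-max rescale", {
  raw <- array(c(-1000, 0, 1000, rep(0, 5)), dim = c(2, 2, 2))
  out <- normalize_volume(raw)
  expect_equal(sort(unique(as.vector(out))), c(0, 0.5, 1))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)

  already <- array(seq(0, 1, length.out = 27), dim = c(3, 3, 3))
  expect_equal(normalize_volume(already), already)

  expect_error(normalize_volume(array(7, dim = c(2, 2, 2))), "constant")
})

test_that("patchify tiles the padded volume exactly once and inverts", {
  p <- tiny_phantom(1)                    # 24^3
  one <- patchify(p, c(24, 24, 24))
  expect_length(one, 1)
  expect_identical(one[[1]]$image, p$image)

  tiles <- patchify(p, c(16, 16, 16))     # padded to 32^3 -> 8 patches
  expect_length(tiles, 8)
  for (t in tiles) expect_identical(dim(t$image), c(16L, 16L, 16L))
  expect_patch_equal(unpatchify(tiles), p)

  # a 10^3 volume with 4^3 patches: ceil(10/4) = 3 per axis
  q <- random_patch(10, seed = 2)
  tiles <- patchify(q, 4)
  expect_length(tiles, 27)
  expect_patch_equal(unpatchify(tiles), q)
})

test_that("dice_score matches the closed form", {
  m <- function(v) array(v, dim = c(2, 2, 2))
  a <- m(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, m(c(0, 0, 0, 0, 1, 1, 1, 1))), 0)
  expect_equal(dice_score(a, m(c(1, 1, 0, 0, 1, 1, 0, 0))), 0.5)
  expect_equal(dice_score(m(rep(0, 8)), m(rep(0, 8))), 1)  # both empty
  expect_error(dice_score(a, array(0, dim = c(2, 2, 1))), "same shape")
})

test_that("dice_ce_loss has the closed-form CE and a zero perfect-fit limit", {
  lab <- array(c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L), dim = c(2, 2, 2))

  uniform <- array(0.5, dim = c(2, 2, 2, 2))
  # dice per class = 2 * 0.5 k / (4 + k... ) -> CE part must be exactly ln 2
  ce_part <- dice_ce_loss(uniform, lab) -
    (1 - mean(c(2 * 0.5 * 4 / (4 + 4), 2 * 0.5 * 4 / (4 + 4))))
  expect_equal(ce_part, log(2))

  onehot <- array(0, dim = c(2, 2, 2, 2))
  onehot[, , , 1][lab == 0L] <- 1
  onehot[, , , 2][lab == 1L] <- 1
  expect_equal(dice_ce_loss(onehot, lab), 0)

  # moving mass toward the true class reduces the loss
  lab2 <- array(c(0L, 1L), dim = c(2, 1, 1))
  soft <- function(p1) {
    pr <- array(0, dim = c(2, 1, 1, 2))
    pr[1, 1, 1, ] <- c(p1, 1 - p1)
    pr[2, 1, 1, ] <- c(1 - p1, p1)
    pr
  }
  expect_lt(dice_ce_loss(soft(0.9), lab2), dice_ce_loss(soft(0.6), lab2))

  bad <- uniform
  bad[1, 1, 1, ] <- c(0.9, 0.3)
  expect_error(dice_ce_loss(bad, lab), "sum to 1")
})

test_that("train runs one controller update per K epochs and is deterministic", {
  pair <- make_domain_pair(phantom_config(shape = c(16, 16, 16)),
                           list(), n_source = 4, n_target = 2, seed = 1)
  tr_set <- pair$source[1:3]
  val <- pair$source[4]
  cfg <- train_config(n_buckets = 4, n_ops = 2, val_every_k_epochs = 2,
                      epochs = 6, patch_size = 16, seed = 3)
  res <- train(tr_set, val, toy_trainer(3), cfg)
  expect_equal(nrow(res$log), 3)                       # floor(6 / 2)
  expect_equal(nrow(res$controller$history), 3)
  expect_identical(sum(res$controller$q), sum(res$controller$history$reward))

  res2 <- train(tr_set, val, toy_trainer(3), cfg)
  expect_equal(res$log, res2$log)
  expect_identical(res$controller$q, res2$controller$q)
  expect_equal(res$trainer$weights, res2$trainer$weights)
})

test_that("non-search modes leave the controller untouched", {
  pair <- make_domain_pair(phantom_config(shape = c(16, 16, 16)),
                           list(), n_source = 3, n_target = 1, seed = 2)
  cfg <- train_config(epochs = 4, val_every_k_epochs = 2, patch_size = 16,
                      seed = 1, augmentation_mode = "none")
  res <- train(pair$source[1:2], pair$source[3], toy_trainer(3), cfg)
  expect_equal(nrow(res$controller$history), 0)
  expect_equal(nrow(res$log), 2)
  expect_true(all(is.na(res$log$bucket)))

  cfg$augmentation_mode <- "trivialaugment"
  res <- train(pair$source[1:2], pair$source[3], toy_trainer(3), cfg)
  expect_equal(nrow(res$controller$history), 0)
  expect_equal(nrow(res$log), 2)
})

test_that("train finds the designated helpful bucket with a rigged learner", {
  # Bucket 2 is all-identity; buckets 1 and 3 darken the image to 10% —
  # an EMA learner tracking the clean validation mean improves only when the
  # training stream is un-darkened.
  dark <- transform_spec("intensity", 1)        # magnitude 0.1
  space <- init_search_space(3, 1, seed = 1)
  space$buckets[[1]]$specs <- list(dark)
  space$buckets[[2]]$specs <- list(transform_spec("identity", 1))
  space$buckets[[3]]$specs <- list(dark)

  pair <- make_domain_pair(phantom_config(shape = c(16, 16, 16)),
                           list(), n_source = 4, n_target = 1, seed = 5)
  cfg <- train_config(n_buckets = 3, n_ops = 1, val_every_k_epochs = 1,
                      epochs = 12, patch_size = 16, seed = 2)
  res <- train(pair$source[1:3], pair$source[4], ema_mean_trainer(),
               cfg, space = space)
  expect_identical(best_bucket(res$controller), 2L)
  # the conservation invariant holds after a real training run too
  expect_identical(sum(res$controller$q), sum(res$controller$history$reward))
})

test_that("evaluate_dice matches hand-computed values for scripted models", {
  pair <- make_domain_pair(phantom_config(shape = c(16, 16, 16)),
                           list(), n_source = 2, n_target = 2, seed = 9)
  test_set <- pair$target

  d <- evaluate_dice(lookup_oracle_trainer(test_set), test_set)
  expect_true(all(d$dice == 1))
  expect_setequal(d$class, c(1L, 2L))

  d <- evaluate_dice(background_trainer(), test_set)
  expect_true(all(d$dice == 0))

  expect_error(evaluate_dice(toy_trainer(3), list()), "non-empty")
})

test_that("validation and test sets are never augmented during training", {
  pair <- make_domain_pair(phantom_config(shape = c(16, 16, 16)),
                           list(), n_source = 3, n_target = 1, seed = 4)
  val <- pair$source[3]
  snapshot <- list(image = val[[1]]$image, label = val[[1]]$label)
  cfg <- train_config(n_buckets = 2, n_ops = 2, val_every_k_epochs = 1,
                      epochs = 3, patch_size = 16, seed = 8)
  invisible(train(pair$source[1:2], val, toy_trainer(3), cfg))
  expect_identical(val[[1]]$image, snapshot$image)
  expect_identical(val[[1]]$label, snapshot$label)
})
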