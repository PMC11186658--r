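# Shared fixtures: small phantoms and hand-built patches used across the
# module tests. Everything is generated in code; nothing is read from disk.

tiny_phantom <- function(seed = 1, ...) {
  make_phantom(phantom_config(shape = c(24, 24, 24), seed = seed, ...))
}

# A noiseless patch with an intensity impulse and a small labelled block,
# convenient for exact-geometry checks.
impulse_patch <- function(n = 12, at = c(6, 6, 6)) {
  img <- array(0, dim = rep(n, 3))
  img[at[1], at[2], at[3]] <- 1
  lab <- array(0L, dim = rep(n, 3))
  lab[at[1], at[2], at[3]] <- 1L
  volume_patch(img, lab)
}

random_patch <- function(n = 10, n_classes = 3, seed = 1) {
  withr::with_seed(seed, {
    volume_patch(array(runif(n^3), dim = rep(n, 3)),
                 array(sample.int(n_classes, n^3, replace = TRUE) - 1L,
                       dim = rep(n, 3)))
  })
}

# -- scripted trainers for contract-level tests ------------------------------

# Deterministic learner whose validation loss shrinks only while the training
# stream stays un-darkened: darkened batches (mean intensity < 0.1) inflate
# the loss, clean batches deflate it.
ema_mean_trainer <- function() {
  structure(list(loss_state = 1), class = "ema_mean_trainer")
}
fit_step.ema_mean_trainer <- function(trainer, batch) {
  dark <- mean(vapply(batch, function(p) mean(p$image), numeric(1))) < 0.1
  trainer$loss_state <- trainer$loss_state * (if (dark) 1.1 else 0.9)
  list(trainer = trainer, loss = trainer$loss_state)
}
validate_loss.ema_mean_trainer <- function(trainer, val_set) trainer$loss_state
predict_labels.ema_mean_trainer <- function(trainer, image) {
  array(0L, dim = dim(image))
}

# Oracle that looks the ground truth up by image identity.
lookup_oracle_trainer <- function(patches) {
  structure(list(patches = patches), class = "lookup_oracle_trainer")
}
fit_step.lookup_oracle_trainer <- function(trainer, batch) {
  list(trainer = trainer, loss = 0)
}
validate_loss.lookup_oracle_trainer <- function(trainer, val_set) 0
predict_labels.lookup_oracle_trainer <- function(trainer, image) {
  for (p in trainer$patches) {
    if (identical(p$image, image)) return(p$label)
  }
  stop("image not found in oracle lookup")
}

# Always predicts background.
background_trainer <- function() structure(list(), class = "background_trainer")
fit_step.background_trainer <- function(trainer, batch) {
  list(trainer = trainer, loss = 0)
}
validate_loss.background_trainer <- function(trainer, val_set) 0
predict_labels.background_trainer <- function(trainer, image) {
  array(0L, dim = dim(image))
}

for (cls in c("ema_mean_trainer", "lookup_oracle_trainer",
              "background_trainer")) {
  for (gen in c("fit_step", "validate_loss", "predict_labels")) {
    registerS3method(gen, cls, get(paste0(gen, ".", cls)),
                     envir = asNamespace("bucketaugment"))
  }
}

expect_patch_equal <- function(a, b) {
  expect_identical(a$image, b$image)
  expect_identical(a$label, b$label)
  expect_identical(a$spacing, b$spacing)
}
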