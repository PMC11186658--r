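# The tabular Q-learning controller. Each validation compares the new
# validation loss against the previous one and turns it into a three-valued
# reward: +1 if the loss fell, -1 if it rose, 0 if unchanged. The reward is
# added to the current bucket's Q score; a negative reward additionally
# advances the active bucket to the next one in cyclic order. The previous
# loss starts at the sentinel 1000, so the first validation always rewards
# the starting bucket. No learning rate, no discount: scores are plain
# reward sums, and the highest-scoring bucket at the end is the policy.

#' Initialize a controller state
#'
#' @param n_buckets Number of buckets the controller scores (>= 1).
#' @param seed Optional seed for the uniform draw of the starting bucket.
#' @param equal_loss How an exactly unchanged validation loss is scored:
#'   `"no_update"` (default) gives reward 0 and leaves the Q-table alone;
#'   `"increment"` treats it as an improvement (+1 reward).
#' @return An object of class `bucket_controller` with fields `q` (integer
#'   scores), `current` (active bucket, 1-based), `prev_loss` (sentinel 1000
#'   before the first validation), `history` (a tibble of validation records)
#'   and `n_buckets`.
#' @examples
#' ctrl <- init_controller(10, seed = 1)
#' ctrl$q
#' @export
init_controller <- function(n_buckets, seed = NULL,
                            equal_loss = c("no_update", "increment")) {
  n_buckets <- as.integer(n_buckets)
  if (is.na(n_buckets) || n_buckets < 1L) {
    stop("`n_buckets` must be a positive integer", call. = FALSE)
  }
  equal_loss <- match.arg(equal_loss)
  current <- if (is.null(seed)) {
    sample.int(n_buckets, 1L)
  } else {
    withr::with_seed(seed, sample.int(n_buckets, 1L))
  }
  structure(
    list(
      q = integer(n_buckets),
      current = current,
      prev_loss = 1000,
      history = tibble::tibble(step = integer(), loss = double(),
                               reward = integer(), bucket = integer()),
      n_buckets = n_buckets,
      equal_loss = equal_loss
    ),
    class = "bucket_controller"
  )
}

#' @export
print.bucket_controller <- function(x, ...) {
  cat("<bucket_controller> ", x$n_buckets, " buckets, ",
      nrow(x$history), " validations observed\n", sep = "")
  cat("  q:", paste(x$q, collapse = " "), "\n")
  cat("  current bucket:", x$current,
      " prev loss:", format(x$prev_loss, digits = 6), "\n")
  invisible(x)
}

#' Observe a validation loss and update the controller
#'
#' Computes the reward (+1 loss fell, -1 rose, 0 unchanged), adds it to the
#' active bucket's Q score, advances the active bucket cyclically when the
#' reward is negative (a positive or neutral reward keeps the current
#' bucket), records the step in the history, and replaces the stored previous
#' loss with `new_loss`.
#'
#' @param state A `bucket_controller`.
#' @param new_loss Finite non-negative validation loss.
#' @return A list with elements `state` (the updated controller) and
#'   `reward` (the integer reward just assigned).
#' @export
observe_validation <- function(state, new_loss) {
  stopifnot(inherits(state, "bucket_controller"))
  if (length(new_loss) != 1L || !is.numeric(new_loss) ||
      !is.finite(new_loss) || new_loss < 0) {
    stop("`new_loss` must be a single finite non-negative number",
         call. = FALSE)
  }
  reward <- if (new_loss > state$prev_loss) {
    -1L
  } else if (new_loss < state$prev_loss) {
    1L
  } else if (state$equal_loss == "increment") {
    1L
  } else {
    0L
  }
  bucket_used <- state$current
  state$q[bucket_used] <- state$q[bucket_used] + reward
  if (reward < 0L) {
    state$current <- if (state$current == state$n_buckets) 1L
                     else state$current + 1L
  }
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(step = nrow(state$history) + 1L, loss = new_loss,
                   reward = reward, bucket = bucket_used)
  )
  state$prev_loss <- new_loss
  list(state = state, reward = reward)
}

#' Best bucket under the current Q-table
#'
#' @param state A `bucket_controller`.
#' @return The 1-based index of the bucket with the highest Q score; ties are
#'   broken toward the lowest index.
#' @export
best_bucket <- function(state) {
  stopifnot(inherits(state, "bucket_controller"))
  which.max(state$q)
}

#' Simulate the controller against buckets of known quality
#'
#' A self-contained mock of the training loop used to study controller
#' convergence: each round, the validation loss improves with the active
#' bucket's improvement probability and worsens otherwise. The loss walk is
#' multiplicative (`loss * exp(+-step + noise)`), which keeps losses strictly
#' positive and strictly ordered for any number of rounds.
#'
#' @param effects Vector of per-bucket improvement probabilities in \[0, 1\].
#' @param n_rounds Number of simulated validations (>= 1).
#' @param seed Integer seed.
#' @param step Log-scale loss step per round.
#' @param noise_sd Standard deviation of the log-scale noise.
#' @return The final `bucket_controller`.
#' @examples
#' st <- run_mock_search(c(0.2, 0.9, 0.2), n_rounds = 100, seed = 1)
#' best_bucket(st)
#' @export
run_mock_search <- function(effects, n_rounds, seed, step = 0.05,
                            noise_sd = 0.01) {
  effects <- as.numeric(effects)
  if (length(effects) == 0L) {
    stop("`effects` must contain at least one bucket probability",
         call. = FALSE)
  }
  if (any(!is.finite(effects)) || any(effects < 0) || any(effects > 1)) {
    stop("`effects` must be probabilities in [0, 1]", call. = FALSE)
  }
  n_rounds <- as.integer(n_rounds)
  if (is.na(n_rounds) || n_rounds < 1L) {
    stop("`n_rounds` must be a positive integer", call. = FALSE)
  }
  withr::with_seed(seed, {
    state <- init_controller(length(effects))
    loss <- 1
    for (i in seq_len(n_rounds)) {
      improves <- stats::runif(1) < effects[state$current]
      delta <- if (improves) -step else step
      loss <- loss * exp(delta + stats::rnorm(1, 0, noise_sd))
      state <- observe_validation(state, loss)$state
    }
    state
  })
}

# ---- broom-style accessors and serialization -------------------------------

#' Tidy a controller's validation history
#'
#' @param x A `bucket_controller`.
#' @param ... Unused.
#' @return A tibble with one row per validation: `step`, `loss`, `reward`,
#'   `bucket`.
#' @export
tidy.bucket_controller <- function(x, ...) x$history

#' One-row summary of a controller
#'
#' @param x A `bucket_controller`.
#' @param ... Unused.
#' @return A one-row tibble: `n_buckets`, `n_validations`, `best_bucket`,
#'   `best_q`, `total_reward`.
#' @export
glance.bucket_controller <- function(x, ...) {
  tibble::tibble(
    n_buckets = x$n_buckets,
    n_validations = nrow(x$history),
    best_bucket = best_bucket(x),
    best_q = max(x$q),
    total_reward = sum(x$history$reward)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a controller's Q-table
#'
#' @param object A `bucket_controller`.
#' @param ... Unused.
#' @return A ggplot bar chart of Q scores per bucket, the discovered best
#'   bucket highlighted.
#' @export
autoplot.bucket_controller <- function(object, ...) {
  df <- tibble::tibble(
    bucket = factor(seq_along(object$q)),
    q = object$q,
    best = seq_along(object$q) == best_bucket(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bucket, y = .data$q,
                                   fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#2166ac")) +
    ggplot2::labs(x = "bucket", y = "Q score",
                  title = "Q-table after policy search") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Write / read a controller state as JSON
#'
#' @param state A `bucket_controller`.
#' @param path File path.
#' @return `write_controller()` returns `path` invisibly;
#'   `read_controller()` returns a `bucket_controller`.
#' @export
write_controller <- function(state, path) {
  doc <- list(
    q = state$q, current = state$current, prev_loss = state$prev_loss,
    n_buckets = state$n_buckets, equal_loss = state$equal_loss,
    history = as.data.frame(state$history)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_controller
#' @export
read_controller <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- doc$history
  structure(
    list(
      q = as.integer(doc$q),
      current = as.integer(doc$current),
      prev_loss = as.numeric(doc$prev_loss),
      history = tibble::tibble(step = as.integer(h$step),
                               loss = as.numeric(h$loss),
                               reward = as.integer(h$reward),
                               bucket = as.integer(h$bucket)),
      n_buckets = as.integer(doc$n_buckets),
      equal_loss = doc$equal_loss
    ),
    class = "bucket_controller"
  )
}
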