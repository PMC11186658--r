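# The Q-learning controller: reward semantics, cyclic bucket advancement,
# conservation of Q mass, replay determinism, and mock-search convergence.

replay <- function(state, losses) {
  rewards <- integer(0)
  for (l in losses) {
    obs <- observe_validation(state, l)
    state <- obs$state
    rewards <- c(rewards, obs$reward)
  }
  list(state = state, rewards = rewards)
}

test_that("a fresh controller starts zeroed with the loss sentinel at 1000", {
  st <- init_controller(10, seed = 1)
  expect_identical(st$q, integer(10))
  expect_equal(st$prev_loss, 1000)
  expect_equal(nrow(st$history), 0)
  expect_true(st$current >= 1 && st$current <= 10)
  expect_equal(init_controller(1, seed = 5)$current, 1L)
  expect_error(init_controller(0), "positive")
})

test_that("the hand trace of four losses reproduces the exact Q-table", {
  st <- init_controller(3, seed = 1)
  st$current <- 1L   # fresh state starting at the first bucket
  out <- replay(st, c(0.9, 0.8, 0.85, 0.7))
  expect_identical(out$rewards, c(1L, 1L, -1L, 1L))
  expect_identical(out$state$q, c(1L, 1L, 0L))
  expect_identical(out$state$current, 2L)
  # tie between buckets 1 and 2 breaks to the lowest index
  expect_identical(best_bucket(out$state), 1L)
})

test_that("reward is the sign of the loss decrease and first loss always rewards", {
  st <- init_controller(4, seed = 2)
  expect_equal(observe_validation(st, 999.9)$reward, 1L)

  st2 <- replay(init_controller(4, seed = 2), c(0.5))$state
  same <- observe_validation(st2, 0.5)
  expect_equal(same$reward, 0L)
  expect_identical(same$state$q, st2$q)
  expect_identical(same$state$current, st2$current)

  # pseudocode-style reading: equality counts as an improvement
  st3 <- replay(init_controller(4, seed = 2, equal_loss = "increment"),
                c(0.5))$state
  expect_equal(observe_validation(st3, 0.5)$reward, 1L)

  expect_error(observe_validation(st, -0.1), "non-negative")
  expect_error(observe_validation(st, NaN), "finite")
  expect_error(observe_validation(st, Inf), "finite")
})

test_that("Q mass is conserved and switches happen iff the reward is -1", {
  withr::with_seed(42, {
    for (rep in 1:1000) {
      n <- sample(1:6, 1)
      st <- init_controller(n)
      losses <- round(runif(sample(3:12, 1), 0, 2), 2)
      prev_current <- st$current
      for (l in losses) {
        obs <- observe_validation(st, l)
        switched <- obs$state$current != prev_current
        if (n == 1) {
          expect_false(switched)
        } else {
          expect_identical(switched, obs$reward == -1L)
        }
        st <- obs$state
        prev_current <- st$current
        expect_identical(sum(st$q), sum(st$history$reward))
      }
    }
  })
})

test_that("bucket advancement is cyclic with wraparound", {
  st <- init_controller(3, seed = 1)
  st$current <- 3L
  st <- replay(st, c(0.5))$state        # +1, stays at 3
  st <- observe_validation(st, 0.9)$state   # -1 at bucket 3 -> wraps to 1
  expect_identical(st$current, 1L)
})

test_that("replaying a recorded loss sequence reproduces the state exactly", {
  losses <- withr::with_seed(7, runif(30, 0, 1))
  a <- replay(init_controller(5, seed = 9), losses)$state
  b <- replay(init_controller(5, seed = 9), losses)$state
  expect_identical(a, b)
})

test_that("mock search identifies the known-best bucket", {
  st <- run_mock_search(c(0.0, 1.0), n_rounds = 50, seed = 1)
  expect_identical(best_bucket(st), 2L)

  single <- run_mock_search(c(0.5), n_rounds = 30, seed = 2)
  expect_true(all(single$history$bucket == 1L))

  expect_error(run_mock_search(numeric(0), 10, 1), "at least one")
  expect_error(run_mock_search(c(0.5, 1.2), 10, 1), "probabilities")
})

test_that("controller state round-trips through JSON", {
  st <- run_mock_search(c(0.2, 0.8, 0.4), n_rounds = 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_controller(st, path)
  st2 <- read_controller(path)
  expect_identical(st2$q, st$q)
  expect_identical(st2$current, st$current)
  expect_equal(st2$prev_loss, st$prev_loss)
  expect_equal(as.data.frame(st2$history), as.data.frame(st$history))
})

test_that("tidy and glance summarize the controller", {
  st <- run_mock_search(c(0.1, 0.9), n_rounds = 25, seed = 4)
  h <- tidy(st)
  expect_s3_class(h, "tbl_df")
  expect_equal(nrow(h), 25)
  expect_named(h, c("step", "loss", "reward", "bucket"))
  g <- glance(st)
  expect_equal(g$n_validations, 25L)
  expect_equal(g$best_bucket, best_bucket(st))
  expect_equal(g$total_reward, sum(h$reward))
})
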