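test_that("mean MT length follows the serial-section estimator", {
  expect_equal(mt_mean_length(10, 5, 20), 5)
  expect_equal(mt_mean_length(1, 1, 2), 1)
  # closed-form oracle on random valid inputs, including vectorised calls
  set.seed(6)
  N <- runif(25, 0, 60); a <- runif(25, 0.5, 10); T <- sample(1:40, 25, TRUE)
  expect_equal(mt_mean_length(N, a, T), 2 * N * a / T)
  # linear in N and a, inversely proportional to T, positive
  L <- mt_mean_length(N, a, T)
  expect_equal(mt_mean_length(2 * N, a, T), 2 * L)
  expect_equal(mt_mean_length(N, 3 * a, T), 3 * L)
  expect_equal(mt_mean_length(N, a, 2 * T), L / 2)
  expect_true(all(mt_mean_length(N + 0.1, a, T) > 0))
})

test_that("invalid reconstructions are rejected", {
  expect_error(mt_mean_length(10, 5, 0), "endpoints")
  expect_error(mt_mean_length(-1, 5, 2), "non-negative")
  expect_error(mt_mean_length(1, 0, 2), "positive")
})

test_that("the table helper appends an L column", {
  df <- data.frame(N = c(47, 26, 35), a = c(7.3, 8, 7.85), T = c(40, 30, 28))
  out <- mt_length_table(df)
  expect_equal(out$L, 2 * df$N * df$a / df$T)
  expect_error(mt_length_table(data.frame(N = 1)), "missing required")
})
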