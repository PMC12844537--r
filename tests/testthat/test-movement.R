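test_that("bias strength decays exponentially and is bounded by beta", {
  d <- seq(0, 200, by = 0.5)
  s <- s_bias(d, beta = 0.5, k = 0.02)
  expect_true(all(diff(s) < 0))        # strictly decreasing in distance
  expect_true(all(s <= 0.5))
  expect_equal(s_bias(0, beta = 0.5, k = 0.02), 0.5)   # beta at contact
  expect_equal(s_bias(10, beta = 0.3, k = 0.1), 0.3 * exp(-1))
})

test_that("biased probabilities match direct substitution for a 3-4-5 target", {
  # target south-east, |dx| = 3, |dy| = 4, D = 5; frozen from the closed form
  # s = 0.5 exp(-0.005 * 5), toward-axis 0.25 + s*comp/7, away 0.25 - s/2
  p <- biased_move_probs(3, 4, beta = 0.5, k = 0.005)
  expect_equal(unname(p["E"]), 0.458994981149, tolerance = 1e-9)
  expect_equal(unname(p["S"]), 0.528659974865, tolerance = 1e-9)
  expect_equal(unname(p["W"]), 0.006172521993, tolerance = 1e-6)
  expect_equal(unname(p["N"]), 0.006172521993, tolerance = 1e-6)
  expect_equal(sum(p), 1)
})

test_that("axis-aligned target at full bias drains the away directions", {
  # due east, k -> 0 so s = beta = 0.5: the favoured row direction keeps its
  # unbiased 0.25 (zero bias weight), both away directions hit zero
  p <- biased_move_probs(10, 0, beta = 0.5, k = 1e-12)
  expect_equal(unname(p["E"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(p["S"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(p["W"]), 0)
  expect_equal(unname(p["N"]), 0)
})

test_that("zero bias reduces to the unbiased walk and zero displacement errors", {
  expect_equal(unname(biased_move_probs(2, -7, beta = 0)), rep(0.25, 4))
  expect_error(biased_move_probs(0, 0), "engaged")
})

test_that("probabilities are a distribution for all displacements and beta", {
  set.seed(11)
  for (i in 1:200) {
    dx <- sample(-30:30, 1); dy <- sample(-30:30, 1)
    if (dx == 0 && dy == 0) dx <- 1
    beta <- sample(c(0, 0.2, 0.5, 0.6, 0.75), 1)
    p <- biased_move_probs(dx, dy, beta = beta, k = 0.02)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    if (beta <= 0.5) {
      # no clamping needed below the validity boundary
      expect_true(all(p >= 0.25 - beta / 2 - 1e-12))
    }
  }
})

test_that("compiled and R bias rules agree", {
  set.seed(7)
  for (i in 1:100) {
    dx <- sample(-50:50, 1); dy <- sample(-50:50, 1)
    if (dx == 0 && dy == 0) dy <- -3
    beta <- runif(1, 0, 0.75); k <- runif(1, 0.001, 0.2)
    expect_equal(bias_probs_cpp(dx, dy, beta, k),
                 biased_move_probs(dx, dy, beta, k),
                 tolerance = 1e-12)
  }
})

test_that("unbiased steps are uniform over the Von Neumann neighbourhood", {
  set.seed(1)
  n <- 8000
  moves <- t(replicate(n, unbiased_step(c(10L, 10L))))
  d <- cbind(moves[, 1] - 10L, moves[, 2] - 10L)
  expect_true(all(abs(d[, 1]) + abs(d[, 2]) == 1))  # exactly one axis, one unit
  freq <- table(paste(d[, 1], d[, 2])) / n
  expect_equal(unname(as.vector(freq)), rep(0.25, 4), tolerance = 0.08)
})

test_that("four-step return probability matches exhaustive enumeration", {
  # oracle: enumerate all 4^4 direction sequences
  dirs <- expand.grid(d1 = 1:4, d2 = 1:4, d3 = 1:4, d4 = 1:4)
  step_x <- c(1, -1, 0, 0); step_y <- c(0, 0, -1, 1)
  back <- apply(dirs, 1, function(d) {
    sum(step_x[d]) == 0 && sum(step_y[d]) == 0
  })
  p_oracle <- mean(back)
  expect_equal(p_oracle, 36 / 256)
  set.seed(2)
  n <- 20000
  returned <- replicate(n, {
    pos <- c(0L, 0L)
    for (i in 1:4) pos <- unbiased_step(pos)
    all(pos == c(0L, 0L))
  })
  expect_lt(abs(mean(returned) - p_oracle), 0.01)   # ~4 Monte-Carlo SEs
})

test_that("nearest eligible myelin uses Euclidean distance with the tie rule", {
  cfg <- small_config()
  S <- cfg$n_myelin_states
  state <- matrix(1L, nrow = cfg$lattice_height, ncol = cfg$parenchyma_width)
  # single eligible site forming a 3-4-5 triangle from the query point
  state[6, 13] <- 3L
  res <- nearest_eligible_myelin(c(10 + 8, 10), state, cfg)
  expect_equal(res$distance, 5)
  expect_equal(unname(res$target), c(13 + 8, 6))
  expect_equal(res$s_bias, s_bias(5, cfg$beta, cfg$k))
  # two equidistant sites: lowest row wins
  state2 <- matrix(1L, nrow = 40, ncol = 20)
  state2[14, 10] <- 5L
  state2[6, 10] <- 5L
  res2 <- nearest_eligible_myelin(c(10 + 8, 10), state2, cfg)
  expect_equal(unname(res2$target), c(10 + 8, 6))
  # fully demyelinated field: nothing to seek
  expect_null(nearest_eligible_myelin(c(12, 5),
                                      matrix(1L, nrow = 40, ncol = 20), cfg))
})

test_that("compiled nearest-site search agrees with a brute-force oracle", {
  set.seed(33)
  for (i in 1:40) {
    state <- matrix(sample(1:5, 30 * 12, replace = TRUE, prob = c(0.85, rep(0.0375, 4))),
                    nrow = 30, ncol = 12)
    px <- sample(-7:14, 1); row <- sample(1:30, 1)
    got <- nearest_eligible_cpp(state, px, row)
    want <- nearest_oracle(state, px, row)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$col, want$col)
      expect_equal(got$row, want$row)
      expect_equal(got$distance, sqrt(want$d2))
    }
  }
})
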