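test_that("Kalman filter converges on a constant stream without spike flags", {
  st <- chain_init()
  out <- numeric(20)
  for (i in 1:20) {
    r <- kalman_despike_step(st, 5)
    st <- r$state
    out[i] <- r$despiked
    expect_false(r$was_spike)
  }
  expect_lt(abs(out[10] - 5), 1e-6)
})

test_that("a 10-SD outlier is flagged and its deviation shrunk", {
  set.seed(1)
  vals <- rnorm(50, 10, 0.5)
  vals[40] <- 10 + 10 * 0.5 * 10   # gross spike
  st <- chain_init()
  flagged <- FALSE
  for (i in seq_along(vals)) {
    r <- kalman_despike_step(st, vals[i])
    st <- r$state
    if (i == 40) {
      flagged <- r$was_spike
      expect_lt(abs(r$despiked - 10), abs(vals[40] - 10))
    }
  }
  expect_true(flagged)
})

test_that("zero observation variance gives a pass-through filter", {
  st <- chain_init(chain_settings(obs_var = 0))
  set.seed(2)
  for (v in rnorm(30)) {
    r <- kalman_despike_step(st, v)
    st <- r$state
    expect_identical(r$despiked, v)
    expect_false(r$was_spike)
  }
  expect_error(kalman_despike_step(st, NaN), "non-finite")
})

test_that("expanding-window detrending removes a pure linear ramp", {
  st <- chain_init()
  res <- NA
  for (i in 1:60) {
    r <- cumulative_detrend_step(st, 2 + 0.3 * i, i)
    st <- r$state
    res <- r$detrended
  }
  expect_lt(abs(res), 1e-6)
  # constant stream: zero residual from the second sample on
  st <- chain_init()
  for (i in 1:5) {
    r <- cumulative_detrend_step(st, 7, i)
    st <- r$state
    if (i >= 2) expect_lt(abs(r$detrended), 1e-9)
  }
  expect_error(cumulative_detrend_step(st, 1, 99), "out-of-order")
})

test_that("detrending does not overfit white noise beyond two dof", {
  set.seed(3)
  x <- rnorm(400)
  st <- chain_init()
  res <- numeric(400)
  for (i in seq_along(x)) {
    r <- cumulative_detrend_step(st, x[i], i)
    st <- r$state
    res[i] <- r$detrended
  }
  expect_gt(var(res[50:400]) / var(x[50:400]), 0.85)
  expect_lt(var(res[50:400]) / var(x[50:400]), 1.15)
})

test_that("incremental detrending equals batch least squares on the same window", {
  set.seed(4)
  x <- cumsum(rnorm(260, 0.02, 0.5)) + 0.05 * seq_len(260)
  st <- chain_init()
  inc <- numeric(260)
  for (i in seq_along(x)) {
    r <- cumulative_detrend_step(st, x[i], i)
    st <- r$state
    inc[i] <- r$detrended
  }
  for (n in c(10, 100, 260)) {   # batch oracle on the expanding window
    t <- seq_len(n)
    batch <- resid(lm(x[seq_len(n)] ~ t))
    expect_lt(abs(inc[n] - batch[n]), 1e-8)
  }
})

test_that("AR(1) estimate tracks the generating autocorrelation", {
  x <- make_ar1(220, 0.5, seed = 11)
  st <- chain_init()
  w <- numeric(220)
  rho <- NA
  for (i in seq_along(x)) {
    r <- ar1_step(st, x[i])
    st <- r$state
    w[i] <- r$whitened
    rho <- r$rho
  }
  expect_gt(rho, 0.35)
  expect_lt(rho, 0.65)
  ac <- cor(w[2:220], w[1:219])
  expect_lt(abs(ac), 0.15)
  # white noise: rho stays small
  set.seed(12)
  st <- chain_init()
  for (v in rnorm(220)) { r <- ar1_step(st, v); st <- r$state }
  expect_lt(abs(r$rho), 0.1)
  # constant zero stream maps to zero
  st <- chain_init()
  for (i in 1:5) { r <- ar1_step(st, 0); st <- r$state }
  expect_identical(r$whitened, 0)
})

test_that("dynamic-range bounds average the 5% tails", {
  st <- chain_init()
  st$buffer <- as.numeric(1:100)
  st$n_seen <- 100L
  b <- dynamic_range_bounds(st)
  expect_equal(b, c(3, 98))
  st$buffer <- 7; st$n_seen <- 1L
  expect_equal(dynamic_range_bounds(st), c(7, 7))
  st$buffer <- rep(2, 50); st$n_seen <- 50L
  expect_equal(dynamic_range_bounds(st), c(2, 2))
  st$buffer <- numeric(0); st$n_seen <- 0L
  expect_error(dynamic_range_bounds(st), "no values")
})

test_that("unit scaling hits its endpoints, midpoint and degenerate case", {
  expect_equal(scale_to_unit(4, 2, 4), 1)
  expect_equal(scale_to_unit(2, 2, 4), 0)
  expect_equal(scale_to_unit(3, 2, 4), 0.5)
  expect_equal(scale_to_unit(9, 5, 5), 0.5)
  expect_equal(scale_to_unit(99, 2, 4), 1)  # clipped
  expect_error(scale_to_unit(1, 4, 2), "lo")
  # monotone non-decreasing in the value for fixed bounds
  v <- seq(-1, 6, by = 0.25)
  s <- vapply(v, scale_to_unit, 0, lo = 0, hi = 5)
  expect_true(all(diff(s) >= 0))
})

test_that("the full chain is deterministic, causal, and bounded in [0, 1]", {
  set.seed(13)
  x <- 100 + 0.05 * seq_len(120) + rnorm(120, 0, 0.4)
  a <- process_series(x)
  b <- process_series(x)
  expect_identical(a, b)
  expect_true(all(a$normalized >= 0 & a$normalized <= 1))
  # causality: outputs over a prefix do not depend on the future
  half <- process_series(x[1:60])
  expect_identical(half, a[1:60, ])
})

test_that("drifting block signal keeps its block structure after the chain", {
  d <- make_block_design(sim_config())
  lab <- volume_conditions(d)
  set.seed(14)
  x <- 50 + 0.08 * seq_along(lab) + 2 * (lab == "regulation") +
    rnorm(length(lab), 0, 0.3)
  out <- process_series(x)
  expect_gt(mean(out$normalized[lab == "regulation"]),
            mean(out$normalized[lab == "baseline"]))
  expect_gte(min(out$normalized), 0)
  expect_lte(max(out$normalized), 1)
})
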