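hrf1 <- build_chrf(tr = 1, dt = 0.1)

test_that("the task regressor is a convolved regulation boxcar", {
  d <- make_block_design(sim_config())
  x1 <- build_regressor_x1(d, hrf1)
  expect_length(x1, 240)
  # all-baseline design -> zero column
  d0 <- d
  d0$blocks <- d0$blocks[d0$blocks$kind == "baseline", ]
  expect_equal(max(abs(build_regressor_x1(d0, hrf1))), 0)
  # single-block design matches a direct convolution oracle
  ds <- d
  ds$blocks <- data.frame(onset = 20, duration = 40, kind = "regulation")
  xs <- build_regressor_x1(ds, hrf1)
  box <- rep(0, 2400)
  box[201:600] <- 1
  k <- hrf1$kernel_dt
  oracle <- vapply(1:240, function(v) {
    t <- v * 10
    kk <- seq_len(min(length(k), t))
    sum(k[kk] * box[t - kk + 1]) * 0.1
  }, 0)
  expect_lt(max(abs(xs - oracle)), 1e-10)
  # response peaks roughly one HRF peak delay after block onset
  expect_equal(which.max(xs[1:80]), 20 + 6, tolerance = 2)
})

test_that("the feedback-response regressor is a TR-grid convolution", {
  expect_equal(max(abs(build_regressor_x2(rep(0, 100), hrf1))), 0)
  imp <- c(1, rep(0, 59))
  x2 <- build_regressor_x2(imp, hrf1)
  expect_equal(x2[1:33], hrf1$kernel_tr, tolerance = 1e-12)
  expect_error(build_regressor_x2(numeric(0), hrf1), "empty")
})

test_that("the residual regressor is orthogonal to x1 and x2 by construction", {
  d <- make_block_design(sim_config())
  x1 <- build_regressor_x1(d, hrf1)
  set.seed(21)
  sig <- runif(240)
  x2 <- build_regressor_x2(sig, hrf1)
  x3 <- build_regressor_x3(sig, x1, x2)
  expect_lt(abs(sum(x3 * x1)), 1e-8)
  expect_lt(abs(sum(x3 * x2)), 1e-8)
  expect_lt(abs(sum(x3)), 1e-8)  # orthogonal to the intercept too
  # a signal inside span(x1) leaves no residual
  x3b <- build_regressor_x3(2 * x1, x1, x2)
  expect_lt(sqrt(sum(x3b^2)), 1e-8)
  # a signal already orthogonal to x1, x2 and centered is returned as-is
  q <- qr(cbind(1, x1, x2))
  orth <- qr.resid(q, rnorm(240))
  expect_equal(build_regressor_x3(orth, x1, x2), orth, tolerance = 1e-10)
  # collinear x2 triggers the fallback with a warning
  expect_warning(build_regressor_x3(sig, x1, 2 * x1), "collinear")
})

test_that("run-level OLS recovers noiseless coefficients exactly", {
  d <- make_block_design(sim_config())
  x1 <- build_regressor_x1(d, hrf1)
  set.seed(22)
  x2 <- build_regressor_x2(runif(240), hrf1)
  x3 <- build_regressor_x3(runif(240), x1, x2)
  X <- cbind(intercept = 1, x1 = x1, x2 = x2, x3 = x3)
  fit <- fit_run_glm(3 * x1, X)
  expect_equal(unname(fit$beta["x1"]), 3, tolerance = 1e-10)
  expect_lt(max(abs(fit$beta[c("intercept", "x2", "x3")])), 1e-8)
  expect_error(fit_run_glm(rnorm(240), cbind(X, dup = X[, "x1"])),
               "rank deficient")
})

test_that("OLS standard errors match their sampling distribution", {
  set.seed(23)
  n <- 60
  X <- cbind(1, scale(seq_len(n)), rnorm(n))
  colnames(X) <- c("intercept", "x1", "x2")
  sims <- replicate(1000, {
    fit <- fit_run_glm(rnorm(n), X)
    c(fit$beta["x1"], fit$se["x1"])
  })
  expect_lt(abs(mean(sims[1, ])), 3 * sd(sims[1, ]) / sqrt(1000))
  expect_equal(sd(sims[1, ]), mean(sims[2, ]), tolerance = 0.1)
})

test_that("block betas are recovered exactly from their own regressors", {
  d <- make_block_design(sim_config())
  X <- faceloop:::block_regressors(d, hrf1)
  amp <- c(1, 0.8, 0.6, 0.4)
  y <- as.numeric(X %*% amp) + 2
  b <- extract_block_betas(y, d, hrf1)
  expect_equal(unname(b), amp, tolerance = 1e-8)
  b0 <- extract_block_betas(rep(5, 240), d, hrf1)
  expect_lt(max(abs(b0)), 1e-8)
  expect_error(extract_block_betas(rep(0, 100), d, hrf1), "length")
})

test_that("habituation slopes follow the closed-form line fit", {
  expect_equal(habituation_slope(c(4, 3, 2, 1))[["slope"]], -1)
  expect_equal(habituation_slope(c(2, 2, 2, 2))[["slope"]], 0)
  expect_equal(habituation_slope(c(0, 1, 0, 1))[["slope"]], 0.2)
  expect_error(habituation_slope(c(1, 2, 3)), "exactly 4")
  expect_error(habituation_slope(c(1, 2, NA, 4)), "non-finite")
})

test_that("x1 betas agree between the full and reduced model when the
           other regressors are orthogonalized to x1", {
  d <- make_block_design(sim_config())
  x1 <- build_regressor_x1(d, hrf1)
  set.seed(24)
  sig <- runif(240)
  x2 <- build_regressor_x2(sig, hrf1)
  x2o <- qr.resid(qr(cbind(1, x1)), x2)   # x2 orthogonalized to x1
  x3 <- build_regressor_x3(sig, x1, x2)
  y <- 2 * x1 + rnorm(240, 0, 0.5)
  full <- fit_run_glm(y, cbind(intercept = 1, x1 = x1, x2 = x2o, x3 = x3))
  red <- fit_run_glm(y, cbind(intercept = 1, x1 = x1))
  expect_equal(unname(full$beta["x1"]), unname(red$beta["x1"]),
               tolerance = 1e-10)
})

test_that("design matrices built from simulated runs are full rank and
           orthogonalized", {
  run <- quick_run()
  dm <- build_design_matrix(run)
  expect_equal(qr(dm$X)$rank, ncol(dm$X))
  expect_lt(abs(cor(dm$x3, dm$x1)), 1e-6)
  expect_lt(abs(cor(dm$x3, dm$x2)), 1e-6)
  fit <- fit_run_glm(run$volumes$Amy, dm$X)
  expect_true(all(is.finite(fit$t)))
})
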