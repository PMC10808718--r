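test_that("the model space enumerates every combination of the seven
           candidate connections", {
  space <- enumerate_model_space()
  expect_length(space, 128)
  masks <- vapply(space, function(m) paste(as.integer(m$bits), collapse = ""),
                  "")
  expect_equal(anyDuplicated(masks), 0L)
  # boundary member: the all-off model has only self-connections + C
  off <- space[[1]]
  expect_false(any(off$a_mask))
  expect_false(any(off$b_mask))
  # every mask is a subset of the candidate set
  cand <- candidate_edge_mask()
  for (m in space[c(1, 2, 64, 128)]) {
    expect_true(all(!m$a_mask | cand))
    expect_true(all(!m$b_mask | m$a_mask))
  }
  # the reduced space leads with the full model
  red <- reduced_model_space(8)
  expect_length(red, 8)
  expect_true(all(red[[1]]$bits))
  expect_equal(sum(vapply(red, function(m) sum(m$bits), 0L) == 6L), 7L)
})

test_that("DCM prediction is flat for zero input and self-consistent with
           the simulator", {
  g <- group_spec("fear", "down")
  set.seed(51)
  p <- default_neural_params(g)
  h <- build_chrf(tr = 1, dt = 0.1)
  flat <- dcm_predict(p, rep(0, 500), rep(0, 500), h, 1, 40)
  expect_equal(max(abs(flat)), 0)
  # noiseless closed-loop run is reproduced exactly from its own inputs
  cfg <- sim_config(obs_noise_sd = 0, neural_noise_sd = 0)
  r <- simulate_run_closed_loop(p, g, cfg, seed = 3)
  uf <- rep(c(rep(0, 5), r$volumes$u_face), each = 10)
  ui <- rep(c(rep(0, 5), r$volumes$u_int), each = 10)
  pred <- dcm_predict(p, uf, ui, r$hrf, 1, 245)[, 6:245]
  obs <- t(as.matrix(r$volumes[, c("V1", "FFA", "Amy", "mOFC")]))
  expect_lt(max(abs(pred - obs)), 1e-6)
})

test_that("toggling a modulatory edge changes only post-onset dynamics", {
  g <- group_spec("happy", "up")
  set.seed(52)
  p <- default_neural_params(g)
  p2 <- p
  p2$B_face["Amy", "FFA"] <- p$B_face["Amy", "FFA"] + 0.3
  h <- build_chrf(tr = 1, dt = 0.1)
  uf <- c(rep(0, 300), rep(1, 300))
  ui <- rep(0, 600)
  y1 <- dcm_predict(p, uf, ui, h, 1, 60)
  y2 <- dcm_predict(p2, uf, ui, h, 1, 60)
  expect_equal(y1[, 1:30], y2[, 1:30])          # pre-onset identical
  expect_gt(max(abs(y1[, 35:60] - y2[, 35:60])), 0)
})

test_that("self-inversion recovers the generating parameters", {
  g <- group_spec("fear", "down")
  set.seed(53)
  p <- default_neural_params(g)
  cfg <- sim_config(obs_noise_sd = 0.05, neural_noise_sd = 0)
  r <- simulate_run_closed_loop(p, g, cfg, seed = 9)
  full <- reduced_model_space(1)[[1]]
  fr <- dcm_fit_run(r, list(full))
  fit <- fr$fits[[1]]
  mask <- candidate_edge_mask()
  tru <- (p$A + p$B_face + p$B_int)[mask]
  est <- (fit$A + fit$B_face + fit$B_int)[mask]
  expect_gt(cor(tru, est), 0.95)
  expect_gt(fit$explained_var, 0.95)
  # determinism: repeat inversion gives the identical free energy
  fit2 <- dcm_fit_run(r, list(full))$fits[[1]]
  expect_identical(fit$F, fit2$F)
})

test_that("pure-noise data with no input shrinks the posterior to the prior", {
  set.seed(54)
  data <- matrix(rnorm(4 * 120, 0, 0.1), 4, 120)
  m <- reduced_model_space(1)[[1]]
  h <- build_chrf(tr = 1, dt = 0.1)
  fit <- invert_dcm(m, data, rep(0, 120), rep(0, 120), h, 1)
  expect_lt(max(abs(fit$theta - m$prior$mean)), 0.05)
  expect_true(is.finite(fit$F))
})

test_that("model weights are a softmax with the documented invariances", {
  w <- model_weights(matrix(0, 2, 128))
  expect_equal(w$group, rep(1 / 128, 128))
  f <- c(10, rep(0, 127))
  w1 <- model_weights(matrix(f, 1))
  expect_equal(w1$subject[1, 1], exp(10) / (exp(10) + 127),
               tolerance = 1e-12)
  set.seed(55)
  Fm <- matrix(rnorm(3 * 16), 3, 16)
  ws <- model_weights(Fm)
  expect_equal(rowSums(ws$subject), rep(1, 3), tolerance = 1e-12)
  # invariant to adding a constant to all free energies
  ws2 <- model_weights(Fm + 100)
  expect_equal(ws$subject, ws2$subject, tolerance = 1e-12)
  expect_warning(model_weights(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
})

test_that("model averaging is convex and order invariant", {
  mk_fit <- function(val) {
    A <- diag(-0.5, 4)
    A[3, 2] <- val
    list(A = A, B_face = matrix(0, 4, 4), B_int = matrix(0, 4, 4),
         C = matrix(0, 4, 2))
  }
  fits <- list(list(mk_fit(0.2), mk_fit(0.6)))
  W <- matrix(c(0.5, 0.5), 1)
  res <- bma(fits, W)
  expect_equal(res$group$A[3, 2], 0.4)
  expect_equal(res$group$total[3, 2], 0.4)
  # single model with weight 1 returns that model's posterior
  res1 <- bma(list(list(mk_fit(0.3))), matrix(1, 1, 1))
  expect_equal(res1$group$A[3, 2], 0.3)
  # permuting model order with matching weights leaves the average unchanged
  fits_r <- list(list(mk_fit(0.6), mk_fit(0.2)))
  res_r <- bma(fits_r, matrix(c(0.25, 0.75), 1))
  res_f <- bma(fits, matrix(c(0.75, 0.25), 1))
  expect_equal(res_r$group$A, res_f$group$A)
})

test_that("the generating model's evidence beats an impoverished submodel
           at moderate noise", {
  g <- group_spec("fear", "down")
  cfg <- sim_config(obs_noise_sd = 0.15, neural_noise_sd = 0)
  full <- reduced_model_space(1)[[1]]
  # submodel without the FFA->Amy edge (bit 4 in canonical edge order)
  bits <- rep(TRUE, 7)
  bits[4] <- FALSE
  sub <- dcm_model(bits)
  wins <- 0L
  for (i in 1:5) {
    set.seed(60 + i)
    p <- default_neural_params(g, jitter_sd = 0.02)
    r <- simulate_run_closed_loop(p, g, cfg, seed = 60 + i)
    fr <- dcm_fit_run(r, list(full, sub))
    wins <- wins + (fr$F[1] > fr$F[2])
  }
  expect_gte(wins, 4L)
})
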