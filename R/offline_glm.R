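#' Task regressor x1: regulation boxcar convolved with the canonical HRF
#'
#' The boxcar is 1 during regulation blocks and 0 elsewhere, built on the
#' fine grid, convolved with the canonical kernel, and sampled at the TR.
#'
#' @param design a [make_block_design()] result.
#' @param hrf a [build_chrf()] object.
#' @return numeric vector, one value per retained volume.
#' @export
build_regressor_x1 <- function(design, hrf) {
  n_keep <- design$n_volumes - design$dummy_volumes
  dt <- hrf$dt
  stride <- as.integer(round(design$tr / dt))
  n_steps <- n_keep * stride
  times <- (seq_len(n_steps) - 1) * dt
  box <- rep(0, n_steps)
  reg <- design$blocks[design$blocks$kind == "regulation", , drop = FALSE]
  for (i in seq_len(nrow(reg)))
    box[times >= reg$onset[i] - 1e-9 &
          times < reg$onset[i] + reg$duration[i] - 1e-9] <- 1
  conv_sample(box, hrf$kernel_dt, stride, n_keep) * dt
}

# causal convolution of a fine-grid series with a kernel, sampled at every
# stride-th grid point (end of each TR)
conv_sample <- function(x, kernel, stride, n_out) {
  bold_at_volumes_cpp(matrix(x, nrow = 1), kernel, stride, stride,
                      1.0, as.integer(n_out))[1L, ]
}

#' Neurofeedback-response regressor x2: the normalized feedback trace
#' convolved with the canonical HRF
#'
#' The online-normalized (unit-interval) amygdala trace is the parametric
#' modulator the participant actually saw; it is convolved on the TR grid
#' with the TR-sampled kernel and truncated to the series length.
#'
#' @param norm_signal per-volume normalized feedback series.
#' @param hrf a [build_chrf()] object.
#' @return numeric vector of the same length as `norm_signal`.
#' @export
build_regressor_x2 <- function(norm_signal, hrf) {
  if (!length(norm_signal)) .stopf("empty signal")
  k <- hrf$kernel_tr
  n <- length(norm_signal)
  out <- numeric(n)
  for (v in seq_len(n)) {
    kk <- seq_len(min(length(k), v))
    out[v] <- sum(k[kk] * norm_signal[v - kk + 1L])
  }
  out
}

#' Residual-signal regressor x3
#'
#' Least-squares residual of the normalized amygdala signal on an intercept,
#' x1 and x2: what remains of the feedback source once the task blocks and
#' the displayed-stimulus response are accounted for. Orthogonal to x1 and
#' x2 by construction. If x2 is (near-)collinear with x1 the regression is
#' run against the maximal independent subset and a warning is raised.
#'
#' @param raw_norm_signal per-volume normalized amygdala series.
#' @param x1,x2 regressors of matching length.
#' @return numeric residual vector.
#' @export
build_regressor_x3 <- function(raw_norm_signal, x1, x2) {
  n <- length(raw_norm_signal)
  if (length(x1) != n || length(x2) != n) .stopf("length mismatch")
  X <- cbind(1, x1, x2)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    warning("x1/x2 collinear; residualizing against the independent subset")
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    q <- qr(X)
  }
  as.numeric(qr.resid(q, raw_norm_signal))
}

#' Assemble the circularity-aware design matrix
#'
#' Columns: intercept, x1 (task), x2 (neurofeedback response), x3 (residual
#' signal), and six motion nuisance series.
#'
#' @param run a `run_recording`.
#' @return list with `X` (matrix), `x1`, `x2`, `x3`.
#' @export
build_design_matrix <- function(run) {
  x1 <- build_regressor_x1(run$design, run$hrf)
  x2 <- build_regressor_x2(run$volumes$normalized, run$hrf)
  x3 <- build_regressor_x3(run$volumes$normalized, x1, x2)
  motion <- as.matrix(run$volumes[paste0("motion", 1:6)])
  X <- cbind(intercept = 1, x1 = x1, x2 = x2, x3 = x3, motion)
  list(X = X, x1 = x1, x2 = x2, x3 = x3)
}

#' Ordinary least squares fit of one run-level GLM
#'
#' @param roi_series per-volume response vector.
#' @param X design matrix with named columns (full rank required).
#' @return list with `beta`, `se`, `t`, `sigma2`, `df`, `residuals`.
#' @export
fit_run_glm <- function(roi_series, X) {
  X <- as.matrix(X)
  if (length(roi_series) != nrow(X)) .stopf("length mismatch")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    .stopf("design matrix is rank deficient (collinear: %s)",
           paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(q, roi_series)
  res <- qr.resid(q, roi_series)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(q))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  list(beta = beta, se = se, t = beta / se, sigma2 = sigma2, df = df,
       residuals = res)
}

#' Extract the four regulation-block betas of one run
#'
#' Fits a GLM to the Kalman-processed amygdala series with one convolved
#' boxcar per regulation block plus an intercept; returns the four block
#' coefficients. Motion nuisance columns are excluded by default (the
#' processed series is already cleaned), but can be included.
#'
#' @param processed_series per-volume processed amygdala signal (the
#'   de-spiked trace for simulated runs).
#' @param design a [make_block_design()] result.
#' @param hrf a [build_chrf()] object.
#' @param motion optional matrix of nuisance columns to include.
#' @return named numeric vector of 4 block betas.
#' @export
extract_block_betas <- function(processed_series, design, hrf,
                                motion = NULL) {
  reg <- design$blocks[design$blocks$kind == "regulation", , drop = FALSE]
  if (nrow(reg) < 1L) .stopf("design has no regulation blocks")
  X <- block_regressors(design, hrf)
  if (nrow(X) != length(processed_series))
    .stopf("series length (%d) does not match design (%d volumes)",
           length(processed_series), nrow(X))
  Xf <- cbind(intercept = 1, X)
  if (!is.null(motion)) Xf <- cbind(Xf, as.matrix(motion))
  fit <- fit_run_glm(processed_series, Xf)
  fit$beta[colnames(X)]
}

# one convolved boxcar per regulation block, sampled at the TR
block_regressors <- function(design, hrf) {
  n_keep <- design$n_volumes - design$dummy_volumes
  dt <- hrf$dt
  stride <- as.integer(round(design$tr / dt))
  n_steps <- n_keep * stride
  times <- (seq_len(n_steps) - 1) * dt
  reg <- design$blocks[design$blocks$kind == "regulation", , drop = FALSE]
  X <- matrix(0, n_keep, nrow(reg))
  for (i in seq_len(nrow(reg))) {
    box <- as.numeric(times >= reg$onset[i] - 1e-9 &
                        times < reg$onset[i] + reg$duration[i] - 1e-9)
    X[, i] <- conv_sample(box, hrf$kernel_dt, stride, n_keep) * dt
  }
  colnames(X) <- paste0("block", seq_len(nrow(reg)))
  X
}

#' Within-run habituation slope over the four block betas
#'
#' Least-squares line of the block betas on block index 1..4; the slope is
#' in beta units per block.
#'
#' @param block_betas numeric vector of exactly 4 block betas.
#' @return c(slope, intercept).
#' @export
habituation_slope <- function(block_betas) {
  if (length(block_betas) != 4L) .stopf("exactly 4 block betas required")
  if (any(!is.finite(block_betas))) .stopf("non-finite block betas")
  b <- seq_along(block_betas)
  fit <- lm(block_betas ~ b)
  c(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Block-beta table for a whole cohort
#'
#' One row per participant x run x regulation block, with the amygdala
#' block beta extracted from the Kalman-processed feedback trace.
#'
#' @param cohort a [simulate_cohort()] dataset.
#' @param include_motion include the six motion columns in the block GLM.
#' @return data.frame (participant, group, condition, congruent, run,
#'   block, beta).
#' @export
block_beta_table <- function(cohort, include_motion = FALSE) {
  rows <- list()
  for (p in cohort$participants) {
    for (run in seq_along(p$runs)) {
      rec <- p$runs[[run]]
      motion <- if (include_motion)
        as.matrix(rec$volumes[paste0("motion", 1:6)]) else NULL
      betas <- extract_block_betas(rec$volumes$despiked, rec$design,
                                   rec$hrf, motion)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p$id, group = p$group$label,
        condition = p$group$condition,
        congruent = p$group$congruent, run = run,
        block = seq_along(betas), beta = as.numeric(betas))
    }
  }
  do.call(rbind, rows)
}

#' Habituation slopes for a whole cohort
#'
#' @param betas a [block_beta_table()] data.frame.
#' @return data.frame (participant, group, run, slope, intercept), one row
#'   per participant x run.
#' @export
habituation_slopes <- function(betas) {
  key <- interaction(betas$participant, betas$run, drop = TRUE)
  rows <- lapply(split(betas, key), function(d) {
    d <- d[order(d$block), ]
    hs <- habituation_slope(d$beta)
    data.frame(participant = d$participant[1L], group = d$group[1L],
               run = d$run[1L], slope = hs[["slope"]],
               intercept = hs[["intercept"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$run), ]
}
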