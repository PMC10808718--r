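#' @section DCM conventions:
#' The model space covers the fixed V1-FFA-Amy-mOFC network. Seven optional
#' directed edges (three forward from V1, plus both directions of FFA<->Amy
#' and mOFC<->Amy) are toggled on/off, giving 2^7 = 128 models.
#' Self-connections and the V1 driving input are always present. Modulatory
#' (B) coupling is restricted to the four amygdala-coupled edges and, in
#' each model, follows that model's intrinsic (A) mask.
#' @name dcm-conventions
#' @keywords internal
NULL

# candidate directed edges, (target, source), in fixed order
DCM_EDGES <- data.frame(
  target = c(2L, 3L, 4L, 3L, 2L, 3L, 4L),
  source = c(1L, 1L, 1L, 2L, 3L, 4L, 3L),
  name = c("V1->FFA", "V1->Amy", "V1->mOFC", "FFA->Amy", "Amy->FFA",
           "mOFC->Amy", "Amy->mOFC"),
  modulated = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Names of the seven candidate connections
#' @return character vector in canonical order.
#' @export
dcm_edge_names <- function() DCM_EDGES$name

#' Construct one DCM model structure from a 7-bit edge selection
#'
#' @param bits logical (or 0/1) vector of length 7 over the candidate edges
#'   in [dcm_edge_names()] order.
#' @param id optional integer id.
#' @return An object of class `dcm_model` with masks `a_mask`, `b_mask`
#'   (logical 4x4, off-diagonal), prior means/variances and the bit vector.
#' @export
dcm_model <- function(bits, id = NA_integer_) {
  bits <- as.logical(bits)
  if (length(bits) != 7L) .stopf("bits must have length 7")
  a_mask <- matrix(FALSE, 4, 4, dimnames = list(ROI_NAMES, ROI_NAMES))
  for (e in which(bits))
    a_mask[DCM_EDGES$target[e], DCM_EDGES$source[e]] <- TRUE
  b_mask <- matrix(FALSE, 4, 4, dimnames = list(ROI_NAMES, ROI_NAMES))
  for (e in which(bits & DCM_EDGES$modulated))
    b_mask[DCM_EDGES$target[e], DCM_EDGES$source[e]] <- TRUE
  structure(list(id = id, bits = bits, a_mask = a_mask, b_mask = b_mask,
                 prior = dcm_priors(a_mask, b_mask)),
            class = "dcm_model")
}

# parameter order: self (4), free A edges, free B_face, free B_int, C (2)
dcm_priors <- function(a_mask, b_mask) {
  ka <- sum(a_mask)
  kb <- sum(b_mask)
  mean <- c(rep(-0.5, 4), rep(0, ka + 2 * kb), rep(0, 2))
  var <- c(rep(0.25, 4), rep(0.25, ka + 2 * kb), rep(1, 2))
  names(mean) <- names(var) <- c(
    paste0("self_", ROI_NAMES),
    if (ka) paste0("A_", edge_labels(a_mask)),
    if (kb) paste0("Bf_", edge_labels(b_mask)),
    if (kb) paste0("Bi_", edge_labels(b_mask)),
    c("C_face", "C_int"))
  list(mean = mean, var = var, n_a = ka, n_b = kb)
}

edge_labels <- function(mask) {
  idx <- which(mask)
  vapply(idx, function(i) {
    rc <- arrayInd(i, c(4, 4))
    paste0(ROI_NAMES[rc[2]], ".", ROI_NAMES[rc[1]])
  }, "")
}

# theta vector -> coupling matrices
dcm_unpack <- function(theta, model) {
  A <- diag(theta[1:4])
  pos <- 4L
  ka <- model$prior$n_a; kb <- model$prior$n_b
  if (ka) { A[model$a_mask] <- theta[pos + seq_len(ka)]; pos <- pos + ka }
  Bf <- Bi <- matrix(0, 4, 4)
  if (kb) {
    Bf[model$b_mask] <- theta[pos + seq_len(kb)]; pos <- pos + kb
    Bi[model$b_mask] <- theta[pos + seq_len(kb)]; pos <- pos + kb
  }
  C <- matrix(0, 4, 2)
  C[1, ] <- theta[pos + 1:2]
  dimnames(A) <- dimnames(Bf) <- dimnames(Bi) <- list(ROI_NAMES, ROI_NAMES)
  list(A = A, B_face = Bf, B_int = Bi, C = C)
}

#' Enumerate the full 128-model space
#'
#' Every on/off combination of the seven candidate connections.
#'
#' @return list of [dcm_model()] objects, length 128.
#' @export
enumerate_model_space <- function() {
  n <- 2L^7L
  lapply(seq_len(n), function(i) {
    bits <- as.logical(bitwAnd(bitwShiftR(i - 1L, 0:6), 1L))
    dcm_model(bits, id = i)
  })
}

#' A deterministic reduced model space
#'
#' The `n` structurally richest models: models ordered by descending edge
#' count (ties broken by id), so the full seven-edge model always comes
#' first.
#'
#' @param n number of models.
#' @return list of `dcm_model` objects.
#' @export
reduced_model_space <- function(n = 8) {
  space <- enumerate_model_space()
  k <- vapply(space, function(m) sum(m$bits), 0L)
  space[order(-k, vapply(space, function(m) m$id, 0L))][seq_len(n)]
}

#' Predict four-region BOLD from bilinear parameters and known inputs
#'
#' Integrates the deterministic bilinear state equation on the fine grid
#' and observes each region through the canonical HRF at every TR (the same
#' machinery the simulator uses, without noise).
#'
#' @param params list with A, B_face, B_int, C (e.g. [neural_params()] or
#'   a [dcm_model()] fit).
#' @param face_input,intensity_input input series on the fine (dt) grid.
#' @param hrf a [build_chrf()] object.
#' @param tr repetition time, seconds.
#' @param n_vol number of volumes to predict.
#' @param z0 initial state (default zeros).
#' @return 4 x n_vol matrix.
#' @export
dcm_predict <- function(params, face_input, intensity_input, hrf, tr,
                        n_vol, z0 = rep(0, 4)) {
  if (any(diag(params$A) >= 0)) .stopf("unstable: diag(A) must be negative")
  Z <- integrate_bilinear_cpp(params$A, params$B_face, params$B_int,
                              params$C, as.numeric(face_input),
                              as.numeric(intensity_input),
                              matrix(0, 0, 0), hrf$dt, as.numeric(z0),
                              0.0, 50)
  stride <- as.integer(round(tr / hrf$dt))
  bold_at_volumes_cpp(Z, hrf$kernel_dt, stride, stride, hrf$dt,
                      as.integer(n_vol))
}

# per-volume inputs -> fine-grid step functions (value held across the TR)
expand_inputs <- function(u_vol, stride) rep(as.numeric(u_vol), each = stride)

#' Invert one DCM on a four-region time series
#'
#' MAP estimation under independent Gaussian priors: penalized nonlinear
#' least squares (Levenberg-Marquardt on the prior-augmented residual
#' vector), with per-region noise variances re-estimated in a small outer
#' loop, and a Laplace-approximate log evidence
#' `F = accuracy - complexity`. Deterministic: initialization is at the
#' prior means and no random numbers are drawn.
#'
#' @param model a [dcm_model()].
#' @param data 4 x n_vol matrix of observed (retained-volume) BOLD.
#' @param u_face,u_int per-volume inputs, including `n_lead` lead-in
#'   volumes (e.g. dummies) that precede the data.
#' @param hrf a [build_chrf()] object.
#' @param tr repetition time, seconds.
#' @param n_lead number of lead-in volumes before the first data volume.
#' @param max_iter Levenberg-Marquardt iteration cap per outer pass.
#' @param n_outer outer noise-update passes.
#' @return An object of class `dcm_fit`: theta (posterior mode), coupling
#'   matrices, `F`, per-region `sigma2`, `explained_var`, `converged`.
#' @export
invert_dcm <- function(model, data, u_face, u_int, hrf, tr, n_lead = 0L,
                       max_iter = 40L, n_outer = 3L) {
  n_vol <- ncol(data)
  n_tot <- n_vol + n_lead
  if (length(u_face) != n_tot || length(u_int) != n_tot)
    .stopf("inputs must cover %d lead-in + %d data volumes", n_lead, n_vol)
  stride <- as.integer(round(tr / hrf$dt))
  uf <- expand_inputs(u_face, stride)
  ui <- expand_inputs(u_int, stride)
  keep <- (n_lead + 1L):n_tot
  y <- t(data)                      # n_vol x 4
  prior <- model$prior
  L0 <- 1 / sqrt(prior$var)
  sig <- pmax(apply(y, 2, var) * 0.5, 1e-4)  # initial noise guesses

  predict_theta <- function(theta) {
    p <- dcm_unpack(theta, model)
    # keep self-decay strictly negative during the search
    diag(p$A) <- pmin(diag(p$A), -1e-3)
    t(dcm_predict(p, uf, ui, hrf, tr, n_tot)[, keep, drop = FALSE])
  }
  n_res <- length(y) + length(prior$mean)
  resid_fn <- function(theta) {
    pr <- tryCatch(predict_theta(theta), error = function(e) NULL)
    if (is.null(pr)) return(rep(1e6, n_res))  # divergent trial point
    c(sweep(y - pr, 2, sqrt(sig), "/"), L0 * (theta - prior$mean))
  }
  theta <- prior$mean
  fit <- NULL
  for (pass in seq_len(n_outer)) {
    # iteration-cap warnings are redundant with the `converged` flag
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = theta, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ptol = 1e-6, ftol = 1e-6)))
    theta <- fit$par
    pr <- predict_theta(theta)
    sse <- colSums((y - pr)^2)
    sig <- pmax(sse / nrow(y), 1e-6)
  }
  pr <- predict_theta(theta)
  sse <- colSums((y - pr)^2)
  n <- nrow(y)
  e <- theta - prior$mean
  accuracy <- sum(-0.5 * n * log(2 * pi * sig) - 0.5 * sse / sig)
  # posterior precision = J'J of the augmented residuals (Gauss-Newton)
  H <- fit$hessian
  ldH <- determinant(H, logarithm = TRUE)
  complexity <- 0.5 * sum(e^2 / prior$var) + 0.5 * sum(log(prior$var)) +
    0.5 * as.numeric(ldH$modulus)
  Fe <- accuracy - complexity
  tot_var <- sum(sweep(y, 2, colMeans(y))^2)
  p <- dcm_unpack(theta, model)
  diag(p$A) <- pmin(diag(p$A), -1e-3)
  structure(list(theta = theta, A = p$A, B_face = p$B_face,
                 B_int = p$B_int, C = p$C, F = Fe, sigma2 = sig,
                 explained_var = 1 - sum(sse) / tot_var,
                 converged = fit$info %in% 1:4, model = model),
            class = "dcm_fit")
}

#' Posterior model probabilities from per-subject free energies
#'
#' Per subject, a softmax over models (uniform model prior); the group
#' weight of each model is the average of the subject-level posteriors (a
#' documented simplification of the Dirichlet random-effects scheme).
#' Models with non-finite free energy are excluded with a warning.
#'
#' @param F_matrix subjects x models matrix of free energies.
#' @return list with `subject` (subjects x models posterior matrix) and
#'   `group` (model-wise average weights).
#' @export
model_weights <- function(F_matrix) {
  F_matrix <- as.matrix(F_matrix)
  if (any(!is.finite(F_matrix))) {
    warning("non-finite free energies; affected models excluded per subject")
  }
  W <- t(apply(F_matrix, 1, function(f) {
    w <- rep(0, length(f))
    ok <- is.finite(f)
    fok <- f[ok] - max(f[ok])
    w[ok] <- exp(fok) / sum(exp(fok))
    w
  }))
  dimnames(W) <- dimnames(F_matrix)
  list(subject = W, group = colMeans(W))
}

#' Bayesian model averaging of DCM fits
#'
#' Weighted average of the posterior coupling matrices over the model space
#' (absent edges contribute zero), per subject, plus the group mean. The
#' "total" connectivity is the elementwise sum A + B_face + B_int.
#'
#' @param fits list (subjects) of lists (models) of [invert_dcm()] fits.
#' @param weights a [model_weights()] result (or a subjects x models
#'   matrix of normalized weights).
#' @return An object of class `bma_result`: per-subject and group-mean
#'   averaged A, B_face, B_int, C and total matrices.
#' @export
bma <- function(fits, weights) {
  W <- if (is.list(weights)) weights$subject else as.matrix(weights)
  n_sub <- length(fits)
  if (nrow(W) != n_sub) .stopf("weight rows do not match subjects")
  zero <- matrix(0, 4, 4, dimnames = list(ROI_NAMES, ROI_NAMES))
  per_subject <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    if (length(fits[[s]]) != ncol(W)) .stopf("model count mismatch")
    A <- Bf <- Bi <- zero
    C <- matrix(0, 4, 2, dimnames = list(ROI_NAMES, c("face", "intensity")))
    for (m in seq_along(fits[[s]])) {
      w <- W[s, m]
      if (w == 0) next
      f <- fits[[s]][[m]]
      A <- A + w * f$A
      Bf <- Bf + w * f$B_face
      Bi <- Bi + w * f$B_int
      C <- C + w * f$C
    }
    per_subject[[s]] <- list(A = A, B_face = Bf, B_int = Bi, C = C,
                             total = A + Bf + Bi)
  }
  avg <- function(field) Reduce(`+`, lapply(per_subject, `[[`, field)) / n_sub
  structure(list(subjects = per_subject,
                 group = list(A = avg("A"), B_face = avg("B_face"),
                              B_int = avg("B_int"), C = avg("C"),
                              total = avg("total")),
                 weights = W),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("<bma_result> %d subjects, %d models\n",
              length(x$subjects), ncol(x$weights)))
  cat("group-mean total (A + B_face + B_int):\n")
  print(round(x$group$total, 3))
  invisible(x)
}

#' Invert a model space for one run recording
#'
#' Convenience wrapper extracting the four-region series and recorded
#' inputs from a simulated run and inverting every model in `space`.
#'
#' @param run a `run_recording`.
#' @param space list of [dcm_model()] objects.
#' @param ... passed to [invert_dcm()].
#' @return list with `fits` (per model) and `F` (named vector).
#' @export
dcm_fit_run <- function(run, space, ...) {
  data <- t(as.matrix(run$volumes[, ROI_NAMES]))
  n_lead <- run$design$dummy_volumes
  u_face <- c(rep(0, n_lead), run$volumes$u_face)
  u_int <- c(rep(0, n_lead), run$volumes$u_int)
  fits <- lapply(space, function(m)
    invert_dcm(m, data, u_face, u_int, run$hrf, run$config$tr,
               n_lead = n_lead, ...))
  list(fits = fits, F = vapply(fits, `[[`, 0, "F"))
}

#' Group-level DCM analysis with BMA
#'
#' Runs [dcm_fit_run()] for each participant's recording of the selected
#' runs, computes posterior model weights per subject, and model-averages.
#'
#' @param cohort a [simulate_cohort()] dataset.
#' @param group group label (see [group_labels()]); NULL = all participants.
#' @param runs run indices to analyse (default 1 and 4).
#' @param space model space (default [reduced_model_space()] of 8).
#' @param ... passed to [invert_dcm()].
#' @return list keyed by run: each with `bma` (a `bma_result`), `F_matrix`,
#'   and `participants`.
#' @export
dcm_group_analysis <- function(cohort, group = NULL, runs = c(1, 4),
                               space = reduced_model_space(8), ...) {
  parts <- cohort$participants
  if (!is.null(group))
    parts <- Filter(function(p) p$group$label == group, parts)
  if (!length(parts)) .stopf("no participants selected")
  out <- list()
  for (run in runs) {
    fits <- lapply(parts, function(p) dcm_fit_run(p$runs[[run]], space, ...))
    Fm <- do.call(rbind, lapply(fits, `[[`, "F"))
    rownames(Fm) <- vapply(parts, `[[`, "", "id")
    w <- model_weights(Fm)
    out[[as.character(run)]] <- list(
      bma = bma(lapply(fits, `[[`, "fits"), w),
      F_matrix = Fm,
      participants = vapply(parts, `[[`, "", "id"))
  }
  out
}

#' Tabulate BMA results in the standard layout
#'
#' One row per candidate connection and run: model-averaged intrinsic (A),
#' face-modulation (B1), intensity-modulation (B2) and total values, with
#' between-subject SDs (labelled as such).
#'
#' @param analysis a [dcm_group_analysis()] result.
#' @param group label recorded in the table.
#' @return data.frame.
#' @export
bma_table <- function(analysis, group = NA_character_) {
  rows <- list()
  for (run in names(analysis)) {
    res <- analysis[[run]]$bma
    for (e in seq_len(nrow(DCM_EDGES))) {
      ti <- DCM_EDGES$target[e]; si <- DCM_EDGES$source[e]
      subj <- vapply(res$subjects, function(s) s$total[ti, si], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        connection = DCM_EDGES$name[e], group = group,
        run = as.integer(run),
        A = res$group$A[ti, si], B1 = res$group$B_face[ti, si],
        B2 = res$group$B_int[ti, si], total = res$group$total[ti, si],
        total_sd_between = sd(subj))
    }
  }
  do.call(rbind, rows)
}
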