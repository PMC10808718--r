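#' Bilinear neural-coupling parameters for the four-region network
#'
#' Region order is fixed: V1, FFA, Amy (bilateral pooled), mOFC. Matrices
#' follow the effective-connectivity convention `A[i, j]` = influence of
#' region j on region i (Hz). Directed edges are restricted to the candidate
#' set V1->FFA, V1->Amy, V1->mOFC, FFA<->Amy, mOFC<->Amy; self-connections
#' are always present and strictly negative; driving inputs (face regressor
#' and stimulus intensity) enter V1 only.
#'
#' @param A 4x4 intrinsic coupling matrix (Hz).
#' @param B_face 4x4 modulation of coupling by the regulation condition.
#' @param B_int 4x4 modulation of coupling by stimulus intensity.
#' @param C 4x2 driving-input weights (columns: face regressor, intensity).
#' @return An object of class `neural_params`.
#' @export
neural_params <- function(A, B_face = matrix(0, 4, 4),
                          B_int = matrix(0, 4, 4),
                          C = matrix(0, 4, 2)) {
  dims_ok <- all(dim(A) == c(4, 4)) && all(dim(B_face) == c(4, 4)) &&
    all(dim(B_int) == c(4, 4)) && all(dim(C) == c(4, 2))
  if (!dims_ok) .stopf("A, B_face, B_int must be 4x4 and C 4x2")
  if (any(diag(A) >= 0)) .stopf("all self-connections (diag(A)) must be < 0")
  allowed <- candidate_edge_mask()
  off <- !diag(4) & !allowed
  bad <- function(M) any(abs(M[off]) > 0)
  if (bad(A) || bad(B_face) || bad(B_int))
    .stopf("nonzero coupling outside the candidate edge set")
  if (any(abs(C[-1, ]) > 0)) .stopf("driving inputs may enter V1 only")
  dimnames(A) <- dimnames(B_face) <- dimnames(B_int) <-
    list(ROI_NAMES, ROI_NAMES)
  dimnames(C) <- list(ROI_NAMES, c("face", "intensity"))
  structure(list(A = A, B_face = B_face, B_int = B_int, C = C),
            class = "neural_params")
}

#' Logical mask of the candidate directed edges (target row, source column)
#' @return 4x4 logical matrix with the 7 optional edges TRUE.
#' @export
candidate_edge_mask <- function() {
  m <- matrix(FALSE, 4, 4, dimnames = list(ROI_NAMES, ROI_NAMES))
  m["FFA", "V1"] <- TRUE
  m["Amy", "V1"] <- TRUE
  m["mOFC", "V1"] <- TRUE
  m["Amy", "FFA"] <- TRUE
  m["FFA", "Amy"] <- TRUE
  m["Amy", "mOFC"] <- TRUE
  m["mOFC", "Amy"] <- TRUE
  m
}

#' Default neural parameters of a simulated participant
#'
#' A stable, weakly coupled network in which faces drive V1, the ventral
#' stream relays face information to the amygdala via the FFA, and the mOFC
#' exerts valence-dependent control over the amygdala. `b_scale` uniformly
#' scales both modulatory matrices (used to emulate training-related change
#' across runs).
#'
#' @param group a [group_spec()]; fear groups get an inhibitory
#'   mOFC->Amy modulation (the regulation route the fear condition engages),
#'   happy groups a facilitatory one.
#' @param b_scale scalar multiplier on B_face and B_int.
#' @param jitter_sd SD of Gaussian between-subject jitter added to the free
#'   off-diagonal couplings (0 = population template).
#' @return A `neural_params` object.
#' @export
default_neural_params <- function(group, b_scale = 1, jitter_sd = 0) {
  # intrinsic couplings are weak; the task engages the amygdala mainly
  # through the modulatory terms. mOFC is given a slower time constant and
  # a mostly amygdala-driven input so its time course is distinguishable
  # from the ventral-stream relay.
  A <- diag(c(-0.5, -0.6, -0.5, -0.25))
  A[2, 1] <- 0.25   # V1 -> FFA
  A[3, 1] <- 0.12   # V1 -> Amy
  A[4, 1] <- 0.04   # V1 -> mOFC
  A[3, 2] <- 0.05   # FFA -> Amy
  A[2, 3] <- 0.08   # Amy -> FFA
  A[3, 4] <- 0.02   # mOFC -> Amy
  A[4, 3] <- 0.18   # Amy -> mOFC
  Bf <- matrix(0, 4, 4)
  Bi <- matrix(0, 4, 4)
  Bf[3, 2] <- 0.50   # faces gate FFA -> Amy
  Bi[3, 2] <- 0.30   # emotional intensity amplifies the relay
  if (group$condition == "fear") {
    # inhibitory prefrontal control while downregulating fearful content
    Bf[3, 4] <- -0.25
    Bi[3, 4] <- -0.15
  } else {
    # weaker facilitatory mOFC influence in the happy condition (kept
    # modest so the positive Amy<->mOFC loop stays dissipative)
    Bf[3, 4] <- 0.12
    Bi[3, 4] <- 0.06
  }
  C <- matrix(0, 4, 2)
  C[1, 1] <- 0.8   # face on/off drives V1
  C[1, 2] <- 0.3   # higher-intensity expressions drive V1 slightly more
  if (jitter_sd > 0) {
    mask <- candidate_edge_mask()
    A[mask] <- A[mask] + rnorm(sum(mask), 0, jitter_sd)
    j <- Bf != 0
    Bf[j] <- Bf[j] + rnorm(sum(j), 0, jitter_sd)
    j <- Bi != 0
    Bi[j] <- Bi[j] + rnorm(sum(j), 0, jitter_sd)
  }
  neural_params(A, Bf * b_scale, Bi * b_scale, C)
}

#' Integrate the bilinear neural state equation
#'
#' Fixed-step integration of
#' `dz/dt = (A + u_face B_face + u_int B_int) z + C [u_face, u_int]'`:
#' Heun's method for the drift with an additive Euler-Maruyama noise
#' increment. Deterministic when `noise_sd = 0`; otherwise stochastic
#' innovations are drawn from R's RNG (reproducible under `set.seed()`).
#'
#' @param params a [neural_params()] object (or any list with A, B_face,
#'   B_int, C of conformable dimensions).
#' @param face_input,intensity_input input series sampled on the dt grid.
#' @param dt integration step, seconds.
#' @param noise_sd innovation SD per sqrt-second.
#' @param z0 initial state (default zeros).
#' @param extra optional additive drive matrix (regions x time), e.g. an
#'   instructed-regulation input; default none.
#' @param bound divergence guard: integration aborts with an error if any
#'   |state| exceeds it.
#' @param seed optional integer; when given, `set.seed(seed)` is called first.
#' @return regions x time matrix of latent states.
#' @export
integrate_neural <- function(params, face_input, intensity_input, dt,
                             noise_sd = 0, z0 = NULL, extra = NULL,
                             bound = 50, seed = NULL) {
  if (dt <= 0) .stopf("dt must be > 0")
  if (length(face_input) != length(intensity_input))
    .stopf("input series must have equal length")
  if (any(diag(params$A) >= 0)) .stopf("diag(A) must be negative")
  n <- nrow(params$A)
  if (is.null(z0)) z0 <- rep(0, n)
  if (is.null(extra)) extra <- matrix(0, 0, 0)
  if (!is.null(seed)) set.seed(seed)
  integrate_bilinear_cpp(params$A, params$B_face, params$B_int, params$C,
                         as.numeric(face_input), as.numeric(intensity_input),
                         extra, dt, as.numeric(z0), noise_sd, bound)
}
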