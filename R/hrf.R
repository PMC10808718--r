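#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma kernel (response peak 6 s, undershoot peak 16 s,
#' unit dispersions, peak:undershoot ratio 6, 32-s support), sampled on both
#' the fine integration grid and the TR grid, and normalized to unit peak.
#'
#' @param tr repetition time in seconds.
#' @param dt fine sampling step in seconds.
#' @param peak_delay,undershoot_delay gamma means in seconds.
#' @param peak_disp,undershoot_disp gamma dispersions in seconds.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length_s kernel support in seconds.
#' @return An object of class `canonical_hrf`: list with `kernel_dt`,
#'   `kernel_tr`, the sampling steps, and the parameter set.
#' @export
#' @examples
#' h <- build_chrf(tr = 1, dt = 0.1)
#' which.max(h$kernel_dt) # peak at ~6 s
build_chrf <- function(tr = 1, dt = 0.1, peak_delay = 6,
                       undershoot_delay = 16, peak_disp = 1,
                       undershoot_disp = 1, ratio = 6, length_s = 32) {
  if (tr <= 0 || dt <= 0) .stopf("tr and dt must be > 0")
  # shape chosen so each gamma's mode falls exactly at its stated delay
  shape1 <- peak_delay / peak_disp + 1
  shape2 <- undershoot_delay / undershoot_disp + 1
  eval_kernel <- function(t) {
    dgamma(t, shape = shape1, scale = peak_disp) -
      dgamma(t, shape = shape2, scale = undershoot_disp) / ratio
  }
  t_dt <- seq(0, length_s, by = dt)
  t_tr <- seq(0, length_s, by = tr)
  k_dt <- eval_kernel(t_dt)
  k_tr <- eval_kernel(t_tr)
  peak <- max(k_dt)
  structure(list(kernel_dt = k_dt / peak, kernel_tr = k_tr / peak,
                 dt = dt, tr = tr,
                 params = c(peak_delay = peak_delay,
                            undershoot_delay = undershoot_delay,
                            peak_disp = peak_disp,
                            undershoot_disp = undershoot_disp,
                            ratio = ratio, length_s = length_s)),
            class = "canonical_hrf")
}

#' Convolve a fine-grid neural trajectory with the canonical HRF and sample
#' at volume times
#'
#' Causal discrete convolution on the dt grid, evaluated at every TR. Row
#' order of the input is preserved. Volume v (1-based) is read at fine-grid
#' index `vol_offset + (v-1) * tr/dt`.
#'
#' @param neural numeric matrix, regions x fine-grid samples (a vector is
#'   treated as one region).
#' @param hrf a [build_chrf()] object (its `dt` must match the trajectory).
#' @param tr repetition time in seconds.
#' @param n_vol number of volumes to produce.
#' @param vol_offset 1-based fine-grid index of the first volume sample;
#'   defaults to one TR after the start.
#' @param obs_noise_sd additive Gaussian noise SD (0 = noiseless).
#' @return regions x n_vol matrix of BOLD samples.
#' @export
hemodynamic_observe <- function(neural, hrf, tr, n_vol,
                                vol_offset = NULL, obs_noise_sd = 0) {
  if (is.vector(neural)) neural <- matrix(neural, nrow = 1)
  stride <- tr / hrf$dt
  if (abs(stride - round(stride)) > 1e-9) .stopf("hrf dt must divide tr")
  stride <- as.integer(round(stride))
  if (is.null(vol_offset)) vol_offset <- stride
  if (length(hrf$kernel_dt) > ncol(neural))
    .stopf("HRF kernel (%d samples) longer than trajectory (%d)",
           length(hrf$kernel_dt), ncol(neural))
  y <- bold_at_volumes_cpp(neural, hrf$kernel_dt, stride,
                           as.integer(vol_offset), hrf$dt, as.integer(n_vol))
  if (obs_noise_sd > 0)
    y <- y + matrix(rnorm(length(y), 0, obs_noise_sd), nrow = nrow(y))
  y
}
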