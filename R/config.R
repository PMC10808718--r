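#' Simulation configuration
#'
#' Bundles the acquisition and design constants of one closed-loop
#' neurofeedback experiment. Defaults reproduce the study conditions the
#' simulator targets: TR = 1 s, 5 dummy volumes, four 20-s baseline blocks
#' interleaved with four 40-s regulation blocks, four runs, and four groups
#' of 16 participants.
#'
#' @param tr repetition time in seconds.
#' @param n_dummy number of leading dummy volumes discarded from all outputs.
#' @param baseline_len baseline ("rest"/counting) block length in seconds.
#' @param regulation_len regulation (face feedback) block length in seconds.
#' @param n_blocks_per_kind number of blocks of each kind per run.
#' @param n_runs number of neurofeedback training runs per participant.
#' @param n_per_group participants per experimental group.
#' @param integration_dt Euler integration step in seconds; must divide `tr`.
#' @param obs_noise_sd SD of additive Gaussian measurement noise on each
#'   region's BOLD signal, in signal units.
#' @param neural_noise_sd SD of the stochastic innovation of the latent
#'   neural states (per sqrt-second), in signal units.
#' @param rest_pre,rest_post optional task-free padding, in seconds, before
#'   the first and after the last block (default 0: the printed block design).
#' @param seed master integer seed; every downstream random draw is derived
#'   from it deterministically.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_per_group = 2)
#' cfg$tr
sim_config <- function(tr = 1.0, n_dummy = 5, baseline_len = 20,
                       regulation_len = 40, n_blocks_per_kind = 4,
                       n_runs = 4, n_per_group = 16, integration_dt = 0.1,
                       obs_noise_sd = 0.15, neural_noise_sd = 0.03,
                       rest_pre = 0, rest_post = 0, seed = 1L) {
  cfg <- list(tr = tr, n_dummy = as.integer(n_dummy),
              baseline_len = baseline_len, regulation_len = regulation_len,
              n_blocks_per_kind = as.integer(n_blocks_per_kind),
              n_runs = as.integer(n_runs),
              n_per_group = as.integer(n_per_group),
              integration_dt = integration_dt,
              obs_noise_sd = obs_noise_sd,
              neural_noise_sd = neural_noise_sd,
              rest_pre = rest_pre, rest_post = rest_post,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$tr) || cfg$tr <= 0) .stopf("tr must be > 0")
  if (cfg$baseline_len <= 0 || cfg$regulation_len <= 0)
    .stopf("block durations must be positive")
  if (cfg$integration_dt <= 0) .stopf("integration_dt must be > 0")
  ratio <- cfg$tr / cfg$integration_dt
  if (abs(ratio - round(ratio)) > 1e-9)
    .stopf("integration_dt must divide tr")
  counts <- c(cfg$n_dummy >= 0, cfg$n_blocks_per_kind >= 1,
              cfg$n_runs >= 1, cfg$n_per_group >= 1)
  if (!all(counts)) .stopf("counts must be >= 1 (n_dummy >= 0)")
  if (cfg$obs_noise_sd < 0 || cfg$neural_noise_sd < 0)
    .stopf("noise SDs must be >= 0")
  if (cfg$rest_pre < 0 || cfg$rest_post < 0)
    .stopf("rest padding must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  TR %.3g s, %d dummy volumes, dt %.3g s\n",
              x$tr, x$n_dummy, x$integration_dt))
  cat(sprintf("  %d x (%g s baseline + %g s regulation), %d runs, %d/group\n",
              x$n_blocks_per_kind, x$baseline_len, x$regulation_len,
              x$n_runs, x$n_per_group))
  cat(sprintf("  obs noise %.3g, neural noise %.3g, seed %d\n",
              x$obs_noise_sd, x$neural_noise_sd, x$seed))
  invisible(x)
}

#' Online-chain settings
#'
#' Tuning constants of the causal per-volume feedback signal chain. The
#' Kalman de-spiking filter uses a random-walk state model; its variances
#' default to values for which a flat stream converges within roughly ten
#' samples. The spike gate is `spike_threshold` times the innovation SD.
#'
#' @param process_var Kalman process (state random-walk) variance.
#' @param obs_var Kalman observation variance; 0 gives a pass-through filter.
#' @param spike_threshold innovation gate, in innovation SDs.
#' @param spike_damping multiplier (0..1) applied to the Kalman gain when a
#'   sample is flagged as a spike.
#' @param tail_frac fraction of the observed values averaged in each tail of
#'   the adaptive dynamic-range scaling (ceil(tail_frac * n), minimum 1).
#' @param warmup number of samples below which the scaling falls back to the
#'   running min/max of everything seen so far.
#' @param ar1_limit absolute ceiling for the running AR(1) estimate.
#' @return An object of class `chain_settings`.
#' @export
chain_settings <- function(process_var = 0.05, obs_var = 0.25,
                           spike_threshold = 1.96, spike_damping = 0.1,
                           tail_frac = 0.05, warmup = 10, ar1_limit = 0.95) {
  if (process_var < 0 || obs_var < 0) .stopf("variances must be >= 0")
  if (spike_threshold <= 0) .stopf("spike_threshold must be > 0")
  if (tail_frac <= 0 || tail_frac > 0.5) .stopf("tail_frac must be in (0, 0.5]")
  if (ar1_limit <= 0 || ar1_limit >= 1) .stopf("ar1_limit must be in (0, 1)")
  structure(list(process_var = process_var, obs_var = obs_var,
                 spike_threshold = spike_threshold,
                 spike_damping = spike_damping, tail_frac = tail_frac,
                 warmup = as.integer(warmup), ar1_limit = ar1_limit),
            class = "chain_settings")
}
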