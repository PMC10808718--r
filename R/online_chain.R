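#' Initialize the causal online-chain state
#'
#' The chain processes the amygdala feedback signal one volume at a time,
#' in the order spike removal (scalar Kalman filter), drift removal
#' (expanding-window least squares on constant + linear trend), AR(1)
#' prewhitening, and adaptive dynamic-range scaling to the unit interval.
#'
#' @param settings a [chain_settings()] object.
#' @return An object of class `chain_state`.
#' @export
chain_init <- function(settings = chain_settings()) {
  structure(list(
    settings = settings,
    kalman = list(x = NA_real_, p = 1.0),
    # expanding-window LS sufficient statistics: y on [1, t]
    drift = list(n = 0L, st = 0, stt = 0, sy = 0, sty = 0),
    ar1 = list(prev = NA_real_, s_xy = 0, s_xx = 0, n = 0L),
    buffer = numeric(0),
    n_seen = 0L
  ), class = "chain_state")
}

#' One Kalman de-spiking step
#'
#' Random-walk state model. The innovation is gated at
#' `spike_threshold * sqrt(innovation variance)`; a flagged sample is
#' replaced by the one-step prediction and the filter update is damped so a
#' single outlier cannot drag the state estimate.
#'
#' @param state a `chain_state`.
#' @param raw_value the incoming scalar sample.
#' @return list(state, despiked, was_spike).
#' @export
kalman_despike_step <- function(state, raw_value) {
  if (!is.finite(raw_value)) .stopf("non-finite input to the Kalman step")
  s <- state$settings
  k <- state$kalman
  if (is.na(k$x)) { # first sample initializes the state
    state$kalman <- list(x = raw_value, p = s$obs_var)
    return(list(state = state, despiked = raw_value, was_spike = FALSE))
  }
  if (s$obs_var == 0) { # degenerate pass-through filter
    state$kalman <- list(x = raw_value, p = 0)
    return(list(state = state, despiked = raw_value, was_spike = FALSE))
  }
  p_pred <- k$p + s$process_var
  innov <- raw_value - k$x
  innov_var <- p_pred + s$obs_var
  was_spike <- abs(innov) > s$spike_threshold * sqrt(innov_var)
  gain <- p_pred / innov_var
  if (was_spike) {
    despiked <- k$x                     # prediction replaces the sample
    gain <- gain * s$spike_damping      # damped update
  }
  x_new <- k$x + gain * innov
  if (!was_spike) despiked <- x_new
  state$kalman <- list(x = x_new, p = (1 - gain) * p_pred)
  list(state = state, despiked = despiked, was_spike = was_spike)
}

#' One expanding-window detrending step
#'
#' Cumulative least squares of all samples seen so far on a constant plus
#' linear trend; the returned value is the current sample's residual. With
#' fewer than three samples the fit is the running mean.
#'
#' @param state a `chain_state`.
#' @param value sample (normally the de-spiked value).
#' @param volume_index 1-based index; must increment by one per call.
#' @return list(state, detrended).
#' @export
cumulative_detrend_step <- function(state, value, volume_index) {
  if (!is.finite(value)) .stopf("non-finite input to the detrending step")
  d <- state$drift
  if (volume_index != d$n + 1L)
    .stopf("out-of-order volume index %d (expected %d)", volume_index, d$n + 1L)
  t <- as.numeric(volume_index)
  d$n <- d$n + 1L
  d$st <- d$st + t
  d$stt <- d$stt + t * t
  d$sy <- d$sy + value
  d$sty <- d$sty + t * value
  n <- d$n
  if (n < 3L) {
    fit <- d$sy / n
  } else {
    den <- n * d$stt - d$st^2
    if (abs(den) < 1e-12) {
      fit <- d$sy / n
    } else {
      b <- (n * d$sty - d$st * d$sy) / den
      a <- (d$sy - b * d$st) / n
      fit <- a + b * t
    }
  }
  state$drift <- d
  list(state = state, detrended = value - fit)
}

#' One AR(1) prewhitening step
#'
#' Maintains a running lag-1 autocorrelation estimate of the detrended
#' residual stream (clipped to +/- `ar1_limit`) and returns
#' `residual - rho_hat * previous residual`.
#'
#' @param state a `chain_state`.
#' @param residual the detrended sample.
#' @return list(state, whitened, rho).
#' @export
ar1_step <- function(state, residual) {
  if (!is.finite(residual)) .stopf("non-finite input to the AR(1) step")
  a <- state$ar1
  lim <- state$settings$ar1_limit
  if (is.na(a$prev)) {
    rho <- 0
    whitened <- residual
  } else {
    a$s_xy <- a$s_xy + a$prev * residual
    a$s_xx <- a$s_xx + a$prev^2
    a$n <- a$n + 1L
    rho <- if (a$s_xx > 1e-12) a$s_xy / a$s_xx else 0
    rho <- max(-lim, min(lim, rho))
    whitened <- residual - rho * a$prev
  }
  a$prev <- residual
  state$ar1 <- a
  list(state = state, whitened = whitened, rho = rho)
}

#' Adaptive dynamic-range bounds
#'
#' Bounds are the averages of the `tail_frac` highest and lowest processed
#' values observed so far (ceil(tail_frac * n) values per tail, at least
#' one). During warm-up (fewer than `warmup` samples) the bounds fall back
#' to the running min and max.
#'
#' @param state a `chain_state` with at least one processed value.
#' @return c(lo, hi).
#' @export
dynamic_range_bounds <- function(state) {
  n <- state$n_seen
  if (n < 1L) .stopf("dynamic range undefined: no values seen yet")
  v <- sort(state$buffer)
  if (n < state$settings$warmup) return(c(v[1L], v[n]))
  k <- max(1L, as.integer(ceiling(state$settings$tail_frac * n)))
  c(mean(v[seq_len(k)]), mean(v[seq.int(n - k + 1L, n)]))
}

#' Map a value into the unit interval given dynamic-range bounds
#'
#' `(value - lo) / (hi - lo)` clipped to [0, 1]; a degenerate range
#' (hi == lo) maps to 0.5 so the display never freezes at an extreme.
#'
#' @param value scalar.
#' @param lo,hi bounds with lo <= hi.
#' @return normalized value in [0, 1].
#' @export
scale_to_unit <- function(value, lo, hi) {
  if (lo > hi) .stopf("lo must be <= hi")
  if (hi - lo < 1e-12) return(0.5)
  min(1, max(0, (value - lo) / (hi - lo)))
}

#' Process one volume through the full online chain
#'
#' Applies, in order: Kalman de-spiking, expanding-window detrending, AR(1)
#' prewhitening, then dynamic-range scaling of the whitened value. All
#' intermediates are returned for audit.
#'
#' @param state a `chain_state`.
#' @param raw_value incoming amygdala sample.
#' @param volume_index 1-based, incrementing by one per call.
#' @return list(state, sample) where sample has raw, despiked, detrended,
#'   whitened, normalized, was_spike, rho.
#' @export
process_volume <- function(state, raw_value, volume_index) {
  k <- kalman_despike_step(state, raw_value)
  d <- cumulative_detrend_step(k$state, k$despiked, volume_index)
  w <- ar1_step(d$state, d$detrended)
  state <- w$state
  state$buffer <- c(state$buffer, w$whitened)
  state$n_seen <- state$n_seen + 1L
  b <- dynamic_range_bounds(state)
  normalized <- scale_to_unit(w$whitened, b[1L], b[2L])
  list(state = state,
       sample = list(raw = raw_value, despiked = k$despiked,
                     detrended = d$detrended, whitened = w$whitened,
                     normalized = normalized, was_spike = k$was_spike,
                     rho = w$rho))
}

#' Run the online chain over a whole series at once
#'
#' Convenience wrapper equal to calling [process_volume()] sequentially on a
#' fresh state; useful for testing causality and batch equivalence.
#'
#' @param values numeric vector of raw samples.
#' @param settings a [chain_settings()].
#' @return data.frame with one row per sample (raw, despiked, detrended,
#'   whitened, normalized, was_spike, rho).
#' @export
process_series <- function(values, settings = chain_settings()) {
  st <- chain_init(settings)
  out <- vector("list", length(values))
  for (i in seq_along(values)) {
    r <- process_volume(st, values[i], i)
    st <- r$state
    out[[i]] <- as.data.frame(r$sample)
  }
  do.call(rbind, out)
}
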