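# Iterative learning adaptation. Per gait cycle, each channel's envelope time
# coefficient tau is nudged by a fixed step L when the cycle's stimulation
# time deviates from the mean of the previous five cycles by more than a dead
# zone, and the LG pulse width is nudged by L_PW when the shank angle at
# toe-off deviates from its five-cycle mean by more than 2 degrees:
#
#   tau(n+1) = tau(n) + L   if  dt < -0.04 s     dt = t_s(n) - mean_5(t_s)
#            = tau(n) - L   if  dt >  0.04 s
#   PW(n+1)  = PW(n) + L_PW if  dphi < -2 deg    dphi = phi_TO(n) - mean_5(phi_TO)
#            = PW(n) - L_PW if  dphi >  2 deg
#
# tau is clamped to [0.01, 1] s and PW to [250, 500] us. Updates only start
# once five complete cycles have been observed (warm-up); the current cycle is
# compared against the previous five and only then enters the history.

#' Adaptive controller state
#'
#' Mutable parameter set of the iterative-learning layer: the eight time
#' coefficients, the two LG pulse widths, and per-channel ring buffers of the
#' last five cycles' feedback.
#'
#' @param calibration An `fes_calibration`; initial `tau`/`pulse_width` are
#'   taken per channel from it unless overridden.
#' @param tau_init,pw_init Optional scalar overrides for all channels.
#' @param L Learning step for `tau` (seconds of time coefficient per cycle).
#' @param L_pw Learning step for the LG pulse width (microseconds per cycle).
#' @param dt_threshold Dead zone on the stimulation-time deviation, seconds.
#' @param dphi_threshold Dead zone on the toe-off shank-angle deviation,
#'   degrees.
#' @param tau_bounds,pw_bounds Clamping ranges.
#' @param flip_tau_sign Invert the direction of the `tau` update (the printed
#'   rule lengthens the envelope when stimulation time falls short; this flag
#'   selects the opposite convention). Default off.
#' @param history_len Ring-buffer length (cycles averaged over).
#' @return A list of class `adaptive_state`.
#' @export
adaptive_state <- function(calibration = default_calibration(),
                           tau_init = NULL, pw_init = NULL,
                           L = 0.01, L_pw = 20,
                           dt_threshold = 0.04, dphi_threshold = 2,
                           tau_bounds = c(0.01, 1), pw_bounds = c(250, 500),
                           flip_tau_sign = FALSE, history_len = 5L) {
  stopifnot(L > 0, L_pw > 0, dt_threshold >= 0, dphi_threshold >= 0,
            length(tau_bounds) == 2L, tau_bounds[1] < tau_bounds[2],
            length(pw_bounds) == 2L, pw_bounds[1] < pw_bounds[2],
            history_len >= 1L)
  channels <- names(calibration)
  tau <- vapply(channels, function(k) calibration[[k]]$tau, numeric(1))
  if (!is.null(tau_init)) tau[] <- tau_init
  lg <- channels[vapply(channels, function(k) calibration[[k]]$muscle == "LG",
                        logical(1))]
  sides <- unique(vapply(lg, function(k) calibration[[k]]$side, character(1)))
  pw <- vapply(sides, function(s) calibration[[paste(s, "LG", sep = ".")]]$pulse_width,
               numeric(1))
  if (!is.null(pw_init)) pw[] <- pw_init
  tau <- pmin(pmax(tau, tau_bounds[1]), tau_bounds[2])
  pw <- pmin(pmax(pw, pw_bounds[1]), pw_bounds[2])
  hist_ts <- stats::setNames(rep(list(numeric(0)), length(channels)), channels)
  hist_phi <- stats::setNames(rep(list(numeric(0)), length(sides)), sides)
  structure(list(tau = tau, pw = pw, hist_ts = hist_ts, hist_phi = hist_phi,
                 L = L, L_pw = L_pw, dt_threshold = dt_threshold,
                 dphi_threshold = dphi_threshold, tau_bounds = tau_bounds,
                 pw_bounds = pw_bounds, flip_tau_sign = flip_tau_sign,
                 history_len = as.integer(history_len), cycle = 0L),
            class = "adaptive_state")
}

#' @export
print.adaptive_state <- function(x, ...) {
  cat(sprintf("Adaptive FES state after %d recorded cycle(s)\n", x$cycle))
  cat("  tau (s): ", paste(sprintf("%s=%.3g", names(x$tau), x$tau),
                           collapse = ", "), "\n", sep = "")
  cat("  LG pulse width (us): ",
      paste(sprintf("%s=%g", names(x$pw), x$pw), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Stimulation time of one channel over one gait cycle
#'
#' Total duration within the cycle during which the commanded amplitude
#' exceeds the channel's resting level `c_min`, i.e. the gate is on and the
#' envelope is positive, summed across branches.
#'
#' @param amplitude Amplitude samples (mA) of the channel over one cycle, or a
#'   data frame with an `amplitude_mA` column.
#' @param c_min The channel's minimum threshold current (mA).
#' @param dt Sample period, seconds.
#' @return Seconds of active stimulation (0 for an empty trace).
#' @export
measure_stimulation_time <- function(amplitude, c_min, dt) {
  if (is.data.frame(amplitude)) amplitude <- amplitude$amplitude_mA
  if (!length(amplitude)) return(0)
  stopifnot(dt > 0, is.finite(c_min))
  sum(amplitude > c_min + 1e-9) * dt
}

#' Mean feedback value over the five-cycle history
#'
#' @param state An [adaptive_state()].
#' @param channel Channel key (`"left.TA"`, ...) for the stimulation-time
#'   history, or a side (`"left"`/`"right"`) with `what = "phi"`.
#' @param what `"ts"` (stimulation time) or `"phi"` (toe-off shank angle).
#' @return The arithmetic mean over the full buffer, or `NA_real_` while the
#'   buffer holds fewer than `history_len` cycles (warm-up).
#' @export
mean_of_history <- function(state, channel, what = c("ts", "phi")) {
  what <- match.arg(what)
  buf <- if (what == "ts") state$hist_ts[[channel]] else state$hist_phi[[channel]]
  if (is.null(buf)) stop("unknown channel '", channel, "'", call. = FALSE)
  if (length(buf) < state$history_len) return(NA_real_)
  mean(buf)
}

# Shared dead-zone step: +step below -threshold, -step above +threshold,
# unchanged inside the (closed) dead zone; clamped to bounds.
.ilc_step <- function(value, delta, step, threshold, bounds, flip = FALSE) {
  if (flip) step <- -step
  out <- if (delta < -threshold) value + step
         else if (delta > threshold) value - step
         else value
  min(max(out, bounds[1]), bounds[2])
}

#' Single iterative-learning update of a channel's time coefficient
#'
#' Compares the current cycle's stimulation time against the five-cycle mean
#' and applies the dead-zone step rule; no-op during warm-up (history not yet
#' full). Does not push `t_current` into the history (see [record_cycle()]).
#'
#' @param state An [adaptive_state()].
#' @param channel Channel key, e.g. `"left.TA"`.
#' @param t_current Stimulation time of the current cycle, seconds.
#' @return The updated `adaptive_state`.
#' @export
update_tau <- function(state, channel, t_current) {
  if (!channel %in% names(state$tau)) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  m <- mean_of_history(state, channel, "ts")
  if (is.na(m)) return(state)
  state$tau[[channel]] <- .ilc_step(state$tau[[channel]], t_current - m,
                                    state$L, state$dt_threshold,
                                    state$tau_bounds, state$flip_tau_sign)
  state
}

#' Single iterative-learning update of an LG pulse width
#'
#' Same dead-zone rule on the toe-off shank angle: a toe-off angle more than
#' `dphi_threshold` below the five-cycle mean widens the pulses by `L_pw`,
#' more than `dphi_threshold` above narrows them; clamped to `pw_bounds`.
#'
#' @param state An [adaptive_state()].
#' @param side `"left"` or `"right"`.
#' @param phi_current Shank angle at toe-off in the current cycle, degrees.
#' @return The updated `adaptive_state`.
#' @export
update_pw <- function(state, side, phi_current) {
  if (!side %in% names(state$pw)) {
    stop("unknown side '", side, "'", call. = FALSE)
  }
  m <- mean_of_history(state, side, "phi")
  if (is.na(m)) return(state)
  state$pw[[side]] <- .ilc_step(state$pw[[side]], phi_current - m,
                                state$L_pw, state$dphi_threshold,
                                state$pw_bounds)
  state
}

#' Record one completed gait cycle and adapt the parameters
#'
#' Applies [update_tau()] for every channel present in `t_s` and
#' [update_pw()] for every side present in `phi_to` (both no-ops until the
#' respective history is full), then pushes the cycle's feedback into the ring
#' buffers, dropping the oldest entry. The current cycle is thus compared
#' strictly against the previous five.
#'
#' @param state An [adaptive_state()].
#' @param t_s Named numeric vector of stimulation times (seconds) keyed by
#'   channel (`"left.TA"`, ...).
#' @param phi_to Named numeric vector of toe-off shank angles (degrees) keyed
#'   by side.
#' @return The updated `adaptive_state`.
#' @export
record_cycle <- function(state, t_s = numeric(0), phi_to = numeric(0)) {
  for (ch in names(t_s)) {
    state <- update_tau(state, ch, t_s[[ch]])
    buf <- c(state$hist_ts[[ch]], t_s[[ch]])
    state$hist_ts[[ch]] <- utils::tail(buf, state$history_len)
  }
  for (side in names(phi_to)) {
    state <- update_pw(state, side, phi_to[[side]])
    buf <- c(state$hist_phi[[side]], phi_to[[side]])
    state$hist_phi[[side]] <- utils::tail(buf, state$history_len)
  }
  state$cycle <- state$cycle + 1L
  state
}
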