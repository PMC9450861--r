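# Impulse-response envelope H(t) shared by all stimulation channels.
#
# H(t) = g * (1/tau) * exp(-1.5 t / tau) * sin(3 t / (2 tau))
#
# tau shapes the burst (larger tau = slower, longer burst); g normalizes the
# peak to 1 so the envelope maps directly onto the calibrated current range
# [C_min, C_max]. The sinusoid would go negative after its first post-peak
# zero crossing at t = 2*pi*tau/3; amplitude below C_min is meaningless for a
# stimulator, so the envelope is truncated to 0 there and stimulation bursts
# are single-lobed.

.TAU_MIN <- 0.01
.TAU_MAX <- 1

.check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau < .TAU_MIN || tau > .TAU_MAX) {
    stop("`tau` must be a single finite value in [", .TAU_MIN, ", ",
         .TAU_MAX, "] seconds", call. = FALSE)
  }
  invisible(tau)
}

# Unchecked envelope evaluation; returns 0 outside the single positive lobe
# [0, 2*pi*tau/3]. Used internally where t - t_impulse may be negative.
.envelope <- function(t, tau, g = normalizing_gain(tau)) {
  h <- (g / tau) * exp(-1.5 * t / tau) * sin(1.5 * t / tau)
  h[t < 0 | t > 2 * pi * tau / 3] <- 0
  pmax(h, 0)
}

#' Parameters of one stimulation envelope
#'
#' Bundles the time coefficient `tau`, the normalizing gain `g`, and the
#' muscle/side/trigger the envelope belongs to. The gain defaults to
#' [normalizing_gain()] so that the peak of the envelope is exactly 1.
#'
#' @param tau Time coefficient in seconds, in `[0.01, 1]`.
#' @param g Dimensionless gain; defaults to the peak-normalizing gain.
#' @param muscle One of `"TA"`, `"LG"`, `"BF"`, `"RF"`.
#' @param side `"left"` or `"right"`.
#' @param trigger Gait-event impulse this envelope is convolved with.
#' @return An object of class `tf_params`.
#' @examples
#' p <- tf_params(0.1, muscle = "TA", trigger = "I_SW")
#' impulse_response(p, peak_time(0.1))  # 1 by construction
#' @export
tf_params <- function(tau, g = normalizing_gain(tau),
                      muscle = c("TA", "LG", "BF", "RF"),
                      side = c("left", "right"),
                      trigger = c("I_SW", "I_LR", "I_PS", "I_TSW")) {
  .check_tau(tau)
  muscle <- match.arg(muscle)
  side <- match.arg(side)
  trigger <- match.arg(trigger)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    stop("`g` must be a single positive finite value", call. = FALSE)
  }
  structure(list(tau = tau, g = g, muscle = muscle, side = side,
                 trigger = trigger),
            class = "tf_params")
}

#' @export
print.tf_params <- function(x, ...) {
  cat(sprintf(
    "Stimulation envelope: %s %s (trigger %s)\n  tau = %.4g s, g = %.4g, peak at %.4g s, active for %.4g s\n",
    x$side, x$muscle, x$trigger, x$tau, x$g,
    peak_time(x$tau), activation_duration(x$tau)))
  invisible(x)
}

#' Evaluate the stimulation impulse-response envelope
#'
#' Returns the dimensionless envelope amplitude in `[0, 1]` at time `t` after
#' the triggering gait-event impulse. The envelope is truncated to zero after
#' its first post-peak zero crossing at `2*pi*tau/3` seconds, so stimulation
#' bursts are single positive lobes.
#'
#' @param params A [tf_params()] object, or a single numeric `tau` (the
#'   normalizing gain is then used).
#' @param t Time since the impulse, seconds; finite and non-negative
#'   (vectorized).
#' @param g Optional gain override.
#' @return Numeric vector of envelope values in `[0, 1]`.
#' @examples
#' impulse_response(0.1, 0)                 # 0: bursts start at C_min
#' impulse_response(0.1, pi * 0.1 / 6)      # 1: normalized peak
#' impulse_response(0.1, 2 * pi * 0.1 / 3)  # 0: end of the lobe
#' @export
impulse_response <- function(params, t, g = NULL) {
  if (inherits(params, "tf_params")) {
    tau <- params$tau
    if (is.null(g)) g <- params$g
  } else {
    tau <- params
    .check_tau(tau)
    if (is.null(g)) g <- normalizing_gain(tau)
  }
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  .envelope(t, tau, g)
}

#' Gain normalizing the envelope peak to one
#'
#' The envelope peaks at `t = pi*tau/6` (where `tan(1.5 t/tau) = 1`); solving
#' `H(t_peak) = 1` gives the closed form `g = tau * sqrt(2) * exp(pi/4)`.
#'
#' @param tau Time coefficient in seconds, in `[0.01, 1]`.
#' @return The dimensionless gain making `max_t H(t) = 1`.
#' @export
normalizing_gain <- function(tau) {
  .check_tau(tau)
  tau * sqrt(2) * exp(pi / 4)
}

#' Time of the envelope peak
#'
#' Analytic argmax of the envelope, `pi*tau/6` seconds. This is the response
#' time of the stimulation burst: one-fourth of [activation_duration()].
#'
#' @inheritParams normalizing_gain
#' @return Seconds.
#' @export
peak_time <- function(tau) {
  .check_tau(tau)
  pi * tau / 6
}

#' Duration of the active stimulation lobe
#'
#' First zero crossing of the envelope after its peak, `2*pi*tau/3` seconds;
#' the envelope is identically zero beyond it.
#'
#' @inheritParams normalizing_gain
#' @return Seconds.
#' @export
activation_duration <- function(tau) {
  .check_tau(tau)
  2 * pi * tau / 3
}

#' Cut-off frequency associated with a time coefficient
#'
#' `f_c = 1 / (2 * pi * tau)`, the low-pass cut-off corresponding to the
#' envelope time coefficient.
#'
#' @param tau Time coefficient in seconds; strictly positive.
#' @return Frequency in hertz.
#' @export
cutoff_frequency <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be finite and strictly positive", call. = FALSE)
  }
  1 / (2 * pi * tau)
}

#' @export
plot.tf_params <- function(x, n = 400L, ...) {
  tt <- seq(0, 1.15 * activation_duration(x$tau), length.out = n)
  graphics::plot(tt, .envelope(tt, x$tau, x$g), type = "l",
                 xlab = "time since impulse (s)",
                 ylab = "envelope amplitude (fraction of current range)",
                 main = sprintf("%s %s envelope, tau = %.3g s",
                                x$side, x$muscle, x$tau), ...)
  graphics::abline(v = peak_time(x$tau), lty = 3)
  invisible(x)
}
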