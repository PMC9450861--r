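# Reflexive stimulation controller: each gait-event impulse triggers an
# impulse-response envelope on the muscle channels wired to it, and a
# phase-dependent state function gates the channel on or off.
#
# Channel wiring (per side):
#   TA <- I_SW          gate: SW or TSW
#   LG <- I_LR          gate: LR        (first branch)
#   LG <- I_PS          gate: PS        (second branch)
#   BF <- I_SW          gate: SW or TSW
#   RF <- I_LR          gate: LR        (first branch)
#   RF <- I_TSW         gate: TSW       (second branch)
#
# Amplitude of a branch at time t:  gate * (delta_c * H(t - t_impulse) + C_min),
# clamped to [0, C_max]. A new qualifying impulse restarts the branch envelope.

.MUSCLES <- c("TA", "LG", "BF", "RF")
.SIDES <- c("left", "right")

.branch_table <- function() {
  data.frame(
    muscle = c("TA", "LG", "LG", "BF", "RF", "RF"),
    branch = c("SW", "LR", "PS", "SW", "LR", "TSW"),
    trigger = c("I_SW", "I_LR", "I_PS", "I_SW", "I_LR", "I_TSW"),
    stringsAsFactors = FALSE)
}

.branches_for <- function(muscle) {
  bt <- .branch_table()
  bt[bt$muscle == muscle, , drop = FALSE]
}

#' Phase gate of a muscle channel branch
#'
#' The finite-state layer of the controller: 1 when the branch may stimulate
#' in the given gait phase, 0 otherwise. TA and BF are gated on during swing
#' and terminal swing; LG's two branches during load response and pre-swing
#' respectively; RF's two branches during load response and terminal swing.
#'
#' @param muscle `"TA"`, `"LG"`, `"BF"` or `"RF"`.
#' @param branch Branch name: `"SW"` for TA/BF, `"LR"`/`"PS"` for LG,
#'   `"LR"`/`"TSW"` for RF.
#' @param phase Gait phase label (vectorized): `"LR"`, `"ST"`, `"PS"`, `"SW"`,
#'   `"TSW"`.
#' @return Integer 0/1 vector.
#' @export
state_gate <- function(muscle, branch, phase) {
  muscle <- match.arg(muscle, .MUSCLES)
  br <- .branches_for(muscle)
  if (!branch %in% br$branch) {
    stop("unknown branch '", branch, "' for muscle ", muscle, call. = FALSE)
  }
  if (!all(phase %in% .PHASES)) stop("unknown gait phase", call. = FALSE)
  on_phases <- switch(paste(muscle, branch, sep = "."),
                      "TA.SW" = c("SW", "TSW"),
                      "BF.SW" = c("SW", "TSW"),
                      "LG.LR" = "LR",
                      "LG.PS" = "PS",
                      "RF.LR" = "LR",
                      "RF.TSW" = "TSW")
  as.integer(phase %in% on_phases)
}

#' Per-channel stimulation calibration
#'
#' @param muscle,side Channel identity.
#' @param c_min Minimum threshold current (mA): smallest amplitude eliciting a
#'   visible contraction.
#' @param c_max Maximum comfortable current (mA); `delta_c = c_max - c_min` is
#'   the modulated range.
#' @param pulse_width Stimulation pulse width, microseconds. Adapted at run
#'   time for LG channels only (and therefore required to start within
#'   `[250, 500]` for LG).
#' @param stim_frequency Stimulation pulse frequency, Hz (constant per
#'   channel).
#' @param tau Initial envelope time coefficient, seconds.
#' @return A list of class `channel_config`.
#' @export
channel_config <- function(muscle, side, c_min, c_max, pulse_width = 300,
                           stim_frequency = 25, tau = 0.1) {
  muscle <- match.arg(muscle, .MUSCLES)
  side <- match.arg(side, .SIDES)
  stopifnot(is.finite(c_min), is.finite(c_max), c_min > 0, c_max > c_min,
            is.finite(pulse_width), pulse_width > 0, stim_frequency > 0)
  if (muscle == "LG" && (pulse_width < 250 || pulse_width > 500)) {
    stop("LG pulse width must start within [250, 500] microseconds",
         call. = FALSE)
  }
  .check_tau(tau)
  structure(list(muscle = muscle, side = side, c_min = c_min, c_max = c_max,
                 delta_c = c_max - c_min, pulse_width = pulse_width,
                 stim_frequency = stim_frequency, tau = tau),
            class = "channel_config")
}

#' Default eight-channel calibration
#'
#' Plausible current thresholds (mA) for the four muscles of each leg, for
#' simulation work; real use replaces them with per-participant calibration
#' (see [read_calibration()]).
#'
#' @param tau Initial time coefficient for every channel, seconds.
#' @param pulse_width Initial pulse width, microseconds.
#' @return Named list of class `fes_calibration` keyed `side.muscle`.
#' @export
default_calibration <- function(tau = 0.1, pulse_width = 300) {
  base <- list(TA = c(15, 30), LG = c(12, 28), BF = c(18, 35), RF = c(16, 32))
  out <- list()
  for (side in .SIDES) {
    for (m in .MUSCLES) {
      out[[paste(side, m, sep = ".")]] <-
        channel_config(m, side, base[[m]][1], base[[m]][2],
                       pulse_width = pulse_width, tau = tau)
    }
  }
  structure(out, class = "fes_calibration")
}

#' Read / write an eight-channel calibration file
#'
#' YAML schema: `side: muscle: {c_min, c_max, pulse_width, stim_frequency,
#' tau}` with both sides and all four muscles present.
#'
#' @param path File path.
#' @return `read_calibration()`: an `fes_calibration` list.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  for (side in .SIDES) {
    if (is.null(y[[side]])) {
      stop("calibration file is missing side '", side, "'", call. = FALSE)
    }
    for (m in .MUSCLES) {
      ch <- y[[side]][[m]]
      if (is.null(ch) || is.null(ch$c_min) || is.null(ch$c_max)) {
        stop("calibration file is missing channel ", side, ".", m,
             call. = FALSE)
      }
      out[[paste(side, m, sep = ".")]] <- channel_config(
        m, side, ch$c_min, ch$c_max,
        pulse_width = ch$pulse_width %||% 300,
        stim_frequency = ch$stim_frequency %||% 25,
        tau = ch$tau %||% 0.1)
    }
  }
  structure(out, class = "fes_calibration")
}

#' @rdname read_calibration
#' @param calibration An `fes_calibration` list.
#' @export
write_calibration <- function(calibration, path) {
  y <- list()
  for (key in names(calibration)) {
    ch <- calibration[[key]]
    y[[ch$side]][[ch$muscle]] <- list(
      c_min = ch$c_min, c_max = ch$c_max, pulse_width = ch$pulse_width,
      stim_frequency = ch$stim_frequency, tau = ch$tau)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.fes_calibration <- function(x, ...) {
  cat("FES calibration (", length(x), " channels)\n", sep = "")
  for (key in names(x)) {
    ch <- x[[key]]
    cat(sprintf("  %-9s C_min %4.1f mA  C_max %4.1f mA  PW %3.0f us  %2.0f Hz  tau %.3g s\n",
                key, ch$c_min, ch$c_max, ch$pulse_width, ch$stim_frequency,
                ch$tau))
  }
  invisible(x)
}

#' Stimulation amplitude of one channel at one instant
#'
#' Sums the channel's branch contributions
#' `gate * (delta_c * H(t - t_impulse) + c_min)` and clamps to
#' `[0, c_max]`. With a gate on but no (or an expired) envelope the amplitude
#' rests at `c_min`; with all gates off it is 0.
#'
#' @param cfg A [channel_config()].
#' @param phase Current gait phase of the channel's leg.
#' @param t Time, seconds.
#' @param impulses Optional data frame `t, kind` of impulses already emitted
#'   on that leg (only the most recent impulse of each branch's trigger kind
#'   matters: a new impulse restarts the branch envelope).
#' @param tau,pw Overrides for the channel's time coefficient and pulse width
#'   (used by the adaptive layer).
#' @return Amplitude in mA.
#' @export
channel_amplitude <- function(cfg, phase, t, impulses = NULL,
                              tau = cfg$tau, pw = cfg$pulse_width) {
  stopifnot(inherits(cfg, "channel_config"))
  g <- normalizing_gain(tau)
  amp <- 0
  for (bi in seq_len(nrow(br <- .branches_for(cfg$muscle)))) {
    gate <- state_gate(cfg$muscle, br$branch[bi], phase)
    if (gate == 0L) next
    env <- 0
    if (!is.null(impulses) && nrow(impulses)) {
      it <- impulses$t[impulses$kind == br$trigger[bi] & impulses$t <= t]
      if (length(it)) env <- .envelope(t - max(it), tau, g)
    }
    amp <- amp + gate * (cfg$delta_c * env + cfg$c_min)
  }
  min(max(amp, 0), cfg$c_max)
}

# Vectorized stimulation trace for one channel over a sampled window.
# phases: phase label per sample; impulses: data frame t, kind (sorted).
# Later impulses overwrite earlier envelopes within their lobe (restart
# semantics).
.stim_trace <- function(times, phases, impulses, cfg, tau = cfg$tau) {
  n <- length(times)
  g <- normalizing_gain(tau)
  dur <- activation_duration(tau)
  amp <- numeric(n)
  br <- .branches_for(cfg$muscle)
  for (bi in seq_len(nrow(br))) {
    gate <- state_gate(cfg$muscle, br$branch[bi], phases)
    env <- numeric(n)
    it <- sort(impulses$t[impulses$kind == br$trigger[bi]])
    for (ti in it) {
      idx <- which(times >= ti & times <= ti + dur)
      if (length(idx)) env[idx] <- .envelope(times[idx] - ti, tau, g)
    }
    amp <- amp + gate * (cfg$delta_c * env + cfg$c_min)
  }
  pmin(pmax(amp, 0), cfg$c_max)
}

#' Generate the eight-channel stimulation sequence for a detected session
#'
#' The purely reflexive controller: fixed time coefficients and pulse widths,
#' one amplitude sample per channel per sensor tick. See [closed_loop_run()]
#' for the adaptive variant.
#'
#' @param detections Named list (`left`, `right`) of [detect_stream()]
#'   results; a single `gait_detection` is treated as one side.
#' @param calibration An [default_calibration()]-style `fes_calibration`.
#' @return Data frame `t, side, muscle, amplitude_mA, pulse_width_us`, one
#'   row per channel per tick, of class `fes_stimulation`.
#' @export
reflexive_stimulation <- function(detections, calibration = default_calibration()) {
  if (inherits(detections, "gait_detection")) {
    detections <- list(left = detections)
  }
  missing_ch <- setdiff(
    as.vector(outer(names(detections), .MUSCLES, paste, sep = ".")),
    names(calibration))
  if (length(missing_ch)) {
    stop("calibration is missing channels: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (side in names(detections)) {
    det <- detections[[side]]
    for (m in .MUSCLES) {
      cfg <- calibration[[paste(side, m, sep = ".")]]
      a <- .stim_trace(det$phases$t, det$phases$phase, det$impulses, cfg)
      out[[paste(side, m)]] <- data.frame(
        t = det$phases$t, side = side, muscle = m, amplitude_mA = a,
        pulse_width_us = cfg$pulse_width, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fes_stimulation", "data.frame")
  res
}

#' Streaming controller state
#'
#' Holds the per-branch envelope clocks and current adaptive parameters for
#' sample-by-sample operation via [controller_tick()].
#'
#' @param calibration An `fes_calibration` with all eight channels.
#' @return A list of class `controller_state`.
#' @export
controller_state <- function(calibration = default_calibration()) {
  need <- as.vector(outer(.SIDES, .MUSCLES, paste, sep = "."))
  missing_ch <- setdiff(need, names(calibration))
  if (length(missing_ch)) {
    stop("calibration is missing channels: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  clocks <- list()
  bt <- .branch_table()
  for (side in .SIDES) {
    for (bi in seq_len(nrow(bt))) {
      clocks[[paste(side, bt$muscle[bi], bt$branch[bi], sep = ".")]] <- -Inf
    }
  }
  tau <- vapply(need, function(k) calibration[[k]]$tau, numeric(1))
  pw <- vapply(need, function(k) calibration[[k]]$pulse_width, numeric(1))
  structure(list(calibration = calibration, clocks = clocks,
                 tau = tau, pw = pw),
            class = "controller_state")
}

#' One controller tick: eight stimulation commands
#'
#' Restarts the branch envelopes of any impulses arriving at this tick, then
#' evaluates every channel's amplitude.
#'
#' @param ctrl A [controller_state()].
#' @param t Time, seconds.
#' @param phase_by_side Named character vector, gait phase per side, e.g.
#'   `c(left = "SW", right = "ST")`.
#' @param impulses_now Optional data frame `kind, side` of impulses emitted at
#'   this tick.
#' @return `list(ctrl, commands)` where `commands` is a data frame with one
#'   row per channel: `t, side, muscle, amplitude_mA, pulse_width_us`.
#' @export
controller_tick <- function(ctrl, t, phase_by_side, impulses_now = NULL) {
  stopifnot(inherits(ctrl, "controller_state"))
  bt <- .branch_table()
  if (!is.null(impulses_now) && nrow(impulses_now)) {
    for (i in seq_len(nrow(impulses_now))) {
      hit <- bt$trigger == impulses_now$kind[i]
      for (bi in which(hit)) {
        key <- paste(impulses_now$side[i], bt$muscle[bi], bt$branch[bi],
                     sep = ".")
        ctrl$clocks[[key]] <- t
      }
    }
  }
  rows <- list()
  for (side in names(phase_by_side)) {
    phase <- phase_by_side[[side]]
    for (m in .MUSCLES) {
      key <- paste(side, m, sep = ".")
      cfg <- ctrl$calibration[[key]]
      tau <- ctrl$tau[[key]]
      g <- normalizing_gain(tau)
      amp <- 0
      br <- .branches_for(m)
      for (bi in seq_len(nrow(br))) {
        gate <- state_gate(m, br$branch[bi], phase)
        if (gate == 0L) next
        t0 <- ctrl$clocks[[paste(side, m, br$branch[bi], sep = ".")]]
        env <- if (is.finite(t0)) .envelope(t - t0, tau, g) else 0
        amp <- amp + gate * (cfg$delta_c * env + cfg$c_min)
      }
      rows[[key]] <- data.frame(
        t = t, side = side, muscle = m,
        amplitude_mA = min(max(amp, 0), cfg$c_max),
        pulse_width_us = unname(ctrl$pw[[key]]), stringsAsFactors = FALSE)
    }
  }
  commands <- do.call(rbind, rows)
  rownames(commands) <- NULL
  list(ctrl = ctrl, commands = commands)
}
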