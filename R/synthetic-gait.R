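# Synthetic treadmill gait generator. Emulates the sensor streams of one
# walking session — heel/toe insole forces and the sagittal shank angle of
# both legs — with ground-truth events, phases and cycle boundaries, across
# an up-then-down treadmill speed ramp. Every downstream module is testable
# against these labels without hardware.

#' Parameters of the synthetic gait cycle model
#'
#' @param speed Treadmill speed, km/h.
#' @param cycle_duration Gait-cycle duration, seconds. Defaults to a linear
#'   speed-cadence map: 1.4 s at 1.0 km/h shortening to 1.0 s at 2.0 km/h.
#' @param phase_fractions Named fractions of the cycle spent in each phase
#'   (`LR`, `ST`, `PS`, `SW`, `TSW`); must sum to 1.
#' @param force_amplitude Plateau contact force, arbitrary units.
#' @param phi_to Sagittal shank angle at toe-off, degrees. Defaults to a
#'   linear speed map 10 + 15 * (speed - 1), i.e. 10-25 degrees over the
#'   protocol, so that the 2-degree adaptation dead zone is clearly exceeded
#'   at speed changes.
#' @param angle_hs Shank angle at heel strike, degrees (also the lead-in
#'   resting angle).
#' @param sta_threshold Sagittal threshold angle the trajectory crosses
#'   upward exactly at the terminal-swing boundary, degrees.
#' @param noise_sd Named vector `c(force =, angle =)` of additive Gaussian
#'   noise standard deviations (0 = noise-free).
#' @param sample_rate Samples per second.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(speed = 1.0, cycle_duration = NULL,
                        phase_fractions = c(LR = 0.10, ST = 0.30, PS = 0.10,
                                            SW = 0.37, TSW = 0.13),
                        force_amplitude = 1, phi_to = NULL, angle_hs = 20,
                        sta_threshold = 15,
                        noise_sd = c(force = 0, angle = 0),
                        sample_rate = 100) {
  if (is.null(cycle_duration)) cycle_duration <- 1.4 - 0.4 * (speed - 1)
  if (is.null(phi_to)) phi_to <- 10 + 15 * (speed - 1)
  if (!all(.PHASES %in% names(phase_fractions)) ||
      abs(sum(phase_fractions) - 1) > 1e-9 || any(phase_fractions <= 0)) {
    stop("`phase_fractions` must be positive, named LR/ST/PS/SW/TSW and sum to 1",
         call. = FALSE)
  }
  stopifnot(cycle_duration > 0, force_amplitude > 0, sample_rate > 0,
            all(noise_sd >= 0), angle_hs > sta_threshold)
  structure(list(speed = speed, cycle_duration = cycle_duration,
                 phase_fractions = phase_fractions[.PHASES],
                 force_amplitude = force_amplitude, phi_to = phi_to,
                 angle_hs = angle_hs, sta_threshold = sta_threshold,
                 noise_sd = noise_sd, sample_rate = sample_rate),
            class = "gait_params")
}

#' Treadmill speed protocol
#'
#' An up-then-down speed ramp; every visited level (each visit counted) lasts
#' `cycles_per_level` gait cycles. The default reproduces the 1.0 -> 2.0 ->
#' 1.0 km/h ramp in 0.2 km/h steps with 15 cycles per level: 11 visited
#' levels, 165 cycles per leg.
#'
#' @param start,stop,step Speeds in km/h; `step` must divide `stop - start`.
#' @param cycles_per_level Gait cycles walked at each visited level.
#' @return A list of class `speed_protocol` with a `levels` vector (km/h).
#' @export
speed_protocol <- function(start = 1.0, stop = 2.0, step = 0.2,
                           cycles_per_level = 15L) {
  stopifnot(start > 0, stop >= start, cycles_per_level >= 1L)
  if (stop > start) {
    k <- (stop - start) / step
    if (step <= 0 || abs(k - round(k)) > 1e-9) {
      stop("`step` must be positive and divide stop - start exactly",
           call. = FALSE)
    }
    up <- start + step * (0:round(k))
    levels <- c(up, rev(up)[-1])
  } else {
    levels <- start
  }
  structure(list(start = start, stop = stop, step = step,
                 cycles_per_level = as.integer(cycles_per_level),
                 levels = levels),
            class = "speed_protocol")
}

# Event fractions of the cycle derived from the phase schedule.
.event_fractions <- function(fr) {
  c(HS = 0,
    FF = unname(fr["LR"]),
    HO = unname(fr["LR"] + fr["ST"]),
    TO = unname(fr["LR"] + fr["ST"] + fr["PS"]),
    STA = unname(fr["LR"] + fr["ST"] + fr["PS"] + fr["SW"]))
}

#' Generate one synthetic gait cycle
#'
#' Heel force is a plateau over load response and stance; toe force switches
#' on 50 ms (the detector's foot-flat debounce) before the LR/ST boundary and
#' off at toe-off, so the detector's FF event lands on the scheduled phase
#' boundary. The shank angle is a piecewise-linear knot trajectory: `angle_hs`
#' at heel strike, `phi_to` at toe-off, a mid-swing dip to 0 degrees, an
#' upward crossing of `sta_threshold` exactly at the terminal-swing boundary,
#' and back to `angle_hs` at the next heel strike.
#'
#' @param params A [gait_params()].
#' @param t0 Cycle start time (heel strike), seconds.
#' @return List: `samples` (data frame `t, heel, toe, shank_angle`), `events`
#'   (data frame `t, kind`), `phases` (truth phase per sample), `phi_to`,
#'   `duration`.
#' @export
generate_cycle <- function(params, t0 = 0) {
  stopifnot(inherits(params, "gait_params"))
  Tc <- params$cycle_duration
  dt <- 1 / params$sample_rate
  n <- round(Tc / dt)
  tl <- (seq_len(n) - 1L) * dt       # local time in [0, Tc)
  u <- tl / Tc
  fr <- params$phase_fractions
  ef <- .event_fractions(fr)

  toe_on <- max(ef[["FF"]] * Tc - 0.05, dt)
  heel <- ifelse(tl < ef[["HO"]] * Tc, params$force_amplitude, 0)
  toe <- ifelse(tl >= toe_on & tl < ef[["TO"]] * Tc,
                params$force_amplitude, 0)

  dip_u <- (ef[["TO"]] + ef[["STA"]]) / 2
  knots_u <- c(0, ef[["TO"]], dip_u, ef[["STA"]], 1)
  knots_v <- c(params$angle_hs, params$phi_to, 0, params$sta_threshold,
               params$angle_hs)
  angle <- stats::approx(knots_u, knots_v, xout = u)$y

  if (params$noise_sd[["force"]] > 0) {
    heel <- pmax(heel + stats::rnorm(n, 0, params$noise_sd[["force"]]), 0)
    toe <- pmax(toe + stats::rnorm(n, 0, params$noise_sd[["force"]]), 0)
  }
  if (params$noise_sd[["angle"]] > 0) {
    angle <- angle + stats::rnorm(n, 0, params$noise_sd[["angle"]])
  }

  phase_breaks <- cumsum(fr) # LR ST PS SW TSW -> upper fraction bounds
  phases <- .PHASES[findInterval(u, c(0, phase_breaks[-5]))]

  list(samples = data.frame(t = t0 + tl, heel = heel, toe = toe,
                            shank_angle = angle),
       events = data.frame(t = t0 + unname(ef) * Tc, kind = names(ef),
                           stringsAsFactors = FALSE),
       phases = phases, phi_to = params$phi_to, duration = Tc)
}

#' Generate a labeled synthetic treadmill session
#'
#' Concatenates `cycles_per_level` cycles at every visited speed level of the
#' protocol for both legs, the right leg offset by half of the first cycle. A
#' short no-contact lead-in precedes the first heel strike (so it produces a
#' detectable edge) and a heel-only tail closes the last cycle with a final
#' heel strike.
#'
#' @param protocol A [speed_protocol()].
#' @param seed Integer seed for the noise generator (ignored when noise is 0;
#'   identical seeds give bit-identical sessions).
#' @param sample_rate Samples per second.
#' @param noise_sd Named noise standard deviations, see [gait_params()].
#' @param cycle_duration_fn,phi_to_fn Speed maps for the cycle duration (s)
#'   and toe-off shank angle (degrees).
#' @param lead_in,tail Durations (s) of the lead-in swing segment and the
#'   closing heel-contact tail.
#' @param ... Further arguments passed to [gait_params()] for every level.
#' @return A list of class `fes_gait_session`: `streams` (`$left`, `$right`
#'   sensor data frames), `truth` (per side: `events`, `cycles` boundary
#'   times, `phases` per sample, `speed` and `phi_to` per cycle), `protocol`,
#'   `n_cycles` (ground-truth gait cycles per leg), `sample_rate`.
#' @export
generate_protocol <- function(protocol = speed_protocol(), seed = NULL,
                              sample_rate = 100,
                              noise_sd = c(force = 0, angle = 0),
                              cycle_duration_fn = function(s) 1.4 - 0.4 * (s - 1),
                              phi_to_fn = function(s) 10 + 15 * (s - 1),
                              lead_in = 0.3, tail = 0.3, ...) {
  stopifnot(inherits(protocol, "speed_protocol"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / sample_rate
  speeds_per_cycle <- rep(protocol$levels, each = protocol$cycles_per_level)
  first_T <- cycle_duration_fn(protocol$levels[1])
  offsets <- c(left = 0, right = first_T / 2)

  sides <- list()
  truth <- list()
  for (side in .SIDES) {
    li <- lead_in + offsets[[side]]
    n_li <- round(li / dt)
    p1 <- gait_params(speed = protocol$levels[1], sample_rate = sample_rate,
                      noise_sd = noise_sd, ...)
    lead <- data.frame(t = (seq_len(n_li) - 1L) * dt, heel = 0, toe = 0,
                       shank_angle = p1$angle_hs)
    lead_phase <- rep("TSW", n_li)
    if (any(noise_sd > 0)) {
      lead$heel <- pmax(lead$heel + stats::rnorm(n_li, 0, noise_sd[["force"]]), 0)
      lead$toe <- pmax(lead$toe + stats::rnorm(n_li, 0, noise_sd[["force"]]), 0)
      lead$shank_angle <- lead$shank_angle +
        stats::rnorm(n_li, 0, noise_sd[["angle"]])
    }
    t0 <- n_li * dt
    chunks <- list(lead)
    phases <- list(lead_phase)
    events <- list()
    cyc_start <- numeric(0)
    phi_to <- numeric(0)
    for (sp in speeds_per_cycle) {
      p <- gait_params(speed = sp, cycle_duration = cycle_duration_fn(sp),
                       phi_to = phi_to_fn(sp), sample_rate = sample_rate,
                       noise_sd = noise_sd, ...)
      cyc <- generate_cycle(p, t0 = t0)
      chunks <- c(chunks, list(cyc$samples))
      phases <- c(phases, list(cyc$phases))
      events <- c(events, list(cyc$events))
      cyc_start <- c(cyc_start, t0)
      phi_to <- c(phi_to, cyc$phi_to)
      t0 <- t0 + cyc$duration
    }
    # Closing heel strike + heel-only tail bounds the last cycle.
    n_tail <- round(tail / dt)
    tl <- data.frame(t = t0 + (seq_len(n_tail) - 1L) * dt,
                     heel = p1$force_amplitude, toe = 0,
                     shank_angle = p1$angle_hs)
    if (any(noise_sd > 0)) {
      tl$heel <- pmax(tl$heel + stats::rnorm(n_tail, 0, noise_sd[["force"]]), 0)
      tl$toe <- pmax(tl$toe + stats::rnorm(n_tail, 0, noise_sd[["force"]]), 0)
      tl$shank_angle <- tl$shank_angle +
        stats::rnorm(n_tail, 0, noise_sd[["angle"]])
    }
    chunks <- c(chunks, list(tl))
    phases <- c(phases, list(rep("LR", n_tail)))
    events <- c(events, list(data.frame(t = t0, kind = "HS",
                                        stringsAsFactors = FALSE)))
    stream <- do.call(rbind, chunks)
    rownames(stream) <- NULL
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$t), , drop = FALSE]
    rownames(ev) <- NULL
    sides[[side]] <- stream
    truth[[side]] <- list(events = ev,
                          cycles = c(cyc_start, t0),
                          phases = unlist(phases),
                          speed = speeds_per_cycle,
                          phi_to = phi_to)
  }
  structure(list(streams = sides, truth = truth, protocol = protocol,
                 n_cycles = length(speeds_per_cycle),
                 sample_rate = sample_rate, noise_sd = noise_sd),
            class = "fes_gait_session")
}

#' @export
print.fes_gait_session <- function(x, ...) {
  pr <- x$protocol
  cat(sprintf(
    "Synthetic treadmill session: %.1f -> %.1f -> %.1f km/h (step %.1f), %d cycles/level\n",
    pr$start, pr$stop, pr$start, pr$step, pr$cycles_per_level))
  cat(sprintf("  %d visited speed levels, %d gait cycles per leg, %d samples/leg at %g Hz\n",
              length(pr$levels), x$n_cycles, nrow(x$streams$left),
              x$sample_rate))
  cat(sprintf("  noise sd: force %g, angle %g deg\n",
              x$noise_sd[["force"]], x$noise_sd[["angle"]]))
  invisible(x)
}
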