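# End-to-end closed loop: sensors -> gait FSM -> reflexive controller ->
# iterative-learning adaptation, cycle by cycle, per leg.

#' Run the adaptive reflexive controller over a synthetic session
#'
#' For each leg the stream is passed through [detect_stream()]; every detected
#' gait cycle is stimulated with the current time coefficients and pulse
#' widths, the cycle's stimulation times and toe-off shank angle are measured
#' from the commanded trace, and [record_cycle()] adapts the parameters for
#' the next cycle. With `adapt = FALSE` the parameters stay fixed (purely
#' reflexive control).
#'
#' @param session An [generate_protocol()] session, or a named list of sensor
#'   streams (`left`/`right` data frames with `t, heel, toe, shank_angle`).
#' @param calibration An `fes_calibration` covering every `side.muscle`
#'   channel present.
#' @param state An [adaptive_state()]; defaults to one built from
#'   `calibration`.
#' @param config An [fsm_config()].
#' @param adapt Apply the iterative-learning updates (`TRUE`) or run purely
#'   reflexively (`FALSE`).
#' @param keep_trace Keep the full stimulation trace (one row per channel per
#'   tick) in the result.
#' @return A list of class `fes_run`: `stimulation` (data frame
#'   `t, side, muscle, amplitude_mA, pulse_width_us`), `adaptation` (data
#'   frame `cycle, side, muscle, speed, t_s, phi_to, tau, pw`, one row per
#'   channel per completed cycle), `detection` (per-side [detect_stream()]
#'   results), `evaluation` (per-side [evaluate_detection()] tables when the
#'   session carries ground truth), `state` (final [adaptive_state()]).
#' @export
closed_loop_run <- function(session, calibration = default_calibration(),
                            state = NULL, config = fsm_config(),
                            adapt = TRUE, keep_trace = TRUE) {
  streams <- if (inherits(session, "fes_gait_session")) session$streams
             else session
  truth <- if (inherits(session, "fes_gait_session")) session$truth else NULL
  if (is.null(state)) state <- adaptive_state(calibration)

  need <- as.vector(outer(names(streams), .MUSCLES, paste, sep = "."))
  missing_ch <- setdiff(need, names(calibration))
  if (length(missing_ch)) {
    stop("calibration is missing channels: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }

  detections <- list()
  evaluation <- list()
  stim_rows <- list()
  adapt_rows <- list()

  for (side in names(streams)) {
    det <- detect_stream(streams[[side]], config)
    detections[[side]] <- det
    b <- det$cycles
    tt <- det$phases$t
    ph <- det$phases$phase
    n_cycles <- max(0L, length(b) - 1L)
    for (k in seq_len(n_cycles)) {
      idx <- which(tt >= b[k] & tt < b[k + 1L])
      win_t <- tt[idx]
      win_ph <- ph[idx]
      imps <- det$impulses[det$impulses$t >= b[k] &
                             det$impulses$t < b[k + 1L], , drop = FALSE]
      to_t <- det$events$t[det$events$kind == "TO" &
                             det$events$t >= b[k] & det$events$t < b[k + 1L]]
      phi <- if (length(to_t)) {
        streams[[side]]$shank_angle[which.min(abs(tt - to_t[1L]))]
      } else NA_real_

      t_s <- numeric(0)
      for (m in .MUSCLES) {
        key <- paste(side, m, sep = ".")
        cfg <- calibration[[key]]
        amp <- .stim_trace(win_t, win_ph, imps, cfg, tau = state$tau[[key]])
        pw_now <- if (m == "LG") state$pw[[side]] else cfg$pulse_width
        stim_rows[[paste(side, m, k)]] <- data.frame(
          t = win_t, side = side, muscle = m, amplitude_mA = amp,
          pulse_width_us = pw_now, stringsAsFactors = FALSE)
        t_s[[key]] <- measure_stimulation_time(amp, cfg$c_min, det$dt)
        adapt_rows[[paste(side, m, k)]] <- data.frame(
          cycle = k, side = side, muscle = m,
          speed = if (!is.null(truth)) truth[[side]]$speed[k] else NA_real_,
          t_s = t_s[[key]], phi_to = phi,
          tau = unname(state$tau[[key]]),
          pw = unname(pw_now), stringsAsFactors = FALSE)
      }
      if (adapt) {
        phi_vec <- if (is.finite(phi)) stats::setNames(phi, side)
                   else numeric(0)
        state <- record_cycle(state, t_s = t_s, phi_to = phi_vec)
      }
    }
    if (!is.null(truth)) {
      evaluation[[side]] <- evaluate_detection(det$events,
                                               truth[[side]]$events,
                                               tol = 0.05)
    }
  }

  stimulation <- if (keep_trace && length(stim_rows)) {
    res <- do.call(rbind, stim_rows)
    rownames(res) <- NULL
    res
  } else NULL
  adaptation <- if (length(adapt_rows)) {
    res <- do.call(rbind, adapt_rows)
    rownames(res) <- NULL
    res
  } else {
    data.frame(cycle = integer(0), side = character(0), muscle = character(0),
               speed = numeric(0), t_s = numeric(0), phi_to = numeric(0),
               tau = numeric(0), pw = numeric(0))
  }

  structure(list(stimulation = stimulation, adaptation = adaptation,
                 detection = detections, evaluation = evaluation,
                 state = state, calibration = calibration,
                 adapt = adapt,
                 session = if (inherits(session, "fes_gait_session"))
                   session[c("protocol", "n_cycles", "sample_rate")]
                 else NULL),
            class = "fes_run")
}

#' @export
print.fes_run <- function(x, ...) {
  n_cyc <- if (nrow(x$adaptation)) max(x$adaptation$cycle) else 0L
  cat(sprintf("Closed-loop FES run (%s): %d gait cycles per leg\n",
              if (x$adapt) "adaptive reflexive" else "purely reflexive",
              n_cyc))
  if (length(x$evaluation)) {
    for (side in names(x$evaluation)) {
      ev <- x$evaluation[[side]]
      cat(sprintf("  %s event detection: %.1f%% recall, mean |latency| %.1f ms\n",
                  side, mean(ev$accuracy_pct, na.rm = TRUE),
                  mean(abs(ev$mean_latency_ms), na.rm = TRUE)))
    }
  }
  cat("  final parameters:\n")
  print(x$state)
  invisible(x)
}

#' @export
summary.fes_run <- function(object, ...) {
  summarize_session(object)
}

#' @export
plot.fes_run <- function(x, side = "left", cycles = 1:3, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  stim <- x$stimulation
  if (!is.null(stim)) {
    det <- x$detection[[side]]
    b <- det$cycles
    kmax <- min(max(cycles), length(b) - 1L)
    win <- c(b[min(cycles)], b[kmax + 1L])
    s <- stim[stim$side == side & stim$t >= win[1] & stim$t < win[2], ]
    graphics::plot(NA, xlim = win, ylim = c(0, max(s$amplitude_mA) * 1.05),
                   xlab = "time (s)", ylab = "amplitude (mA)",
                   main = paste(side, "stimulation sequences"))
    cols <- c(TA = 1, LG = 2, BF = 3, RF = 4)
    for (m in names(cols)) {
      sm <- s[s$muscle == m, ]
      graphics::lines(sm$t, sm$amplitude_mA, col = cols[[m]])
    }
    graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  ad <- x$adaptation[x$adaptation$side == side, ]
  if (nrow(ad)) {
    ta <- ad[ad$muscle == "TA", ]
    graphics::plot(ta$cycle, ta$tau, type = "s", xlab = "gait cycle",
                   ylab = "tau (s)", main = paste(side, "TA time coefficient"))
    lg <- ad[ad$muscle == "LG", ]
    graphics::plot(lg$cycle, lg$pw, type = "s", xlab = "gait cycle",
                   ylab = "pulse width (us)",
                   main = paste(side, "LG pulse width"))
  }
  invisible(x)
}
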