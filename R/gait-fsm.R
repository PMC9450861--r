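# Gait-phase detection: adaptive-threshold binarization of heel/toe force and
# shank angle, and a rule-based (IF-THEN) finite state machine over the binary
# signals S_H (heel contact), S_T (toe contact), S_phi (shank angle past the
# sagittal threshold, evaluated only during swing).
#
# Phases: LR (load response), ST (stance), PS (pre-swing), SW (swing),
# TSW (terminal swing). Events: HS, FF, HO, TO, STA. Impulses for the
# controller: I_LR, I_PS, I_SW, I_TSW.

.PHASES <- c("LR", "ST", "PS", "SW", "TSW")
.EVENTS <- c("HS", "FF", "HO", "TO", "STA")
.IMPULSES <- c("I_LR", "I_PS", "I_SW", "I_TSW")

#' Configuration of the gait-phase detector
#'
#' @param theta_on,theta_off Hysteresis thresholds for foot-contact
#'   binarization, as fractions of the decayed running maximum force. A sensor
#'   switches on above `theta_on * max` and off below `theta_off * max`.
#' @param sta_threshold Sagittal threshold angle (degrees, positive = shank
#'   rotated forward): `S_phi = 1` when the shank angle reaches it during
#'   swing.
#' @param decay_cycles,cycle_hint Horizon of the exponentially decayed running
#'   maximum, expressed as a number of nominal gait cycles of `cycle_hint`
#'   seconds; keeps the thresholds tracking slow drift in contact force.
#' @param debounce_samples A binary signal must hold a new value for this many
#'   consecutive samples before the edge is accepted (FSR chatter rejection);
#'   the accepted edge keeps the time of its first sample.
#' @param ff_debounce Seconds both sensors must remain in contact before load
#'   response ends and foot flat (FF) is declared.
#' @return A list of class `fsm_config`.
#' @export
fsm_config <- function(theta_on = 0.20, theta_off = 0.10, sta_threshold = 15,
                       decay_cycles = 3, cycle_hint = 1.2,
                       debounce_samples = 2L, ff_debounce = 0.05) {
  stopifnot(theta_on > theta_off, theta_off > 0, theta_on < 1,
            sta_threshold > 0, decay_cycles > 0, cycle_hint > 0,
            debounce_samples >= 1L, ff_debounce >= 0)
  structure(list(theta_on = theta_on, theta_off = theta_off,
                 sta_threshold = sta_threshold, decay_cycles = decay_cycles,
                 cycle_hint = cycle_hint,
                 debounce_samples = as.integer(debounce_samples),
                 ff_debounce = ff_debounce),
            class = "fsm_config")
}

#' Threshold state for per-sample binarization
#'
#' Holds the running force maxima and current hysteresis bits. Seed the maxima
#' from a calibration pass (or at least one observed cycle) so the relative
#' thresholds are meaningful from the first sample.
#'
#' @param heel_max,toe_max Seed values for the running maxima (force units).
#' @param dt Sample period, seconds.
#' @param config An [fsm_config()].
#' @return A list of class `binarize_state`.
#' @export
binarize_state <- function(heel_max, toe_max, dt = 0.01,
                           config = fsm_config()) {
  stopifnot(is.finite(heel_max), heel_max > 0, is.finite(toe_max),
            toe_max > 0, dt > 0)
  decay <- exp(-dt / (config$decay_cycles * config$cycle_hint))
  structure(list(heel_max = heel_max, toe_max = toe_max, decay = decay,
                 S_H = 0L, S_T = 0L, config = config),
            class = "binarize_state")
}

#' Binarize one sensor sample
#'
#' Applies relative hysteresis to the heel and toe forces (thresholds are
#' fractions of a decayed running maximum, so the bits are invariant under
#' rescaling of the force units) and thresholds the shank angle against the
#' sagittal threshold angle. `S_phi` is computed unconditionally here; the FSM
#' only interprets it during swing.
#'
#' @param heel,toe Non-negative contact forces (arbitrary units).
#' @param shank_angle Sagittal shank angle, degrees.
#' @param state A [binarize_state()].
#' @return `list(bits = c(S_H, S_T, S_phi), state = <updated state>)`.
#' @export
binarize <- function(heel, toe, shank_angle, state) {
  if (any(!is.finite(c(heel, toe, shank_angle))) || heel < 0 || toe < 0) {
    stop("sample values must be finite and forces non-negative", call. = FALSE)
  }
  cfg <- state$config
  state$heel_max <- max(heel, state$heel_max * state$decay)
  state$toe_max <- max(toe, state$toe_max * state$decay)
  state$S_H <- .hyst_step(state$S_H, heel, state$heel_max, cfg)
  state$S_T <- .hyst_step(state$S_T, toe, state$toe_max, cfg)
  bits <- c(S_H = state$S_H, S_T = state$S_T,
            S_phi = as.integer(shank_angle >= cfg$sta_threshold))
  list(bits = bits, state = state)
}

.hyst_step <- function(bit, x, xmax, cfg) {
  if (bit == 0L && x >= cfg$theta_on * xmax) 1L
  else if (bit == 1L && x <= cfg$theta_off * xmax) 0L
  else bit
}

# Debounce a 0/1 sequence: a run shorter than k samples cannot flip the
# committed value; an accepted flip takes effect at the run's first sample.
.debounce_bits <- function(b, k) {
  if (k <= 1L || length(b) < 2L) return(b)
  r <- rle(b)
  vals <- r$values
  cur <- vals[1L]
  for (j in seq_along(vals)) {
    if (r$lengths[j] >= k) cur <- r$values[j]
    vals[j] <- cur
  }
  inverse.rle(list(lengths = r$lengths, values = vals))
}

# Exponentially decayed running maximum.
.running_max <- function(x, seed, decay) {
  n <- length(x)
  out <- numeric(n)
  m <- seed
  for (i in seq_len(n)) {
    m <- max(x[i], m * decay)
    out[i] <- m
  }
  out
}

# Hysteresis bits over a whole stream given the running maxima.
.hysteresis_bits <- function(x, rmax, theta_on, theta_off) {
  n <- length(x)
  b <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cur == 0L && x[i] >= theta_on * rmax[i]) cur <- 1L
    else if (cur == 1L && x[i] <= theta_off * rmax[i]) cur <- 0L
    b[i] <- cur
  }
  b
}

#' Initial FSM state
#'
#' @param phase Starting gait phase.
#' @param bits Starting binary inputs `c(S_H, S_T, S_phi)`.
#' @param config An [fsm_config()].
#' @return A list of class `fsm_state`.
#' @export
fsm_state <- function(phase = "SW", bits = c(S_H = 0L, S_T = 0L, S_phi = 0L),
                      config = fsm_config()) {
  phase <- match.arg(phase, .PHASES)
  structure(list(phase = phase, prev = bits, both_since = NA_real_,
                 sta_armed = FALSE, config = config),
            class = "fsm_state")
}

#' Advance the gait finite state machine by one sample
#'
#' Implements the four printed bit-pattern transitions plus the foot-flat
#' debounce:
#' * no contact -> any contact: phase LR, impulse `I_LR`, event `HS`;
#' * heel+toe contact -> toe only: phase PS, impulse `I_PS`, event `HO`;
#' * any contact -> no contact: phase SW, impulse `I_SW`, event `TO`;
#' * during swing, `S_phi` rising 0 -> 1 (after the angle has been observed
#'   below threshold in this swing): phase TSW, impulse `I_TSW`, event `STA`;
#' * LR -> ST once both sensors have been in contact for the foot-flat
#'   debounce window, event `FF`.
#'
#' Any other bit pattern keeps the current phase (robustness contract: the FSM
#' never errors on unexpected input).
#'
#' @param state An [fsm_state()].
#' @param bits Current binary inputs `c(S_H, S_T, S_phi)` (already debounced).
#' @param t Sample time, seconds.
#' @return `list(state, phase, events, impulses)`; `events`/`impulses` are
#'   character vectors (possibly empty).
#' @export
step_fsm <- function(state, bits, t) {
  cfg <- state$config
  p <- state$prev
  events <- character(0)
  impulses <- character(0)
  phase <- state$phase

  contact_prev <- p[["S_H"]] == 1L || p[["S_T"]] == 1L
  contact_cur <- bits[["S_H"]] == 1L || bits[["S_T"]] == 1L

  if (!contact_prev && contact_cur) {
    phase <- "LR"
    impulses <- "I_LR"
    events <- "HS"
    state$both_since <- NA_real_
    state$sta_armed <- FALSE
  } else if (p[["S_H"]] == 1L && p[["S_T"]] == 1L &&
             bits[["S_H"]] == 0L && bits[["S_T"]] == 1L) {
    phase <- "PS"
    impulses <- "I_PS"
    events <- "HO"
  } else if (contact_prev && !contact_cur) {
    phase <- "SW"
    impulses <- "I_SW"
    events <- "TO"
    state$sta_armed <- FALSE
  } else if (!contact_prev && !contact_cur) {
    if (bits[["S_phi"]] == 0L) state$sta_armed <- TRUE
    if (phase == "SW" && state$sta_armed &&
        p[["S_phi"]] == 0L && bits[["S_phi"]] == 1L) {
      phase <- "TSW"
      impulses <- "I_TSW"
      events <- "STA"
      state$sta_armed <- FALSE
    }
  }

  # LR ends when both sensors have stayed in contact for the debounce window.
  if (phase == "LR") {
    if (bits[["S_H"]] == 1L && bits[["S_T"]] == 1L) {
      if (is.na(state$both_since)) state$both_since <- t
      if (t - state$both_since >= cfg$ff_debounce - 1e-9) {
        phase <- "ST"
        events <- c(events, "FF")
      }
    } else {
      state$both_since <- NA_real_
    }
  }

  state$phase <- phase
  state$prev <- bits
  list(state = state, phase = phase, events = events, impulses = impulses)
}

#' Detect gait phases, events and impulses over a sensor stream
#'
#' Runs the adaptive-threshold binarizer (with edge debouncing) and the gait
#' FSM over one leg's stream. Gait-cycle boundaries are the heel strikes where
#' the heel lands first (`S_H = 1, S_T = 0`); if no heel-first strike occurs
#' (forefoot-first pathological gait) any initial-contact impulse serves as a
#' boundary.
#'
#' @param stream Data frame with columns `t` (seconds, strictly increasing),
#'   `heel`, `toe` (forces, arbitrary units), `shank_angle` (degrees).
#' @param config An [fsm_config()].
#' @return A list of class `gait_detection`: `phases` (data frame `t, phase`),
#'   `events` and `impulses` (data frames `t, kind`), `cycles` (numeric vector
#'   of boundary times; `n` boundaries delimit `n - 1` cycles), `bits`
#'   (debounced binary signals).
#' @export
detect_stream <- function(stream, config = fsm_config()) {
  req <- c("t", "heel", "toe", "shank_angle")
  if (!is.data.frame(stream) || !all(req %in% names(stream))) {
    stop("`stream` must be a data frame with columns t, heel, toe, shank_angle",
         call. = FALSE)
  }
  t <- stream$t
  n <- length(t)
  if (n < 2L || any(diff(t) <= 0)) {
    stop("`stream$t` must be strictly increasing with >= 2 samples",
         call. = FALSE)
  }
  if (any(!is.finite(as.matrix(stream[req])))) {
    stop("stream contains non-finite values", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  decay <- exp(-dt / (config$decay_cycles * config$cycle_hint))

  # Seed running maxima from the first nominal cycle (floor avoids 0/0 on
  # all-zero streams, for which no bit ever turns on).
  head_idx <- t <= t[1L] + config$cycle_hint
  seed_h <- max(stream$heel[head_idx], 1e-12)
  seed_t <- max(stream$toe[head_idx], 1e-12)

  rb_h <- .hysteresis_bits(stream$heel,
                           .running_max(stream$heel, seed_h, decay),
                           config$theta_on, config$theta_off)
  rb_t <- .hysteresis_bits(stream$toe,
                           .running_max(stream$toe, seed_t, decay),
                           config$theta_on, config$theta_off)
  rb_p <- as.integer(stream$shank_angle >= config$sta_threshold)

  k <- config$debounce_samples
  b_h <- .debounce_bits(rb_h, k)
  b_t <- .debounce_bits(rb_t, k)
  b_p <- .debounce_bits(rb_p, k)

  phase0 <- if (b_h[1L] == 1L && b_t[1L] == 1L) "ST"
            else if (b_h[1L] == 1L || b_t[1L] == 1L) "LR"
            else "SW"
  st <- fsm_state(phase = phase0,
                  bits = c(S_H = b_h[1L], S_T = b_t[1L], S_phi = b_p[1L]),
                  config = config)
  if (phase0 == "LR" && b_h[1L] == 1L && b_t[1L] == 1L) st$both_since <- t[1L]

  phases <- character(n)
  phases[1L] <- phase0
  ev_t <- ev_k <- im_t <- im_k <- list()
  heel_only <- logical(0)
  for (i in 2:n) {
    bits <- c(S_H = b_h[i], S_T = b_t[i], S_phi = b_p[i])
    out <- step_fsm(st, bits, t[i])
    st <- out$state
    phases[i] <- out$phase
    if (length(out$events)) {
      ev_t <- c(ev_t, list(rep(t[i], length(out$events))))
      ev_k <- c(ev_k, list(out$events))
    }
    if (length(out$impulses)) {
      im_t <- c(im_t, list(rep(t[i], length(out$impulses))))
      im_k <- c(im_k, list(out$impulses))
      if ("I_LR" %in% out$impulses) {
        heel_only <- c(heel_only, b_h[i] == 1L && b_t[i] == 0L)
      }
    }
  }
  events <- data.frame(t = unlist(ev_t) %||% numeric(0),
                       kind = unlist(ev_k) %||% character(0),
                       stringsAsFactors = FALSE)
  impulses <- data.frame(t = unlist(im_t) %||% numeric(0),
                         kind = unlist(im_k) %||% character(0),
                         stringsAsFactors = FALSE)
  ilr <- impulses$t[impulses$kind == "I_LR"]
  cycles <- if (any(heel_only)) ilr[heel_only] else ilr

  structure(list(phases = data.frame(t = t, phase = phases,
                                     stringsAsFactors = FALSE),
                 events = events, impulses = impulses, cycles = cycles,
                 bits = data.frame(t = t, S_H = b_h, S_T = b_t, S_phi = b_p),
                 dt = dt, config = config),
            class = "gait_detection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_detection <- function(x, ...) {
  cat(sprintf("Gait detection over %.1f s: %d events, %d impulses, %d gait cycles\n",
              diff(range(x$phases$t)), nrow(x$events), nrow(x$impulses),
              max(0L, length(x$cycles) - 1L)))
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}

#' Compare detected gait events with ground truth
#'
#' Greedy one-to-one matching per event kind: truth events are visited in time
#' order and each takes the nearest unmatched detection of the same kind
#' within `tol`. Accuracy is the per-kind recall (matched / truth, percent);
#' latency is the mean signed `detected - truth` over matches, in
#' milliseconds.
#'
#' @param detected,truth Data frames with columns `t` (seconds) and `kind`.
#' @param tol Matching tolerance, seconds (> 0).
#' @return Data frame with one row per event kind present in `truth`:
#'   `kind, n_truth, n_detected, n_matched, accuracy_pct, mean_latency_ms`.
#'   `accuracy_pct` is `NA` for kinds with no truth events.
#' @export
evaluate_detection <- function(detected, truth, tol = 0.05) {
  stopifnot(is.data.frame(detected), is.data.frame(truth), tol > 0)
  kinds <- unique(truth$kind)
  rows <- lapply(kinds, function(k) {
    tt <- sort(truth$t[truth$kind == k])
    dd <- sort(detected$t[detected$kind == k])
    used <- rep(FALSE, length(dd))
    lat <- numeric(0)
    for (tv in tt) {
      cand <- which(!used & abs(dd - tv) <= tol)
      if (length(cand)) {
        j <- cand[which.min(abs(dd[cand] - tv))]
        used[j] <- TRUE
        lat <- c(lat, dd[j] - tv)
      }
    }
    data.frame(kind = k, n_truth = length(tt), n_detected = length(dd),
               n_matched = length(lat),
               accuracy_pct = if (length(tt)) 100 * length(lat) / length(tt)
                              else NA_real_,
               mean_latency_ms = if (length(lat)) 1000 * mean(lat)
                                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(kind = character(0), n_truth = integer(0),
                      n_detected = integer(0), n_matched = integer(0),
                      accuracy_pct = numeric(0), mean_latency_ms = numeric(0)))
  }
  do.call(rbind, rows)
}
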