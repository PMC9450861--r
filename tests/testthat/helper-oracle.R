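# Independent brute-force oracle for the reflexive controller: a per-sample
# scan over the impulse list applying the stimulation equations directly,
# with its own copy of the envelope formula and channel wiring. Kept separate
# from the package implementation on purpose.

oracle_envelope <- function(t, tau) {
  g <- tau * sqrt(2) * exp(pi / 4)
  h <- (g / tau) * exp(-1.5 * t / tau) * sin(1.5 * t / tau)
  h[t < 0 | t > 2 * pi * tau / 3] <- 0
  pmax(h, 0)
}

oracle_branches <- list(
  TA = list(list(trigger = "I_SW", phases = c("SW", "TSW"))),
  LG = list(list(trigger = "I_LR", phases = "LR"),
            list(trigger = "I_PS", phases = "PS")),
  BF = list(list(trigger = "I_SW", phases = c("SW", "TSW"))),
  RF = list(list(trigger = "I_LR", phases = "LR"),
            list(trigger = "I_TSW", phases = "TSW")))

oracle_amplitude <- function(times, phases, impulses, muscle,
                             c_min, c_max, tau) {
  dc <- c_max - c_min
  vapply(seq_along(times), function(i) {
    amp <- 0
    for (br in oracle_branches[[muscle]]) {
      if (!phases[i] %in% br$phases) next
      it <- impulses$t[impulses$kind == br$trigger & impulses$t <= times[i]]
      env <- if (length(it)) oracle_envelope(times[i] - max(it), tau) else 0
      amp <- amp + dc * env + c_min
    }
    min(max(amp, 0), c_max)
  }, numeric(1))
}

# Random controller instance: piecewise-constant phase sequence and random
# impulse trains over a ~10-cycle window.
random_instance <- function(seed, duration = 10, fs = 100) {
  set.seed(seed)
  times <- seq(0, duration, by = 1 / fs)
  n_seg <- sample(8:20, 1)
  breaks <- c(0, sort(runif(n_seg - 1, 0, duration)), duration)
  seg_phase <- sample(c("LR", "ST", "PS", "SW", "TSW"), n_seg, replace = TRUE)
  phases <- seg_phase[findInterval(times, breaks, rightmost.closed = TRUE)]
  imp <- do.call(rbind, lapply(c("I_LR", "I_PS", "I_SW", "I_TSW"),
                               function(k) {
    data.frame(t = sort(runif(sample(2:8, 1), 0, duration)), kind = k,
               stringsAsFactors = FALSE)
  }))
  imp <- imp[order(imp$t), ]
  rownames(imp) <- NULL
  list(times = times, phases = phases, impulses = imp)
}

fake_detection <- function(times, phases, impulses) {
  structure(list(phases = data.frame(t = times, phase = phases,
                                     stringsAsFactors = FALSE),
                 impulses = impulses),
            class = "gait_detection")
}

# Small noise-free labeled session shared across test files.
small_session <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- generate_protocol(speed_protocol(1.0, 1.4, 0.2, 3), seed = 42)
    }
    memo
  }
})
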