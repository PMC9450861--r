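# Reflexive controller: phase gates, channel amplitudes, eight-channel
# sequence generation, and equivalence with the brute-force oracle.

test_that("state gates implement the phase switching table", {
  expect_identical(state_gate("TA", "SW", "SW"), 1L)
  expect_identical(state_gate("TA", "SW", "TSW"), 1L)
  expect_identical(state_gate("TA", "SW", "ST"), 0L)
  expect_identical(state_gate("BF", "SW", "SW"), 1L)
  expect_identical(state_gate("LG", "LR", "LR"), 1L)
  expect_identical(state_gate("LG", "LR", "PS"), 0L)
  expect_identical(state_gate("LG", "PS", "PS"), 1L)
  expect_identical(state_gate("RF", "LR", "LR"), 1L)
  expect_identical(state_gate("RF", "TSW", "TSW"), 1L)
  expect_identical(state_gate("RF", "TSW", "LR"), 0L)
  expect_error(state_gate("TA", "LR", "SW"), "branch")
  expect_error(state_gate("LG", "LR", "XX"), "phase")
})

test_that("LG's two branch gates are never simultaneously on", {
  for (ph in c("LR", "ST", "PS", "SW", "TSW")) {
    expect_lte(state_gate("LG", "LR", ph) + state_gate("LG", "PS", ph), 1L)
  }
})

test_that("channel amplitude follows envelope * range + C_min, gated", {
  cfg <- channel_config("TA", "left", c_min = 15, c_max = 30, tau = 0.1)
  imp <- data.frame(t = 1.0, kind = "I_SW")
  # gate off -> 0 regardless of the envelope
  expect_identical(channel_amplitude(cfg, "ST", 1.0 + peak_time(0.1), imp), 0)
  # at the impulse instant the envelope is zero -> C_min
  expect_equal(channel_amplitude(cfg, "SW", 1.0, imp), 15)
  # at the envelope peak -> C_max
  expect_equal(channel_amplitude(cfg, "SW", 1.0 + peak_time(0.1), imp), 30,
               tolerance = 1e-9)
  # gate on, no impulse -> rests at C_min
  expect_equal(channel_amplitude(cfg, "SW", 1.0), 15)
  # a later impulse restarts the envelope
  imp2 <- rbind(imp, data.frame(t = 1.02, kind = "I_SW"))
  expect_equal(channel_amplitude(cfg, "SW", 1.02 + peak_time(0.1), imp2), 30,
               tolerance = 1e-9)
})

test_that("a full gait cycle gives two bursts on LG and RF, one on TA and BF", {
  s <- generate_protocol(speed_protocol(1.0, 1.0, cycles_per_level = 2),
                         seed = 3)
  det <- detect_stream(s$streams$left)
  stim <- reflexive_stimulation(list(left = det))
  cal <- default_calibration()
  count_bursts <- function(muscle) {
    x <- stim[stim$muscle == muscle & stim$t >= det$cycles[1] &
                stim$t < det$cycles[2], "amplitude_mA"]
    on <- x > cal[[paste0("left.", muscle)]]$c_min + 1e-9
    sum(diff(c(FALSE, on)) == 1)
  }
  expect_identical(count_bursts("LG"), 2L)  # I_LR and I_PS branches
  expect_identical(count_bursts("RF"), 2L)  # I_LR and I_TSW branches
  expect_identical(count_bursts("TA"), 1L)  # I_SW
  expect_identical(count_bursts("BF"), 1L)
  # mid-stance: all TA gates off -> amplitude 0
  st_t <- det$phases$t[det$phases$phase == "ST"][5]
  ta <- stim[stim$muscle == "TA" & stim$t == st_t, "amplitude_mA"]
  expect_identical(ta, 0)
})

test_that("controller output equals the brute-force oracle on random instances", {
  cal <- default_calibration()
  for (seed in c(11, 12, 13, 14)) {
    inst <- random_instance(seed)
    det <- fake_detection(inst$times, inst$phases, inst$impulses)
    stim <- reflexive_stimulation(list(left = det), cal)
    for (m in c("TA", "LG", "BF", "RF")) {
      cfg <- cal[[paste0("left.", m)]]
      got <- stim[stim$muscle == m, "amplitude_mA"]
      want <- oracle_amplitude(inst$times, inst$phases, inst$impulses, m,
                               cfg$c_min, cfg$c_max, cfg$tau)
      expect_lt(max(abs(got - want)), 1e-9)
      # bounds invariant
      expect_true(all(got >= 0 & got <= cfg$c_max + 1e-12))
    }
  }
})

test_that("without impulses every channel rests at C_min times its gate", {
  cal <- default_calibration()
  times <- seq(0, 2, by = 0.01)
  phases <- rep(c("LR", "ST", "PS", "SW", "TSW"), length.out = length(times))
  det <- fake_detection(times, phases,
                        data.frame(t = numeric(0), kind = character(0)))
  stim <- reflexive_stimulation(list(left = det), cal)
  for (m in c("TA", "LG", "BF", "RF")) {
    cfg <- cal[[paste0("left.", m)]]
    got <- stim[stim$muscle == m, "amplitude_mA"]
    gate <- switch(m,
                   TA = , BF = phases %in% c("SW", "TSW"),
                   LG = phases %in% c("LR", "PS"),
                   RF = phases %in% c("LR", "TSW"))
    expect_equal(got, cfg$c_min * as.numeric(gate))
  }
})

test_that("the streaming tick matches the vectorized controller", {
  inst <- random_instance(21, duration = 4)
  # the streaming controller restarts envelopes at tick times, so align the
  # impulse train to the sample grid for an exact comparison
  inst$impulses$t <- round(inst$impulses$t, 2)
  inst$impulses <- inst$impulses[order(inst$impulses$t), ]
  cal <- default_calibration()
  det <- fake_detection(inst$times, inst$phases, inst$impulses)
  stim <- reflexive_stimulation(list(left = det), cal)
  ctrl <- controller_state(cal)
  for (i in seq_along(inst$times)) {
    now <- inst$impulses[abs(inst$impulses$t - inst$times[i]) < 1e-9, ,
                         drop = FALSE]
    if (nrow(now)) now$side <- "left"
    out <- controller_tick(ctrl, inst$times[i],
                           c(left = inst$phases[i]),
                           if (nrow(now)) now else NULL)
    ctrl <- out$ctrl
    for (m in c("TA", "LG", "BF", "RF")) {
      want <- stim[stim$muscle == m, "amplitude_mA"][i]
      got <- out$commands$amplitude_mA[out$commands$muscle == m]
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("calibration validates its invariants and round-trips through YAML", {
  expect_error(channel_config("TA", "left", c_min = 30, c_max = 15), "c_max")
  expect_error(channel_config("LG", "left", 12, 28, pulse_width = 200),
               "250")
  cfg <- channel_config("LG", "right", 12, 28, pulse_width = 400)
  expect_equal(cfg$delta_c, 16)
  cal <- default_calibration(tau = 0.2)
  path <- tempfile(fileext = ".yaml")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2, cal)
  expect_error(reflexive_stimulation(
    list(left = fake_detection(0:1, c("ST", "ST"),
                               data.frame(t = numeric(0),
                                          kind = character(0)))),
    structure(cal[1:3], class = "fes_calibration")), "missing channels")
})
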