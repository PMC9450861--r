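# Iterative-learning adaptation: stimulation-time measurement, five-cycle
# history, dead-zone step updates, clamping, and independence properties.

test_that("stimulation time counts samples above the resting level", {
  dt <- 0.01
  # gate on for 0.25 s with a positive envelope throughout
  amp <- c(rep(20, 25), rep(0, 25))
  expect_equal(measure_stimulation_time(amp, c_min = 15, dt = dt), 0.25)
  expect_equal(measure_stimulation_time(rep(0, 100), 15, dt), 0)
  expect_equal(measure_stimulation_time(numeric(0), 15, dt), 0)
  # time at exactly C_min (gate on, envelope zero) does not count
  expect_equal(measure_stimulation_time(rep(15, 50), 15, dt), 0)
  # envelope truncated by an early gate-off at 0.6 of the activation lobe
  tau <- 0.2
  tt <- seq(0, activation_duration(tau), by = dt)
  cut <- 0.6 * activation_duration(tau)
  amp <- ifelse(tt < cut, 15 + 10 * impulse_response(tau, tt), 0)
  got <- measure_stimulation_time(amp, 15, dt)
  expect_lt(abs(got - cut), dt + 1e-9)
})

test_that("history means require a full five-cycle buffer", {
  st <- adaptive_state()
  for (v in c(0.1, 0.2, 0.3, 0.4)) {
    st <- record_cycle(st, t_s = c(left.TA = v))
  }
  expect_true(is.na(mean_of_history(st, "left.TA")))   # warm-up
  st <- record_cycle(st, t_s = c(left.TA = 0.5))
  expect_equal(mean_of_history(st, "left.TA"), 0.3)
  st2 <- adaptive_state()
  for (i in 1:5) st2 <- record_cycle(st2, t_s = c(left.TA = 0.2))
  expect_equal(mean_of_history(st2, "left.TA"), 0.2)
  # ring buffer drops the oldest entry
  st <- record_cycle(st, t_s = c(left.TA = 0.6))
  expect_equal(mean_of_history(st, "left.TA"), 0.4)
  expect_error(mean_of_history(st, "left.XX"), "unknown")
})

test_that("tau updates by exactly L outside the dead zone and clamps at the bounds", {
  fill <- function(st, v = 0.30) {
    for (i in 1:5) st <- record_cycle(st, t_s = c(left.TA = v))
    st
  }
  st <- fill(adaptive_state(tau_init = 0.5))
  # shorter than average by 0.10 s -> tau + L
  expect_equal(update_tau(st, "left.TA", 0.20)$tau[["left.TA"]], 0.51)
  # longer than average -> tau - L
  expect_equal(update_tau(st, "left.TA", 0.40)$tau[["left.TA"]], 0.49)
  # inside the dead zone (|dt| <= 0.04 s) -> unchanged
  expect_identical(update_tau(st, "left.TA", 0.32)$tau[["left.TA"]], 0.5)
  expect_identical(update_tau(st, "left.TA", 0.28)$tau[["left.TA"]], 0.5)
  # the boundary itself is a no-op (strict inequalities); exercised with
  # exactly representable values so the comparison is not at float noise
  stb <- adaptive_state(tau_init = 0.5, dt_threshold = 0.0625)
  for (i in 1:5) stb <- record_cycle(stb, t_s = c(left.TA = 0.25))
  expect_identical(update_tau(stb, "left.TA", 0.3125)$tau[["left.TA"]], 0.5)
  expect_identical(update_tau(stb, "left.TA", 0.1875)$tau[["left.TA"]], 0.5)
  expect_equal(update_tau(stb, "left.TA", 0.3130)$tau[["left.TA"]], 0.49)
  # clamping at the upper bound
  st1 <- fill(adaptive_state(tau_init = 1.0))
  expect_identical(update_tau(st1, "left.TA", 0.20)$tau[["left.TA"]], 1.0)
  # warm-up: no update with a short history
  st3 <- adaptive_state(tau_init = 0.5)
  st3 <- record_cycle(st3, t_s = c(left.TA = 0.30))
  expect_identical(update_tau(st3, "left.TA", 0.20)$tau[["left.TA"]], 0.5)
  expect_error(update_tau(st, "left.XX", 0.2), "unknown")
})

test_that("the flip flag inverts the tau update direction only", {
  st <- adaptive_state(tau_init = 0.5, flip_tau_sign = TRUE)
  for (i in 1:5) st <- record_cycle(st, t_s = c(left.TA = 0.30))
  expect_equal(update_tau(st, "left.TA", 0.20)$tau[["left.TA"]], 0.49)
  expect_equal(update_tau(st, "left.TA", 0.40)$tau[["left.TA"]], 0.51)
  expect_identical(update_tau(st, "left.TA", 0.30)$tau[["left.TA"]], 0.5)
})

test_that("pulse width updates by exactly L_PW and clamps to [250, 500]", {
  fill <- function(st, v = 15) {
    for (i in 1:5) st <- record_cycle(st, phi_to = c(left = v))
    st
  }
  st <- fill(adaptive_state(pw_init = 300))
  expect_equal(update_pw(st, "left", 10)$pw[["left"]], 320)   # dphi = -5
  expect_equal(update_pw(st, "left", 20)$pw[["left"]], 280)   # dphi = +5
  expect_identical(update_pw(st, "left", 16)$pw[["left"]], 300) # dead zone
  expect_identical(update_pw(st, "left", 13)$pw[["left"]], 300) # boundary
  st5 <- fill(adaptive_state(pw_init = 500))
  expect_identical(update_pw(st5, "left", 10)$pw[["left"]], 500) # clamp
  expect_error(update_pw(st, "up", 10), "unknown side")
})

test_that("constant-sign forcing is monotone with unit steps until saturation", {
  st <- adaptive_state(tau_init = 0.5)
  for (i in 1:5) st <- record_cycle(st, t_s = c(left.TA = 0.30))
  taus <- numeric(200)
  for (i in 1:200) {
    st <- update_tau(st, "left.TA", 0.20)   # dt = -0.10 each cycle
    taus[i] <- st$tau[["left.TA"]]
  }
  steps <- diff(c(0.5, taus))
  expect_true(all(steps >= -1e-12))
  expect_true(all(abs(steps[steps > 1e-12] - 0.01) < 1e-12))
  expect_identical(taus[200], 1.0)
  expect_identical(taus[50], 1.0)  # bound reached after 50 steps

  st <- adaptive_state(pw_init = 500)
  for (i in 1:5) st <- record_cycle(st, phi_to = c(right = 15))
  pws <- numeric(50)
  for (i in 1:50) {
    st <- update_pw(st, "right", 20)        # dphi = +5 each cycle
    pws[i] <- st$pw[["right"]]
  }
  expect_identical(pws[13], 250)   # 13 steps of 20 us reach the lower bound
  expect_identical(pws[50], 250)
  expect_true(all(diff(pws) <= 0))
})

test_that("identical cycles leave the adapted parameters bit-identical", {
  st <- adaptive_state()
  for (i in 1:10) {
    st <- record_cycle(st, t_s = c(left.TA = 0.22, left.LG = 0.31,
                                   right.TA = 0.22, right.LG = 0.31),
                       phi_to = c(left = 14.2, right = 14.2))
  }
  ref <- adaptive_state()
  expect_identical(st$tau, ref$tau)
  expect_identical(st$pw, ref$pw)
})

test_that("channel updates are order-independent", {
  chans <- names(adaptive_state()$tau)
  set.seed(99)
  vals <- matrix(runif(8 * 12, 0.1, 0.5), nrow = 12,
                 dimnames = list(NULL, chans))
  run_order <- function(perm) {
    st <- adaptive_state()
    for (i in 1:12) {
      st <- record_cycle(st, t_s = stats::setNames(vals[i, perm], perm))
    }
    st$tau[sort(names(st$tau))]
  }
  base <- run_order(chans)
  for (s in 1:3) {
    set.seed(s)
    expect_identical(run_order(sample(chans)), base)
  }
})

test_that("tau and pulse width never leave their bounds under random forcing", {
  set.seed(7)
  st <- adaptive_state(tau_init = 0.05, pw_init = 260)
  for (i in 1:400) {
    st <- record_cycle(st,
                       t_s = c(left.TA = runif(1, 0, 1.2),
                               right.LG = runif(1, 0, 1.2)),
                       phi_to = c(left = runif(1, -30, 40)))
    expect_true(all(st$tau >= 0.01 & st$tau <= 1))
    expect_true(all(st$pw >= 250 & st$pw <= 500))
  }
})
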