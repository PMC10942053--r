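specs <- aisnav:::make_channel_specs()

test_that("NaV1.2 kinetics are the NaV1.6 kinetics right-shifted by 13 mV", {
  V <- seq(-100, 40, by = 5)
  for (g in c("m", "h")) {
    expect_equal(steady_state(specs$nav12$gating[[g]], V),
                 steady_state(specs$nav16$gating[[g]], V - 13),
                 tolerance = 1e-14)
    expect_equal(time_constant(specs$nav12$gating[[g]], V),
                 time_constant(specs$nav16$gating[[g]], V - 13),
                 tolerance = 1e-14)
  }
})

test_that("steady states saturate and translate correctly", {
  m <- specs$nav16$gating$m; h <- specs$nav16$gating$h
  expect_equal(steady_state(m, 200), 1, tolerance = 1e-10)
  expect_equal(steady_state(h, 200), 0, tolerance = 1e-10)
  expect_true(all(diff(steady_state(m, seq(-100, 50, 2))) > 0))
  expect_true(all(diff(steady_state(h, seq(-100, 50, 2))) < 0))
  # shifting delta_inf by +5 and evaluating at V+5 equals the unshifted value
  m5 <- m; m5$delta_inf <- 5
  expect_equal(steady_state(m5, -40 + 5), steady_state(m, -40),
               tolerance = 1e-14)
})

test_that("time constants are positive with one interior maximum that moves with delta_tau", {
  h <- specs$nav16$gating$h
  V <- seq(-150, 100, by = 0.01)
  tau <- time_constant(h, V)
  expect_true(all(tau > 0))
  i <- which.max(tau)
  expect_true(i > 1 && i < length(V))
  h7 <- h; h7$delta_tau <- 7
  expect_equal(V[which.max(time_constant(h7, V))], V[i] + 7,
               tolerance = 0.011)
  expect_equal(time_constant(h, V), time_constant(specs$nav16$gating$h, V))
})

test_that("rates and (steady state, time constant) are mutually consistent", {
  gv <- specs$nav16$gating$m
  V <- seq(-90, 30, by = 3)
  r <- rates_from_inf_tau(gv, V)
  expect_true(all(r$alpha >= 0) && all(r$beta >= 0))
  # algebraic round trip: u_inf = a/(a+b), tau = 1/(a+b)
  expect_equal(r$alpha / (r$alpha + r$beta), steady_state(gv, V),
               tolerance = 1e-13)
  expect_equal(1 / (r$alpha + r$beta), time_constant(gv, V),
               tolerance = 1e-13)
  # equivalence: shifting u_inf and tau together equals shifting the rate
  # arguments (the reference shift-clamp identity)
  gs <- gv; gs$delta_inf <- 6; gs$delta_tau <- 6
  rs <- rates_from_inf_tau(gs, V)
  r0 <- rates_from_inf_tau(gv, V - 6)
  expect_equal(rs$alpha, r0$alpha, tolerance = 1e-13)
  expect_equal(rs$beta, r0$beta, tolerance = 1e-13)
})

test_that("rates arithmetic matches hand values", {
  gv <- gating_variable("u", 1, list(vhalf = 0, k = 1),
                        list(base = 2, amp = 0, vmax = 0, w1 = 1, w2 = 1))
  r <- rates_from_inf_tau(gv, 0)   # u_inf = 0.5, tau = 2
  expect_equal(r$alpha, 0.25)
  expect_equal(r$beta, 0.25)
  r2 <- rates_from_inf_tau(gv, 1e4)  # u_inf -> 1
  expect_equal(r2$beta, 0, tolerance = 1e-12)
})

test_that("exponential-Euler gating update is exact, bounded and a semigroup", {
  gv <- specs$nav16$gating$h
  uinf <- steady_state(gv, -50)
  expect_equal(step_gating(uinf, -50, 0.1, gv), uinf, tolerance = 1e-14)
  expect_equal(step_gating(0.2, -50, 1e6, gv), uinf, tolerance = 1e-10)
  # two half steps equal one full step at fixed voltage
  full <- step_gating(0.3, -50, 0.2, gv)
  half <- step_gating(step_gating(0.3, -50, 0.1, gv), -50, 0.1, gv)
  expect_equal(half, full, tolerance = 1e-14)
  # stays in [0,1] along an arbitrary voltage trajectory
  set.seed(42)
  u <- 0.5
  for (V in runif(200, -120, 60)) {
    u <- step_gating(u, V, 0.25, gv)
    expect_true(u >= 0 && u <= 1)
  }
})

test_that("shift clamp touches exactly the named properties", {
  V <- seq(-90, 20, by = 5)
  # ALL with dVrs = -13 makes NaV1.2 coincide with NaV1.6
  all13 <- shift_clamp(specs$nav12, "all", -13)
  for (g in c("m", "h")) {
    expect_equal(steady_state(all13$gating[[g]], V),
                 steady_state(specs$nav16$gating[[g]], V), tolerance = 1e-14)
    expect_equal(time_constant(all13$gating[[g]], V),
                 time_constant(specs$nav16$gating[[g]], V), tolerance = 1e-14)
  }
  # TAU_H only moves the availability time constant
  th <- shift_clamp(specs$nav12, "tau_h", -5)
  expect_equal(steady_state(th$gating$h, V),
               steady_state(specs$nav12$gating$h, V), tolerance = 1e-14)
  expect_equal(steady_state(th$gating$m, V),
               steady_state(specs$nav12$gating$m, V), tolerance = 1e-14)
  expect_equal(time_constant(th$gating$m, V),
               time_constant(specs$nav12$gating$m, V), tolerance = 1e-14)
  expect_equal(time_constant(th$gating$h, V),
               time_constant(specs$nav12$gating$h, V + 5), tolerance = 1e-14)
  # dVrs = 0 is the identity for every condition, and the seven conditions
  # are mutually exclusive in the delta fields they touch
  for (cond in shift_conditions()) {
    z <- shift_clamp(specs$nav12, cond, 0)
    for (g in c("m", "h")) {
      expect_equal(steady_state(z$gating[[g]], V),
                   steady_state(specs$nav12$gating[[g]], V),
                   tolerance = 1e-14)
    }
  }
  touched <- sapply(shift_conditions(), function(cond) {
    s <- shift_clamp(specs$nav12, cond, 1)
    c(m_inf = s$gating$m$delta_inf, m_tau = s$gating$m$delta_tau,
      h_inf = s$gating$h$delta_inf, h_tau = s$gating$h$delta_tau)
  })
  expect_equal(unname(colSums(touched != 0)), c(4, 1, 1, 2, 1, 1, 2))
  expect_error(shift_clamp(specs$nav12, "bogus", 1))
  expect_error(shift_clamp(specs$nav16, "all", 1), "NaV1.2")
})
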