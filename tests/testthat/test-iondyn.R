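test_that("Nernst potential matches the closed form", {
  expect_equal(nernst(140, 140, 1, 310), 0)
  # K+ at body temperature, typical mammalian concentrations
  u <- 1e3 * 8.31446262 * 310 / 96485.33212
  expect_equal(nernst(140, 5, 1, 310), u * log(5 / 140), tolerance = 1e-12)
  expect_equal(nernst(140, 5, 1, 310), -89.0, tolerance = 0.1 / 89)
  # valence sign flip: chloride with swapped ratio equals the K+ value
  expect_equal(nernst(5, 140, -1, 310), nernst(140, 5, 1, 310),
               tolerance = 1e-12)
  expect_error(nernst(0, 5, 1), "positive")
  expect_error(nernst(5, -1, 1), "positive")
})

test_that("pump current has the Michaelis-Menten form and limits", {
  p <- list(imax = 0.02, km_k = 2, km_na = 10)
  # at both Michaelis constants the occupancy is (1/2)^2 (1/2)^3
  expect_equal(pump_current(2, 10, p), 0.02 / 32, tolerance = 1e-14)
  expect_equal(pump_current(1e9, 1e9, p), 0.02, tolerance = 1e-6)
  expect_equal(pump_current(5, 10, list(imax = 0, km_k = 2, km_na = 10)), 0)
  expect_true(pump_current(5, 10, p) > 0 && pump_current(5, 10, p) < p$imax)
  expect_error(pump_current(0, 10, p), "positive")
})

test_that("per-ion membrane currents follow the conductance-pump budget", {
  ions <- list(na_in = 10, na_out = 145, k_in = 140, k_out = 5,
               cl_in = 8.7, cl_out = 120)
  pump <- list(imax = 0.01, km_k = 2, km_na = 10)
  gates <- list(m12 = 0.2, h12 = 0.6, m16 = 0.3, h16 = 0.5, n = 0.1)
  # at V = E_K with only K channels and no pump, the K current vanishes
  ek <- nernst(140, 5, 1, 310)
  i <- membrane_currents(ek, gates,
                         list(nav12 = 0, nav16 = 0, kv = 0.1, leak_na = 0,
                              leak_k = 1e-4, leak_cl = 0),
                         ions, list(imax = 0, km_k = 2, km_na = 10))
  expect_equal(i$I_k, 0, tolerance = 1e-14)
  # with all conductances zero, only the pump's 3:2 stoichiometry remains
  ip <- pump_current(5, 10, pump)
  i0 <- membrane_currents(-70, gates,
                          list(nav12 = 0, nav16 = 0, kv = 0, leak_na = 0,
                               leak_k = 0, leak_cl = 0), ions, pump)
  expect_equal(i0$I_na, 3 * ip, tolerance = 1e-14)
  expect_equal(i0$I_k, -2 * ip, tolerance = 1e-14)
  expect_equal(i0$I_total, ip, tolerance = 1e-14)
  # m = 0 silences NaV regardless of availability (m^3 h form)
  im <- membrane_currents(0, list(m12 = 0, h12 = 1, m16 = 0, h16 = 1, n = 0),
                          list(nav12 = 1, nav16 = 1, kv = 0, leak_na = 0,
                               leak_k = 0, leak_cl = 0), ions,
                          list(imax = 0, km_k = 2, km_na = 10))
  expect_equal(im$I_na, 0)
})

chain_geom <- function(n, area = 1e-6, vol_in = 100, vol_out = 15,
                       ax = 1, ds = 10) {
  list(area = rep(area, n), vol_in = rep(vol_in, n), vol_out = rep(vol_out, n),
       parent = c(NA, seq_len(n - 1)), ax_in = c(NA, rep(ax, n - 1)),
       ax_out = c(NA, rep(ax * 0.15, n - 1)), ds = c(NA, rep(ds, n - 1)))
}

test_that("concentration update: fixed point, drift rate and conservation", {
  g <- chain_geom(4)
  # zero currents + uniform concentrations: exact fixed point
  r <- update_concentrations(rep(10, 4), rep(145, 4), rep(0, 4), g, 1.33, 0.025)
  expect_identical(r$conc_in, rep(10, 4))
  expect_identical(r$conc_out, rep(145, 4))
  # single compartment, constant outward current, no diffusion:
  # linear drift at rate A*I/(F*Vol)
  g1 <- chain_geom(1)
  I <- 0.5  # mA/cm^2
  r1 <- update_concentrations(10, 145, I, g1, 0, 0.025)
  rate <- 1e4 * (1e-6 * 1e8) * I / (96485.33212 * 100)  # mM/ms
  expect_equal(r1$conc_in, 10 - 0.025 * rate, tolerance = 1e-12)
  expect_equal(r1$conc_out, 145 + 0.025 * rate * (100 / 15), tolerance = 1e-9)
  # pure diffusion on a sealed chain conserves moles while the profile
  # relaxes toward the volume-weighted mean, with variance non-increasing
  g2 <- chain_geom(4, ds = 1)
  cin <- c(20, 10, 5, 1); cout <- rep(145, 4)
  moles0 <- sum(cin * g2$vol_in)
  vars <- numeric(0)
  for (i in 1:10000) {
    r <- update_concentrations(cin, cout, rep(0, 4), g2, 1.33, 0.025)
    cin <- r$conc_in
    if (i %% 1000 == 0) vars <- c(vars, stats::var(cin))
  }
  expect_lt(abs(sum(cin * g2$vol_in) - moles0) / moles0, 1e-10)
  expect_true(all(diff(vars) <= 0))
  expect_lt(stats::var(cin), 0.05 * stats::var(c(20, 10, 5, 1)))
  # a flux large enough to exhaust the pool raises a stability error
  expect_error(update_concentrations(0.01, 145, 50, g1, 0, 1), "dt")
})
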