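test_that("the axial operator is symmetric, zero-row-sum and tree-structured", {
  # two-compartment cable
  secs <- data.frame(name = "c2", kind = "basal", length = 20, diam0 = 2,
                     diam1 = 2, parent = NA, attach = NA, nseg = 2,
                     stringsAsFactors = FALSE)
  cab <- passive_cable(length_um = 20, diam = 2, nseg = 2)
  op <- assemble_operator(cab)
  g <- cab$comp$g_axial[2]
  expect_equal(op$L, matrix(c(g, -g, -g, g), 2, 2))
  # Y-branch: parent row couples to both children, Kirchhoff row sums zero
  cell <- default_cell()
  opc <- assemble_operator(cell)
  expect_equal(opc$L, t(opc$L))
  expect_equal(rowSums(opc$L), rep(0, nrow(cell$comp)), tolerance = 1e-18)
  expect_equal(as.numeric(opc$L %*% rep(-70, nrow(cell$comp))),
               rep(0, nrow(cell$comp)), tolerance = 1e-12)
  soma_children <- which(cell$comp$parent == 1)
  expect_gte(length(which(opc$L[1, ] != 0)) - 1, 2)
})

test_that("the equilibrated default model is stationary and rests at -70 mV", {
  st <- equilibrated_state()
  expect_lt(abs(attr(st, "v_soma") - (-70)), 1)
  expect_lt(attr(st, "max_dvdt"), 1e-4)
  # gating variables sit at their voltage steady state
  cell <- default_cell()
  sp <- cell$specs
  i <- resolve_site(cell, "somatic")
  expect_equal(unname(st$gates[i, "m16"]),
               steady_state(sp$nav16$gating$m, st$V[i]),
               tolerance = 1e-6)
  expect_equal(unname(st$gates[i, "n"]),
               steady_state(sp$kv$gating$n, st$V[i]),
               tolerance = 1e-6)
  # re-running from the returned state changes nothing measurable
  tr <- simulate_cell(cell, st, protocol = NULL, tstop = 10)
  expect_lt(max(abs(tr$state$V - st$V)), 1e-6)
  # zero-amplitude stimulus leaves all traces flat at rest
  tr0 <- simulate_cell(cell, st, stimulus("somatic", 0), tstop = 10)
  expect_lt(max(abs(tr0$V - tr0$V[1, 1])), 1e-6)
})

test_that("a single step at rest is the identity and matches simulate_cell", {
  cell <- default_cell()
  st <- equilibrated_state()
  s1 <- step_state(cell, st)
  expect_equal(s1$V, st$V, tolerance = 1e-10)
  expect_equal(s1$conc, st$conc, tolerance = 1e-12)
  # two half steps track one full step closely away from rest
  st2 <- init_state(cell, v = -60)
  full <- step_state(cell, st2, dt = 0.025)
  half <- step_state(cell, step_state(cell, st2, dt = 0.0125), dt = 0.0125)
  expect_equal(half$V, full$V, tolerance = 1e-3)
})

test_that("simulations are deterministic", {
  cell <- default_cell()
  st <- equilibrated_state()
  t1 <- simulate_cell(cell, st, stimulus("somatic", 5), 20)
  t2 <- simulate_cell(cell, st, stimulus("somatic", 5), 20)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$state$conc, t2$state$conc)
})

test_that("a suprathreshold somatic pulse evokes a spike initiated in the AIS", {
  cell <- default_cell()
  st <- equilibrated_state()
  tr <- simulate_cell(cell, st, stimulus("somatic", 6), 30)
  expect_gt(tr$vmax[["soma"]], 0)       # somatic AP overshoots 0 mV
  expect_gt(tr$vmax[["ais_dist"]], 20)
  fc <- tr$first_cross_time
  expect_true(any(!is.na(fc)))
  ais <- cell$comp$kind == "ais"
  dist_half <- ais & cell$comp$s_norm > 0.5
  prox_end <- ais & cell$comp$s_norm < 0.25
  # the earliest crossing is inside the AIS, and the distal half fires no
  # later than the proximal end or the soma
  expect_equal(min(fc, na.rm = TRUE), min(fc[ais], na.rm = TRUE))
  expect_lte(min(fc[dist_half], na.rm = TRUE),
             min(fc[prox_end], na.rm = TRUE))
  expect_lt(min(fc[ais], na.rm = TRUE),
            fc[resolve_site(cell, "somatic")])
})

test_that("halving the time step moves the AP peak by less than 0.1 ms", {
  cell <- default_cell()
  st <- equilibrated_state()
  peak_t <- function(dt) {
    tr <- simulate_cell(cell, st, stimulus("somatic", 6), 15, dt = dt)
    tr$time[which.max(tr$V[, "ais_dist"])]
  }
  expect_lt(abs(peak_t(0.025) - peak_t(0.0125)), 0.1)
})

test_that("concentrations respond to spiking and then recover toward rest", {
  cell <- default_cell()
  st <- equilibrated_state()
  tr <- simulate_cell(cell, st, stimulus("somatic", 6), 40)
  i <- resolve_site(cell, "ais", 0.95)
  dna <- tr$state$conc[i, "na_in"] - st$conc[i, "na_in"]
  expect_gt(dna, 0.01)   # sodium entered during the AP
  # continue with no stimulus: the pump pulls Na+ back toward rest
  tr2 <- simulate_cell(cell, tr$state, protocol = NULL, tstop = 1500)
  dna2 <- tr2$state$conc[i, "na_in"] - st$conc[i, "na_in"]
  expect_lt(abs(dna2), abs(dna))
  expect_lt(abs(dna2) / st$conc[i, "na_in"], 0.01)  # within 1 % of rest
})
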