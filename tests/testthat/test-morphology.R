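test_that("the default recipe builds the reduced pyramidal morphology", {
  rec <- default_recipe()
  expect_equal(rec$sections$length[rec$sections$kind == "ais"], 25)
  expect_equal(rec$sections$length[rec$sections$kind == "hillock"], 10)
  expect_gte(sum(rec$sections$kind == "apical_tip"), 2)
  expect_gte(sum(rec$sections$kind == "basal"), 1)
  cell <- default_cell()
  expect_s3_class(cell, "cell_model")
  # soma -> hillock -> ais chain with the stimulation stub past the AIS
  expect_equal(cell$sections$parent[cell$sections$name == "hillock"], "soma")
  expect_equal(cell$sections$parent[cell$sections$name == "ais"], "hillock")
  # compartment lengths add up to section lengths
  for (nm in cell$sections$name) {
    expect_equal(sum(cell$comp$length[cell$comp$section == nm]),
                 cell$sections$length[cell$sections$name == nm])
  }
  expect_true(all(cell$comp$area > 0))
  expect_true(all(cell$comp$vol_in > 0) && all(cell$comp$vol_out > 0))
  # two builds from the same recipe are identical
  expect_identical(cell$comp, build_reduced_pyramidal()$comp)
})

test_that("discretize computes cylinder geometry and axial couplings", {
  secs <- data.frame(name = c("a", "b", "c"),
                     kind = c("soma", "basal", "basal"),
                     length = c(100, 50, 50), diam0 = c(1, 2, 4),
                     diam1 = c(1, 2, 2), parent = c(NA, "a", "b"),
                     attach = c(NA, 1, 1), nseg = c(4, 1, 2),
                     stringsAsFactors = FALSE)
  comp <- discretize(secs, global_params())
  # 7 compartments, 6 axial couplings (a chain)
  expect_equal(nrow(comp), 7)
  expect_equal(sum(!is.na(comp$g_axial)), 6)
  # cylinder L=100, d=1, n=4: each compartment area = pi * 1 * 25 um^2
  a <- comp[comp$section == "a", ]
  expect_equal(a$area, rep(pi * 25 * 1e-8, 4), tolerance = 1e-14)
  # tapered section: diameters interpolate the endpoints at centers
  cc <- comp[comp$section == "c", ]
  expect_equal(cc$diam, c(3.5, 2.5))
  # minimal chain with one compartment per section
  secs1 <- secs; secs1$nseg <- 1
  comp1 <- discretize(secs1, global_params())
  expect_equal(nrow(comp1), 3)
  expect_equal(sum(!is.na(comp1$g_axial)), 2)
})

test_that("section validation rejects malformed trees", {
  base <- data.frame(name = c("a", "b"), kind = c("soma", "basal"),
                     length = c(10, 10), diam0 = c(1, 1), diam1 = c(1, 1),
                     parent = c(NA, "a"), attach = c(NA, 1), nseg = c(1, 1),
                     stringsAsFactors = FALSE)
  bad <- base; bad$parent[2] <- "zzz"
  expect_error(discretize(bad, global_params()), "unknown parent")
  bad <- base; bad$length[1] <- -5
  expect_error(discretize(bad, global_params()), "positive")
  bad <- base; bad$parent <- c("b", "a")  # cycle / child before parent
  expect_error(discretize(bad, global_params()))
  bad <- base; bad$parent[2] <- NA  # two roots
  expect_error(discretize(bad, global_params()), "root")
  bad <- base; bad$attach[2] <- 1.5
  expect_error(discretize(bad, global_params()), "attach")
})

test_that("passive input resistance converges monotonically under refinement", {
  rin <- sapply(c(10, 20, 40, 80), function(n) {
    cab <- passive_cable(length_um = 1000, nseg = n)
    st <- init_state(cab)
    tr <- simulate_cell(cab, st,
                        stimulus("cab", 0.1, duration = 300, onset = 0,
                                 pos = 0),
                        tstop = 300, record = list(x0 = c("cab", 0)),
                        record_every = 1000L)
    (tr$V[nrow(tr$V), 1] + 70) / 0.1  # MOhm-scale units (mV / nA)
  })
  d <- abs(diff(rin))
  expect_true(all(diff(d) < 0))          # successive changes shrink
  expect_lt(d[3] / rin[4], 0.01)
})

test_that("steady-state attenuation follows the cable length constant", {
  # semi-infinite-like: 3500 um = 4.3 length constants, stimulated at one end
  cab <- passive_cable(length_um = 3500, diam = 2, nseg = 175, g_leak = 5e-5)
  lam_um <- sqrt((2e-4 / 4) * (1 / 5e-5) / 150) * 1e4
  st <- init_state(cab)
  pos <- c(0.003, 0.1, 0.2, 0.3)
  rec <- lapply(pos, function(p) c("cab", p))
  names(rec) <- paste0("p", seq_along(pos))
  tr <- simulate_cell(cab, st,
                      stimulus("cab", 0.1, duration = 400, onset = 0, pos = 0),
                      tstop = 400, record = rec, record_every = 1000L)
  v <- tr$V[nrow(tr$V), ] + 70
  x_um <- (pos - 0.5 / 175) * 3500    # distance from the injected compartment
  pred <- v[[1]] * exp(-(x_um - x_um[1]) / lam_um)
  expect_equal(unname(unlist(v)), unname(pred), tolerance = 0.02)
})

test_that("SWC round trip preserves topology and coordinates", {
  f <- tempfile(fileext = ".swc")
  tiny_swc(f)
  cell <- read_swc(f)
  # 3-point soma contour + 2-point apical neurite -> 2 sections
  expect_equal(nrow(cell$sections), 2)
  expect_equal(cell$sections$kind, c("soma", "apical_tip"))
  expect_equal(cell$sections$parent[2], "soma")
  # soma collapsed to a cylinder: diameter from the middle contour sample
  expect_equal(cell$sections$diam0[1], 12)
  expect_equal(cell$sections$length[2], 35)  # soma(y=5)->15 plus 15->40
  out <- tempfile(fileext = ".swc")
  write_swc(cell, out)
  again <- read_swc(out)
  expect_equal(again$sections, cell$sections)
  expect_equal(again$swc, cell$swc)
  # a reduced-morphology cell can be exported with generated coordinates
  out2 <- tempfile(fileext = ".swc")
  write_swc(default_cell(), out2)
  pts <- aisnav:::parse_swc(out2)
  expect_equal(ncol(pts), 7)
  expect_true(all(pts$parent[-1] < pts$id[-1]))
})

test_that("SWC parser reports malformed rows and dangling parents", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 5 0 oops 1"), f)
  expect_error(read_swc(f), "line 2")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 5 0 1 7"), f)
  expect_error(read_swc(f), "not defined before line 2")
})
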