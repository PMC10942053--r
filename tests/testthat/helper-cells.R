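# Shared fixtures, built once per session.

.fixtures <- new.env(parent = emptyenv())

default_cell <- function() {
  if (is.null(.fixtures$cell))
    .fixtures$cell <- build_reduced_pyramidal()
  .fixtures$cell
}

equilibrated_state <- function() {
  if (is.null(.fixtures$state))
    .fixtures$state <- run_to_steady_state(default_cell())
  .fixtures$state
}

# A single passive cylinder with only the chloride leak (pump off), so the
# membrane resistance is exactly 1 / g_leak_cl.
passive_cable <- function(length_um = 3500, diam = 2, nseg = 175,
                          g_leak = 5e-5) {
  secs <- data.frame(name = "cab", kind = "basal", length = length_um,
                     diam0 = diam, diam1 = diam, parent = NA, attach = NA,
                     nseg = nseg, stringsAsFactors = FALSE)
  rec <- default_recipe()
  rec$sections <- secs
  rec$densities$basal <- c(nav12 = 0, nav16 = 0, kv = 0)
  rec$g_leak_cl <- c(default = g_leak)
  rec$pump$kinds_off <- c("myelin", "basal")
  rec$stim_sites <- list(somatic = "cab", axonal = "cab", fp = "cab")
  aisnav:::assemble_cell(secs, rec, global_params())
}

# A synthetic trace_set with given per-site peak voltages, for detector tests.
fake_traces <- function(peaks, rest = -70, onset = 1) {
  tm <- seq(0, 10, by = 0.5)
  V <- sapply(peaks, function(p) {
    v <- rep(rest, length(tm))
    v[tm >= onset + 1 & tm <= onset + 2] <- p
    v
  })
  colnames(V) <- names(peaks)
  structure(list(time = tm, V = V,
                 vmax = apply(V, 2, max),
                 protocol = stimulus("soma", 1, onset = onset)),
            class = "trace_set")
}

# Tiny SWC file text: 3-point soma contour plus a 2-point apical neurite.
tiny_swc <- function(path) {
  writeLines(c(
    "# minimal test morphology",
    "1 1 0 0 0 5 -1",
    "2 1 0 5 0 6 1",
    "3 1 0 10 0 5 2",
    "4 4 0 15 0 1 2",
    "5 4 0 40 0 1 4"), path)
  path
}
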