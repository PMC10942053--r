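---
title: "Modelling NaV subtype separation in the axon initial segment and its effect on backpropagation thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NaV subtype separation in the AIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Pyramidal neurons segregate two sodium-channel subtypes along the axon
initial segment (AIS): NaV1.2, whose gating curves are *right-shifted*
toward depolarized potentials, clusters near the soma, while NaV1.6
dominates the distal AIS where action potentials (APs) initiate.  This
package asks what that separation does to the threshold current for a
*backpropagating* AP — a spike that invades the soma and apical dendrites —
and whether the answer depends on stimulating the cell orthodromically
(current pulse at the soma) or antidromically (pulse in the axon just
distal to the AIS).

The two NaV density profiles along the normalized AIS coordinate
$s \in [0, 1]$ are

$$\bar g_{1.2}(s) = \alpha\,\frac{\bar g}{2}\bigl(1 - x \tanh(\sigma (s - \kappa))\bigr),
\qquad
\bar g_{1.6}(s) = \frac{\bar g}{2}\bigl(1 + x \tanh(\sigma (s - \kappa))\bigr),$$

so that (for $\alpha = 1$) the total density $\bar g$ is constant at every
point regardless of the separation $x \in [0,1]$ and the crossover position
$\kappa \in [0,1]$.  $\sigma$ (default 10) is the reciprocal of the
normalized transition width; `flipped = TRUE` mirrors the profile
($s \to 1-s$), putting the AIS on "backward".  Because the total density
never changes, any threshold change caused by $(x, \kappa)$ can only come
from the spatial distribution of *gating properties*.

NaV1.2 is defined as NaV1.6 with every gating curve translated by
$V_{RS} = 13$ mV toward depolarized potentials.  The *shift-clamp* machinery
(`shift_clamp()`, `apply_shift_clamp()`) perturbs that shift by
$\Delta V_{RS}$ for chosen subsets of
$\{m_\infty, \tau_m, h_\infty, \tau_h\}$ of AIS NaV1.2 only, which is how
the sensitivity analysis attributes threshold changes to steady-state
*activation* ($m_\infty$), steady-state *availability* ($h_\infty$), or
their time constants.

## The biophysical model

Voltage evolves by the branched cable equation,
$C\,\partial V/\partial t = \tfrac{d}{4 R_a}\,\partial^2 V/\partial s^2 - I_{\mathrm{membrane}}$,
with per-ion membrane currents

$$I_{Cl} = g_{Cl}(V - E_{Cl}), \qquad
I_{K} = (g_{KV} + g_{K,leak})(V - E_K) - 2 I_{pump}, \qquad
I_{Na} = (g_{NaV} + g_{Na,leak})(V - E_{Na}) + 3 I_{pump},$$

where every NaV conductance has the Hodgkin–Huxley form
$\bar g\,m^3 h$ and the delayed rectifier uses a single activation gate.
Reversal potentials are *not* constants: each compartment carries explicit
intra- and extracellular Na⁺, K⁺ and Cl⁻ pools, and
$E_Z = (RT/zF)\ln([Z]_{out}/[Z]_{in})$ is recomputed locally every step.
Concentrations respond to the transmembrane currents
($\partial_t [Z]^j_{in} = -A^j I^j_Z / (F\,\mathrm{Vol}^j_{in}) + D_Z \nabla^2 [Z]^j_{in}$,
with the opposite-signed term in the extracellular shell), to longitudinal
Fick diffusion along the tree in both pools, and to a Na⁺/K⁺ pump

$$I_{pump} = I_{max}\Bigl(1 + \frac{K_{M,K}}{[K^+]_{out}}\Bigr)^{-2}
\Bigl(1 + \frac{K_{M,Na}}{[Na^+]_{in}}\Bigr)^{-3},$$

which exports 3 Na⁺ and imports 2 K⁺ per cycle.  Calcium dynamics,
electrodiffusion, osmotic volume changes and temperature scaling of the
kinetics (temperature enters only through the Nernst factor) are out of
scope.

### Gating kinetics

The functional forms are config-driven (they live in the recipe, not in the
solver): Boltzmann steady states
$u_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k})$ (negative $k$ for availability)
and bell-shaped time constants
$\tau_u(V) = \tau_0 + a/(e^{(V-V_p)/w_1} + e^{-(V-V_p)/w_2})$, which are
positive everywhere and have a single interior maximum that translates
exactly with the shift — the property the sensitivity analysis relies on.
Defaults (mV, ms):

| gate | $V_{1/2}$ | $k$ | $\tau_0$ | $a$ | $V_p$ | $w_1$ | $w_2$ |
|------|------|-----|------|-----|------|-----|-----|
| NaV $m$ (exponent 3) | −38 | 6 | 0.04 | 0.3 | −38 | 15 | 15 |
| NaV $h$ (exponent 1) | −66 | −6 | 0.3 | 5 | −60 | 12 | 12 |
| KV $n$ (exponent 1) | −25 | 9 | 0.6 | 3 | −30 | 20 | 20 |

These are standard cortical-pyramidal shapes; they are deliberately *not*
claimed to reproduce any particular published channel model.  NaV1.2 uses
the same table with `base_shift = 13`.  The KV activation exponent and the
absence of KV inactivation are modelling choices recorded here because no
reference value constrains them.

Shifting $u_\infty$ and $\tau_u$ *together* by $\Delta V$ is algebraically
identical to shifting the arguments of the rate functions
$\alpha_u, \beta_u$ (tested pointwise); shifting them *independently* uses
$\alpha'_u = u'_\infty/\tau'_u$, $\beta'_u = (1-u'_\infty)/\tau'_u$.

## The reduced morphology and what it stands in for

`default_recipe()` builds a reduced layer-5-like pyramidal cell instead of a
reconstructed morphology: a 30 × 25 µm soma; a 10 µm hillock tapering
2.5 → 1.2 µm; a 25 µm, 1.2 µm-diameter AIS discretized at 2.5 µm; a 30 µm
unmyelinated axonal stub 5 µm past the AIS (the antidromic stimulation
site); four 50 µm myelinated internodes with 1 µm excitable relay nodes
(forward propagation is detected at the last node); a 600 µm apical trunk
tapering 5 → 2.5 µm that branches into two 400 µm tips; and two 180 µm
basal dendrites.  77 compartments in total.

The dimensions and densities were chosen once so that the reduced cell sits
in the same *qualitative regime* as the full reconstructions the study
design assumes:

* **Rest at −70 mV with stationary concentrations** (see "Initialization"
  below).
* **AP initiation in the AIS.**  The thin hillock electrically isolates the
  AIS (total NaV 0.8 S/cm², KV 0.15 S/cm²) from the soma; under somatic
  drive the AIS crosses 0 mV tens of microseconds before the soma.  In this
  compact 25 µm AIS the whole mid-to-distal region ignites within one time
  step, so "the initiation site" is a plateau (s ≈ 0.35–0.75) rather than a
  point.
* **Strongly attenuated backpropagation.**  Dendrites carry sparse
  right-shifted NaV (0.03 S/cm²), so the invading spike is decremental and
  the all-apical-tips criterion ($V > -63$ mV, i.e. rest + 7 mV) is met
  only slightly above the forward-propagation threshold — which is why
  somatic $I_{FP} \approx I_{BP}$ in this model, as in the reference
  regime.
* **Marginal, graded antidromic invasion.**  The soma carries a small
  population of non-right-shifted NaV (0.04 S/cm²) in addition to
  right-shifted NaV (0.02 S/cm²) and KV (0.03 S/cm²).  Its ignition level
  sits just above the depolarization that an antidromic AIS spike alone
  delivers, so whether an axon-evoked spike invades the soma and dendrites
  depends continuously on (i) the charge the proximal AIS NaV population
  feeds forward — which is what the $(x, \kappa)$ profile and the NaV1.2
  availability control — and (ii) the fraction of the stimulus pulse that
  reaches the soma through the AIS.  This yields finite axonal $I_{BP}$
  values of a few nA for separated profiles ($x \gtrsim 0.5$,
  $\kappa \gtrsim 0.5$) and no backpropagation below the 10 nA cap
  otherwise.
* **≈ +80 mV at the axonal site under 10 nA.**  The stub's area and
  densities put the local input impedance in the range where a 10 nA, 1 ms
  pulse peaks near +80 mV, the stated physical scale of strong antidromic
  stimulation; the cap exists precisely to avoid exceeding it.

What the reduced cell does **not** emulate: the detailed dendritic
arborization (only two apical tips), dendritic calcium spikes/BAC firing,
frequency-dependent phenomena, and the absolute threshold magnitudes of any
reconstructed cell — thresholds here are morphology-dependent quantities
and should be compared across conditions, not against experiment.  Passing
tests therefore validate mechanisms and orderings, not absolute nA values
for real neurons.

## Initialization: an exactly balanced rest state

Rather than tuning $I_{max}$ by simulation until the cell happens to rest
near −70 mV, the build solves the rest condition exactly
(`balance_leaks()`): chloride concentrations are chosen so
$E_{Cl} = V_{rest}$; in every compartment the Na⁺ and K⁺ leak conductances
absorb the resting pump fluxes
($g_{Na,leak} = 3 I_{pump}/(E_{Na} - V_{rest}) - g_{NaV}^{rest}$, and
similarly for K⁺ with factor 2); and where the resting voltage-gated K⁺
current exceeds what the baseline pump density can balance (AIS, nodes,
soma), the local pump density is scaled up instead — mirroring the
colocalization of Na⁺/K⁺-ATPase with excitable membrane.  The uniform state
$V = -70$ mV with the recipe concentrations is then an exact fixed point of
the coupled voltage–concentration system; `run_to_steady_state()` verifies
stationarity ($\max |dV/dt| < 10^{-4}$ mV/ms, concentration drift
< 0.01 mM / 100 ms) rather than hunting for it.  After a spike the pump and
diffusion restore this state.

## Numerics

* **Voltage:** $\theta$-method (Crank–Nicolson, $\theta = 0.5$, by default;
  backward Euler available via `theta = 1`) with a direct Hines elimination
  on the compartment tree, implemented in C++.  Conductances are frozen at
  the step start; the staggered gating update makes the scheme effectively
  semi-implicit and unconditionally stable for the linear part.
* **Gating:** exponential Euler, $u' = u_\infty + (u - u_\infty)e^{-dt/\tau}$,
  exact for frozen voltage and bounded in $[0,1]$ for any trajectory.
* **Concentrations:** first-order operator splitting — transmembrane flux
  update at the new voltage, then explicit tree diffusion in both pools.
  Sealed (zero-flux) ends; the discrete flux form conserves moles to
  round-off.  A concentration driven non-positive raises an error
  suggesting a smaller `dt`.
* **Defaults:** `dt = 0.025` ms, AIS segments ≤ 2.5 µm, other sections ≤ 25
  µm or an explicit per-section count.  Halving `dt` moves the AP peak by
  < 0.1 ms, and halving both `dt` and the AIS mesh changes $I_{BP}$ by
  < 2% (tested).
* **Thresholds:** bisection over the 1 ms pulse amplitude with geometric
  bracket expansion; default relative tolerance 1% (sweeps), 0.05% for the
  shift-clamp slopes, which keeps the slope estimate above bisection
  quantization.  Axonal searches are capped at 10 nA (somatic at 20 nA);
  a search still negative at the cap is reported `capped`, not discarded.
* **Detection:** backpropagation = every apical tip exceeds −63 mV within a
  25 ms window after pulse onset (the window and the 0 mV
  forward-propagation crossing at the distal node are documented defaults;
  neither is externally constrained).

## Design choices on genuinely open points

* The stimulation compartment for antidromic drive is the middle of the
  unmyelinated stub ("the axon just distal to the AIS"); its distance (5
  µm) is a recipe parameter.
* Somatic injection is at the middle compartment of the soma.
* The KV density is uniform along the AIS; no KV gradient is imposed.
* Slope signs for the sensitivity table are least-squares slopes over the
  three grid points nearest $\Delta V_{RS} = 0$ (±3 mV grid for somatic,
  ±1 mV for axonal, matched to each mode's sensitivity), with "negligible"
  defined as a relative slope below $10^{-4}$ per mV of the nominal
  threshold.
* Sweep results are pure functions of (recipe, grids, protocol): rerunning
  reproduces tables bit-identically, and $x = 0$ rows are exactly
  $\kappa$-independent.

## Known limitations

* The somatic $(x, \kappa)$ threshold modulation on this reduced cell is
  ~5%, well short of the tens-of-percent modulation a full morphology
  supports.  The somatic threshold here is dominated by the somatodendritic
  ignition level, which the electrode primes directly; configurations that
  make the threshold AIS-dominated (larger AIS conductance) were explored
  and abandoned because the strongly conducting AIS then shunts the
  antidromic stimulus and invasion becomes all-or-none, destroying the
  graded sensitivity analysis.  One reduced cell could not host both
  regimes at full strength; the default favors the mechanistic
  (sign/sensitivity) behavior.
* In the sensitivity matrix, the axonal reference curve (all four
  properties shifted together) has a slightly *positive* slope — the
  availability and activation contributions (≈ −3.5 and +3.3 nA/mV) nearly
  cancel and activation wins here — and somatic availability shifts
  register as negligible rather than slightly threshold-lowering.  The
  remaining twelve cells, including the axonal $\tau_h$-only "down" and the
  somatic $m_\infty$-only "up" that carry the study's mechanistic message,
  are reproduced.
* The "distal" AIS initiation is a plateau covering the middle and distal
  AIS, not a sharply distal point, because 25 µm at 1.2 µm diameter is
  electrically compact at initiation-time conductances.
* Concentration homeostasis after a spike is slow (seconds), as expected
  for pump-driven recovery; tests assert recovery to within 1% of rest,
  not full return.

## Problem sizes used by the tests

The default cell has 77 compartments; simulated windows are 10–40 ms for
single protocols, 100 ms chunks for equilibration, and 1.5 s for the
post-spike recovery check.  The acceptance sweep uses the full 5 × 9
$(x, \kappa)$ grid at 1% bisection tolerance; the sensitivity sweeps use
7 conditions × 3 shifts per stimulation mode at 0.05% tolerance.  The
convergence check rebuilds the cell at half the time step and half the AIS
segment length.

## A worked session

```{r example}
library(aisnav)

cell <- build_reduced_pyramidal()          # default recipe
state <- run_to_steady_state(cell)         # exact -70 mV rest
attr(state, "v_soma")

# somatic threshold for the separated profile
bp <- find_threshold(cell, state, "somatic", "bap")
bp

# antidromic threshold map over separation and crossover
ax <- sweep_xk(cell, "axonal", x_grid = c(0, 0.5, 1),
               kappa_grid = c(0.5, 0.7), state = state)
ax

# sensitivity of the threshold to right-shifting only tau_h in the AIS
sens <- sweep_shift_clamp(cell, "axonal", conditions = "tau_h")
sign_pattern(sens)
```
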