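---
title: "Modeling Cdc42 polarization dynamics on the fission yeast cell surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Cdc42 polarization dynamics on the fission yeast cell surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Fission yeast grows from its cell tips, and the master regulator of that
choice is the small GTPase Cdc42, cycling between a fast-diffusing inactive
GDP-bound form and a slow-diffusing active GTP-bound form on the plasma
membrane. `cdc42sim` integrates six coupled fields on a closed
spherocylinder surface (a cylinder of radius R capped by two hemispheres,
the idealized shape of the cell):

* `CD`, `CT` — Cdc42-GDP and Cdc42-GTP surface concentrations (1/µm²).
  Cdc42-GDP associates from a constant cytoplasmic pool at flux `jDp` and
  dissociates at `rD`; Cdc42-GTP dissociates at `rT`. Activation
  (GDP→GTP) is catalyzed by membrane GEF and biased to the cell tips by the
  factor `exp(-s/lambda)`, where `s` is the meridian arc length to the
  nearest pole; deactivation is catalyzed by two GAP systems plus a small
  spontaneous rate `k1n`.
* `CGEF` — the activator (GEF) field. A fixed whole-cell pool of `Ectot`
  molecules equilibrates quasi-statically with the Cdc42-GTP field:
  `CGEF = (k1p*CT + k2p*CT^2) * Ec / V`, with the free cytoplasmic count
  `Ec = Ectot / (1 + ∫ (k1p*CT + k2p*CT^2)/V da)`. The quadratic term makes
  the positive feedback strong enough to break symmetry; the shared scalar
  `Ec` is the only global coupling and is what makes the two tips compete
  for a limiting activator.
* `CGAPI` — a tip-localized inhibitor recruited by Cdc42-GTP through a
  saturating Hill function `k4n * CT^h / (ksat^h + CT^h)` (`h = 2`). Its
  delayed build-up at an active tip is the nonlinear negative feedback that
  generates oscillations.
* `CGAPIIfast`, `CGAPIIslow` — a side-localized inhibitor with two
  diffusive states. It is recruited at tips in the fast form (`k5n*CT`),
  converts spontaneously to the slow form (`k6n`), and is converted back
  wherever Cdc42-GTP is high (`k7n*CGAPIIslow*CT`). The net effect is a
  slow-diffusing "collar" of inhibitor that accumulates around, not on,
  the active zone.

All parameter defaults are the package's reference set
(`default_params()`), with concentrations in molecules/µm², rates in 1/s,
bimolecular constants in µm²/s, and the GEF pool as a molecule count. The
reference geometry is `L = 8` µm tip-to-tip, `R = 2` µm.

Depending on the GEF pool size and the feedback strengths, a cell started
from an unpolarized state settles into one of a small set of terminal
states: monopolar stable (MPS), bipolar stable (BPS), bipolar oscillatory
(BPO, tips alternating with periods of a few minutes), monopolar with
damped oscillations (MPDO), or — with the tip bias removed — dynamic
patches and traveling waves.

## Surface discretization

The membrane is discretized with a quasi-uniform mesh built by
`build_mesh()`: nodes are placed on rings of constant meridian position,
spaced uniformly along the pole-to-pole meridian, with each ring's
azimuthal count proportional to its circumference, a zipper triangulation
between adjacent rings, and a single pinned node at each cap apex (so tip
traces have a well-defined anchor). At the default target cell area of
0.03 µm² (~3,300 nodes for the reference cell) every Voronoi cell area
falls in the 0.017–0.046 µm² working band and the total area matches
`2πR(L−2R) + 4πR²` to about 0.1%.

The Laplace–Beltrami operator uses cotangent edge weights with barycentric
(one-third-of-triangle) vertex areas. Two numerical choices matter:

* **Symmetry.** The weight matrix is symmetric with zero row sums, so for
  any field the area-weighted integral of the discrete Laplacian vanishes
  identically — diffusion conserves mass to machine precision on the
  closed surface, by construction rather than by tolerance.
* **Positivity.** The ~1% of edge weights that come out negative (obtuse
  triangle pairs at ring-count transitions) are clamped to zero. This
  makes the operator an M-matrix, so explicit diffusion within the
  stability bound can never push a concentration negative. The cost is a
  small consistency error: on a near-sphere mesh the ℓ = 1 spherical
  harmonic decays at `2D/R²` within 0.6% (0.2% without clamping) — far
  inside the 5% band the spectral test asserts. Without clamping, sharp
  single-cell Cdc42-GTP spikes next to a negative-weight edge drive
  neighboring concentrations below zero and abort the run.

Arc length `s` is computed analytically from the node coordinates (`R`
times the polar angle on a cap, quarter-meridian plus axial distance on
the cylinder), not by graph shortest path, so the `exp(-s/lambda)` bias
carries no mesh-resolution error.

## Time integration

`run()` advances all five dynamic fields with a forward-Euler step of
`dt = 0.01` s: diffusion and reactions in one additive update, then the
activation-noise events (if stochastic), then the quasi-static GEF
refresh. The hot loop is compiled (Rcpp) — a 1200 s reference-cell run
takes ~20 s — while `step()` is the plain-R reference implementation of
the same update; a suite test holds the two paths to 1e-10 relative
agreement. The explicit-diffusion bound `dt < min_i a_i / (D max_i Σ_j w_ij)`
is checked at setup and a violating `dt` is rejected before any work.
Single-node kinetics are pinned to an independently coded scalar oracle
and to a high-accuracy `deSolve` solution; the residual O(dt) error of the
explicit scheme is about 0.2% over 100 s, and halving `dt` moves
mid-transient tip traces by ~1.4%, halving again thereafter (first-order
convergence).

Concentrations in `[-1e-9, 0)` are clamped to zero (roundoff); anything
below `-1e-9` aborts with a diagnostic naming the field — instability is
an error, never silently absorbed.

## The random-activation term

The reference parameters include a small random Cdc42 activation rate
`rnoise`. The package implements three readings, selected by
`noise_mode`:

* `"deterministic"` (default) — the literal `−rnoise·CD` / `+rnoise·CD`
  exchange terms of the rate equations.
* `"stochastic"` — discrete conversion events: per node, a Poisson number
  of molecules with mean `rnoise·CD·a·dt` moves from GDP to GTP (the
  compiled path draws the summed-Poisson total and assigns nodes
  multinomially, which is distributionally identical). Total Cdc42 is
  conserved exactly by each event.
* `"off"`.

The deterministic reading is the default for a physical reason: at this
model's concentration scale a single molecule in a 0.03 µm² Voronoi cell
is a +33/µm² perturbation — roughly twice the unpolarized Cdc42-GTP
level — so molecule-resolution noise is not a small perturbation but a
stream of order-unity kicks that the quadratic GEF feedback amplifies. In
stochastic mode the bipolar stationary state at `Ectot = 1800` is
destroyed (the system switches monopolar), whereas the deterministic
reading preserves it along with the bipolar oscillations (period ≈ 5.7 min
at `k5n = 0.01`, `Ectot = 500`) and the reference-parameter oscillatory
state. Shot noise at single-molecule granularity also raises the
effective positive feedback (it feels `⟨CT²⟩ > ⟨CT⟩²`), which shifts the
phase boundaries. Both alternative modes remain available and tested.

With deterministic noise, symmetry breaking is seeded by the initial
condition: Cdc42-GDP starts at its resting concentration `jDp/rD` with
±1% uniform random fluctuations, plus a small random Cdc42-GTP field in
`[0, 1%·jDp/rD]` (the generator's amplitude choice; the reference source
states only "small").

## State classification

`classify_state()` reduces a pair of tip traces (area-weighted mean
Cdc42-GTP within 0.5 µm of each pole — averaging a region rather than a
single node is robust to mesh noise) to a label via explicit, exported
thresholds:

* stationary — relative drift of both smoothed traces < 1% over the final
  400 s;
* asymmetric — final-window tip ratio > 1.5;
* oscillatory — ≥ 3 peaks per trace with topographic prominence above 10%
  of the trace mean, and negative zero-lag cross-correlation between tips;
* damped — successive peak prominences decaying (median ratio < 0.7 per
  cycle) with the final-window swing collapsed below half the early
  envelope, ending asymmetric.

Sustained anticorrelated oscillation is `BPO`; damped-to-asymmetric is
`MPDO`; stationary states split into `MPS`, `BPS`, or `UNPOLARIZED` (both
tips below 160/µm², i.e. ~2× the resting Cdc42-GDP level). A
non-stationary symmetric trace with fewer than three detected peaks but
anticorrelated tips and at least one dominance switch per tip is a slow
oscillation (period beyond the peak-count window) and is labeled `BPO`,
not mistaken for a stable state. Too-short
traces return an explicit `INDETERMINATE` rather than a default. All
thresholds are function arguments; the label is invariant under swapping
tip identities.

For unbiased-activation regimes (`lambda = Inf`), `patch_tracking()`
follows the area-weighted centroid of the top-decile Cdc42-GTP nodes
through snapshots: coherent azimuthal or axial drift beyond the patch
diameter is a `WAVE`; appearance/disappearance events or incoherent
relocation is `PATCH_DYNAMIC`. The azimuth only contributes when the
track stays off the cell axis, where the angle is well defined.

## Profiles and decay lengths

`profile_vs_arclength()` bins each species against meridian distance from
the dominant tip, area-weighted within bins; each bin's coordinate is the
area-weighted mean arc length of its nodes (bin centers bias the
subsequent fit where node density varies, e.g. near the poles — using the
weighted mean removes a ~5% systematic in recovered decay lengths).
`decay_length_fit()` then fits `c0·exp(-s/λ)` by nonlinear least squares
over 0–2 µm, seeded by a log-linear regression; planted exponentials over
0.3–1.5 µm are recovered within 2%. `decay_experiment()` packages the
profiling protocol: run with the GAP_I saturation lowered to
`ksat = 450` (an oscillatory regime), detect the first prominent
dominant-tip peak after 1000 s, snapshot 20 s later, fit. Halving the
GAP_II recruitment rate `k5n` widens the activation zone and strictly
increases the fitted decay length.

## Figure-level drivers

* `run_scan()` — 2-D grids over any two parameters, one classification
  per cell, optional replicates with a majority label plus a coexistence
  flag (near regime boundaries different seeds may settle differently).
  Default cell duration 1200 s, the upper end of the 800–1200 s window
  used for terminal-state calls, to limit misclassification of slowly
  damping states.
* `neto_series()` — fixed-length cells with the GEF pool scaled in
  proportion to cell volume (`Ectot = 300` at `L = 7` µm, `ksat = 650`),
  emulating growth of the limiting activator with cell size. The
  monopolar→bipolar-oscillatory transition along this series is the
  model's account of new-end take-off (NETO); very long cells revert to
  bipolar stationary.
* `mutant_run()` — named scenarios: `gapII_half` (`k5n` halved, the
  side-GAP-deletion analogue), `gapII_off`, `unbiased` (`lambda = Inf`
  with `k0p = 0.01`, giving patch appearance/disappearance at random
  locations), `unbiased_gapII_off` (additionally `k5n = 0`, giving a
  traveling wave chased by the remaining tip-type GAP).

Every driver is a pure function of (parameters, seed); the JSON/CSV
records written by the I/O helpers are sufficient to reproduce any run
exactly.

## What the defaults do and do not show

The reference conditions reproduce the qualitative repertoire robustly:
symmetry breaking from an unpolarized start, 2–3× tip enrichment of total
Cdc42 in asymmetric states, GAP_I peaking at the active tip with the
GAP_II collar offset from it, anticorrelated tip oscillations with
periods of several minutes, reversion to bipolar stationary at large GEF
pools, wider activation zones when GAP_II recruitment is reduced, and
patch appearance/disappearance at random membrane locations without tip
bias. In the `unbiased_gapII_off` regime the active zone relocates over
large distances between snapshots rather than drifting steadily, so the
tracker usually calls it `PATCH_DYNAMIC` rather than `WAVE`; the
wave-versus-relocation call depends on the snapshot interval relative to
the zone's speed.

Quantitative regime *boundaries*, however, are sensitive to details that
are not recoverable from the printed description (the noise realization,
the original mesh and operator weights): in this implementation the
monopolar-stable and damped-oscillatory islands sit at somewhat lower GEF
pools than the reference figure captions place them, and the fitted decay
lengths at `ksat = 450` come out wider than the reference values (by
roughly 0.3 µm at the reference recruitment rate, more when `k5n` is
halved), with the `k5n` ordering preserved. The acceptance suite asserts
the reference protocols verbatim, so these show up as explicit failures
rather than adjusted expectations.

Problem sizes used throughout (the package's own defaults): ~3,300-node
meshes, 1200 s classification runs, 1800 s decay-length runs, 2000 s
period measurements, single runs per scan cell with seeds derived
deterministically from the base seed.

Simplifications to keep in mind: Cdc42 and the GAPs exchange with
implicitly infinite cytoplasmic pools (only the GEF is conserved);
activation bias stands in for all tip-delivery machinery; the cell
neither grows nor deforms within a run; and the two GAP species bundle
families of real regulators, so mutant scenarios are analogies, not
gene-level predictions.
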