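---
title: "tilsim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilsim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilsim)
```

## The model

`tilsim` simulates the contest between a growing solid tumour and
tumour-infiltrating CD8+ T cells on a cubic lattice of `N^3` voxels of 10 um
(the reference domain is `N = 100`, i.e. 1 mm^3). Cancer cells are 20 um
agents occupying aligned 2x2x2 voxel blocks; T cells occupy single voxels.
Adjacency between agents is the Moore (26-neighbour) relation between any
voxel of one and any voxel of the other, chosen for isotropy.

Each agent step of `dtHours` executes six sub-phases in a fixed order —
recruitment, IL-2 secretion/diffusion/decay, contact interactions,
divisions, migration, death/clearance — with agents processed in a freshly
shuffled order inside every sub-phase so no lattice index is systematically
favoured. All stochastic decisions draw from R's RNG, so a seed fixes the
trajectory bit-for-bit.

The rules are:

* **Recruitment.** Effector T cells arrive as a Poisson stream with rate
  `rBase * kA * (kI * D) / (1 + kI * D)` per hour, where `D` is the
  cumulative number of dead cancer cells. Mutational burden `kA` acts as a
  capacity (the saturated rate is `rBase * kA`; more neoantigens mean more
  recruitable clones), antigen strength `kI` as an affinity (how little
  dead-cell signal is needed to approach saturation). Arrivals are placed
  uniformly on unoccupied vasculature entry voxels; if every entry voxel is
  occupied the arrival is forfeited and logged. Entry voxels are drawn once
  per run: a voxel at depth `d` um from the nearest lattice face is an entry
  point with probability `baseDensity * exp(-lambdaVasc * d)`. Depth is
  measured from the static lattice boundary, not the moving tumour surface.
* **Contact interactions.** An effector T cell touching a living cancer cell
  becomes cytotoxic deterministically (and can act in the same step). Each
  cytotoxic T cell makes one kill attempt per step against one uniformly
  chosen adjacent living cancer cell, succeeding with `pKillNeg` (PDL1-
  target) or the smaller `pKillPos` (PDL1+ target). A PDL1- cell surviving
  an attempt converts to PDL1+ with probability `pPdl1Induction`
  (a config switch `inductionOnContact` instead draws induction for every
  contacted PDL1- cell, independent of the attempt). Independently, a
  cytotoxic T cell adjacent to at least one PDL1+ cancer cell is suppressed
  with probability `pSupp` per step; suppressed cells never kill, secrete or
  divide again. PDL1+ is irreversible.
* **Division.** A non-suppressed agent whose cooldown has elapsed divides
  into a uniformly chosen free adjacent site (aligned free 2x2x2 block for
  cancer); T-cell division additionally requires local IL-2 at or above
  `il2DivisionThreshold` and fewer than `maxTCellDivisions` prior divisions.
  When no free site exists the cooldown is reset to a full cycle, so blocked
  cells re-attempt once per cycle rather than every step; this keeps the
  engine cost proportional to divisions rather than agents and reads
  naturally as re-entry into the cell cycle. Cooldowns reset for both
  daughter and parent; daughters inherit the parent's PDL1 state.
* **Necrotic turnover.** A cancer cell whose division attempt finds no free
  block dies at that attempt with probability `pNecrosis`. This is the
  model's only immune-independent death channel: it produces a necrotic
  core in compact tumours and — critically — it bootstraps the dead-cell
  signal `D` that recruitment needs, while leaving small uncrowded tumours
  safe from stochastic extinction. Dead cells (killed or necrotic) occupy
  their block for `deadClearanceTime` hours, are excluded from targeting
  and division, then free it.
* **Migration.** Motile agents take `speed * dt / voxelSize` lattice moves
  per step (fractional remainder resolved stochastically), each in a
  uniformly chosen Moore direction; blocked moves are forfeited. Ensemble
  mean squared displacement is linear in time, i.e. an unbiased random
  walk.
* **T-cell death.** T cells die at `tCellLifespan` or upon reaching
  `maxTCellDivisions` (replicative exhaustion); both remove the agent and
  free its voxel.

Anti-PDL1 therapy rescales the suppression probability to
`pSupp * (1 - mSupp)` from `startDay` onward (default `mSupp = 0.8`,
read as an 80% reduction; the residual models incomplete blockade through
redundant ligands such as PDL2). Kill probabilities are untouched. Paired
treated/untreated runs started from the same seed share the RNG stream and
are identical up to the start day.

## The IL-2 field

Cytotoxic T cells secrete IL-2 (`secretionRate` units/h into their voxel);
the field diffuses with effective diffusivity `diffusionCoeff` and decays
with rate `decayRate`, and gates T-cell division through
`il2DivisionThreshold`. The solver is an alternating-direction-explicit
(Saul'yev) scheme: an ascending and a descending sweep are averaged, then
decay is applied as an exact exponential factor. Boundary ghosts are chosen
so each sweep conserves mass exactly under the zero-flux faces (the minus
ghost takes the old centre value, the plus ghost the new centre value, and
mirrored in the descending sweep); a final clamp to zero guards round-off.
For per-substep diffusion numbers `a = D * dt_pde / dx^2 <= 1/3` every
update coefficient is non-negative, so positivity is structural.

Two numerical choices matter:

* **Effective diffusivity.** The default `D = 0.18` um^2/s is an effective
  tissue value, not the free-solution diffusivity of IL-2. Together with the
  1 h half-life it gives a paracrine signalling range
  `sqrt(D / k) ~ 30` um, consistent with measured cytokine niches around
  secreting T cells: in tissue, receptor-mediated capture confines IL-2 to
  the immediate neighbourhood of the secreting cluster. A free-solution
  value (~100 um^2/s) would additionally put any explicit-family solver at
  unusably large diffusion numbers at affordable sub-stepping; the effective
  value keeps the default `dt_pde = dt/5` in the positivity-preserving
  regime. Accuracy against a fine-step forward-Euler oracle is ~0.6% (L-inf,
  relative) at `a ~ 0.1` and degrades smoothly with `a`.
* **Grid coarsening.** `pdeCoarsen = f` solves the field on an `(N/f)^3`
  grid with `dx = 10 f` um, storing concentrations per cell-lattice voxel so
  secretion, decay, mass and the division threshold are `f`-independent.
  With the ~30 um IL-2 range, `f = 2` (20 um cells) loses little spatial
  structure and cuts solver cost eightfold; the scaled scenario batteries
  below use it. `f = 1` is the default.

## Default parameters and calibration

Defaults ship in `inst/extdata/default_params.yaml` (schema-versioned) and
are documented field by field in `?RuleParameters`. The interaction
probabilities are per agent step of 0.25 h. Cell-scale values (10/20 um
diameters, 1 um/min T-cell speed, cancer speeds at the low end of the
0.01-5 um/min range, a 7-day T-cell lifespan) are standard for early-stage
solid tumours. The remaining rates have no published source values, so they
were calibrated once, jointly, against the qualitative course the model is
meant to reproduce, and then frozen:

* untreated baseline (`kA = 20`, `kI = 0.1`): T cells arrive from about
  day 10-15, tumour growth slows under attack, a PDL1+ population emerges
  and the tumour escapes;
* under treatment from day 20 (N = 50 battery): both high-burden quadrants
  shrink (`kI = 0.1` to elimination, `kI = 0.001` more slowly), both
  low-burden quadrants keep progressing, and every untreated arm
  progresses.

The mechanism behind the burden split is worth stating because it guided
the calibration. Untreated, suppression (~`pSupp * 4` contact draws/h)
outpaces T-cell division, so the attack force decays at the PDL1+ front and
any recruitment level loses. Treated, suppression drops fivefold and the
front becomes survivable; whether the attack overturns tumour growth then
depends on the recruitment capacity `rBase * kA` amplified by a bounded
number of IL-2-driven divisions (`maxTCellDivisions = 4` caps clone size,
keeping the outcome roughly linear in `kA` rather than bistable in every
quadrant). `rBase = 0.31` places the tipping point between `kA = 10` and
`kA = 20` at the day-20 tumour size; it was chosen with a 20-seed margin
check on the two knife-edge quadrants so the split is a property of the
parameter set, not of particular seeds.

## What the generator emulates — and what it does not

Simulated cohorts vary only the neoantigen profile and the seed; real
cohorts vary far more (growth rates, vascularisation, antigen presentation,
stromal content). Passing the scenario checks shows the model reproduces
the intended qualitative structure — treatment response stratified by
mutational burden, PDL1 immuno-architecture at the tumour rim, insensitivity
of net growth to entry-point geometry — not that it predicts any particular
cancer. The spatial pipeline (smoothing, flood-fill tumour region, distance
maps, rim scores) is exact and tested against brute-force oracles, so
conclusions about the *analytics* transfer directly; conclusions about
*biology* are qualitative.

Known limitations worth flagging:

* PDL1+ cell counts retain a mild sensitivity to the vascular decay length
  `lambdaVasc` (fewer T cells reach the tumour when entries hug the
  boundary, so cumulative induction drops ~20% across the swept range) even
  though total burden shows no significant trend; the insensitivity
  statement is asserted for total counts.
* The rim-score/response association in generated cohorts is moderate
  (AUC ~ 0.7): the score tracks antigen strength more strongly than burden,
  while response is burden-driven, and the high-burden/low-strength
  responders score near zero. Because the depth profile of the score is
  proportionally similar in every quadrant, the AUC is essentially flat in
  rim depth (differences < 0.01 between 20 and 150 um): the model does not
  express a detectable predictive advantage of shallow over deep rims at
  this cohort size, and the corresponding ordering check is sensitive to
  seeds and calibration.
* Suppressed T cells persist until natural death and block lattice sites;
  there is no Treg/MDSC biology, no oxygen or nutrient field, no mechanistic
  PD1/PDL1 receptor kinetics, and vasculature does nothing but admit
  T cells.

## Numerical and degenerate-input conventions

* Smoothing is the zero-padded 3x3x3 box mean thresholded at `>= 0.5`. With
  27 samples the mean never equals 0.5, so the strictness of the comparison
  is unobservable. A consequence of zero padding worth knowing: an all-ones
  volume erodes at edges and corners (12/27 and 8/27 < 0.5).
* The tumour region is the complement of the 6-connected flood fill of
  zero voxels seeded from the lattice faces; sealed cavities therefore count
  as tumour. Background connectivity is 6 so that foreground effectively
  carries the complementary connectivity, the standard pairing in 3D
  labelling.
* Distance maps are 2D per cross-section, in um, measured to the nearest
  background pixel *centre* (an exact Euclidean distance transform); an
  isolated tumour pixel is 10 um from its adjacent background. Rim masks
  threshold the depth-to-surface `distance - voxelSize`, so threshold 0
  selects the boundary-adjacent layer exactly and rims nest monotonically.
  A section with no background at all returns infinite distances.
* Rim scores exclude dead cells everywhere; an empty rim yields NA and is
  excluded from ROC construction. Agent-level counting (default) counts a
  cancer cell once if any voxel of its block intersects the rim;
  voxel-level counting is the config alternative. The responder cutoff on
  the shrinkage ratio (`< 1`) is exposed, not hard-coded.
* The ROC is the empirical curve over all cutoffs with ties grouped and
  trapezoidal AUC; it is checked against an independent implementation.
* PRCC uses the precision matrix of the rank-transformed data (plain
  Spearman when there is a single parameter, where the matrix route is
  singular for perfectly monotone pairs); p-values use the t statistic with
  `n - 2 - (k - 1)` degrees of freedom and the significance flag defaults
  to the conservative `alpha = 1e-9`. Replicates are averaged before
  correlation; no multiple-testing correction beyond the extreme alpha.
* One R RNG stream drives everything; per-run seeds in scenario and design
  batteries are derived deterministically from the battery seed, and every
  artefact embeds the seed and parameters needed to re-run it
  (`rerunFromSnapshot()` reproduces the time series exactly).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run scaled-down configurations
chosen to exercise every mechanism at meaningful effect sizes: scenario
batteries at `N = 50` (35 simulated days, treatment at day 20, ten paired
seeds per quadrant, `pdeCoarsen = 2`), the vascular sweep at `N = 50` for
30 days across `lambda` in {1/3200, 1/400, 1/100, 1/25} 1/um, exactness
checks on random 16^3 volumes and 48-64^2 sections, solver checks on 20^3
grids, and growth-law checks on a 40^3 lattice in a well-mixed (high
cancer motility) configuration where contact inhibition is negligible and
the doubling law is the correct closed form. The reference `N = 100`
configuration runs unchanged, only longer.
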