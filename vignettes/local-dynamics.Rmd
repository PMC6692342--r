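---
title: "Quantifying local conformational and dynamic shifts between paired trajectory ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local conformational and dynamic shifts between paired trajectory ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdyn)
```

## The problem

A point mutation rarely unfolds a protein; it redistributes the protein's
*local* conformational states and changes which residues move together.
Global metrics (overall RMSD, radius of gyration) are dominated by loop and
rigid-body motion and miss these effects.  `mutdyn` implements an integrated
local analysis of paired Cα trajectory ensembles — a reference condition
("WT") and a perturbed condition ("mutant"), each a time series of residue
coordinates — that answers three questions:

1. **Which residue pairs change their average separation?**  Via a
   coordination-shell pair-distance difference map
   $\Delta\bar R_{ij} = \bar R_{ij,\mathrm{mut}} - \bar R_{ij,\mathrm{wt}}$.
2. **How do the underlying conformational states shift?**  Via per-pair
   distance distributions $W(R_{ij})$, their peaks (the local states) and
   state occupancies, plus a magnitude-matrix PCA that partitions frames
   into conformational states on the (PC1, PC2) plane.
3. **How does the dynamics change?**  Via per-residue RMSF profiles,
   dynamic cross-correlation maps $C_{ij} \in [-1, 1]$, and categorical
   difference maps (gained/lost couplings), complemented by geometric
   salt-bridge and hydrogen-bond occupancy calls.

This vignette records the model choices, conventions, parameters and known
limitations; the README shows a worked example.

## Trajectory preparation

Frames are superposed onto frame 1 of each condition with a closed-form
least-squares rigid fit (Kabsch) on Cα atoms.  Each condition is aligned to
its own first frame; no shared reference is imposed across conditions,
because all downstream metrics are internal (distances, fluctuations).
Alignment on Cα only is consistent with every downstream metric being
Cα-based.  `slice_equilibrated()` drops an initial non-equilibrated stretch;
for production MD runs a 10% discard (e.g. the first 100 ns of a 1 µs run
saved every 10 ps) is a common choice and is the file-pipeline default.

Degenerate reference frames (collinear or coincident atoms) are rejected:
the rotation is then not identifiable.

## Pair-distance difference maps

The **first coordination shell** of a residue is the conventional contact
sphere of radius $r_1 \approx 7.2$ Å around its Cα; the **second shell** is
the sphere of twice the volume, radius $r_1 \cdot 2^{1/3} \approx 9.1$ Å.
The neighbor graph contains every pair whose *time-averaged* distance in
the **reference** condition is at most the shell radius.  Thresholding the
time average (rather than any single frame or instantaneous membership)
makes the pair set deterministic and frame-order independent.  The graph is
frozen on the reference and reused for the perturbed condition so that
$\Delta\bar R_{ij}$ is defined on a fixed pair set.

Pairs with $\Delta\bar R_{ij} > 2.50$ Å ("apart") or $< -1.40$ Å ("closer")
are flagged significant.  Both thresholds are plain configuration values
with those defaults.  The per-residue profile
$\Delta\bar R_i = \sum_j \Delta\bar R_{ij} / N_n$ (mean over the residue's
$N_n$ second-shell neighbors) summarizes local expansion (positive) or
compaction (negative); residues without neighbors are flagged undefined
rather than zero.

## Magnitude-matrix PCA and conformational states

Each residue's position is mean-centered over time and reduced to its
fluctuation magnitude $\lVert r_i(t_m) - \langle r_i\rangle\rVert$, giving
an $N \times M$ matrix.  The mode decomposition diagonalizes
$C = \frac{1}{M}\,\mathrm{mag}\,\mathrm{mag}^\top$ — deliberately *without*
re-centering the magnitude rows.  Magnitudes have non-zero means, so $C$ is
a second-moment matrix rather than a covariance in the textbook sense; the
equation is implemented literally and the consequence is documented rather
than "fixed", because the mode structure of the second moment is what the
downstream state partitioning consumes.  Numerical conventions: eigenpairs
sorted by descending eigenvalue; each eigenvector's sign fixed so its
largest-magnitude component is positive (deterministic output across
platforms); eigenvalues clipped at zero against roundoff.

Frames are partitioned into states on the (PC1, PC2) projection plane with
a 2-D histogram: Freedman–Diaconis bin widths per axis, capped at roughly
$2 M^{1/3}$ bins per axis so that a tight, well-separated cluster fills
contiguous cells instead of fragmenting a sparse histogram into spurious
components.  Bins with at least 10% of the maximal bin count (the density
floor, configurable) seed states as 4-neighborhood connected components;
frames in below-floor bins attach to the nearest dense bin, so every frame
is labeled.  States are relabeled by descending occupancy with ties broken
by centroid (lexicographic), so the dominant state is always state 1 and an
exact tie resolves to the lower label.

**State weighting.**  Downstream averages can be restricted to the most
densely populated state, each frame carrying the state's occupancy as its
weight.  Two conventions are exposed because "weighting a calculation by
the probability of a state" admits two readings: `"select"` (default)
computes ordinary weighted means over the dominant-state frames — with a
constant weight this is the plain dominant-state mean, which keeps
distances in Angstrom; `"multiply"` additionally scales the mean by the
occupancy (the dominant-state mean times its probability).  The pipeline
default applies `"select"` weighting to mean pair distances and correlation
maps, and leaves distance distributions unweighted (they describe the full
ensemble).

## Distance distributions, peaks and occupancies

$W(R_{ij})$ is a weighted, normalized histogram smoothed with a Gaussian
kernel of one bin width.  `distance_distribution()` defaults to
Freedman–Diaconis binning; the comparison pipeline uses a fixed 0.25 Å bin
width instead, for two reasons chosen up front: fixed edges make densities
comparable across conditions, and peak positions are read off bin centers,
so a fine fixed width bounds the quantization error of a peak position at
0.125 Å.  Peaks are local maxima of the smoothed density above a height
floor (default 5% of the maximal density); a floor of 1 returns only the
global maximum.  Frames are assigned to their nearest peak (1-D Voronoi) to
report per-state occupancies, and `state_occupancy()` reports the weighted
fraction of frames beyond an explicit distance boundary — the boundary is a
required parameter, never inferred, because occupancy readouts are
meaningless without it.

`population_shift()` compares two conditions of the same pair: it re-bins
both raw sample sets onto common edges (union range, the finer bin width),
reports the total-variation distance ($0$ identical, $1$ disjoint), greedily
matches peaks across conditions by nearest position within 1.0 Å, and
labels the pattern "state collapse" / "state splitting" / "stable" by the
change in peak count.

## RMSF and cross-correlation maps

$\mathrm{RMSF}_i = \sqrt{\langle\lVert r_i(t) - \langle r_i\rangle\rVert^2\rangle}$
with weighted temporal means; for iid isotropic per-coordinate noise of
standard deviation $\sigma$ the closed form is $\sigma\sqrt3$, which the
test suite uses as an oracle.  The cross-correlation map uses the standard
dynamic cross-correlation convention on 3-D fluctuation vectors,
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle}$; a
scalar-magnitude variant is exposed for sensitivity checks since prior
literature is not unanimous on the convention.  Residues with zero
fluctuation are flagged (`NA`) rather than propagating NaN.
`difference_map()` emits both the numeric delta and a categorical map
(gained-positive / gained-negative / lost / unchanged / undefined) at a
configurable magnitude threshold, default 0.4 — small enough to catch
moderate couplings, large enough that sampling noise
($\sim M^{-1/2} \approx 0.03$ at 2000 frames) never crosses it.

## Interactions

Salt bridges: any acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2)
within 3.2 Å of a basic side-chain nitrogen (Lys NZ, Arg NE/NH1/NH2;
His only via an explicit flag, default off) — the widely used convention of
the VMD salt-bridge tool.  Hydrogen bonds: donor–acceptor distance
≤ 3.5 Å *and* donor–H–acceptor angle ≥ 150°, community-standard geometric
criteria, with a distance-only fallback (and warning) when hydrogens are
absent.  `interaction_timeline()` conditions occupancies on the PCA states
so bond formation can be related to conformational states.  These criteria
are explicit replacements for visualization-tool plugins; no claim is made
that they reproduce any particular tool's calls.

## The synthetic generator

Raw multi-microsecond MD ensembles are rarely deposited, so the package
ships a generator whose defaults define the study conditions used by the
tests and the acceptance script: 50 residues × 2000 frames at 10 ps
spacing (a `paper_scale` flag switches to 165 × 10000, the regime of a
long single-protein MD run), per-coordinate Gaussian noise of 0.3 Å,
and a compact self-avoiding backbone with 3.8 Å Cα–Cα steps.  Planted
features, all recorded as machine-readable ground truth:

* **Five +3 Å mean-distance shifts.**  Each planted pair's endpoints are
  displaced (a small 1.2 Å move of one endpoint — below both significance
  thresholds in any direction — plus a direction-searched ≤ 2.3 Å move of
  the other) so the pair's baseline distance grows by exactly 3 Å while
  every other potential shell pair changes within (−1.3, +2.4) Å, inside
  the ±(2.50/−1.40) significance thresholds.  Exact recovery with zero
  false positives therefore holds by construction; a backbone that admits
  no such placement is regrown, and 25 failures raise an explicit
  infeasibility error.
* **A two-state reporter pair** with state distances 8.3 and 16 Å
  (within-state SD 0.5 Å), Markov switching, and a population shift from
  0.5/0.5 in the reference to 0.8/0.2 in the perturbed condition — the
  "predominant conformation" signature.  The probe residue moves along an
  axis chosen so its time-averaged distance to every other residue stays
  above the shell radius, keeping the reporter's own pairs out of the
  difference map.  Switching is memoryless by default (`persistence = 0`),
  a choice made so that state draws are independent and occupancy errors
  are exactly binomial — the error model the recovery checks assume; a
  stickiness knob is exposed for realism studies, with the caveat that
  autocorrelation inflates occupancy variance beyond binomial.
* **Factor-model correlation blocks**, perturbed condition only: a source
  block anti-correlated (target magnitude 0.7) with three target blocks
  along a common random axis.  The raw field is projected orthogonal to
  the rigid-body modes (zero net translation and zero linearized torque
  via an inertia-tensor solve) before use: otherwise per-frame
  superposition absorbs part of the coherent block motion and smears
  counter-rotation over all residues, attenuating the planted correlations
  and creating spurious ones.  The generator verifies the analytic
  correlation pattern of the projected field (all source × target pairs
  ≤ −0.5, no stray pair below −0.3) and regrows the backbone if the
  geometry distorts it.
* **Rigid-body drift** (0.01°/frame accumulating rotation, 0.002 Å/frame
  translation) applied last, so superposition is genuinely exercised.
* **Pseudo-side-chain atoms**: a Glu–Lys salt bridge whose O–N gap is 3.0 Å
  in state 1 and 6.0 Å in state 2 (coupling bond occupancy to the
  conformational states) and an always-formed collinear Ser→Asn hydrogen
  bond, with 0.02 Å atomic jitter.

What the generator does *not* emulate: force-field physics, solvent,
periodic boundaries, realistic backbone dihedrals, or thermodynamically
consistent state kinetics.  Passing the recovery suite therefore shows the
*analysis chain* is correct and well-calibrated at realistic noise levels —
not that any particular biological system behaves this way.

## Problem sizes and numerical choices

The shipped study conditions (50 residues × 2000 frames; 10000-frame runs
for the occupancy and RMSF closed-form checks; 20 replicate seeds for peak
recovery) keep the full suite under a minute on one CPU while leaving the
planted effects 5–100× their standard errors.  Tolerances used by the
checks are stated next to their oracles: PCA vs a double-loop + Jacobi
oracle at 1e-8 relative; RMSF vs $\sigma\sqrt3$ within 2%; correlations vs
the closed-form factor model within 0.05; peaks within 0.3 Å; occupancies
within 3 binomial SE; significant-pair sets exactly.  Ties and degenerate
inputs all have declared behavior: single-state degenerate partitions,
plateau peaks counted once at their first bin, exact occupancy ties
resolved to the lower state label, flagged zero-fluctuation residues.

## Known limitations

* The pair set and all distances are Cα-based; side-chain geometry enters
  only through the interaction module's atom detail.
* XTC input is not supported (PDB, DCD and a plain text table are); no
  periodic-boundary imaging is performed, so trajectories must be whole.
* The magnitude-matrix PCA discards fluctuation direction by design; it
  detects amplitude states, not directional substates.
* Replicate simulations are treated as separate inputs to be compared (or
  pooled by concatenation upstream if the user chooses); the package takes
  no position on pooling.
* Peak calling is density-based (as distribution figures in this field
  imply), not a mixture-model fit; heavily overlapping states
  (separation ≲ 2 bin widths + smoothing) merge into one peak.
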