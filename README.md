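# mutdyn

Quantify how a point mutation (or any paired perturbation) shifts a
protein's **local** conformational states and dynamics from Cα trajectory
data.

Comparing a mutant's MD ensemble to the wild type with global metrics
(RMSD, radius of gyration) mostly measures loop and rigid-body motion.
`mutdyn` instead implements an integrated *local* analysis for a paired
reference/perturbed comparison:

* **Pair-distance difference maps** on coordination-shell neighbors:
  `ΔR̄ᵢⱼ = R̄ᵢⱼ,mut − R̄ᵢⱼ,wt` over all residue pairs within the second
  coordination shell (radius `r₁·2^⅓ ≈ 9.1 Å` for the conventional
  `r₁ = 7.2 Å` contact shell) of the reference structure, with significance
  thresholds `> +2.50` / `< −1.40 Å` and the per-residue local
  expansion profile `ΔR̄ᵢ = Σⱼ ΔR̄ᵢⱼ / Nₙ`.
* **Conformational states**: per-pair distance distributions `W(Rᵢⱼ)` with
  peak detection and state occupancies; magnitude-matrix PCA
  (`C = (1/M)·ΔR̄·ΔR̄ᵀ`, symmetric eigendecomposition, projection onto the
  top modes) with density-based partitioning of frames into states on the
  (PC1, PC2) plane and probability-weighted dominant-state statistics.
* **Dynamics**: per-residue RMSF, dynamic cross-correlation maps
  `Cᵢⱼ ∈ [−1, 1]` on 3-D fluctuation vectors, and categorical difference
  maps (gained-negative / gained-positive / lost couplings).
* **Interactions**: geometric salt-bridge (O–N ≤ 3.2 Å) and hydrogen-bond
  (D–A ≤ 3.5 Å, D–H···A ≥ 150°) occupancy calls, conditioned on the PCA
  states.
* **A synthetic trajectory generator** with planted ground truth
  (mean-distance shifts, Markov multi-state pairs, factor-model correlated
  fluctuation blocks, rigid-body drift, pseudo-side-chains), so the entire
  chain is testable without multi-microsecond MD data.

Everything is tidyverse-native: trajectories are light S3 containers, every
analysis returns a tibble, fitted objects have `tidy()`/`glance()` methods,
and result types have `autoplot()` methods.

## Worked example

Generate a paired synthetic ensemble (50 residues × 2000 frames: five
planted +3 Å pair shifts, an 8.3/16 Å two-state reporter pair whose
occupancies shift 0.5/0.5 → 0.8/0.2, anti-correlated fluctuation blocks in
the perturbed condition, rigid drift) and run the full comparison:

```r
library(mutdyn)

gen <- generate_pair(synthetic_config(seed = 42))
bundle <- compare_conditions(gen$wt, gen$mut,
  extra_pairs = list(c(gen$truth$state_pair$i, gen$truth$state_pair$j)))

glance(bundle)
#> # A tibble: 1 × 7
#>   n_pairs n_significant n_apart n_closer max_delta min_delta n_gained_negative
#>     <int>         <int>   <int>    <int>     <dbl>     <dbl>             <int>
#> 1     317             5       5        0      3.01     -1.28                45

bundle$significant
#> # A tibble: 5 × 6
#>       i     j  r_wt r_mut delta direction
#>   <int> <int> <dbl> <dbl> <dbl> <chr>
#> 1    17    39  7.08  10.1  3.01 apart
#> 2     1     7  7.89  10.9  3.00 apart
#> 3     9    21  7.44  10.4  3.00 apart
#> 4     4    49  7.93  10.9  2.98 apart
#> 5     2    45  8.33  11.3  2.96 apart
```

317 reference shell pairs were analysed; exactly the five planted pairs
cross the +2.50 Å threshold (each recovered within 0.05 Å of the planted
+3 Å), with no false positives, and the 45 planted source×target
anti-correlations are the gained-negative set.  The reporter pair's
distribution shows the planted two-state structure:

```r
bundle$distributions[[6]]$wt
#> <distance_distribution> pair 5-25 (WT): 2000 frames, 2 peak(s) at 8.37, 15.9 A
bundle$shifts[[6]]
#> <population_shift> pair 5-25: peak count +0 (stable), TV = 0.293
```

`verify_recovery(bundle, gen$truth)` re-checks every planted claim
(significant-pair set equality, peak positions within 0.3 Å, occupancies
within 3 binomial SE, gained-negative block membership) and returns a
pass/fail table.  `report(bundle)` prints a markdown summary;
`autoplot(bundle$delta)`, `autoplot(bundle$correlation$mut)` and
`plot_rmsf(bundle$rmsf$delta)` draw the standard figures.

For file-based runs (PDB topology + plain-table or DCD coordinates per
condition) use `comparison_config()` + `run_comparison()`, or the thin CLI
at `inst/scripts/mutdyn` (`simulate` / `analyze` / `report` subcommands).

## Package layout

* `R/trajectory.R` — trajectory container, PDB/DCD/plain-table I/O, Kabsch
  superposition, equilibration slicing
* `R/pca.R`, `R/states.R` — magnitude-matrix PCA, state partitioning,
  dominant-state weighting
* `R/pair_geometry.R` — coordination shells, neighbor graph, ΔR̄ᵢⱼ maps,
  significant pairs, ΔR̄ᵢ profiles
* `R/distributions.R` — W(Rᵢⱼ), peaks, occupancies, population shifts
* `R/dynamics.R` — RMSF, cross-correlation maps, difference maps
* `R/interactions.R` — salt bridges, hydrogen bonds, state-conditioned
  occupancies
* `R/synthetic.R` — the ground-truth generator
* `R/pipeline.R` — end-to-end comparison, artifact writing, reporting,
  truth verification
* `vignettes/local-dynamics.Rmd` — the methods vignette (models,
  conventions, parameter choices, limitations)
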