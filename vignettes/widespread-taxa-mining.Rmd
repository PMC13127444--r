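---
title: "Mining widespread taxa along deep-sea sediment redox gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining widespread taxa along deep-sea sediment redox gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxtaxa)
```

## The problem

Deep-sea sediments are redox-stratified: oxygen is consumed within the
upper decimetres, nitrate below it, and reduced species — ammonium and
divalent manganese — accumulate beneath. Microbial community structure
tracks this zonation, and families whose relative abundance covaries with
the pore-fluid redox constituents across *many* geographic areas are
candidates for globally relevant geochemical roles. `redoxtaxa`
implements a pipeline for identifying such "widespread taxa" from a
taxon-by-sample 16S count table plus per-core pore-fluid profiles of
O~2~, NO~3~^−^, NH~4~^+^, and Mn^2+^:

1. **Preprocess** — bin counts to family level; linearly interpolate each
   core's chemistry onto the microbial sampling depths; assign 0 µM O~2~
   to unmeasured samples with NH~4~^+^ ≥ 10 µM and manganese present.
2. **Compositional transform** — add pseudo-values (1 count, 0.001 µM),
   apply the centered log-ratio (CLR) transform; distances between
   samples are Aitchison distances (Euclidean in CLR space).
3. **Screen** — keep families whose CLR abundance differs between
   presence and absence of at least one constituent, with Storey q-value
   FDR control per constituent.
4. **Mine** — CART regression trees (sum-of-squared-deviation splitting,
   target = CLR-scale concentration) and classification trees (Gini
   splitting, target = presence/absence), refit over Monte-Carlo
   cross-validation (70/30 splits); per-family usage accumulates into a
   stability importance.
5. **Select** — the `k = 20` top-importance families that are present in
   every geographic area.
6. **Ordinate** — compositional PCA of the selected families' CLR
   subtable, and distance-based redundancy analysis (db-RDA) constrained
   on the four standardized log concentrations.

Every step is exported, and `run_pipeline()` chains them with one config
and one master seed.

## The synthetic study generator

Real surveys of this design pool hundreds of samples from many cruises;
the package ships a generator that emulates the *structure* of such data
at desk scale so that every stage can be tested against known ground
truth.

**Chemistry.** Each core draws an oxygen-depletion depth `z_ox` ~ U(60,
140) cm and a nitrate-depletion depth `z_no3 = z_ox +` U(40, 100) cm.
Oxygen decays from a bottom-water value (U(150, 300) µM) as
`o2_surface * (1 - z/z_ox)^2`, clamped at zero; nitrate rises from half
its peak (peak U(20, 40) µM) at the surface to the peak at `z_ox`, then
declines linearly to zero at `z_no3`; ammonium and manganese accumulate
linearly below `z_ox` and `z_no3` (slopes U(0.05, 0.2) and U(0.02, 0.1)
µM cm^−1^). Gaussian measurement noise (sd U(0.5, 2) µM) is added only
where the model concentration is positive and truncated at zero: a
constituent that is truly absent reads exactly 0, as a below-detection
measurement would. This keeps the zonation ordering (Mn^2+^ only below
nitrate depletion, NH~4~^+^ only below oxygen depletion) intact at any
noise level; an alternative that noises true zeros as well would make
half of all truly-absent readings spuriously "present" under a zero
detection limit.

**Community.** Four responsive guilds of five families each — aerobic
nitrifiers (+O~2~), facultative anaerobic heterotrophs (oxic zone),
anammox (oxygen-depleted but not manganese-rich), anaerobic heterotrophs
(+NH~4~^+^, +Mn^2+^, −O~2~) — plus 200 unresponsive background families.
Expected relative abundances follow a softmax (log-linear) response to
the standardized covariates O~2~, NH~4~^+^, Mn^2+^, and an oxic
indicator; counts are Dirichlet-multinomial (concentration 50, chosen to
give visible biological overdispersion) with exact library-size column
sums (20,000 reads). Area-level random intercepts (sd 0.3) emulate
between-region compositional differences.

**Within-guild heterogeneity.** Each family scales its guild's response
coefficients by an independent factor U(0.4, 1.6). This width matters:
members of a guild must be similar enough to cluster (shared sign
pattern, same niche) yet different enough in magnitude that a greedy
decision tree sometimes prefers one member and sometimes another across
resampled training sets. With a much narrower spread, guild members
become statistically redundant — no single tree ever needs a second,
near-collinear copy of a feature it has already used — and no
importance-based selection can recover them all, which would defeat the
generator's purpose of supporting parameter-recovery tests. The guild
base coefficients (magnitude 2–2.5 on their driving covariates) stay
strong enough that every guild carries |β| ≥ 2 responders.

**Sizes.** The default design is 6 areas × 2 cores × 20 samples (240
samples, 220 families), the desk-scale analogue of a six-area,
~1100-sample survey; tests and the acceptance script mine with 200
Monte-Carlo iterations rather than the 1,000 of `pipeline_config()`'s
default, which leaves the importance rankings stable while keeping a
full run in tens of seconds.

What the generator does *not* emulate: sequencing-read artefacts
(chimeras, primer bias), within-family OTU structure (each synthetic
taxon is its own family, so family binning is exercised by unit fixtures
rather than by the synthetic study), non-monotone niche shapes (the
log-linear model cannot place a guild's optimum strictly inside the
gradient), uneven sampling designs, or contamination. Passing recovery
tests therefore show that the chain of statistics is implemented
correctly and is sensitive under its stated model — not that it would
recover every truth from real survey data.

## Decisions where the method description left room

**Significance test.** Differential-abundance screening uses the
two-sided Wilcoxon rank-sum test (exact enumeration for combined n ≤ 12
without ties, otherwise the normal approximation with tie and continuity
corrections): robust, assumption-light, standard for relative-abundance
comparisons. Storey's π~0~ uses a fixed λ = 0.5 (no smoother), clipped to
[1/m, 1]; q < 0.05 defines candidacy. On data where planted structure is
strong, most families genuinely covary with the redox gradient through
compositional closure, π~0~ collapses, and the screen retains nearly all
families — its dimension-reduction role shows when families outnumber
samples, which is the regime it exists for.

**Presence/absence.** Presence means raw (pre-pseudo-value)
concentration above a detection limit of 0 µM, so the 0.001 µM
pseudo-value can never create presence; anoxia-assigned oxygen zeros
count as absent. "Presence of manganese" in the anoxia rule is Mn^2+^ >
0 µM, configurable.

**No extrapolation.** Chemistry is only interpolated inside a core's
measured depth range; samples outside it are flagged and excluded for
that constituent. Linear interpolation is used precisely because it adds
the fewest assumptions, and extrapolating a redox profile beyond its
deepest measurement would add a strong one.

**Importance operationalization.** A tree's rules rank taxa by how high
they act in the decision path. The default `peak_coverage` score credits
a family once per tree with the sample fraction governed by its
shallowest split (root = 1), averaged over iterations. A plain
coverage *sum* is also available, but deep trees re-use a strong feature
at many small nodes, and the accumulated sum can outrank a family that
splits at the root — inverting the position principle the score is meant
to encode (observed on synthetic data: a family with mean first depth
≈ 3 outscoring the family that holds the root). `count` (uses per tree)
and `depth_decay` (2^−depth^) variants are provided for sensitivity
analysis. Selection aggregates per-family scores across constituents by
maximum (mean available), uses the regression miner's tables by default,
and breaks ties lexicographically.

**Tree hyperparameters.** Unlimited depth, 5-sample leaves, any positive
gain; all configurable and echoed in `run_metadata.tsv`. Split ties
(gains equal within a tolerance proportional to the parent impurity)
resolve to the lower feature index, then the lower threshold, making
fits reproducible bit-for-bit.

**Chemistry on a log-ratio scale.** Concentrations enter regression
targets and db-RDA constraints as `ln(c + 0.001)` centered/standardized
across samples (the default `log_center` mode). Treating the four
constituents of one sample as a single composition (CLR across
constituents, `composition` mode) is implemented behind the
`chem_mode` switch; it answers a subtly different question (relative
redox makeup rather than absolute levels) and is not the default.

**Ordination.** CoDa-PCA is the SVD of the column-centered CLR subtable
with (n−1) variance scaling and a largest-loading-positive sign
convention. `db_rda()` takes either a distance matrix (Gower
double-centering → principal coordinates → regression on constraints) or
a response matrix (classical RDA); because the Aitchison distance is
Euclidean in CLR space the two routes coincide, and the test suite
asserts their equality to 1e-8 — plus an independent `vegan::rda`
cross-check. Negative-eigenvalue corrections are deliberately absent:
Aitchison distances cannot produce them, and genuinely non-Euclidean
input is rejected rather than silently repaired. No partialling on
area/site is applied.

**Seeds.** One master seed; every internal step derives its own sub-seed
as `(master * 7919 + k) mod (2^31 − 1)` with a documented counter `k`,
so stages are independently reproducible and the pipeline is
byte-identical across reruns.

## What recovery looks like

Under the default conditions (fixed seed, 200 iterations) screening
retains every strongly responsive planted family (|β| ≥ 2), the
regression and classification miners agree on the top-ranked family per
constituent, and selection at k = 20 recovers 16 of the 20 planted
responsive families. Across master seeds, recovery typically falls
between 60% and 85%: the residual misses are guild members shadowed by a
stronger, correlated sibling — an intrinsic property of greedy
single-tree mining on collinear features, mitigated but not removed by
resampling stability. A null study (all β = 0, no area effects) yields
chance-level held-out R² and calibrated permutation p-values; those
checks are in `tests/testthat/test-acceptance.R`.

## Limitations

- Single trees are used by design (interpretability via explicit rules);
  correlated features share importance unevenly, and rankings below the
  top few positions are noisy.
- The permutation p-value permutes samples freely; depth autocorrelation
  within cores is ignored, so it is anti-conservative for strongly
  depth-structured responses on real data.
- The screen's rank-sum test treats samples as exchangeable across cores
  and areas; no mixed-effects structure.
- CLR makes results subcompositionally dependent by construction: the
  CLR is computed once on the full family table and columns are then
  subset, so downstream stages all see the same geometry.
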