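---
title: "Statistical methods behind g4screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind g4screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4screen)
```

g4screen implements the statistical chain of a drug-modifier pooled CRISPR
dropout screen — from raw spacer counting to gene-level depletion scores,
hit consolidation, and the bench assays used to validate hits — together
with a synthetic-data layer that generates inputs with exactly the
structure each stage assumes. This vignette explains the models, the
tunable parameters, and the design decisions taken where more than one
reasonable convention exists.

## Guide counting and library QC

Screen reads carry a 20-base spacer behind an invariant vector sequence,
with staggered forward primers shifting the spacer position across reads.
`extract_counts()` locates the anchor at any offset and requires an exact
match of the following 20 bases against the library: a read whose anchor is
absent, truncated, or whose spacer differs at even one base is tallied as
unmapped. Exact-match extraction is equivalent to no-mismatch alignment for
this read structure and keeps the counting rule auditable; the anchor is a
parameter (default `CACCG`, the U6/scaffold junction of lentiCRISPR-style
vectors).

`median_ratio_normalize()` computes per-sample size factors as the median
ratio of counts to the per-guide geometric mean across samples, over guides
with a nonzero geometric mean — the standard compositional correction for
count data. When fewer than `min_guides` (default 100) guides qualify, the
function falls back to total-count scaling; with a single sample it refuses
and points to total-count mode, since median ratios are undefined.

`library_qc()` summarizes representation with the percent of guides
detected and the fold difference between the upper and lower quantiles
bracketing the central 80% of detected guides (90th/10th percentile ratio).
"Central 80%" is a convention — the mass is exposed as `central_mass` so
other windows can be used. `coverage_per_guide()` converts genomic DNA mass
to per-guide coverage assuming 7.5 pg per cell, a typical value for a human
diploid genome measured by bulk DNA; at that default, 10 ug over 2930
guides reproduces the ~455x figure quoted for screens of this size. The
value is configurable because the genome-mass assumption is itself a
choice.

## Per-guide test and alpha-RRA gene scoring

Gene scoring follows the robust-rank-aggregation approach used by
screen-analysis tools such as MAGeCK, with a documented variant of the
count test:

1. A mean-variance relationship is fitted on the control samples by linear
   regression of log variance on log mean, floored at the Poisson variance.
   Flooring matters: sampled variances below the mean are artifacts of few
   replicates, and an NB variance below the mean is undefined.
2. Each guide's treatment-replicate sum is compared against a negative
   binomial with mean `r * mu0` and the modeled variance (exact Poisson
   when the model collapses to variance = mean). Two-sided p-values double
   the smaller tail; depletion evidence is the lower tail.
3. Guides are ranked by depletion evidence; ranks become percentiles
   `rank / (n + 1)`. Ties are broken by sgRNA id so results are
   deterministic.
4. For each gene with guide percentiles `p(1) <= ... <= p(k)`, the score is
   `rho = min over {i : p(i) < alpha} of BetaCDF(p(i); i, k - i + 1)`, the
   probability that the i-th of k uniform order statistics falls at or
   below `p(i)`. Genes with no percentile under `alpha` score 1.
5. The permutation p-value compares `rho` against scores of k uniformly
   drawn percentiles, with the add-one convention
   `p = (1 + #{rho* <= rho}) / (n_perm + 1)`. One null distribution is
   drawn per distinct k and shared across genes, which is what makes
   10,000+ permutations affordable.

`alpha` defaults to 0.05 on the percentile scale. The truncation is what
makes the aggregation robust — inactive guides above `alpha` cannot dilute
a gene's score — but it has a calibration consequence worth stating
plainly: the null score distribution is supported on
`(0, BetaCDF(alpha; 1, k)]` with an atom at 1, so permutation p-values are
exactly uniform below the truncation region and conservative (an atom at 1)
above it. Tests of null calibration therefore check KS-uniformity at
`alpha = 1`, where the score is continuous, and check the lower-tail
rejection rate at the truncated default. Non-targeting guides are folded
into pseudo-genes of the modal guides-per-gene and scored identically, so a
screen carries its own negative calibration set.

Only the depletion direction is scored: these are negative-selection
screens, and enrichment is outside the package's scope.

## Hit consolidation and the published gene table

Per-condition hits are genes with permutation p strictly below `p_cut`
(default 0.045, the cut used in the screens this package models).
Consolidation is a set union; counter-screen exclusion removes any gene
shared with the counter compound's hits; `intersection_sets()` computes
UpSet-style exclusive intersections (each gene assigned to the full
signature of lists containing it, so the sets partition the union).

The package ships its one real dataset as
`inst/extdata/table2_top_depleted.csv`: the published per-condition
top-depleted gene lists (five ragged, alphabetized columns transcribed from
the source table). On this fixture the set arithmetic is exactly
checkable: the five columns consolidate to 81 genes, the four G4-ligand
columns minus the counter screen leave 58, and the counter-excluded
common-to-all-G4 set is {ATM, H2AFX, LIG4, POLQ, RAD54L, RNF168}.

## Blocked bootstrap for competitive growth assays

A competitive growth assay reads out the DRX2+ (transduced) fraction of a
mixed population after drug or vehicle exposure. The experiment has a
two-level structure — independent assays, technical replicates within
assay — and the bootstrap respects it: assays are resampled with
replacement (outer block), then replicates within each drawn assay (inner
block). Per bootstrap replicate, each condition's proportions are averaged
on the logit scale, back-transformed, and differenced; percentile intervals
at 95/99/99.9/99.99% come from the `B` differences (default `B = 400000`;
package tests use 10,000, which changes endpoints only at the Monte-Carlo
`O(B^-1/2)` scale).

Decisions the data do not dictate:

* Proportions of exactly 0 or 1 have infinite logit. `clamp_proportions()`
  applies the continuity correction `(x + 0.5) / (n + 1)` when cell counts
  are available, else clamps at `1e-4`. The bootstrap refuses boundary
  values rather than silently patching them.
* The same resampled assay indices drive both arms of a contrast (an assay
  is one transduced, mixed population split across treatments, so its
  mixing-ratio shift is common to both arms); replicate indices are drawn
  per arm because wells are distinct. `independent_arms = TRUE` switches to
  fully independent resampling.
* Intervals are plain percentile intervals — the simplest reading of
  "confidence intervals from the bootstrap distribution".

Family-wise control is Bonferroni: with 50 contrasts (10 guides x 5 drug
conditions), family alpha 0.05 requires the 99.9% interval to exclude zero
(0.05/50 = 0.001), and family alpha 0.01 the 99.98% interval
(0.01/50 = 0.0002). `fwer_call()` warns when `B * alpha_adj < 20`, i.e.
when too few bootstrap draws land in the adjusted tail to estimate it.

A known limitation, quantified by the acceptance checks: with only three
assays the percentile interval is slightly anticonservative. The bootstrap
spread is estimated from three block-level contributions, and percentile
intervals use it like a known constant (a z-type interval where a t-type
correction would be needed), so the nominal 95% interval covers the truth
in roughly 91-94% of simulated experiments depending on the random stream.
This is a property of the published procedure at this block count, not of
the implementation; users who need guaranteed coverage at three assays
should read the 99% interval as an honest 95%.

## Dose-response fitting and comparison

`fit_4pl()` fits the variable-slope four-parameter logistic
`y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` by
Levenberg-Marquardt least squares in log10-dose space, with multi-start
initialization over a hill/IC50 grid and `bottom >= 0` (viability cannot be
negative). Flat responses are rejected as non-identifiable rather than
returning an arbitrary IC50. The IC50 interval is a profile-likelihood
interval: the three remaining parameters are refit along a log10(IC50)
grid and the interval is where the residual sum of squares crosses
`RSS0 * (1 + F(level; 1, df) / df)`. An essentially exact fit (RSS below
1e-12) has a degenerate profile and the interval collapses onto the
estimate.

IC50s across genotypes are compared with a pooled-variance one-way ANOVA
followed by Dunnett's many-to-one test, two-sided, with adjusted p-values
from the multivariate-t distribution (via multcomp). The multivariate-t
integration is quasi-random, so a seed argument makes reports
reproducible.

## Bliss synergy volumes for checkerboards

Responses are surviving fractions relative to untreated wells. For each
replicate plate, monotherapy inhibition fractions define the
Bliss-expected surface `fx + fy - fx * fy`; the per-cell deviation is
observed minus expected inhibition, in percent. Using each replicate's own
monotherapy rows keeps deviations independent across replicates and
mean-zero under the null; monotherapy fractions are clamped to [0, 1]
before entering the Bliss formula while observed inhibition is left
unclamped so noise stays symmetric.

Deviations are summarized per cell by a t interval at the
Bonferroni-adjusted level `(1 - confidence) / n_cells`. The synergy volume
accumulates significant positive deviations, the antagonism volume
significant negative ones, each weighted by the cell's dose-interval area
(half-intervals at the grid edges). The dose scale for the weights is
linear by default — matching volumes reported in dose-squared-times-percent
units — with log10 and unit weighting available, and raw (unthresholded)
volumes are always reported alongside. MacSynergyII-style tools differ in
exactly this bookkeeping; the CI-thresholded, dose-weighted definition is
this package's primary one and both variants are returned. With replicate
standard deviation exactly zero (noise-free data) the interval collapses
to the point deviation, which is what makes planted-deviation recovery
exact in tests.

On simulated Bliss-null boards with noise, the fraction of boards showing
any nonzero volume at the adjusted 95% level sits at the family alpha
(about 5% over 500 boards in the acceptance run), slightly conservative
because cells sharing a monotherapy row are positively correlated.

## Densitometry ANCOVA and foci statistics

Immunoblot densities are analyzed on the log2 scale — removing the lower
bound at zero, making Gaussian assumptions tenable, and turning condition
differences into fold-changes — with the loading control as a covariate
under a single shared slope (with two lanes per condition, per-condition
slopes would leave no residual degrees of freedom). The ANOVA table is
sequential (Type I) in the order covariate, genotype, treatment,
interaction, so the covariate is adjusted for first and the sequential sums
of squares add exactly to the total. Contrasts of every genotype x
treatment cell against the reference cell (wild-type vehicle) are
back-transformed to fold-changes with t-based intervals. Densities of zero
are rejected, not offset: a zero photo density is a measurement failure,
and an arbitrary offset would silently change every fold-change.

Foci tables are per-cell counts. Positivity uses per-marker minimum counts
(gamma-H2AX >= 5, 53BP1 >= 3, RNF168 >= 3, FK2 >= 10, and 10 for GFP-K63
foci) reflecting each marker's background; colocalization is directional
(percent of A foci that are B-positive and the reverse, computed per cell
and averaged within condition). Classical tests wrap the standard
implementations: Student/Welch two-tailed t-tests (Welch-Satterthwaite
degrees of freedom) and Tukey HSD on the studentized range. Two constant
samples with equal means yield p = 1 by convention rather than an error in
a pipeline context.

## What the generators emulate — and what they do not

Each generator produces data with the statistical structure its consumer
assumes, under one fixed set of study conditions:

* `simulate_screen()`: negative-binomial counts (shared dispersion, default
  size 10; mean depth 700 reads per guide, matching the 700-1000x
  representation such screens maintain) over a log-normal baseline
  representation (sdlog 0.4), a 480 x 6 + 50 guide library, essential genes
  (10% of genes, -1 log2 per passage) depleting everywhere and
  drug-interacting genes depleting only in matching arms. Depletion
  kinetics are a convention — the screens publish none — parameterized as
  log2 fold-change per passage with passages indexed by timepoint order.
* `simulate_cga()`: logit-normal variation at two levels (assay sd 0.15
  shared across the assay's conditions, replicate sd 0.15) around a 50%
  transduced baseline, plus additive logit drug effects.
* `simulate_checkerboard()`: 4PL monotherapy survival, Bliss-multiplicative
  combinations, optional planted deviations, additive Gaussian noise.
* `simulate_blot()` / `simulate_foci()`: the exact ANCOVA generative model;
  a two-component (Poisson background / negative-binomial positive) count
  mixture with binomial marker overlap.

Not modeled: sequencing error, PCR jackpotting, cell-cycle or growth
kinetics, flow-gating artifacts, plate-position effects. Passing tests
therefore demonstrate that the estimators recover what they target when
their assumptions hold and stay calibrated under the matching nulls — not
that those assumptions hold in any particular wet-lab dataset.

Problem sizes in the shipped tests and acceptance run are the package's
reporting choices: 500 simulated experiments for coverage and family-error
rates, 50 seeded screens for ranking reliability, 200 noisy curves for
IC50 bias, bootstrap B of 10,000 against the 400,000 default. All
generators are seed-deterministic, and every randomized routine takes an
explicit seed.
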