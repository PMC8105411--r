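# g4screen

Statistics for drug-modifier pooled CRISPR screens and the bench assays
that validate their hits.

Pooled dropout screens against a drug ask which gene knockouts become
selectively lethal under treatment — for example, which DNA-repair losses
sensitize cancer cells to G-quadruplex-stabilizing ligands. Answering that
requires a chain of statistics that rarely lives in one place: counting
sgRNA spacers out of staggered sequencing reads, normalizing and
QC-checking guide representation, turning per-guide count changes into
gene-level depletion scores, consolidating hits across drugs and doses
while excluding counter-screen artifacts, and then quantifying the
follow-up assays — competitive growth, dose-response shifts, drug-synergy
checkerboards, immunoblot densitometry, and nuclear-foci counts. g4screen
implements that whole chain as an R package for screen analysts and
bench scientists, plus a synthetic-data layer that generates inputs with
the statistical structure each stage assumes, so every estimator in the
package is testable end to end without any external download.

## The statistics at the core

**alpha-RRA gene scoring.** Guides are ranked by depletion evidence from a
negative-binomial test (control-fitted mean-variance model, floored at
Poisson) and converted to percentiles p(1) <= ... <= p(k) per gene. The
gene score is the alpha-truncated robust rank aggregation value

    rho = min over {i : p(i) < alpha} of  BetaCDF( p(i); i, k - i + 1 ),

the smallest probability that the i-th of k uniform order statistics falls
at or below p(i), with rho = 1 when no guide percentile beats alpha.
Significance comes from a permutation null of k uniform percentiles with
the add-one convention p = (1 + #{rho* <= rho}) / (n_perm + 1).

**Blocked bootstrap for competitive growth assays.** The DRX2+ (transduced)
fraction has a two-level error structure: assays, then replicates within
assays. Each bootstrap replicate resamples N_a assays with replacement and
then N_r replicates within each drawn assay, averages each condition's
proportions on the logit scale, back-transforms, and differences drug minus
vehicle. Percentile intervals at 95/99/99.9/99.99% come from B = 400,000
differences; Bonferroni over 50 contrasts makes 0.05/50 = 0.001 (the 99.9%
interval) the family-wise 5% criterion.

**Bliss synergy volumes.** A checkerboard's expected combined inhibition
under independence is fx + fy - fx fy from the monotherapy fractions; the
synergy volume accumulates per-cell deviations whose Bonferroni-adjusted
t-interval excludes zero, weighted by each cell's dose-interval area
(dose^2 x percent units), and the antagonism volume its negative mirror.

Around these sit the supporting machinery: exact-match spacer extraction
at any stagger offset, median-ratio normalization, library-representation
QC, 4PL (variable-slope) dose-response fits with profile-likelihood IC50
intervals, Dunnett many-to-one IC50 comparisons, sequential-SS ANCOVA on
log2 densitometry with a loading-control covariate, and foci
positivity/colocalization summaries. See `vignettes/g4screen-methods.Rmd`
for models, assumptions, and design decisions.

## Worked example

```r
library(g4screen)

# 1. simulate a drug-modifier dropout screen with one planted interaction
cfg <- screen_sim_config(
  interacting_genes = data.frame(gene = "GENE010", drug = "CX5461",
                                 lfc = -2.5),
  seed = 1)
screen <- simulate_screen(cfg)
screen
#> count_matrix: 2930 guides x 12 samples
#> conditions: vehicle, CX5461

# 2. score genes for depletion under drug vs vehicle at day 19
lib <- simulate_guide_library(seed = 1)
scores <- score_screen(screen, lib,
                       treatment = list(condition = "CX5461", day = 19),
                       control = list(condition = "vehicle", day = 19),
                       n_perm = 10000, seed = 2)
head(as.data.frame(scores), 3)
#>      gene    rra_score    p_value rank n_guides n_guides_below_alpha is_nt
#> 1 GENE010 7.358895e-17 0.00009999    1        6                    6 FALSE
#> 2 GENE177 2.160844e-05 0.00019998    2        6                    4 FALSE
#> 3 GENE434 1.914080e-03 0.00519948    3        6                    3 FALSE
```

The planted gene ranks first with the smallest attainable permutation
p-value (1/10001); all six of its guides fall below the alpha = 0.05
percentile cut. The packaged published hit table then reproduces the
screen's set arithmetic exactly:

```r
t2 <- table2_hits()
length(consolidate_hits(t2))
#> [1] 81
g4 <- t2[c("CX5461_IC50", "CX5461_IC30", "PDS_IC50", "PDS_IC30")]
length(counter_screen_exclude(g4, t2$BMH21_IC30))
#> [1] 58
sort(setdiff(Reduce(intersect, g4), t2$BMH21_IC30))
#> [1] "ATM"    "H2AFX"  "LIG4"   "POLQ"   "RAD54L" "RNF168"
```

— 81 genes consolidated across the five drug conditions, 58 specific to
the G4 ligands after counter-screen exclusion, and the six-gene core
common to every CX-5461 and PDS condition. Finally, a competitive growth
assay contrast with a planted logit effect of -1:

```r
cga <- simulate_cga(cga_sim_config(drug_effects = c(CX5461 = -1), seed = 3),
                    sgrna = "sgUBE2N.1")
fold_change(cga, "CX5461")
#> [1] 0.5314292
blocked_bootstrap(cga, "CX5461", B = 400000, seed = 4)
#> blocked bootstrap (CX5461 vs vehicle): difference -0.2262, B = 400000
#>          lower   upper
#> 95%    -0.2559 -0.1981
#> 99%    -0.2650 -0.1901
#> 99.9%  -0.2753 -0.1811
#> 99.99% -0.2827 -0.1742
```

The knockout population drops to 53% of its vehicle representation; the
99.9% interval (the Bonferroni family-wise 5% criterion over 50
comparisons) excludes zero, so the fitness defect is called significant.

## The analysis workflow

`analysis/` holds numbered drivers that walk the full pipeline on
generated data, writing tables under `results/`:

| script | stage |
| --- | --- |
| `01_simulate_screen.R` | library + screen counts, FASTQ extraction round-trip, representation QC, coverage/titer arithmetic |
| `02_score_screen.R` | per-condition alpha-RRA gene scores |
| `03_consolidate_hits.R` | p < 0.045 hits, consolidation, counter-screen exclusion, UpSet intersections; published-table arithmetic |
| `04_cga_bootstrap.R` | blocked bootstrap (B = 400,000) over a guide x drug panel with Bonferroni calls |
| `05_dose_response_synergy.R` | 4PL fits, Dunnett IC50 comparison, checkerboard synergy volumes |
| `06_blot_foci.R` | densitometry ANCOVA, foci positivity, colocalization, Welch/Tukey tests |

Run them in order with `Rscript analysis/01_simulate_screen.R` etc.

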