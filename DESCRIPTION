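Package: g4screen
Title: Statistics for Drug-Modifier Pooled CRISPR Screens and Their Validation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end statistical toolkit for pooled CRISPR dropout screens
    run against drug treatments (for example G-quadruplex stabilizers) and the
    bench assays used to validate screen hits. Provides guide-library handling,
    exact-match spacer counting from FASTQ, median-ratio normalization and
    library QC; a negative-binomial per-guide test with alpha-truncated robust
    rank aggregation (alpha-RRA) and permutation p-values for gene-level
    depletion scoring; hit consolidation across drug conditions with
    counter-screen exclusion and UpSet-style exclusive intersections; blocked
    (two-level) bootstrap inference for competitive growth assays with
    Bonferroni family-wise calibration; four-parameter logistic dose-response
    fitting with profile-likelihood IC50 intervals and Dunnett many-to-one
    comparisons; Bliss-independence synergy/antagonism volume analysis for
    dose checkerboards; ANCOVA for loading-control-adjusted densitometry; and
    immunofluorescence foci positivity and colocalization summaries. A
    synthetic-data module generates inputs with the statistical structure each
    stage assumes, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    multcomp,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
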