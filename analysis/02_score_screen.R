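#!/usr/bin/env Rscript
# Stage 2: gene-level depletion scoring of every drug arm against vehicle.
#
# Normalizes day-19 counts by median ratios, runs the per-guide
# negative-binomial depletion test, aggregates guides per gene with
# alpha-truncated robust rank aggregation, and attaches permutation
# p-values. One gene-score table per drug condition lands in results/.

library(g4screen)
dir.create("results", showWarnings = FALSE)

scr <- read_count_matrix("results/screen_counts.tsv")
lib <- read_guide_library("results/guide_library.tsv")
drugs <- setdiff(unique(scr$samples$condition), "vehicle")

for (drug in drugs) {
  gs <- score_screen(scr, lib,
                     treatment = list(condition = drug, day = 19),
                     control = list(condition = "vehicle", day = 19),
                     alpha = 0.05, n_perm = 10000, seed = 42)
  out <- file.path("results", sprintf("gene_scores_%s.tsv", drug))
  write.table(as.data.frame(gs), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  top <- head(gs[!gs$is_nt, ], 5)
  cat(sprintf("%s vs vehicle: top depleted genes %s (scores %s)\n", drug,
              paste(top$gene, collapse = ", "),
              paste(signif(top$rra_score, 2), collapse = ", ")))
}
cat("gene score tables written under results/\n")
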