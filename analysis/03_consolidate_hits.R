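#!/usr/bin/env Rscript
# Stage 3: hit consolidation across drug conditions.
#
# Thresholds each condition's gene scores at p < 0.045, consolidates the
# G4-ligand hits, removes genes shared with the counter screen, and builds
# UpSet-style exclusive intersections. The same set arithmetic is then
# applied to the packaged published top-depleted-gene table, reproducing
# its 81-gene union and 58 G4-specific genes.

library(g4screen)
dir.create("results", showWarnings = FALSE)

score_files <- list.files("results", "^gene_scores_.*\\.tsv$",
                          full.names = TRUE)
scores <- lapply(score_files, read.delim)
names(scores) <- sub("^gene_scores_(.*)\\.tsv$", "\\1", basename(score_files))

hits <- lapply(scores, threshold_hits, p_cut = 0.045)
cat("hits per condition:",
    paste(sprintf("%s=%d", names(hits), lengths(hits)), collapse = ", "),
    "\n")

g4_conditions <- setdiff(names(hits), "BMH21")
consolidated <- consolidate_hits(hits[g4_conditions])
specific <- counter_screen_exclude(hits[g4_conditions], hits$BMH21)
cat(sprintf("consolidated G4 hits: %d; specific after counter-screen exclusion: %d\n",
            length(consolidated), length(specific)))
isets <- intersection_sets(hits)
cat("largest exclusive intersections:\n")
print(head(sort(lengths(isets), decreasing = TRUE)))

# published table: the in-paper dataset that makes the arithmetic checkable
t2 <- table2_hits()
t2_union <- consolidate_hits(t2)
t2_g4 <- t2[c("CX5461_IC50", "CX5461_IC30", "PDS_IC50", "PDS_IC30")]
t2_specific <- counter_screen_exclude(t2_g4, t2$BMH21_IC30)
t2_core <- setdiff(Reduce(intersect, t2_g4), t2$BMH21_IC30)
cat(sprintf("published table: union %d genes, G4-specific %d, core common set: %s\n",
            length(t2_union), length(t2_specific),
            paste(t2_core, collapse = ", ")))

json <- c(
  sprintf('"simulated_consolidated": [%s]',
          paste(sprintf('"%s"', consolidated), collapse = ",")),
  sprintf('"simulated_g4_specific": [%s]',
          paste(sprintf('"%s"', specific), collapse = ",")),
  sprintf('"published_union_n": %d', length(t2_union)),
  sprintf('"published_g4_specific_n": %d', length(t2_specific)),
  sprintf('"published_core_common": [%s]',
          paste(sprintf('"%s"', t2_core), collapse = ",")))
writeLines(paste0("{", paste(json, collapse = ", "), "}"),
           "results/hits.json")
cat("hit sets written to results/hits.json\n")
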