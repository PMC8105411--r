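#!/usr/bin/env Rscript
# Stage 1: generate the focused-library dropout screen and check library QC.
#
# Builds a 480-gene x 6-guide library with 50 non-targeting controls,
# simulates negative-binomial counts for vehicle and three drug arms with
# planted drug-gene interactions, and writes the library, the count matrix
# and a QC report under results/.

library(g4screen)
dir.create("results", showWarnings = FALSE)

# planted truths: a handful of G4-drug-specific genes plus one
# counter-screen-shared gene, mirroring a drug-modifier screen's structure
interactions <- rbind(
  data.frame(gene = c("GENE010", "GENE020", "GENE030", "GENE040"),
             drug = "CX5461", lfc = c(-2.5, -2, -1.5, -1.2)),
  data.frame(gene = c("GENE010", "GENE020", "GENE050"),
             drug = "PDS", lfc = c(-2, -1.8, -1.5)),
  data.frame(gene = "GENE040", drug = "BMH21", lfc = -1.5))

cfg <- screen_sim_config(interacting_genes = interactions,
                         essential_fraction = 0.1, essential_lfc = -1,
                         depth = 700, dispersion = 10,
                         timepoints = c(1, 19), replicates = 3, seed = 20260920)
lib <- simulate_guide_library(seed = cfg$seed)
scr <- simulate_screen(cfg, lib)

write_guide_library(lib, "results/guide_library.tsv")
write_count_matrix(scr, "results/screen_counts.tsv")
cat(sprintf("simulated %d guides x %d samples (%s)\n", nrow(scr$counts),
            ncol(scr$counts), paste(unique(scr$samples$condition),
                                    collapse = ", ")))

# spacer-extraction round trip on a small FASTQ carrying the day-1 pool
sub <- lib[seq(1, nrow(lib), by = 30), ]
sub_lib <- guide_library(sub$sgrna, sub$gene, sub$spacer, sub$is_nt)
write_screen_fastq("results/day1_pool.fastq.gz", sub_lib,
                   reads_per_guide = 20L, anchor = "CACCG", seed = cfg$seed)
cm_fq <- extract_counts("results/day1_pool.fastq.gz", sub_lib,
                        anchor = "CACCG", sample_name = "day1_pool")
cat(sprintf("FASTQ extraction: %d reads mapped, %d unmapped\n",
            sum(cm_fq$counts), cm_fq$unmapped[[1]]))
stopifnot(all(cm_fq$counts == 20L))

# library representation QC on the day-1 vehicle sample (the pool proxy)
pool <- count_matrix(scr$counts[, "vehicle_d1_r1", drop = FALSE],
                     scr$guides$gene)
qc <- library_qc(pool, lib)
print(qc)
writeLines(sprintf(
  '{"percent_detected": %.4f, "fold_difference_80pct": %.4f, "n_zero": %d}',
  qc$percent_detected, qc$quantile_fold_difference,
  length(qc$zero_count_guides)), "results/library_qc.json")

cat(sprintf("sequencing 10 ug gDNA at 7.5 pg/cell covers each of %d guides %.0fx\n",
            nrow(lib), coverage_per_guide(10, 7.5, nrow(lib))))
cat(sprintf("titration example: survival 0.5, 1e6 cells, 50 ul -> %.2e TU/mL\n",
            viral_titer(0.5, 1e6, 50)))
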