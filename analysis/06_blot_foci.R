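#!/usr/bin/env Rscript
# Stage 6: validation-assay statistics — ANCOVA densitometry and foci
# summaries.
#
# Fits the loading-control-adjusted ANCOVA to simulated immunoblot
# densities (log2 signal ~ log2 loading + genotype * treatment), prints the
# sequential ANOVA table and fold-change contrasts, then summarizes per-cell
# foci tables: positivity at per-marker thresholds, directional
# colocalization, and Welch / Tukey tests.

library(g4screen)
dir.create("results", showWarnings = FALSE)

## densitometry: knockout suppresses the ubiquitination signal
blot <- simulate_blot(genotypes = c("WT", "KO"),
                      treatments = c("vehicle", "1h", "3h", "5h"),
                      lanes_per_cell = 2, beta0 = 9, beta_load = 1,
                      genotype_effects = c(KO = -1.2),
                      treatment_effects = c(`3h` = 0.6, `5h` = 0.8),
                      noise_sd = 0.4, seed = 31)
write.csv(blot, "results/blot_densitometry.csv", row.names = FALSE)
fit <- ancova_blot(blot, ref_genotype = "WT", ref_treatment = "vehicle")
print(fit)
write.table(cbind(term = rownames(fit$anova_table), fit$anova_table),
            "results/blot_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("fold changes vs the wild-type vehicle reference:\n")
print(fit$contrasts, row.names = FALSE)

## foci: drug raises the focus-positive subpopulation
foci <- rbind(
  simulate_foci(500, positive_fraction = 0.40, mu_pos = 18, mu_neg = 1,
                marker = "FK2", condition = "CX5461_0.1uM", seed = 41),
  simulate_foci(500, positive_fraction = 0.06, mu_pos = 14, mu_neg = 1,
                marker = "FK2", condition = "vehicle", seed = 42))
write.csv(foci, "results/foci_counts.csv", row.names = FALSE)
pos <- foci_positive(foci)
print(pos, row.names = FALSE)

co <- colocalization(
  rbind(simulate_foci(300, 0.5, 12, marker = "FK2",
                      condition = "CX5461_0.1uM", overlap_prob = 0.6,
                      seed = 43),
        simulate_foci(300, 0.5, 9, marker = "BG4",
                      condition = "CX5461_0.1uM", overlap_prob = 0.45,
                      seed = 44)),
  "FK2", "BG4")
print(co, row.names = FALSE)

w <- two_sample_test(foci$foci_count[foci$condition == "CX5461_0.1uM"],
                     foci$foci_count[foci$condition == "vehicle"],
                     mode = "welch")
cat(sprintf("Welch two-tailed test on per-cell foci counts: t = %.2f, df = %.1f, p = %.3g\n",
            w$t, w$df, w$p_value))
tk <- tukey_hsd(foci$foci_count, foci$condition)
cat("Tukey HSD at 95% family-wise confidence:\n")
print(tk, row.names = FALSE)
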