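#!/usr/bin/env Rscript
# Stage 5: dose-response comparison and drug-combination synergy.
#
# Fits four-parameter logistic curves per genotype, compares per-replicate
# IC50s against the control by one-way ANOVA with Dunnett's test, then
# analyzes an equipotency checkerboard (5 x 9 doses, anchored at the two
# drugs' IC50s) for Bliss synergy/antagonism volumes.

library(g4screen)
dir.create("results", showWarnings = FALSE)

## genotype IC50 shifts: knockouts sensitize ~3x to the G4 ligand
doses <- 10^seq(-1.5, 2, length.out = 9)   # nM
genos <- list(WT = 30, sgKO.1 = 10, sgKO.2 = 12, sgKO.3 = 11)
fits <- list(); ic50_reps <- list()
for (g in names(genos)) {
  reps <- vapply(1:3, function(r) {
    d <- simulate_dose_response(doses, bottom = 0.05, top = 1,
                                ic50 = genos[[g]], hill = 1.3, cv = 0.05,
                                replicates = 1, group = g, seed = 100 + r +
                                  10 * match(g, names(genos)))
    fit_4pl(d)$ic50
  }, numeric(1))
  ic50_reps[[g]] <- reps
  d_all <- simulate_dose_response(doses, 0.05, 1, genos[[g]], 1.3, 0.05,
                                  replicates = 3, group = g,
                                  seed = 10 * match(g, names(genos)))
  fits[[g]] <- fit_4pl(d_all)
  cat(sprintf("%-8s IC50 %6.2f nM (95%% CI %.2f-%.2f)\n", g,
              fits[[g]]$ic50, fits[[g]]$ic50_ci[1], fits[[g]]$ic50_ci[2]))
}
cmp <- compare_ic50_anova_dunnett(ic50_reps, control = "WT", seed = 2)
cat(sprintf("one-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n", cmp$anova$df1,
            cmp$anova$df2, cmp$anova$F, cmp$anova$p))
print(cmp$comparisons, row.names = FALSE)
write.table(cmp$comparisons, "results/ic50_dunnett.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## checkerboard at the published equipotency anchors (nM)
dx <- equipotency_doses(166.1)                                   # 5 doses
dy <- equipotency_doses(7.4, c(0.03125, 0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8))
board <- simulate_checkerboard(
  dx, dy,
  params_x = list(bottom = 0, top = 1, ic50 = 166.1, hill = 1.3),
  params_y = list(bottom = 0, top = 1, ic50 = 7.4, hill = 1.3),
  synergy_bump = data.frame(dose_x = 166.1, dose_y = c(1.85, 3.7),
                            dev = c(0.15, 0.12)),
  noise_sd = 0.02, replicates = 6, seed = 77)
write.csv(board, "results/checkerboard.csv", row.names = FALSE)
for (conf in c(0.95, 0.99, 0.999)) {
  sv <- synergy_volumes(board, confidence = conf)
  cat(sprintf("at %g%% CI (Bonferroni %d): synergy %.1f nM^2%%, antagonism %.2f nM^2%% (log volumes %.2f / %.2f)\n",
              100 * conf, sv$bonferroni, sv$synergy_volume,
              sv$antagonism_volume, sv$log_synergy_volume,
              sv$log_antagonism_volume))
}
sv_un <- synergy_volumes(board, confidence = 0.95, bonferroni = 1)
cat(sprintf("without Bonferroni adjustment (95%% CI): synergy %.1f nM^2%%, antagonism %.2f nM^2%%\n",
            sv_un$synergy_volume, sv_un$antagonism_volume))
sv95 <- synergy_volumes(board, confidence = 0.95)
peak <- which(sv95$deviation == max(sv95$deviation), arr.ind = TRUE)
cat(sprintf("peak deviation %.1f%% at %s nM x %s nM\n",
            max(sv95$deviation), rownames(sv95$deviation)[peak[1]],
            colnames(sv95$deviation)[peak[2]]))
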