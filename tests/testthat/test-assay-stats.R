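test_that("ANCOVA reproduces exact model data with zero residual", {
  b <- simulate_blot(genotypes = c("WT", "KO"),
                     treatments = c("vehicle", "drug"),
                     lanes_per_cell = 3, beta0 = 9, beta_load = 1.2,
                     genotype_effects = c(KO = -1),
                     treatment_effects = c(drug = 0.5),
                     noise_sd = 0, seed = 4)
  fit <- suppressWarnings(ancova_blot(b, ref_genotype = "WT",
                                      ref_treatment = "vehicle"))
  atab <- fit$anova_table
  expect_lt(atab["Residuals", "Sum Sq"], 1e-18)
  cf <- coef(fit$fit)
  expect_equal(unname(cf["l"]), 1.2, tolerance = 1e-9)
  ko <- fit$contrasts
  expect_equal(ko$log2_fc[ko$genotype == "KO" & ko$treatment == "vehicle"],
               -1, tolerance = 1e-9)
  expect_equal(ko$fold_change[ko$genotype == "KO" & ko$treatment == "vehicle"],
               0.5, tolerance = 1e-9)
  expect_equal(ko$log2_fc[ko$genotype == "WT" & ko$treatment == "drug"],
               0.5, tolerance = 1e-9)
  expect_equal(ko$log2_fc[ko$genotype == "WT" & ko$treatment == "vehicle"], 0)
})

test_that("sequential SS match marginal SS on a balanced covariate-orthogonal design against a normal-equations oracle", {
  # every cell receives the same loading values, so log2(loading) is
  # orthogonal to the genotype/treatment contrasts
  cells <- expand.grid(genotype = c("WT", "KO"),
                       treatment = c("veh", "drug"),
                       stringsAsFactors = FALSE)
  loads <- c(100, 200, 400, 800)
  df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(genotype = cells$genotype[i], treatment = cells$treatment[i],
               loading = loads)))
  set.seed(12)
  df$signal <- 2^(8 + 0.9 * log2(df$loading) +
                    ifelse(df$genotype == "KO", -0.7, 0) +
                    ifelse(df$treatment == "drug", 0.4, 0) +
                    rnorm(nrow(df), 0, 0.2))
  fit <- ancova_blot(df, ref_genotype = "WT", ref_treatment = "veh")
  atab <- fit$anova_table

  # normal-equations oracle: sequential SS via explicit projections
  y <- log2(df$signal)
  # sum-to-zero contrast columns: mutually orthogonal in this balanced
  # design and orthogonal to the cell-repeated loading covariate
  gc_ <- ifelse(df$genotype == "KO", 1, -1)
  tc_ <- ifelse(df$treatment == "drug", 1, -1)
  X_parts <- list(intercept = matrix(1, nrow(df), 1),
                  l = cbind(log2(df$loading)),
                  genotype = cbind(gc_),
                  treatment = cbind(tc_),
                  `genotype:treatment` = cbind(gc_ * tc_))
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  seq_ss <- numeric(0)
  X <- X_parts$intercept
  prev <- rss(X)
  for (term in c("l", "genotype", "treatment", "genotype:treatment")) {
    X <- cbind(X, X_parts[[term]])
    cur <- rss(X)
    seq_ss[term] <- prev - cur
    prev <- cur
  }
  expect_equal(atab[c("l", "genotype", "treatment", "genotype:treatment"),
                    "Sum Sq"], unname(seq_ss), tolerance = 1e-10)
  expect_equal(atab["Residuals", "Sum Sq"], prev, tolerance = 1e-10)

  # marginal (drop-one-from-full) SS for the factor main effects coincide
  full_terms <- c("l", "genotype", "treatment", "genotype:treatment")
  X_full <- do.call(cbind, c(list(X_parts$intercept), X_parts[full_terms]))
  for (term in c("l", "genotype", "treatment")) {
    X_red <- do.call(cbind, c(list(X_parts$intercept),
                              X_parts[setdiff(full_terms, term)]))
    expect_equal(atab[term, "Sum Sq"], rss(X_red) - rss(X_full),
                 tolerance = 1e-10)
  }
  # sequential SS sum exactly to the total SS
  expect_equal(sum(atab[, "Sum Sq"]), sum((y - mean(y))^2),
               tolerance = 1e-10)
})

test_that("ANCOVA rejects non-positive densities and aliased designs", {
  b <- simulate_blot(seed = 1)
  b$signal[1] <- 0
  expect_error(ancova_blot(b), "strictly positive")
  b2 <- simulate_blot(genotypes = c("WT", "KO"),
                      treatments = c("veh", "drug"), seed = 2)
  b2 <- b2[!(b2$genotype == "KO" & b2$treatment == "drug"), ]
  expect_error(suppressWarnings(ancova_blot(b2)), "aliased")
})

test_that("the treatment F-test is uniformly calibrated under a true null", {
  pvals <- vapply(1:300, function(s) {
    b <- simulate_blot(genotypes = c("WT", "KO"),
                       treatments = c("veh", "drug"), lanes_per_cell = 3,
                       genotype_effects = c(KO = -0.8), noise_sd = 0.3,
                       seed = s)
    ancova_blot(b)$anova_table["treatment", "Pr(>F)"]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("foci positivity applies per-marker thresholds", {
  tab <- data.frame(cell = paste0("c", 1:6), marker = "FK2",
                    foci_count = c(10, 9, 0, 25, 11, 3),
                    condition = rep(c("drug", "vehicle"), each = 3))
  out <- foci_positive(tab)
  # manual count: drug cells (10, 9, 0) -> 1/3; vehicle (25, 11, 3) -> 2/3
  expect_equal(out$percent_positive[out$condition == "drug"], 100 / 3)
  expect_equal(out$percent_positive[out$condition == "vehicle"], 200 / 3)
  tab0 <- transform(tab, foci_count = 0)
  expect_true(all(foci_positive(tab0)$percent_positive == 0))
  expect_error(foci_positive(transform(tab, marker = "new")), "threshold")
  # monotone non-increasing in the threshold
  f <- simulate_foci(n_cells = 500, seed = 3)
  pcts <- vapply(c(2, 5, 10, 15), function(th)
    foci_positive(f, thresholds = c(FK2 = th))$percent_positive, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("colocalization is directional and matches brute-force per-cell arithmetic", {
  tab <- rbind(data.frame(cell = "c1", marker = "A", foci_count = 10,
                          overlap_count = 4, condition = "drug"),
               data.frame(cell = "c1", marker = "B", foci_count = 8,
                          overlap_count = 4, condition = "drug"))
  out <- colocalization(tab, "A", "B")
  expect_equal(out$percent_overlap[grepl("^A", out$direction)], 40)
  expect_equal(out$percent_overlap[grepl("^B", out$direction)], 50)

  full <- transform(tab, overlap_count = foci_count)
  expect_true(all(colocalization(full, "A", "B")$percent_overlap == 100))
  expect_error(colocalization(transform(tab, overlap_count = foci_count + 1),
                              "A", "B"), "integrity")

  set.seed(9)
  rnd <- data.frame(cell = rep(paste0("c", 1:20), 2),
                    marker = rep(c("A", "B"), each = 20),
                    foci_count = rpois(40, 6) + 1,
                    condition = "x")
  rnd$overlap_count <- rbinom(40, rnd$foci_count, 0.5)
  out2 <- colocalization(rnd, "A", "B")
  brute <- mean(100 * rnd$overlap_count[rnd$marker == "A"] /
                  rnd$foci_count[rnd$marker == "A"])
  expect_equal(out2$percent_overlap[grepl("^A", out2$direction)], brute)
})

test_that("classical tests match their analytic identities", {
  x <- c(1, 1, 1); y <- c(1, 1, 1)
  res <- two_sample_test(x, y)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_error(two_sample_test(c(1, 1), c(2, 2)), "degenerate")

  set.seed(10)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  w <- two_sample_test(a, b, mode = "welch")
  s <- two_sample_test(a, b, mode = "student")
  # equal n: Welch and Student t statistics coincide; dfs differ unless the
  # sample variances are equal
  expect_equal(w$t, s$t, tolerance = 1e-12)
  a2 <- a; b2 <- a + 1    # identical variances
  expect_equal(two_sample_test(a2, b2, "welch")$p_value,
               two_sample_test(a2, b2, "student")$p_value, tolerance = 1e-12)

  # Tukey with two groups collapses to the pooled t-test (q = t * sqrt(2))
  tk <- tukey_hsd(c(a, b), rep(c("g1", "g2"), each = 8))
  expect_equal(tk$p_adj, t.test(b, a, var.equal = TRUE)$p.value,
               tolerance = 1e-8)
  expect_equal(tk$diff, mean(b) - mean(a))
})
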