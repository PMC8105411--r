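#' ANCOVA for loading-control-adjusted densitometry
#'
#' Fits `log2(signal) ~ log2(loading) + genotype * treatment` by least
#' squares: photo densities are log2-transformed (removing the lower bound
#' of zero and turning treatment differences into fold-changes), the loading
#' control enters as a covariate with a single shared slope (equal-slopes
#' assumption), and genotype, treatment and their interaction are fixed
#' effects. The ANOVA table is sequential (Type I) in the order
#' covariate, genotype, treatment, interaction. Contrasts of every occupied
#' genotype x treatment cell against the reference cell are back-transformed
#' to fold-changes with confidence intervals.
#'
#' @param table data.frame with columns `signal`, `loading` (both strictly
#'   positive densities), `genotype`, `treatment`.
#' @param ref_genotype,ref_treatment reference cell (defaults: first levels,
#'   e.g. wild-type vehicle).
#' @param ci_level confidence level for fold-change intervals.
#' @return list of class `blot_ancova`: `anova_table` (Df, Sum Sq, Mean Sq,
#'   F value, Pr(>F)), `contrasts` (per-cell log2 fold-change, fold-change,
#'   CI), `fit` (the `lm` object).
#' @export
ancova_blot <- function(table, ref_genotype = NULL, ref_treatment = NULL,
                        ci_level = 0.95) {
  check_columns(table, c("signal", "loading", "genotype", "treatment"),
                "table")
  if (any(table$signal <= 0) || any(table$loading <= 0))
    stop("densities must be strictly positive for the log2 transform",
         call. = FALSE)
  d <- data.frame(y = log2(table$signal), l = log2(table$loading),
                  genotype = factor(table$genotype),
                  treatment = factor(table$treatment))
  if (!is.null(ref_genotype)) d$genotype <- stats::relevel(d$genotype,
                                                           ref_genotype)
  if (!is.null(ref_treatment)) d$treatment <- stats::relevel(d$treatment,
                                                             ref_treatment)
  fit <- stats::lm(y ~ l + genotype * treatment, data = d)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  atab <- as.data.frame(stats::anova(fit))

  # cell contrasts vs the reference cell at equal loading
  cells <- unique(d[, c("genotype", "treatment")])
  cells <- cells[order(cells$genotype, cells$treatment), ]
  ref <- data.frame(genotype = factor(levels(d$genotype)[1],
                                      levels(d$genotype)),
                    treatment = factor(levels(d$treatment)[1],
                                       levels(d$treatment)))
  mm <- function(cell) {
    cell$genotype <- factor(cell$genotype, levels(d$genotype))
    cell$treatment <- factor(cell$treatment, levels(d$treatment))
    cell$l <- 0
    stats::model.matrix(stats::delete.response(stats::terms(fit)), cell)
  }
  x_ref <- mm(ref)
  tq <- stats::qt(1 - (1 - ci_level) / 2, fit$df.residual)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    x <- mm(cells[i, ]) - x_ref
    est <- drop(x %*% stats::coef(fit))
    se <- sqrt(drop(x %*% stats::vcov(fit) %*% t(x)))
    data.frame(genotype = as.character(cells$genotype[i]),
               treatment = as.character(cells$treatment[i]),
               log2_fc = est, fold_change = 2^est,
               fc_lower = 2^(est - tq * se), fc_upper = 2^(est + tq * se),
               stringsAsFactors = FALSE)
  })
  structure(list(anova_table = atab, contrasts = do.call(rbind, rows),
                 fit = fit, ci_level = ci_level),
            class = "blot_ancova")
}

#' @export
print.blot_ancova <- function(x, ...) {
  cat("ANCOVA on log2 densitometry (sequential ANOVA table):\n")
  print(round(x$anova_table, 4))
  invisible(x)
}

#' Percent of foci-positive cells per condition
#'
#' A cell is focus-positive when its count reaches the marker's minimum
#' (defaults: gamma-H2AX >= 5, 53BP1 >= 3, RNF168 >= 3, FK2 >= 10, and 10
#' for GFP-K63 foci).
#'
#' @param table data.frame with columns `cell`, `marker`, `foci_count`,
#'   `condition`.
#' @param thresholds named numeric vector, marker -> minimum count.
#' @return data.frame `condition`, `marker`, `n_cells`, `percent_positive`.
#' @export
foci_positive <- function(table,
                          thresholds = c(gH2AX = 5, `53BP1` = 3, RNF168 = 3,
                                         FK2 = 10, K63 = 10)) {
  check_columns(table, c("marker", "foci_count", "condition"), "table")
  miss <- setdiff(unique(table$marker), names(thresholds))
  if (length(miss))
    stop("no positivity threshold for marker(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  agg <- function(sub) {
    thr <- thresholds[[sub$marker[1]]]
    data.frame(condition = sub$condition[1], marker = sub$marker[1],
               n_cells = nrow(sub),
               percent_positive = 100 * mean(sub$foci_count >= thr),
               stringsAsFactors = FALSE)
  }
  parts <- split(table, list(table$condition, table$marker), drop = TRUE)
  out <- do.call(rbind, lapply(parts, agg))
  rownames(out) <- NULL
  out
}

#' Directional foci colocalization
#'
#' Percent of marker-A foci that are also marker-B positive and the reverse,
#' computed per cell (100 * overlap / total) and averaged within condition.
#' The two directions are not symmetric because the denominators differ.
#'
#' @param table data.frame with columns `cell`, `marker`, `foci_count`,
#'   `overlap_count`, `condition`; `overlap_count` is the number of that
#'   marker's foci overlapping the other marker.
#' @param marker_a,marker_b the two marker labels.
#' @return data.frame `condition`, `direction`, `n_cells`,
#'   `percent_overlap`.
#' @export
colocalization <- function(table, marker_a, marker_b) {
  check_columns(table, c("cell", "marker", "foci_count", "overlap_count",
                         "condition"), "table")
  if (any(table$overlap_count > table$foci_count))
    stop("overlap_count exceeds foci_count: integrity error", call. = FALSE)
  one_direction <- function(m, label) {
    sub <- table[table$marker == m & table$foci_count > 0, ]
    if (!nrow(sub)) return(NULL)
    per_cell <- 100 * sub$overlap_count / sub$foci_count
    agg <- tapply(per_cell, sub$condition, mean)
    data.frame(condition = names(agg), direction = label,
               n_cells = as.integer(table(sub$condition)[names(agg)]),
               percent_overlap = unname(agg), stringsAsFactors = FALSE)
  }
  out <- rbind(one_direction(marker_a,
                             paste0(marker_a, " foci that are ", marker_b,
                                    "+")),
               one_direction(marker_b,
                             paste0(marker_b, " foci that are ", marker_a,
                                    "+")))
  rownames(out) <- NULL
  out
}

#' Two-sample t-tests (Student or Welch)
#'
#' Two-tailed unpaired t-test; `mode = "welch"` uses the Welch-Satterthwaite
#' degrees of freedom for unequal variances. When both samples are constant
#' with equal means, p = 1 by convention; constant samples with unequal
#' means are a degenerate-input error.
#'
#' @param x,y numeric samples (>= 2 observations each).
#' @param mode `"student"` (pooled variance) or `"welch"`.
#' @return list with `t`, `df`, `p_value`, `estimate` (mean difference).
#' @export
two_sample_test <- function(x, y, mode = c("welch", "student")) {
  mode <- match.arg(mode)
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 observations per sample", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  estimate = 0))
    stop("both samples constant with unequal means: degenerate input",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = (mode == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, estimate = unname(diff(rev(tt$estimate))))
}

#' Tukey honest significant differences
#'
#' All pairwise group comparisons via the studentized-range distribution at
#' a family-wise confidence level.
#'
#' @param values numeric vector.
#' @param groups group labels (same length).
#' @param conf_level family-wise confidence level.
#' @return data.frame `comparison`, `diff`, `lower`, `upper`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  df <- data.frame(value = values, group = factor(groups))
  if (nlevels(df$group) < 2L) stop("need >= 2 groups", call. = FALSE)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lower = tk[, "lwr"], upper = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}
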