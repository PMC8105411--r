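#' Read a competitive growth assay table
#'
#' CSV with columns `sgrna`, `assay`, `replicate`, `condition` and either
#' `proportion` (in (0,1)) or `percent_drx2` (0-100, converted).
#'
#' @param path file path.
#' @return data.frame with a `proportion` column.
#' @export
read_cga <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sgrna", "assay", "replicate", "condition"), "CGA file")
  if (is.null(df$proportion)) {
    check_columns(df, "percent_drx2", "CGA file")
    df$proportion <- df$percent_drx2 / 100
  }
  df
}

#' Fold-change of the DRX2+ fraction, drug vs vehicle
#'
#' Ratio of the grand mean (over assays and replicates) of the DRX2+
#' proportion under the drug condition to the vehicle grand mean.
#'
#' @param cga data.frame with columns `assay`, `replicate`, `condition`,
#'   `proportion`.
#' @param condition drug condition label.
#' @param vehicle vehicle condition label.
#' @return the fold-change (a positive ratio).
#' @export
fold_change <- function(cga, condition, vehicle = "vehicle") {
  check_columns(cga, c("condition", "proportion"), "cga")
  for (cc in c(condition, vehicle))
    if (!cc %in% cga$condition)
      stop("condition not present: ", cc, call. = FALSE)
  mv <- mean(cga$proportion[cga$condition == vehicle])
  if (mv == 0) stop("vehicle mean proportion is zero", call. = FALSE)
  mean(cga$proportion[cga$condition == condition]) / mv
}

#' Blocked bootstrap for a competitive growth assay contrast
#'
#' Resamples the experiment's grouping structure: assays are drawn with
#' replacement (outer block), then replicates within each drawn assay are
#' drawn with replacement (inner block), giving a resampled data set of the
#' original shape. Per bootstrap replicate, the mean DRX2+ proportion of
#' each condition is computed in logit space, back-transformed, and the
#' drug-minus-vehicle difference recorded. Percentile confidence intervals
#' at 95/99/99.9/99.99\% are read from the `B` bootstrapped differences.
#'
#' By default the same resampled assay indices are applied to both arms
#' (paired resampling, reflecting that an assay contributes wells to every
#' condition); replicate indices are drawn independently per arm since the
#' wells are distinct. Set `independent_arms = TRUE` to resample assays
#' independently per arm.
#'
#' @param cga data.frame with columns `assay`, `replicate`, `condition`,
#'   `proportion` (all proportions strictly inside (0, 1); see
#'   [clamp_proportions()]).
#' @param condition drug condition label.
#' @param vehicle vehicle condition label.
#' @param B number of bootstrap replicates (default 400000, the full-scale
#'   analysis; >= 1000 required for CI reporting).
#' @param seed integer seed.
#' @param levels confidence levels for the reported intervals.
#' @param independent_arms resample assays independently in the two arms.
#' @param keep_samples retain the bootstrap differences (needed by
#'   [fwer_call()]).
#' @return an object of class `cga_bootstrap`: `point` (observed difference,
#'   proportion scale), `cis` (matrix level x \[lower, upper\]), `B`, `seed`,
#'   `boot_mean`, `boot_sd`, and `samples` when `keep_samples`.
#' @export
blocked_bootstrap <- function(cga, condition, vehicle = "vehicle",
                              B = 400000L, seed = 1L,
                              levels = c(0.95, 0.99, 0.999, 0.9999),
                              independent_arms = FALSE,
                              keep_samples = TRUE) {
  check_columns(cga, c("assay", "replicate", "condition", "proportion"),
                "cga")
  check_count_scalar(B, "B", min = 1000L)
  if (any(cga$proportion <= 0 | cga$proportion >= 1))
    stop("proportions of exactly 0 or 1 present; apply clamp_proportions() ",
         "before bootstrapping", call. = FALSE)
  arms <- list(drug = cga[cga$condition == condition, ],
               veh = cga[cga$condition == vehicle, ])
  if (!nrow(arms$drug) || !nrow(arms$veh))
    stop("contrast conditions not present in the data", call. = FALSE)

  assays <- sort(unique(c(arms$drug$assay, arms$veh$assay)))
  n_a <- length(assays)
  # logit values per assay per arm
  val <- lapply(arms, function(a)
    lapply(assays, function(id) {
      x <- logit(a$proportion[a$assay == id])
      if (!length(x)) stop("assay ", id, " missing from one arm", call. = FALSE)
      x
    }))
  n_r <- vapply(val$drug, length, integer(1))
  balanced <- length(unique(c(n_r, vapply(val$veh, length, integer(1))))) == 1L

  point <- inv_logit(mean(unlist(val$drug))) -
    inv_logit(mean(unlist(val$veh)))

  set.seed(seed)
  draw_assays <- function() matrix(sample.int(n_a, B * n_a, replace = TRUE),
                                   B, n_a)
  A_drug <- draw_assays()
  A_veh <- if (independent_arms) draw_assays() else A_drug

  boot_arm_mean <- function(A, vals) {
    if (balanced) {
      nr <- length(vals[[1]])
      m <- matrix(unlist(vals), nrow = nr)  # replicates x assays
      # replicate draws: B x (n_a * nr) indices into rows of m
      ridx <- matrix(sample.int(nr, B * n_a * nr, replace = TRUE), B)
      aidx <- A[, rep(seq_len(n_a), each = nr), drop = FALSE]
      rowMeans(matrix(m[cbind(as.vector(ridx), as.vector(aidx))], B))
    } else {
      vapply(seq_len(B), function(b) {
        mean(unlist(lapply(A[b, ], function(a) {
          x <- vals[[a]]
          x[sample.int(length(x), length(x), replace = TRUE)]
        })))
      }, numeric(1))
    }
  }
  d <- inv_logit(boot_arm_mean(A_drug, val$drug)) -
    inv_logit(boot_arm_mean(A_veh, val$veh))

  cis <- t(vapply(levels, function(l)
    stats::quantile(d, c((1 - l) / 2, 1 - (1 - l) / 2), names = FALSE),
    numeric(2)))
  dimnames(cis) <- list(sprintf("%g%%", 100 * levels), c("lower", "upper"))
  structure(list(condition = condition, vehicle = vehicle, point = point,
                 B = as.integer(B), seed = as.integer(seed),
                 levels = levels, cis = cis,
                 boot_mean = mean(d), boot_sd = stats::sd(d),
                 samples = if (keep_samples) d else NULL),
            class = "cga_bootstrap")
}

#' @export
print.cga_bootstrap <- function(x, ...) {
  cat(sprintf("blocked bootstrap (%s vs %s): difference %.4f, B = %d\n",
              x$condition, x$vehicle, x$point, x$B))
  print(round(x$cis, 4))
  invisible(x)
}

#' Bonferroni family-wise significance calls for bootstrap contrasts
#'
#' For a family of `n_comparisons` contrasts at family-wise level
#' `family_alpha`, the per-comparison level is
#' `alpha_adj = family_alpha / n_comparisons` and a contrast is called
#' significant when its `1 - alpha_adj` percentile interval excludes zero
#' (0.05/50 = 0.001 and 0.01/50 = 0.0002 at the defaults used in the CGA
#' family of 10 sgRNAs x 5 drug conditions).
#'
#' @param results a list of [blocked_bootstrap()] results (with retained
#'   samples).
#' @param n_comparisons size of the comparison family (default 50).
#' @param family_alpha family-wise error rate.
#' @return data.frame with one row per result: `contrast`, `point`, `lower`,
#'   `upper`, `alpha_adj`, `significant`. Warns when `B * alpha_adj < 20`
#'   (too few bootstrap draws to resolve the adjusted tail).
#' @export
fwer_call <- function(results, n_comparisons = 50L, family_alpha = 0.05) {
  if (inherits(results, "cga_bootstrap")) results <- list(results)
  check_count_scalar(n_comparisons, "n_comparisons")
  check_proportion_scalar(family_alpha, "family_alpha", open = TRUE)
  alpha_adj <- family_alpha / n_comparisons
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "cga_bootstrap"))
    if (is.null(r$samples))
      stop("bootstrap result lacks retained samples; rerun with ",
           "keep_samples = TRUE", call. = FALSE)
    if (r$B * alpha_adj < 20)
      warning("B = ", r$B, " is too small to resolve the adjusted tail ",
              "(B * alpha_adj < 20)", call. = FALSE)
    ci <- stats::quantile(r$samples, c(alpha_adj / 2, 1 - alpha_adj / 2),
                          names = FALSE)
    data.frame(contrast = paste(r$condition, "vs", r$vehicle),
               point = r$point, lower = ci[1], upper = ci[2],
               alpha_adj = alpha_adj,
               significant = ci[1] > 0 | ci[2] < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
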