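#' Bliss-independence expected inhibition
#'
#' Expected combined inhibition fraction of two independently acting drugs:
#' `fx + fy - fx * fy`.
#'
#' @param fx,fy inhibition fractions in \[0, 1\] (recycled).
#' @return expected combined inhibition fraction.
#' @export
bliss_expected <- function(fx, fy) {
  if (any(fx < 0 | fx > 1 | fy < 0 | fy > 1))
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  fx + fy - fx * fy
}

#' Equipotency dose series
#'
#' Builds a dose series around an IC50 by fold steps, the diagonal
#' constant-ratio design used for checkerboard synergy experiments.
#'
#' @param ic50 anchor dose.
#' @param folds multiples of the IC50 (default five doses 0.25x-4x).
#' @return numeric dose vector.
#' @export
equipotency_doses <- function(ic50, folds = c(0.25, 0.5, 1, 2, 4)) {
  check_positive_scalar(ic50, "ic50")
  sort(ic50 * folds)
}

#' Bliss synergy and antagonism volumes for a dose checkerboard
#'
#' Converts replicate responses (surviving fraction relative to untreated)
#' to percent inhibition, forms each replicate's Bliss-expected surface from
#' its own monotherapy rows/columns, and summarizes the per-cell deviation
#' (observed - expected, in percent) with a t-based confidence interval at a
#' Bonferroni-adjusted per-cell level. The synergy volume accumulates the
#' significant positive deviations and the antagonism volume the significant
#' negative ones, each weighted by the cell's dose-interval area:
#'
#' `synergy = sum over cells of max(0, CI_lower) * w_ij`,
#' `antagonism = sum over cells of min(0, CI_upper) * w_ij`,
#'
#' with `w_ij` the product of the two dose-interval widths on the configured
#' dose scale (linear by default, matching volumes printed in dose^2 x
#' percent units; `"log10"` uses log10-dose widths; `"unit"` weights every
#' cell equally). Raw (non-thresholded) volumes are also reported.
#'
#' @param board data.frame with columns `dose_x`, `dose_y`, `replicate`,
#'   `response`; rows with both doses 0 are untreated wells, rows with one
#'   dose 0 are monotherapy wells.
#' @param confidence per-family confidence level (default 0.95).
#' @param bonferroni number of comparisons for the per-cell adjustment;
#'   defaults to the number of combination cells.
#' @param dose_scale `"linear"`, `"log10"` or `"unit"` weighting.
#' @return list of class `synergy_result`: `deviation` (mean deviation
#'   matrix, %), `ci_lower`, `ci_upper`, `synergy_volume`,
#'   `antagonism_volume`, `raw_synergy_volume`, `raw_antagonism_volume`,
#'   `log_synergy_volume`, `log_antagonism_volume`, `weights`, `n_combos`,
#'   `confidence`, `bonferroni`.
#' @export
synergy_volumes <- function(board, confidence = 0.95, bonferroni = NULL,
                            dose_scale = c("linear", "log10", "unit")) {
  check_columns(board, c("dose_x", "dose_y", "replicate", "response"),
                "board")
  dose_scale <- match.arg(dose_scale)
  check_proportion_scalar(confidence, "confidence", open = TRUE)
  doses_x <- sort(unique(board$dose_x[board$dose_x > 0]))
  doses_y <- sort(unique(board$dose_y[board$dose_y > 0]))
  reps <- sort(unique(board$replicate))
  if (!nrow(board[board$dose_x == 0 & board$dose_y == 0, , drop = FALSE]))
    stop("untreated wells (dose_x = dose_y = 0) are required", call. = FALSE)
  n_cells <- length(doses_x) * length(doses_y)
  if (is.null(bonferroni)) bonferroni <- n_cells
  check_count_scalar(bonferroni, "bonferroni")

  # per replicate: percent inhibition relative to that replicate's untreated
  dev <- array(NA_real_, c(length(doses_x), length(doses_y), length(reps)),
               dimnames = list(doses_x, doses_y, reps))
  for (r in seq_along(reps)) {
    b <- board[board$replicate == reps[r], ]
    untr <- mean(b$response[b$dose_x == 0 & b$dose_y == 0])
    inhib <- function(resp) 1 - resp / untr
    # monotherapy fractions feed the Bliss formula and are clamped to [0,1];
    # observed inhibition is left unclamped so noise stays mean-zero
    mono_x <- vapply(doses_x, function(d)
      mean(inhib(b$response[b$dose_x == d & b$dose_y == 0])), numeric(1))
    mono_y <- vapply(doses_y, function(d)
      mean(inhib(b$response[b$dose_x == 0 & b$dose_y == d])), numeric(1))
    mono_x <- pmin(pmax(mono_x, 0), 1)
    mono_y <- pmin(pmax(mono_y, 0), 1)
    if (anyNA(mono_x) || anyNA(mono_y))
      stop("missing monotherapy row/column in replicate ", reps[r],
           call. = FALSE)
    for (i in seq_along(doses_x)) for (j in seq_along(doses_y)) {
      obs <- b$response[b$dose_x == doses_x[i] & b$dose_y == doses_y[j]]
      if (!length(obs))
        stop("missing combination well (", doses_x[i], ", ", doses_y[j],
             ") in replicate ", reps[r], call. = FALSE)
      dev[i, j, r] <- 100 * (mean(inhib(obs)) -
                               bliss_expected(mono_x[i], mono_y[j]))
    }
  }

  n_rep <- length(reps)
  mean_dev <- apply(dev, c(1, 2), mean)
  if (n_rep >= 2L) {
    sd_dev <- apply(dev, c(1, 2), stats::sd)
    alpha_cell <- (1 - confidence) / bonferroni
    tq <- stats::qt(1 - alpha_cell / 2, n_rep - 1)
    half <- tq * sd_dev / sqrt(n_rep)
    half[sd_dev == 0] <- 0  # degenerate replicates: exact deviation
  } else {
    half <- mean_dev * 0
  }
  lo <- mean_dev - half
  hi <- mean_dev + half

  widths <- function(d, scale) {
    if (scale == "unit") return(rep(1, length(d)))
    v <- if (scale == "log10") log10(d) else d
    n <- length(v)
    if (n == 1L) return(1)
    w <- numeric(n)
    w[1] <- (v[2] - v[1]) / 2
    w[n] <- (v[n] - v[n - 1]) / 2
    if (n > 2) w[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    w
  }
  vol <- function(mat, scale) {
    w <- outer(widths(doses_x, scale), widths(doses_y, scale))
    list(syn = sum(pmax(mat$lo, 0) * w), ant = sum(pmin(mat$hi, 0) * w),
         raw_syn = sum(pmax(mat$mean, 0) * w),
         raw_ant = sum(pmin(mat$mean, 0) * w), w = w)
  }
  lin <- vol(list(lo = lo, hi = hi, mean = mean_dev), dose_scale)
  lg <- vol(list(lo = lo, hi = hi, mean = mean_dev),
            if (dose_scale == "unit") "unit" else "log10")

  structure(list(deviation = mean_dev, ci_lower = lo, ci_upper = hi,
                 synergy_volume = lin$syn, antagonism_volume = lin$ant,
                 raw_synergy_volume = lin$raw_syn,
                 raw_antagonism_volume = lin$raw_ant,
                 log_synergy_volume = lg$syn, log_antagonism_volume = lg$ant,
                 weights = lin$w, n_combos = n_cells,
                 confidence = confidence, bonferroni = bonferroni,
                 dose_scale = dose_scale, n_replicates = n_rep),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("Bliss synergy analysis over %d combinations (%d replicates)\n",
              x$n_combos, x$n_replicates))
  cat(sprintf("  synergy volume    %10.4g (CI-thresholded, %s dose scale)\n",
              x$synergy_volume, x$dose_scale))
  cat(sprintf("  antagonism volume %10.4g\n", x$antagonism_volume))
  cat(sprintf("  at %g%% confidence, Bonferroni %d\n", 100 * x$confidence,
              x$bonferroni))
  invisible(x)
}
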