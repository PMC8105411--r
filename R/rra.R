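#' Fit a mean-variance model on control counts
#'
#' Regresses log variance on log mean (linear) across guides of the control
#' samples and returns a function mapping a mean to a modeled variance,
#' floored at the Poisson variance (variance >= mean). With a single control
#' sample the Poisson floor alone is used.
#'
#' @param control normalized counts, guides x control samples.
#' @return function(mu) giving modeled variance.
#' @export
fit_mean_variance <- function(control) {
  control <- as.matrix(control)
  if (ncol(control) >= 2L) {
    m <- rowMeans(control)
    v <- apply(control, 1, stats::var)
    ok <- m > 0 & v > 0
    if (sum(ok) >= 10L) {
      fit <- stats::lm(log(v[ok]) ~ log(m[ok]))
      a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
      return(function(mu) pmax(mu, exp(a + b * log(pmax(mu, 1e-8)))))
    }
  }
  function(mu) mu
}

#' Per-sgRNA negative-binomial depletion test
#'
#' Compares each guide's treatment counts against its control mean under a
#' negative binomial with variance from a fitted mean-variance model
#' (a documented variant of the usual screen count test). The sum of the
#' treatment replicates is tested against the null sum distribution
#' (NB mean `r * mu0`, variance `r * v(mu0)`; exact Poisson when the modeled
#' variance collapses to the mean). Two-sided p-values use the doubled
#' smaller tail; the depletion percentile ranks guides by their lower-tail
#' (depletion) evidence, ties broken by sgRNA id for determinism.
#'
#' @param treatment,control normalized count matrices (guides x replicates)
#'   with identical rownames (the guide universe).
#' @param variance_fun optional mean-variance function; fitted on `control`
#'   via [fit_mean_variance()] when NULL.
#' @return data.frame with `sgrna`, `log2_fold_change`, `p_value` (two-sided),
#'   `p_depletion` (lower tail), `percentile` (rank/(n+1) by depletion
#'   evidence).
#' @export
sgrna_nb_test <- function(treatment, control, variance_fun = NULL) {
  treatment <- as.matrix(treatment); control <- as.matrix(control)
  if (is.null(rownames(treatment)) || is.null(rownames(control)) ||
      !identical(rownames(treatment), rownames(control)))
    stop("treatment and control must share the same guide universe ",
         "(identical rownames)", call. = FALSE)
  if (is.null(variance_fun)) variance_fun <- fit_mean_variance(control)
  mu0 <- rowMeans(control)
  r <- ncol(treatment)
  obs <- round(rowSums(treatment))
  mu_sum <- r * mu0
  v_sum <- r * variance_fun(mu0)

  p_lo <- p_hi <- rep(1, length(mu0))
  pois <- v_sum <= mu_sum * (1 + 1e-12)
  zero <- mu0 <= 0
  # Poisson branch (variance floored at the mean)
  i <- pois & !zero
  p_lo[i] <- stats::ppois(obs[i], mu_sum[i])
  p_hi[i] <- 1 - stats::ppois(obs[i] - 1, mu_sum[i])
  # NB branch: size chosen so the sum has the modeled variance
  i <- !pois & !zero
  size <- mu_sum[i]^2 / (v_sum[i] - mu_sum[i])
  p_lo[i] <- stats::pnbinom(obs[i], mu = mu_sum[i], size = size)
  p_hi[i] <- 1 - stats::pnbinom(obs[i] - 1, mu = mu_sum[i], size = size)

  p_two <- pmin(1, 2 * pmin(p_lo, p_hi))
  lfc <- log2((rowMeans(treatment) + 0.5) / (mu0 + 0.5))
  # depletion evidence: smaller lower-tail p ranks first; undetected guides last
  p_dep <- ifelse(zero, 1, p_lo)
  ord <- order(p_dep, rownames(treatment))
  pct <- numeric(length(p_dep))
  pct[ord] <- seq_along(p_dep) / (length(p_dep) + 1)
  data.frame(sgrna = rownames(treatment), log2_fold_change = lfc,
             p_value = p_two, p_depletion = p_dep, percentile = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Alpha-truncated robust rank aggregation score
#'
#' Given the ascending percentiles `p(1..k)` of one gene's guides among all
#' guides, considers only those below the truncation threshold `alpha` and
#' returns the minimum over qualifying positions `i` of
#' `BetaCDF(p(i); i, k - i + 1)` — the probability that the i-th uniform
#' order statistic is at most `p(i)`. Genes with no percentile below `alpha`
#' score 1.
#'
#' @param percentiles ascending guide percentiles strictly inside (0, 1).
#' @param alpha truncation threshold in (0, 1].
#' @return the RRA score rho in (0, 1].
#' @export
rra_score <- function(percentiles, alpha = 0.05) {
  if (is.unsorted(percentiles))
    stop("percentiles must be sorted ascending", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 1))
    stop("percentiles must lie strictly inside (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  k <- length(percentiles)
  qual <- which(percentiles < alpha)
  if (!length(qual)) return(1)
  min(stats::pbeta(percentiles[qual], qual, k - qual + 1))
}

# null RRA scores for k uniform percentiles (shared across genes of equal k)
rra_null_scores <- function(k, alpha, n_perm) {
  u <- matrix(stats::runif(n_perm * k), n_perm, k)
  if (k > 1L) u <- t(apply(u, 1, sort))
  ik <- seq_len(k)
  b <- stats::pbeta(u, matrix(ik, n_perm, k, byrow = TRUE),
                    matrix(k - ik + 1, n_perm, k, byrow = TRUE))
  b[u >= alpha] <- Inf
  rho <- apply(b, 1, min)
  rho[!is.finite(rho)] <- 1
  rho
}

#' Permutation p-value for an RRA score
#'
#' Draws `k` percentiles uniformly, scores them with [rra_score()], and
#' reports `p = (1 + #\{rho* <= rho_obs\}) / (n_perm + 1)` (add-one
#' convention, so the smallest attainable p is `1/(n_perm + 1)`).
#'
#' @param rho_observed observed RRA score.
#' @param k number of guides for the gene.
#' @param alpha truncation threshold used for the observed score.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
permutation_pvalue <- function(rho_observed, k, alpha = 0.05,
                               n_perm = 10000L, seed = 1L) {
  check_count_scalar(k, "k")
  check_count_scalar(n_perm, "n_perm", min = 100L)
  set.seed(seed)
  null <- rra_null_scores(k, alpha, n_perm)
  (1 + sum(null <= rho_observed)) / (n_perm + 1)
}

#' Gene-level depletion scoring of a screen contrast
#'
#' Runs the full gene-scoring path: median-ratio normalization of the
#' contrast samples, the per-guide negative-binomial depletion test with a
#' control-fitted mean-variance model, alpha-truncated robust rank
#' aggregation of each gene's guide percentiles, and permutation p-values
#' from a shared uniform null (one null distribution per guide-count `k`).
#' Non-targeting guides are chunked into pseudo-genes of the modal library
#' guides-per-gene and scored identically, for calibration.
#'
#' @param cm a [count_matrix()].
#' @param library a [guide_library()] covering the matrix rows.
#' @param treatment,control character vectors of sample names, or a list
#'   `list(condition=, day=)` selecting samples by metadata.
#' @param alpha truncation threshold on the sgRNA percentile scale.
#' @param n_perm permutations for the gene p-value.
#' @param seed integer seed for the permutation null.
#' @param include_nt score non-targeting pseudo-genes alongside genes.
#' @return a data.frame of class `gene_score_table`: `gene`, `rra_score`,
#'   `p_value`, `rank`, `n_guides`, `n_guides_below_alpha`, `is_nt`, ordered
#'   by rank. The per-guide test is attached as attribute `"sgrna_results"`.
#' @export
score_screen <- function(cm, library, treatment, control, alpha = 0.05,
                         n_perm = 10000L, seed = 1L, include_nt = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(library, "guide_library"))
  pick <- function(sel, arm) {
    if (is.list(sel)) {
      keep <- rep(TRUE, nrow(cm$samples))
      for (f in names(sel)) keep <- keep & cm$samples[[f]] %in% sel[[f]]
      s <- cm$samples$sample[keep]
    } else s <- sel
    miss <- setdiff(s, colnames(cm$counts))
    if (length(miss) || !length(s))
      stop("missing ", arm, " samples", if (length(miss))
        paste0(": ", paste(miss, collapse = ", ")), call. = FALSE)
    s
  }
  trt <- pick(treatment, "treatment"); ctl <- pick(control, "control")
  sub <- count_matrix(cm$counts[, c(trt, ctl), drop = FALSE],
                      cm$guides$gene,
                      samples = cm$samples[cm$samples$sample %in% c(trt, ctl), ,
                                           drop = FALSE])
  norm <- median_ratio_normalize(sub)$normalized
  vf <- fit_mean_variance(norm[, ctl, drop = FALSE])
  sg <- sgrna_nb_test(norm[, trt, drop = FALSE], norm[, ctl, drop = FALSE],
                      variance_fun = vf)

  lib <- library[match(rownames(cm$counts), library$sgrna), ]
  if (anyNA(lib$sgrna))
    stop("count matrix rows not all present in the library", call. = FALSE)
  gene_of <- lib$gene
  is_nt <- lib$is_nt
  gpg <- as.integer(stats::median(table(gene_of[!is_nt])))
  if (any(is_nt)) {
    nt_idx <- which(is_nt)
    gene_of[nt_idx] <- sprintf("NT_pseudo%02d",
                               ((seq_along(nt_idx) - 1L) %/% gpg) + 1L)
  }
  keep <- if (include_nt) rep(TRUE, length(gene_of)) else !is_nt
  pct <- stats::setNames(sg$percentile, sg$sgrna)[rownames(cm$counts)]

  genes <- split(seq_along(gene_of)[keep], gene_of[keep])
  rho <- vapply(genes, function(i) rra_score(sort(pct[i]), alpha), numeric(1))
  nbelow <- vapply(genes, function(i) sum(pct[i] < alpha), integer(1))
  ks <- lengths(genes)

  set.seed(seed)
  pval <- numeric(length(genes))
  for (k in sort(unique(ks))) {
    null <- rra_null_scores(k, alpha, n_perm)
    sel <- ks == k
    pval[sel] <- (1 + vapply(rho[sel], function(r) sum(null <= r),
                             numeric(1))) / (n_perm + 1)
  }
  out <- data.frame(gene = names(genes), rra_score = unname(rho),
                    p_value = pval, n_guides = unname(ks),
                    n_guides_below_alpha = unname(nbelow),
                    is_nt = startsWith(names(genes), "NT_pseudo"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rra_score, out$p_value, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("gene", "rra_score", "p_value", "rank", "n_guides",
                 "n_guides_below_alpha", "is_nt")]
  class(out) <- c("gene_score_table", "data.frame")
  attr(out, "sgrna_results") <- sg
  out
}
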