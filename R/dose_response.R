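#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the variable-slope model
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` with the IC50
#' parameterized as log10(ic50) and the bottom constrained >= 0 (viability
#' data). Optimization uses Levenberg-Marquardt with multi-start
#' initialization over a hill/IC50 grid; the IC50 confidence interval is
#' computed by profile likelihood (F threshold on the residual sum of
#' squares).
#'
#' @param data data.frame with columns `dose` (> 0) and `response`.
#' @param ci_level confidence level for the IC50 interval.
#' @return list of class `fit_4pl` with `bottom`, `top`, `ic50`, `hill`,
#'   `rss`, `df`, `ic50_ci`, `n`, and the fitted `nls` object as `fit`.
#' @export
fit_4pl <- function(data, ci_level = 0.95) {
  check_columns(data, c("dose", "response"), "data")
  data <- data[stats::complete.cases(data[, c("dose", "response")]), ]
  if (any(data$dose <= 0))
    stop("doses must be strictly positive (the vehicle is the normalizer, ",
         "not a point)", call. = FALSE)
  if (length(unique(data$dose)) < 4L)
    stop("need >= 4 distinct doses to fit a 4PL", call. = FALSE)
  dm <- tapply(data$response, data$dose, mean)
  if (diff(range(dm)) < 1e-9 * max(1, abs(mean(dm))))
    stop("flat response: IC50 is non-identifiable", call. = FALSE)

  df_fit <- data.frame(lx = log10(data$dose), y = data$response)
  top0 <- max(dm); bot0 <- max(0, min(dm))
  lx_range <- range(df_fit$lx)
  starts <- expand.grid(
    lic50 = stats::quantile(df_fit$lx, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2, 4))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - lic50))),
        data = df_fit,
        start = list(bottom = bot0, top = top0,
                     lic50 = starts$lic50[s], hill = starts$hill[s]),
        lower = c(bottom = 0, top = 0, lic50 = lx_range[1] - 6, hill = 1e-3),
        upper = c(bottom = Inf, top = Inf, lic50 = lx_range[2] + 6,
                  hill = 50),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit,
                                                              rss = rss)
  }
  if (is.null(best))
    stop("4PL fit did not converge from any start", call. = FALSE)
  cf <- stats::coef(best$fit)
  if (cf[["top"]] - cf[["bottom"]] < 1e-6 * max(1, cf[["top"]]))
    stop("fitted curve is flat (top ~ bottom): IC50 non-identifiable",
         call. = FALSE)
  n <- nrow(df_fit); dof <- n - 4L
  ci <- profile_ic50_ci(df_fit, cf, best$rss, dof, ci_level)
  structure(list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                 ic50 = 10^unname(cf["lic50"]), hill = unname(cf["hill"]),
                 rss = best$rss, df = dof, n = n, ic50_ci = ci,
                 ci_level = ci_level, fit = best$fit),
            class = "fit_4pl")
}

# profile-likelihood CI for log10(ic50): refit the other three parameters on
# a lic50 grid and find where RSS crosses the F-based threshold
profile_ic50_ci <- function(df_fit, cf, rss0, dof, level) {
  if (dof <= 0) return(c(NA_real_, NA_real_))
  # an (essentially) exact fit has a degenerate profile: the CI collapses
  if (rss0 < 1e-12) return(rep(10^cf[["lic50"]], 2))
  thresh <- rss0 * (1 + stats::qf(level, 1, dof) / dof)
  rss_at <- function(l0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - l0))),
        data = df_fit,
        start = list(bottom = cf[["bottom"]], top = cf[["top"]],
                     hill = cf[["hill"]]),
        lower = c(bottom = 0, top = 0, hill = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) Inf else sum(stats::resid(fit)^2)
  }
  l0 <- cf[["lic50"]]
  bound <- function(dir) {
    step <- 0.1; hi <- l0
    for (i in 1:60) {
      hi <- hi + dir * step
      if (rss_at(hi) > thresh) {
        root <- tryCatch(stats::uniroot(function(l) rss_at(l) - thresh,
                                        sort(c(hi - dir * step, hi)),
                                        tol = 1e-5)$root,
                         error = function(e) NA_real_)
        return(root)
      }
      step <- step * 1.5
    }
    NA_real_
  }
  lo <- bound(-1); hi <- bound(1)
  c(10^lo, 10^hi)
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf("4PL fit: bottom %.4g, top %.4g, IC50 %.4g (%.0f%% CI %.4g-%.4g), hill %.3g\n",
              x$bottom, x$top, x$ic50, 100 * x$ci_level, x$ic50_ci[1],
              x$ic50_ci[2], x$hill))
  invisible(x)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Pooled-variance one-way ANOVA over per-replicate IC50 estimates (or any
#' group-wise values), followed by Dunnett's test of every group against the
#' control with two-sided adjusted p-values from the multivariate-t null.
#'
#' @param values named list of numeric vectors (one per group, >= 2
#'   replicates each) or a data.frame with columns `group`, `value`.
#' @param control name of the control group.
#' @param seed integer seed (the multivariate-t integration is randomized).
#' @return list with `anova` (F statistic, df, p), and `comparisons`
#'   (data.frame `group`, `estimate`, `se`, `p_adj` for each non-control
#'   group vs control).
#' @export
compare_ic50_anova_dunnett <- function(values, control, seed = 1L) {
  if (is.data.frame(values)) {
    check_columns(values, c("group", "value"), "values")
    values <- split(values$value, values$group)
  }
  if (length(values) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (!control %in% names(values))
    stop("control group not found: ", control, call. = FALSE)
  sizes <- lengths(values)
  if (any(sizes < 2L))
    stop("every group needs >= 2 replicates (",
         paste(names(values)[sizes < 2], collapse = ", "), ")",
         call. = FALSE)
  df <- data.frame(group = factor(rep(names(values), sizes),
                                  levels = c(control,
                                             setdiff(names(values), control))),
                   value = unlist(values, use.names = FALSE))
  fit <- stats::aov(value ~ group, data = df)
  a <- summary(fit)[[1]]
  set.seed(seed)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl, test = multcomp::adjusted("single-step"))
  comparisons <- data.frame(
    group = sub(" - .*$", "", names(sm$test$coefficients)),
    estimate = unname(sm$test$coefficients),
    se = unname(sm$test$sigma),
    p_adj = unname(as.numeric(sm$test$pvalues)),
    stringsAsFactors = FALSE)
  list(anova = list(F = a[["F value"]][1], df1 = a[["Df"]][1],
                    df2 = a[["Df"]][2], p = a[["Pr(>F)"]][1]),
       comparisons = comparisons)
}
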