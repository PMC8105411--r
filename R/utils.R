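#' Logit and inverse-logit
#'
#' Transforms between the proportion scale and the logit (log-odds) scale.
#' Competitive-growth-assay inference averages on the logit scale before
#' back-transforming, so these are exported for callers that preprocess
#' their own tables.
#'
#' @param p proportions strictly inside (0, 1).
#' @param x real values on the logit scale.
#' @return `logit()` returns log(p / (1 - p)); `inv_logit()` its inverse.
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires proportions strictly inside (0, 1); ",
         "see clamp_proportions()", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clamp proportions away from 0 and 1
#'
#' Proportions of exactly 0 or 1 have infinite logit. When the raw cell
#' counts behind a proportion are available a continuity correction
#' (x + 0.5) / (n + 1) is applied; otherwise values are clamped to
#' \[eps, 1 - eps\].
#'
#' @param p observed proportions in \[0, 1\].
#' @param n optional vector of denominators (cells counted); when supplied,
#'   the continuity correction uses `x = p * n` events.
#' @param eps clamp width when `n` is not available (default 1e-4).
#' @return proportions strictly inside (0, 1).
#' @export
clamp_proportions <- function(p, n = NULL, eps = 1e-4) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  if (!is.null(n)) {
    if (length(n) != length(p) && length(n) != 1L)
      stop("`n` must be length 1 or length(p)", call. = FALSE)
    (p * n + 0.5) / (n + 1)
  } else {
    pmin(pmax(p, eps), 1 - eps)
  }
}

# shared argument checks -----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("`", name, "` must be a single positive number", call. = FALSE)
  invisible(x)
}

check_count_scalar <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

check_proportion_scalar <- function(x, name, open = FALSE) {
  lo <- if (open) x <= 0 else x < 0
  hi <- if (open) x >= 1 else x > 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || lo || hi)
    stop("`", name, "` must be a proportion ",
         if (open) "strictly inside (0, 1)" else "in [0, 1]", call. = FALSE)
  invisible(x)
}

check_columns <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("`", name, "` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Normalize gene symbols
#'
#' Uppercases and trims whitespace; no alias resolution is attempted.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene_symbols <- function(x) toupper(trimws(as.character(x)))
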