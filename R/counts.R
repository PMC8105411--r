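#' Construct a count matrix
#'
#' Guide-level counts for one or more samples together with sample metadata
#' (condition, day, replicate) and per-sample unmapped-read tallies.
#'
#' @param counts numeric matrix, guides x samples, with sgRNA ids as
#'   rownames and sample names as colnames; all values >= 0.
#' @param gene character vector of gene symbols, one per row of `counts`.
#' @param samples data.frame of sample metadata with at least a `sample`
#'   column matching `colnames(counts)`; `condition`, `day` and `replicate`
#'   are filled with NA when absent.
#' @param unmapped named numeric vector of unmapped reads per sample
#'   (defaults to 0).
#' @return a list of class `count_matrix` with elements `counts`, `guides`
#'   (data.frame sgrna/gene), `samples`, `unmapped`.
#' @export
count_matrix <- function(counts, gene, samples = NULL, unmapped = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs sgRNA rownames", call. = FALSE)
  if (is.null(colnames(counts))) stop("counts needs sample colnames", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(gene) != nrow(counts))
    stop("`gene` must have one entry per guide", call. = FALSE)
  if (is.null(samples))
    samples <- data.frame(sample = colnames(counts), stringsAsFactors = FALSE)
  check_columns(samples, "sample", "samples")
  if (!identical(sort(samples$sample), sort(colnames(counts))))
    stop("sample metadata does not match count columns", call. = FALSE)
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  for (col in c("condition", "day", "replicate"))
    if (is.null(samples[[col]])) samples[[col]] <- NA
  rownames(samples) <- NULL
  if (is.null(unmapped))
    unmapped <- stats::setNames(rep(0, ncol(counts)), colnames(counts))
  structure(list(counts = counts,
                 guides = data.frame(sgrna = rownames(counts),
                                     gene = normalize_gene_symbols(gene),
                                     stringsAsFactors = FALSE),
                 samples = samples, unmapped = unmapped),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read / write a count matrix TSV
#'
#' The on-disk format mirrors common screen-count tables: columns `sgRNA`,
#' `gene`, then one column per sample. Sample metadata (condition, day,
#' replicate) is recovered from sample names of the form
#' `<condition>_d<day>_r<replicate>` when present.
#'
#' @param path file path.
#' @return `read_count_matrix()` returns a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_columns(df, c("sgRNA", "gene"), "count file")
  if (anyDuplicated(df$sgRNA))
    stop("duplicate sgRNA ids in count file", call. = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), c("sgRNA", "gene")), drop = FALSE])
  rownames(mat) <- df$sgRNA
  meta <- parse_sample_names(colnames(mat))
  count_matrix(mat, df$gene, samples = meta)
}

parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^(.*)_d([^_]+)_r(\\d+)$", x))
  ok <- lengths(m) == 4L
  data.frame(sample = x,
             condition = ifelse(ok, vapply(m, function(v) v[2] %||% NA_character_,
                                           character(1)), NA),
             day = ifelse(ok, suppressWarnings(
               as.numeric(vapply(m, function(v) v[3] %||% NA_character_,
                                 character(1)))), NA),
             replicate = ifelse(ok, suppressWarnings(
               as.integer(vapply(m, function(v) v[4] %||% NA_character_,
                                 character(1)))), NA),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (length(a)) a else b

#' @rdname read_count_matrix
#' @param cm a [count_matrix()].
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- cbind(data.frame(sgRNA = cm$guides$sgrna, gene = cm$guides$gene,
                         stringsAsFactors = FALSE),
              as.data.frame(cm$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count guide spacers in a FASTQ file by exact anchor matching
#'
#' For each read, the invariant `anchor` sequence is located at any offset
#' (accommodating staggered forward primers); the 20 bases (spacer length of
#' the library) following the anchor are matched exactly against the library
#' spacers. Reads whose anchor is absent, whose spacer is truncated, or whose
#' spacer has any mismatch against the library are tallied as unmapped — no
#' mismatches are tolerated.
#'
#' @param fastq_path path to a FASTQ file (gzip accepted).
#' @param library a [guide_library()].
#' @param anchor invariant DNA sequence immediately 5' of the spacer.
#' @param sample_name column name for the resulting single-sample matrix.
#' @return a single-sample [count_matrix()]; the `unmapped` element carries
#'   the unmapped read count.
#' @export
extract_counts <- function(fastq_path, library, anchor = "CACCG",
                           sample_name = "sample1") {
  stopifnot(inherits(library, "guide_library"))
  if (!nzchar(anchor) || grepl("[^ACGT]", anchor))
    stop("`anchor` must be a non-empty ACGT string", call. = FALSE)
  if (!file.exists(fastq_path))
    stop("cannot read FASTQ: ", fastq_path, call. = FALSE)
  lines <- readLines(fastq_path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  seqs <- lines[seq_along(lines) %% 4L == 2L]
  spacer_len <- nchar(library$spacer[1])
  counts <- stats::setNames(integer(nrow(library)), library$sgrna)
  unmapped <- 0L
  if (length(seqs)) {
    pos <- regexpr(anchor, seqs, fixed = TRUE)
    start <- ifelse(pos > 0, pos + nchar(anchor), NA_integer_)
    cand <- substr(seqs, start, start + spacer_len - 1L)
    cand[is.na(start) | nchar(cand) < spacer_len] <- NA
    hit <- match(cand, library$spacer)
    unmapped <- sum(is.na(hit))
    tab <- table(hit)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  mat <- matrix(counts, ncol = 1,
                dimnames = list(library$sgrna, sample_name))
  count_matrix(mat, library$gene,
               unmapped = stats::setNames(unmapped, sample_name))
}

#' Median-ratio normalization
#'
#' Size factor per sample = median over guides of count / (geometric mean of
#' that guide across samples), computed over guides whose geometric mean is
#' nonzero. When fewer than `min_guides` such guides exist, total-count
#' scaling is used instead. Normalized counts are count / size factor.
#'
#' @param cm a [count_matrix()] with at least two samples.
#' @param min_guides minimum guides with nonzero geometric mean before
#'   falling back to total-count scaling (default 100).
#' @return a list with `normalized` (real-valued guides x samples matrix),
#'   `size_factors` (named vector), and `method` ("median_ratio" or
#'   "total_count").
#' @export
median_ratio_normalize <- function(cm, min_guides = 100L) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (ncol(counts) < 2L)
    stop("median-ratio normalization needs >= 2 samples; ",
         "use total-count scaling for a single sample", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  geo <- exp(rowMeans(log(counts)))  # zero count anywhere -> geo 0
  eligible <- is.finite(geo) & geo > 0
  if (sum(eligible) >= min_guides) {
    sf <- apply(counts[eligible, , drop = FALSE] / geo[eligible], 2,
                stats::median)
    method <- "median_ratio"
  } else {
    tot <- colSums(counts)
    sf <- tot / mean(tot)
    method <- "total_count"
  }
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf,
       method = method)
}

#' Library representation QC
#'
#' Percent of guides detected and the fold difference in representation over
#' the central `central_mass` of detected guides (the 90th/10th percentile
#' ratio at the default 0.80), computed on one sample — typically the
#' plasmid pool.
#'
#' @param cm a [count_matrix()]; `sample` selects the column when there are
#'   several.
#' @param library optional [guide_library()] to check row coverage against.
#' @param central_mass central probability mass for the fold-difference
#'   quantiles (default 0.80).
#' @param sample sample name (default: the single sample present).
#' @return a list of class `library_qc_report` with `percent_detected`,
#'   `quantile_fold_difference`, `zero_count_guides`, `n_guides`,
#'   `central_mass`.
#' @export
library_qc <- function(cm, library = NULL, central_mass = 0.80,
                       sample = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (nrow(cm$counts) == 0) stop("empty count matrix", call. = FALSE)
  check_proportion_scalar(central_mass, "central_mass", open = TRUE)
  if (is.null(sample)) {
    if (ncol(cm$counts) != 1L)
      stop("specify `sample` for a multi-sample matrix", call. = FALSE)
    sample <- colnames(cm$counts)[1]
  }
  x <- cm$counts[, sample]
  if (!is.null(library)) {
    miss <- setdiff(library$sgrna, rownames(cm$counts))
    if (length(miss))
      stop(length(miss), " library guides absent from the count matrix",
           call. = FALSE)
  }
  detected <- x > 0
  probs <- c(0.5 - central_mass / 2, 0.5 + central_mass / 2)
  q <- stats::quantile(x[detected], probs, names = FALSE)
  structure(list(percent_detected = 100 * sum(detected) / length(x),
                 quantile_fold_difference = if (sum(detected)) q[2] / q[1]
                   else NA_real_,
                 zero_count_guides = names(x)[!detected],
                 n_guides = length(x), central_mass = central_mass),
            class = "library_qc_report")
}

#' @export
print.library_qc_report <- function(x, ...) {
  cat(sprintf("library QC: %.2f%% of %d guides detected; %.2f-fold\n",
              x$percent_detected, x$n_guides, x$quantile_fold_difference))
  cat(sprintf("difference over the central %.0f%% of detected guides\n",
              100 * x$central_mass))
  invisible(x)
}

#' Sequencing coverage per guide from genomic DNA mass
#'
#' Converts a genomic-DNA input mass to fold coverage per guide assuming a
#' fixed DNA mass per cell: `(mass_ug * 1e6 / pg_per_cell) / n_guides`.
#' At the 7.5 pg/cell default, 10 ug over 2930 guides gives ~455x.
#'
#' @param dna_mass_ug genomic DNA input in micrograms.
#' @param pg_per_cell DNA mass per diploid cell in picograms (default 7.5).
#' @param n_guides number of guides in the library.
#' @return fold coverage per guide.
#' @export
coverage_per_guide <- function(dna_mass_ug, pg_per_cell = 7.5, n_guides) {
  check_positive_scalar(dna_mass_ug, "dna_mass_ug")
  check_positive_scalar(pg_per_cell, "pg_per_cell")
  check_count_scalar(n_guides, "n_guides")
  (dna_mass_ug * 1e6 / pg_per_cell) / n_guides
}

#' Lentiviral titer from a puromycin-survival titration
#'
#' `titer (TU/mL) = survival_fraction * cells_per_well * 1000 / volume_ul`.
#'
#' @param survival_fraction fraction of cells surviving selection in \[0, 1\].
#' @param cells_per_well cells plated per well.
#' @param virus_volume_ul virus volume added, in microliters.
#' @return transducing units per mL.
#' @export
viral_titer <- function(survival_fraction, cells_per_well, virus_volume_ul) {
  check_proportion_scalar(survival_fraction, "survival_fraction")
  check_positive_scalar(cells_per_well, "cells_per_well")
  check_positive_scalar(virus_volume_ul, "virus_volume_ul")
  survival_fraction * cells_per_well * 1000 / virus_volume_ul
}
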