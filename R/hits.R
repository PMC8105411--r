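#' Top depleted genes per drug condition (published table)
#'
#' Loads the packaged transcription of the study's table of top depleted
#' genes per drug condition (five columns: CX-5461 at IC50 and IC30, PDS at
#' IC50 and IC30, and the BMH-21 counter-screen at IC30). The union of the
#' five lists is the consolidated 81-gene list; the union of the four
#' G4-ligand lists minus the BMH-21 list gives the 58 G4-specific genes.
#'
#' @return a named list of character vectors of gene symbols, one per
#'   condition (`CX5461_IC50`, `CX5461_IC30`, `PDS_IC50`, `PDS_IC30`,
#'   `BMH21_IC30`).
#' @export
table2_hits <- function() {
  path <- system.file("extdata", "table2_top_depleted.csv",
                      package = "g4screen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(normalize_gene_symbols(df$gene), df$condition)[
    unique(df$condition)], unname)
}

#' Threshold a gene score table into a hit list
#'
#' Genes with p-value strictly below `p_cut` (default 0.045, the cut used to
#' call per-condition screen hits). Non-targeting pseudo-genes are excluded.
#'
#' @param gene_scores a data.frame with columns `gene` and `p_value`
#'   (e.g. from [score_screen()]).
#' @param p_cut probability cut; strict inequality.
#' @return character vector of normalized gene symbols.
#' @export
threshold_hits <- function(gene_scores, p_cut = 0.045) {
  check_columns(gene_scores, c("gene", "p_value"), "gene_scores")
  keep <- gene_scores$p_value < p_cut
  if (!is.null(gene_scores$is_nt)) keep <- keep & !gene_scores$is_nt
  unique(normalize_gene_symbols(gene_scores$gene[keep]))
}

#' Consolidate hit lists across conditions
#'
#' Set union of per-condition hit lists.
#'
#' @param ... character vectors of gene symbols, or a single list of them.
#' @return sorted character vector of the union.
#' @export
consolidate_hits <- function(...) {
  lists <- flatten_gene_lists(list(...))
  if (!length(lists)) stop("need at least one hit list", call. = FALSE)
  sort(unique(normalize_gene_symbols(unlist(lists, use.names = FALSE))))
}

#' Counter-screen exclusion
#'
#' Union of the focal (e.g. G4-ligand) hit lists minus every gene present in
#' the counter-screen list.
#'
#' @param g4_lists list of character vectors (focal conditions).
#' @param counter character vector (counter-screen hits).
#' @return sorted character vector of focal-specific genes.
#' @export
counter_screen_exclude <- function(g4_lists, counter) {
  if (missing(counter)) stop("a counter-screen list is required", call. = FALSE)
  u <- consolidate_hits(g4_lists)
  sort(setdiff(u, normalize_gene_symbols(counter)))
}

#' Exclusive intersection sets (UpSet semantics)
#'
#' Assigns each gene in the union to exactly one signature: the full set of
#' input lists that contain it. The resulting sets are pairwise disjoint and
#' cover the union.
#'
#' @param lists named list (>= 2) of character vectors of gene symbols.
#' @return named list of character vectors; names are signatures formed by
#'   joining member list names with `"&"`.
#' @export
intersection_sets <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need >= 2 named lists", call. = FALSE)
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named", call. = FALSE)
  lists <- lapply(lists, normalize_gene_symbols)
  u <- sort(unique(unlist(lists, use.names = FALSE)))
  sig <- vapply(u, function(g)
    paste(names(lists)[vapply(lists, function(l) g %in% l, logical(1))],
          collapse = "&"), character(1))
  split(u, sig)
}

flatten_gene_lists <- function(args) {
  if (length(args) == 1L && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  args
}
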