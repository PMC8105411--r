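#' Construct a guide library
#'
#' A guide library maps each sgRNA to its target gene and 20-base spacer
#' sequence, and flags non-targeting control guides. It is the guide universe
#' for spacer counting, normalization and gene-level ranking.
#'
#' @param sgrna character vector of unique sgRNA identifiers.
#' @param gene character vector of target gene symbols (non-targeting guides
#'   may share a placeholder symbol such as "NT").
#' @param spacer character vector of uppercase ACGT spacer sequences, all the
#'   same length (20 bases in the screens this package models).
#' @param is_nt logical vector flagging non-targeting guides.
#' @return a `data.frame` of class `guide_library` with columns
#'   `sgrna`, `gene`, `spacer`, `is_nt`.
#' @export
guide_library <- function(sgrna, gene, spacer, is_nt = rep(FALSE, length(sgrna))) {
  sgrna <- as.character(sgrna)
  gene <- normalize_gene_symbols(gene)
  spacer <- toupper(as.character(spacer))
  if (anyDuplicated(sgrna)) {
    dup <- unique(sgrna[duplicated(sgrna)])
    stop("duplicate sgRNA id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(nchar(spacer))) > 1L)
    stop("all spacers must have identical length", call. = FALSE)
  bad <- grepl("[^ACGT]", spacer)
  if (any(bad))
    stop("non-ACGT spacer at entry ", which(bad)[1], " (", sgrna[which(bad)[1]],
         ")", call. = FALSE)
  if (length(gene) != length(sgrna) || length(spacer) != length(sgrna) ||
      length(is_nt) != length(sgrna))
    stop("sgrna, gene, spacer and is_nt must have equal length", call. = FALSE)
  out <- data.frame(sgrna = sgrna, gene = gene, spacer = spacer,
                    is_nt = as.logical(is_nt), stringsAsFactors = FALSE)
  class(out) <- c("guide_library", "data.frame")
  out
}

#' Read / write a guide library TSV
#'
#' The on-disk format is a four-column TSV with header
#' `sgrna  gene  spacer  is_nt`.
#'
#' @param path file path.
#' @return `read_guide_library()` returns a validated [guide_library()].
#' @export
read_guide_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sgrna", "gene", "spacer"), "library file")
  if (is.null(df$is_nt)) df$is_nt <- FALSE
  guide_library(df$sgrna, df$gene, df$spacer, as.logical(df$is_nt))
}

#' @rdname read_guide_library
#' @param library a [guide_library()].
#' @export
write_guide_library <- function(library, path) {
  stopifnot(inherits(library, "guide_library"))
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
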