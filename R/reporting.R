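## Final outputs: fusion-call tables, per-cell occupancy, and the exact
## association test used for downstream contingency tables.

#' Two-sided Fisher's exact test of a 2x2 table
#'
#' Association between fusion status and a binary cell attribute
#' (expression above a threshold, treatment, ...). The two-sided p-value
#' follows the probability-based rule: the sum over all tables with the
#' observed margins whose hypergeometric probability does not exceed that
#' of the observed table (as in [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return two-sided p-value.
#' @examples
#' fisher_association(matrix(c(18, 3, 90, 78), 2)) # 0.0047
#' @export
fisher_association <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("both margins must be positive")
  }
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Dichotomize an expression vector
#'
#' Helper for association tables: splits cells into high/low expression at
#' a threshold (default: expression greater than 1 is high).
#'
#' @param expr numeric vector of per-cell expression.
#' @param threshold cutoff (strictly greater counts as high).
#' @return logical vector, `TRUE` = high.
#' @export
dichotomize_expression <- function(expr, threshold = 1) {
  expr > threshold
}

#' Per-cell fusion occupancy matrix
#'
#' Binary cells-by-fusions matrix: a cell is marked 1 for a fusion call
#' if it has at least one supporting read for it.
#'
#' @param calls a `fusion_calls` data.frame (see [finalize_calls()]) with
#'   a `supporting_cells` column of comma-separated cell ids, or a
#'   `fusion_candidates` object.
#' @param cells cell ordering for the rows.
#' @return binary matrix (cells x fusions).
#' @export
per_cell_fusion_matrix <- function(calls, cells) {
  if (is(calls, "fusion_candidates")) {
    ids <- calls$candidates$id
    sup <- split(calls$support$cell_id, factor(calls$support$candidate_id, levels = ids))
  } else {
    ids <- calls$id
    sup <- lapply(strsplit(ifelse(is.na(calls$supporting_cells), "", calls$supporting_cells), ","),
                  function(x) x[nzchar(x)])
  }
  m <- matrix(0L, length(cells), length(ids), dimnames = list(cells, ids))
  for (k in seq_along(ids)) m[intersect(sup[[k]], cells), k] <- 1L
  m
}

#' Assemble the final fusion-call table
#'
#' Joins the surviving candidates with their test results and artifact
#' scores into the output call set.
#'
#' @param candidates filtered `fusion_candidates`.
#' @param tests [test_candidates()] result (superset of the candidates).
#' @param scores named or aligned artifact scores (`NA` allowed), or
#'   `NULL`.
#' @return data.frame of class `fusion_calls`: id, gene5, gene3,
#'   breakpoints, support totals, `n_cells`, `nu`, `sigma`, `pvalue`,
#'   `artifact_score`, `supporting_cells`.
#' @export
finalize_calls <- function(candidates, tests, scores = NULL) {
  cd <- candidates$candidates
  m <- match(cd$id, tests$candidate_id)
  sup <- split(candidates$support$cell_id,
               factor(candidates$support$candidate_id, levels = cd$id))
  out <- data.frame(
    id = cd$id, gene5 = cd$gene5, gene3 = cd$gene3,
    chrom5 = cd$chrom5, pos5 = cd$pos5, strand5 = cd$strand5,
    chrom3 = cd$chrom3, pos3 = cd$pos3, strand3 = cd$strand3,
    n_cells = cd$n_cells, n_split = cd$n_split, n_discordant = cd$n_discordant,
    nu = tests$nu[m], sigma = tests$sigma[m], pvalue = tests$pvalue[m],
    artifact_score = if (is.null(scores)) rep(NA_real_, nrow(cd)) else as.numeric(scores),
    supporting_cells = vapply(sup, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("fusion_calls", "data.frame")
  out
}

#' Write / read a fusion-call table
#'
#' Round-tripping TSV persistence of the final call set.
#'
#' @param calls a `fusion_calls` data.frame.
#' @param path TSV file.
#' @return `read_fusion_calls()` returns the restored calls.
#' @export
write_fusion_calls <- function(calls, path) {
  df <- as.data.frame(calls)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fusion_calls
#' @export
read_fusion_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(supporting_cells = "character"))
  df$supporting_cells[is.na(df$supporting_cells)] <- ""
  class(df) <- c("fusion_calls", "data.frame")
  df
}
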