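## Annotation-based and ad hoc candidate filters. Each filter removes whole
## candidates (never mutating support counts) and records its removal count,
## so a run reproduces the full filter funnel.

# drop candidate rows by id, keeping support/membership consistent
.drop_candidates <- function(candidates, drop_ids, label) {
  keep <- !(candidates$candidates$id %in% drop_ids)
  out <- candidates
  out$candidates <- candidates$candidates[keep, , drop = FALSE]
  rownames(out$candidates) <- NULL
  out$support <- candidates$support[candidates$support$candidate_id %in% out$candidates$id, , drop = FALSE]
  rownames(out$support) <- NULL
  out$membership[out$membership %in% drop_ids] <- NA_character_
  attr(out, "removed") <- setNames(sum(!keep), label)
  out
}

#' Annotation-based candidate filter
#'
#' Removes candidates with a pseudogene partner; optionally removes
#' candidates with an lncRNA partner or a partner without an approved gene
#' symbol (both filters can be disabled); and removes candidates whose
#' consensus breakpoint falls in an intron of the assigned gene (a
#' breakpoint on an exon boundary counts as exonic). A partner gene absent
#' from the annotation is treated as having no approved symbol.
#'
#' @param candidates a `fusion_candidates` object.
#' @param annotation a [gene_annotation()].
#' @param enable_lncrna apply the lncRNA filter?
#' @param enable_symbol apply the approved-symbol filter?
#' @return filtered `fusion_candidates` (removal count in attribute
#'   `"removed"`).
#' @export
annotation_filter <- function(candidates, annotation,
                              enable_lncrna = TRUE, enable_symbol = TRUE) {
  cd <- candidates$candidates
  if (!nrow(cd)) return(candidates)
  g <- annotation$genes
  look <- function(ids, col, default) {
    v <- g[[col]][match(ids, g$gene_id)]
    v[is.na(v)] <- default
    v
  }
  bt5 <- look(cd$gene5, "biotype", "unknown")
  bt3 <- look(cd$gene3, "biotype", "unknown")
  is_pseudo <- grepl("pseudogene", bt5) | grepl("pseudogene", bt3)
  is_lnc <- grepl("lncRNA|lincRNA", bt5) | grepl("lncRNA|lincRNA", bt3)
  approved <- look(cd$gene5, "approved", FALSE) & look(cd$gene3, "approved", FALSE)
  intronic <- !in_exon(annotation, cd$gene5, cd$chrom5, cd$pos5) |
    !in_exon(annotation, cd$gene3, cd$chrom3, cd$pos3)
  drop <- is_pseudo | intronic
  if (enable_lncrna) drop <- drop | is_lnc
  if (enable_symbol) drop <- drop | !approved
  .drop_candidates(candidates, cd$id[drop], "annotation")
}

#' Minimum supporting-cell filter
#'
#' Keeps candidates supported (split or discordant reads) in at least
#' `min_cells` cells. For a bare support matrix, keeps rows with at least
#' `min_cells` nonzero entries.
#'
#' @param x a `fusion_candidates` object or a candidate-by-cell count
#'   matrix.
#' @param min_cells minimum number of supporting cells (default 2).
#' @return object of the same type, filtered.
#' @export
min_cell_filter <- function(x, min_cells = 2L) {
  if (is(x, "fusion_candidates")) {
    drop <- x$candidates$id[x$candidates$n_cells < min_cells]
    return(.drop_candidates(x, drop, "min_cells"))
  }
  nz <- Matrix::rowSums(x > 0)
  x[nz >= min_cells, , drop = FALSE]
}

#' Promiscuous-partner filter
#'
#' If a gene occurs in more than `max_partners` candidates, every candidate
#' involving that gene is removed. The degree is computed once on the input
#' list (no cascading re-evaluation).
#'
#' @param candidates a `fusion_candidates` object.
#' @param max_partners maximum candidate count per gene (default 5; the
#'   comparison is strict, a gene in exactly `max_partners` candidates is
#'   kept).
#' @return filtered `fusion_candidates`.
#' @export
too_many_partner_filter <- function(candidates, max_partners = 5L) {
  cd <- candidates$candidates
  if (!nrow(cd)) return(candidates)
  deg <- table(c(cd$gene5, cd$gene3))
  bad <- names(deg)[deg > max_partners]
  drop <- cd$id[cd$gene5 %in% bad | cd$gene3 %in% bad]
  .drop_candidates(candidates, drop, "too_many_partners")
}

#' Discordant-to-split ratio filter
#'
#' Removes candidates whose total discordant support exceeds `ratio` times
#' their total split support (strict comparison; a candidate with zero
#' split reads and any discordant read is removed).
#'
#' @param candidates a `fusion_candidates` object.
#' @param ratio maximum discordant/split ratio (default 10).
#' @return filtered `fusion_candidates`.
#' @export
discordant_ratio_filter <- function(candidates, ratio = 10) {
  cd <- candidates$candidates
  if (!nrow(cd)) return(candidates)
  drop <- cd$id[cd$n_discordant > ratio * cd$n_split]
  .drop_candidates(candidates, drop, "discordant_ratio")
}

#' Filter funnel report
#'
#' Collects the candidate counts remaining after each named filter layer
#' into a small table, mirroring the layered funnel of a detection run.
#'
#' @param counts named integer vector, in application order (first element:
#'   the unfiltered candidate count).
#' @return data.frame with columns `layer`, `n_candidates`, `removed`.
#' @export
filter_funnel <- function(counts) {
  data.frame(layer = names(counts),
             n_candidates = as.integer(counts),
             removed = c(NA_integer_, -diff(as.integer(counts))),
             stringsAsFactors = FALSE)
}
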