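## Gene annotation container: gene table + exon table + a GRanges index used
## to assign genomic positions to genes and to extract exonic sequence
## around candidate junctions.

#' Construct a gene annotation
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand` ("+"/"-"), `biotype`
#'   (e.g. "protein_coding", "pseudogene", "lncRNA"), `approved` (logical;
#'   whether the symbol is an approved gene symbol).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive). Overlapping exons of one gene are unioned.
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons) {
  need_g <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype", "approved")
  need_e <- c("gene_id", "chrom", "start", "end")
  stopifnot(all(need_g %in% names(genes)), all(need_e %in% names(exons)))
  stopifnot(!anyDuplicated(genes$gene_id), all(exons$start <= exons$end))
  stopifnot(all(exons$gene_id %in% genes$gene_id))
  genes <- as.data.frame(genes)[, need_g]
  exons <- as.data.frame(exons)[, need_e]
  # union exons per gene so the exonic test is on disjoint intervals
  grl <- GenomicRanges::reduce(S4Vectors::split(
    GenomicRanges::GRanges(exons$chrom, IRanges::IRanges(exons$start, exons$end)),
    factor(exons$gene_id, levels = genes$gene_id)))
  gr <- unlist(grl, use.names = TRUE)
  ex <- data.frame(
    gene_id = names(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(match(ex$gene_id, genes$gene_id), ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  exon_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  S4Vectors::mcols(exon_gr)$gene_id <- ex$gene_id
  structure(list(genes = genes, exons = ex, exon_gr = exon_gr),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exon intervals, biotypes: %s\n",
              nrow(x$genes), nrow(x$exons),
              paste(names(sort(table(x$genes$biotype), decreasing = TRUE)), collapse = ", ")))
  invisible(x)
}

#' Read a gene annotation from a GTF file
#'
#' Imports gene and exon records with [rtracklayer::import()]. The biotype
#' is looked up in the first of `biotype_attr` present; approved-symbol
#' status comes from `symbol_status` (see [read_symbol_status()]) when
#' given, otherwise all symbols are treated as approved.
#'
#' @param path GTF file.
#' @param symbol_status optional data.frame from [read_symbol_status()] or
#'   path to such a table.
#' @param biotype_attr candidate GTF attribute names holding the biotype.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path, symbol_status = NULL,
                                 biotype_attr = c("gene_biotype", "gene_type")) {
  gtf <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gtf)
  btcol <- intersect(biotype_attr, colnames(mc))
  bt <- if (length(btcol)) as.character(mc[[btcol[1]]]) else rep("protein_coding", length(gtf))
  sym <- if ("gene_name" %in% colnames(mc)) as.character(mc$gene_name) else as.character(mc$gene_id)
  is_exon <- mc$type == "exon"
  ex_df <- data.frame(
    gene_id = as.character(mc$gene_id[is_exon]),
    chrom = as.character(GenomicRanges::seqnames(gtf)[is_exon]),
    start = GenomicRanges::start(gtf)[is_exon],
    end = GenomicRanges::end(gtf)[is_exon],
    stringsAsFactors = FALSE
  )
  is_gene <- mc$type == "gene"
  if (!any(is_gene)) {
    # derive gene extents from exons
    agg_min <- tapply(ex_df$start, ex_df$gene_id, min)
    agg_max <- tapply(ex_df$end, ex_df$gene_id, max)
    first <- !duplicated(mc$gene_id[is_exon])
    ids <- as.character(mc$gene_id[is_exon])[first]
    g_df <- data.frame(
      gene_id = ids,
      symbol = sym[is_exon][first],
      chrom = ex_df$chrom[first],
      start = as.integer(agg_min[ids]),
      end = as.integer(agg_max[ids]),
      strand = as.character(GenomicRanges::strand(gtf)[is_exon])[first],
      biotype = bt[is_exon][first],
      stringsAsFactors = FALSE
    )
  } else {
    g_df <- data.frame(
      gene_id = as.character(mc$gene_id[is_gene]),
      symbol = sym[is_gene],
      chrom = as.character(GenomicRanges::seqnames(gtf)[is_gene]),
      start = GenomicRanges::start(gtf)[is_gene],
      end = GenomicRanges::end(gtf)[is_gene],
      strand = as.character(GenomicRanges::strand(gtf)[is_gene]),
      biotype = bt[is_gene],
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(symbol_status)) {
    if (is.character(symbol_status)) symbol_status <- read_symbol_status(symbol_status)
    g_df$approved <- g_df$symbol %in% symbol_status$symbol[symbol_status$status == "approved"]
  } else {
    g_df$approved <- TRUE
  }
  gene_annotation(g_df, ex_df)
}

#' Read a gene-symbol status table
#'
#' Two-column TSV (`symbol`, `status`) where status is `"approved"` for
#' approved gene symbols and anything else otherwise.
#'
#' @param path TSV file.
#' @return data.frame with columns `symbol`, `status`.
#' @export
read_symbol_status <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "status") %in% names(df)))
  df
}

#' Assign genomic positions to genes by exon overlap
#'
#' A position overlapping the exons of several genes is assigned to all of
#' them.
#'
#' @param annotation a [gene_annotation()].
#' @param chrom,pos character/integer vectors of equal length.
#' @return list (one element per position) of character vectors of gene ids
#'   (possibly empty).
#' @export
assign_genes <- function(annotation, chrom, pos) {
  stopifnot(is(annotation, "gene_annotation"), length(chrom) == length(pos))
  if (length(pos) == 0L) return(list())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, annotation$exon_gr)
  gid <- S4Vectors::mcols(annotation$exon_gr)$gene_id[S4Vectors::subjectHits(hits)]
  res <- rep(list(character(0)), length(pos))
  if (length(hits)) {
    sp <- split(gid, S4Vectors::queryHits(hits))
    res[as.integer(names(sp))] <- lapply(sp, unique)
  }
  res
}

#' Is a position inside an exon of a given gene?
#'
#' Exon boundaries count as exonic.
#'
#' @inheritParams assign_genes
#' @param gene_id character vector, recycled with `chrom`/`pos`.
#' @return logical vector.
#' @export
in_exon <- function(annotation, gene_id, chrom, pos) {
  n <- max(length(gene_id), length(pos))
  gene_id <- rep_len(gene_id, n); chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  if (n == 0L) return(logical(0))
  hit <- assign_genes(annotation, chrom, pos)
  mapply(function(g, h) g %in% h, gene_id, hit, USE.NAMES = FALSE)
}

# transcript coordinate of a genomic position within a gene's exon union,
# measured from the transcript 5' end (strand-aware); NA if intronic/outside
.transcript_coord <- function(annotation, gene_id, pos) {
  n <- length(pos)
  out <- rep(NA_integer_, n)
  ex <- annotation$exons
  gstrand <- annotation$genes$strand[match(gene_id, annotation$genes$gene_id)]
  for (i in seq_len(n)) {
    e <- ex[ex$gene_id == gene_id[i], , drop = FALSE]
    if (!nrow(e)) next
    w <- cumsum(c(0L, e$end - e$start + 1L))
    k <- which(pos[i] >= e$start & pos[i] <= e$end)
    if (!length(k)) next
    tc <- w[k[1]] + (pos[i] - e$start[k[1]] + 1L)
    if (identical(gstrand[i], "-")) tc <- w[length(w)] - tc + 1L
    out[i] <- as.integer(tc)
  }
  out
}

# spliced exonic sequence of a gene in transcript (5'->3') orientation,
# taken from per-gene transcript FASTA if named by gene, else from genome
.gene_transcript_seq <- function(annotation, seqs, gene_id) {
  if (is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  out <- seqs[gene_id]
  if (any(is.na(out))) stop("missing transcript sequence for gene(s): ",
                            paste(unique(gene_id[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Junction window sequence of fusion candidates
#'
#' Reconstructs the read-orientation sequence around a candidate junction
#' from the reference transcript sequences: `flank` exonic bases ending at
#' the 5'-side breakpoint followed by `flank` exonic bases starting at the
#' 3'-side breakpoint. A side whose mapped strand is antisense to its gene
#' is reverse-complemented, so the window reproduces what the supporting
#' reads contained. Sides whose breakpoint cannot be placed on exonic
#' sequence yield `NA`.
#'
#' @param candidates a `fusion_candidates` object (see
#'   [cluster_breakpoints()]).
#' @param annotation a [gene_annotation()].
#' @param seqs transcript sequences named by gene id.
#' @param flank bases per side (default 30, giving the 60 bp classifier
#'   window).
#' @return character vector of windows (length `2 * flank`), `NA` where
#'   sequence is unavailable.
#' @export
junction_window <- function(candidates, annotation, seqs, flank = 30L) {
  cd <- candidates$candidates
  up <- .side_flank(annotation, seqs, cd$gene5, cd$pos5, cd$strand5, flank, side = "five")
  dn <- .side_flank(annotation, seqs, cd$gene3, cd$pos3, cd$strand3, flank, side = "three")
  ifelse(is.na(up) | is.na(dn), NA_character_, paste0(up, dn))
}

# flank on one side of the junction in read orientation
.side_flank <- function(annotation, seqs, gene_id, pos, read_strand, flank, side) {
  n <- length(gene_id)
  gstrand <- annotation$genes$strand[match(gene_id, annotation$genes$gene_id)]
  tc <- .transcript_coord(annotation, gene_id, pos)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(tc[i])) next
    tx <- .gene_transcript_seq(annotation, seqs, gene_id[i])
    L <- nchar(tx)
    sense <- identical(read_strand[i], gstrand[i])
    p <- if (sense) tc[i] else L - tc[i] + 1L  # coordinate on the read strand
    stx <- if (sense) tx else .revcomp(tx)
    s <- if (side == "five") {
      substr(stx, max(1L, p - flank + 1L), p)
    } else {
      substr(stx, p, min(L, p + flank - 1L))
    }
    if (nchar(s) < flank) next  # too close to a transcript end
    out[i] <- s
  }
  out
}

#' Synthetic transcriptome for simulation and testing
#'
#' Generates `n_genes` single-exon genes laid head-to-tail on one synthetic
#' chromosome, with i.i.d. uniform A/C/G/T sequence, protein-coding biotype
#' and approved symbols, plus a log-normal baseline expression profile used
#' by the read simulator.
#'
#' @param n_genes number of genes.
#' @param mean_len,sd_len transcript length distribution (bp; lengths are
#'   drawn log-normally and floored at 6 times the read margin).
#' @param seed RNG seed.
#' @param gap intergenic spacing (bp).
#' @return list with elements `annotation` ([gene_annotation()]), `seqs`
#'   (named character vector of transcript sequences), `baseline`
#'   (named numeric expression profile summing to 1).
#' @export
synthetic_transcriptome <- function(n_genes = 100, mean_len = 1500, sd_len = 300,
                                    seed = 1, gap = 100L) {
  set.seed(seed)
  len <- pmax(600L, as.integer(round(rnorm(n_genes, mean_len, sd_len))))
  ids <- sprintf("G%03d", seq_len(n_genes))
  seqs <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- ids
  start <- cumsum(c(1L, head(len + gap, -1L)))
  genes <- data.frame(
    gene_id = ids, symbol = ids, chrom = "chrS",
    start = start, end = start + len - 1L, strand = "+",
    biotype = "protein_coding", approved = TRUE, stringsAsFactors = FALSE
  )
  exons <- genes[, c("gene_id", "chrom", "start", "end")]
  base <- exp(rnorm(n_genes, 0, 1)) * len / mean(len)
  list(annotation = gene_annotation(genes, exons),
       seqs = seqs,
       baseline = setNames(base / sum(base), ids))
}
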