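## Synthetic full-length scRNA-seq dataset generator: background reads from
## a baseline expression profile, technical chimeras from the mis-priming
## library, and true fusions spiked into a fraction of cells, with full
## ground-truth tables. The generator emits chimeric-junction evidence in
## the same dialect the detection pipeline consumes (alignment itself is
## out of scope), per-cell expression, and optionally FASTQ.

#' Simulation configuration
#'
#' Validated container of generator settings. The defaults are the
#' desk-scale study conditions used throughout the package: 50 cells of
#' 5e4 reads, technical chimeras at 1% of reads per cell drawn from a
#' 2e4-entry mis-priming library with per-entry expressions uniform on
#' 1..100, and true fusions present in 20% of cells on average.
#' Paper-scale settings (hundreds of cells, millions of reads, a
#' multi-million-entry library) are accepted unchanged.
#'
#' @param n_cells number of cells.
#' @param reads_per_cell total reads per cell.
#' @param read_length read length (bp).
#' @param library_size mis-priming library entries.
#' @param chimeric_fraction fraction of each cell's reads that are
#'   technical chimeric reads (default 0.01).
#' @param chimera_expression_range integer range the per-entry chimera
#'   expressions are drawn from (default 1..100).
#' @param entries_per_cell chimera library entries selected per cell
#'   (weighted by W). The default, 10% of the library, reproduces the
#'   hallmark support pattern of real full-length scRNA-seq: tens of
#'   thousands of distinct chimeric junctions per cell, almost all with a
#'   single supporting read, and a support matrix that is >95% zeros.
#' @param true_fusions data.frame of spiked fusions (see
#'   [sample_true_fusions()]) or `NULL`.
#' @param fusion_cell_fraction probability that a cell carries each fusion
#'   (default 0.2).
#' @param overhang minimum read bases on each side of a junction for a
#'   read to be junction-spanning.
#' @param orientation chimera construction geometry, see
#'   [build_chimera_library()].
#' @param seed master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 50L, reads_per_cell = 5e4, read_length = 100L,
                       library_size = 2e4, chimeric_fraction = 0.01,
                       chimera_expression_range = c(1L, 100L),
                       entries_per_cell = NULL,
                       true_fusions = NULL, fusion_cell_fraction = 0.2,
                       overhang = 15L,
                       orientation = c("antiparallel", "parallel"),
                       seed = 1L) {
  orientation <- match.arg(orientation)
  if (is.null(entries_per_cell)) entries_per_cell <- max(50, round(0.1 * library_size))
  stopifnot(n_cells >= 1, reads_per_cell >= 1, read_length >= 40,
            chimeric_fraction >= 0, chimeric_fraction < 1,
            fusion_cell_fraction >= 0, fusion_cell_fraction <= 1,
            length(chimera_expression_range) == 2,
            chimera_expression_range[1] >= 1,
            diff(chimera_expression_range) >= 0)
  structure(list(n_cells = as.integer(n_cells), reads_per_cell = reads_per_cell,
                 read_length = as.integer(read_length),
                 library_size = library_size,
                 chimeric_fraction = chimeric_fraction,
                 chimera_expression_range = as.integer(chimera_expression_range),
                 entries_per_cell = as.integer(entries_per_cell),
                 true_fusions = true_fusions,
                 fusion_cell_fraction = fusion_cell_fraction,
                 overhang = as.integer(overhang),
                 orientation = orientation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw true fusions to spike into a simulation
#'
#' Picks `n` disjoint gene pairs from a synthetic transcriptome and a
#' breakpoint inside each partner (away from the transcript ends), with an
#' expression level per fusion. Expression is TPM-like (absolute, not
#' relative to the transcriptome size): a fusion at expression `e`
#' receives about `e / 1e6` of a bearing cell's non-chimeric reads. The
#' default draws moderate-to-high expressions, log-uniform between 1500
#' and 8000 TPM — the top of that range corresponds to the tens of
#' junction-spanning reads per cell seen for highly expressed driver
#' fusions.
#'
#' @param transcriptome a [synthetic_transcriptome()] result.
#' @param n number of fusions.
#' @param expression numeric scalar/vector of expression levels, or `NULL`
#'   for the log-uniform default.
#' @param margin minimum breakpoint distance from the transcript ends.
#' @param seed RNG seed.
#' @return data.frame: `fusion_id`, `gene5`, `gene3`, `b5`, `b3`
#'   (transcript coordinates), `expression`.
#' @export
sample_true_fusions <- function(transcriptome, n = 20L, expression = NULL,
                                margin = 150L, seed = 1L) {
  set.seed(seed)
  ids <- names(transcriptome$seqs)
  len <- nchar(transcriptome$seqs)
  if (2L * n > length(ids)) stop("not enough genes for disjoint fusion pairs")
  pick <- sample(ids, 2L * n)
  g5 <- pick[seq_len(n)]; g3 <- pick[n + seq_len(n)]
  b5 <- margin + floor(runif(n) * (len[g5] - 2 * margin))
  b3 <- margin + floor(runif(n) * (len[g3] - 2 * margin))
  if (is.null(expression)) expression <- 10^runif(n, log10(1500), log10(8000))
  data.frame(fusion_id = sprintf("FUS%03d", seq_len(n)),
             gene5 = g5, gene3 = g3,
             b5 = as.integer(b5), b3 = as.integer(b3),
             expression = rep_len(expression, n),
             stringsAsFactors = FALSE)
}

# genomic position of a transcript coordinate for single-exon plus-strand
# synthetic genes
.sim_genomic <- function(annotation, gene_id, tpos) {
  g <- annotation$genes
  as.integer(g$start[match(gene_id, g$gene_id)] + tpos - 1L)
}

#' Simulate a full single-cell dataset
#'
#' Generates, for each cell: background reads allocated over the
#' transcriptome baseline profile, technical chimeric reads at
#' `chimeric_fraction` of the cell's reads (library entries selected with
#' probability proportional to the sampling weight W, each with an
#' expression drawn uniformly from the configured range that controls its
#' read count), and junction-spanning reads of the spiked fusions carried
#' by that cell. Split-read junction records (with read sequence and
#' junction offset) are emitted for every chimeric and fusion
#' junction-spanning read; background and non-spanning fusion reads
#' contribute to the expression matrix only. Per-cell read totals are
#' conserved: background + chimeric + fusion = `reads_per_cell`.
#'
#' @param cfg a [sim_config()].
#' @param transcriptome a [synthetic_transcriptome()]; generated from the
#'   master seed when `NULL`.
#' @param library a [build_chimera_library()]; built from the master seed
#'   when `NULL`.
#' @return object of class `sim_dataset`: list with `records` (junction
#'   evidence data.frame with `cell_id`), `expr` (gene-by-cell TPM
#'   matrix), `annotation`, `seqs`, `library`, `truth` (list: `fusions`
#'   with supporting cell lists, `chimeras` per cell-entry read counts,
#'   `accounting` per-cell read totals), and `config`.
#' @export
simulate_dataset <- function(cfg, transcriptome = NULL, library = NULL) {
  stopifnot(is(cfg, "sim_config"))
  if (is.null(transcriptome)) {
    transcriptome <- synthetic_transcriptome(seed = cfg$seed + 1L)
  }
  ann <- transcriptome$annotation
  seqs <- transcriptome$seqs
  base <- transcriptome$baseline
  if (is.null(library) && cfg$chimeric_fraction > 0) {
    library <- build_chimera_library(seqs, size = cfg$library_size,
                                     seed = cfg$seed + 2L,
                                     orientation = cfg$orientation)
  }
  rl <- cfg$read_length
  cells <- sprintf("cell%03d", seq_len(cfg$n_cells))
  fus <- cfg$true_fusions
  n_fus <- if (is.null(fus)) 0L else nrow(fus)

  set.seed(cfg$seed + 3L)
  # fusion-bearing cells: each (fusion, cell) independent with the
  # configured fraction
  bearing <- if (n_fus) matrix(runif(n_fus * cfg$n_cells) < cfg$fusion_cell_fraction,
                               n_fus, cfg$n_cells) else matrix(FALSE, 0, cfg$n_cells)
  # fusion transcript sequences and junction-spanning probability
  if (n_fus) {
    fseq <- paste0(substr(seqs[fus$gene5], 1L, fus$b5),
                   substr(seqs[fus$gene3], fus$b3, nchar(seqs[fus$gene3])))
    flen <- nchar(fseq)
    p_span <- pmin(1, pmax(0, (rl - 2 * cfg$overhang + 1) / (flen - rl + 1)))
  }
  if (cfg$reads_per_cell * cfg$chimeric_fraction < 1 && cfg$chimeric_fraction > 0) {
    warning("chimeric_fraction implies < 1 chimeric read per cell; emitting 0 for some cells")
  }

  expr_counts <- matrix(0, length(base), cfg$n_cells,
                        dimnames = list(names(base), cells))
  rec <- vector("list", cfg$n_cells)
  chim_truth <- vector("list", cfg$n_cells)
  acct <- data.frame(cell_id = cells, background = 0, chimeric = 0, fusion = 0)
  fus_reads <- if (n_fus) matrix(0L, n_fus, cfg$n_cells) else NULL

  for (j in seq_len(cfg$n_cells)) {
    set.seed((cfg$seed + 10L + j) %% .Machine$integer.max)
    n_chim <- if (cfg$chimeric_fraction > 0)
      rbinom(1L, cfg$reads_per_cell, cfg$chimeric_fraction) else 0L
    budget <- cfg$reads_per_cell - n_chim

    # background + active-fusion allocation
    act <- if (n_fus) which(bearing[, j]) else integer(0)
    # expression is TPM-like: weight relative to the whole baseline profile
    wf <- if (length(act)) fus$expression[act] / 1e6 else numeric(0)
    alloc <- drop(rmultinom(1L, budget, c(base, wf)))
    gcounts <- alloc[seq_along(base)]
    cell_rec <- list()

    if (length(act)) {
      nf <- alloc[length(base) + seq_along(act)]
      span <- rbinom(length(act), nf, p_span[act])
      fus_reads[act, j] <- as.integer(span)
      # non-spanning fusion reads raise the partner genes' coverage
      rest <- nf - span
      share5 <- fus$b5[act] / flen[act]
      r5 <- rbinom(length(act), rest, share5)
      gcounts[fus$gene5[act]] <- gcounts[fus$gene5[act]] + r5
      gcounts[fus$gene3[act]] <- gcounts[fus$gene3[act]] + (rest - r5)
      for (k in seq_along(act)) {
        if (span[k] == 0L) next
        f <- act[k]
        off <- cfg$overhang + floor(runif(span[k]) * (rl - 2 * cfg$overhang + 1))
        st <- fus$b5[f] - off + 1L
        cell_rec[[length(cell_rec) + 1L]] <- data.frame(
          chrom_a = "chrS", pos_a = .sim_genomic(ann, fus$gene5[f], fus$b5[f]),
          strand_a = "+",
          chrom_b = "chrS", pos_b = .sim_genomic(ann, fus$gene3[f], fus$b3[f]),
          strand_b = "+",
          jtype = 0L,
          read_name = sprintf("%s_f%d_%d", cells[j], f, seq_len(span[k])),
          cigar_a = sprintf("%dM", off), cigar_b = sprintf("%dM", rl - off),
          mapq_a = 255L, mapq_b = 255L,
          read_seq = substr(rep(fseq[f], span[k]), st, st + rl - 1L),
          junction_offset = as.integer(off),
          stringsAsFactors = FALSE)
      }
      acct$fusion[j] <- sum(span)
      # conservation: non-spanning fusion reads are background coverage
      acct$background[j] <- budget - sum(span)
    } else {
      acct$background[j] <- budget
    }
    expr_counts[, j] <- expr_counts[, j] + gcounts

    if (n_chim > 0L) {
      sel <- sample.int(nrow(library), min(cfg$entries_per_cell, nrow(library)),
                        prob = library$W)
      xr <- cfg$chimera_expression_range
      xe <- xr[1] + floor(runif(length(sel)) * (xr[2] - xr[1] + 1))
      creads <- drop(rmultinom(1L, n_chim, xe))
      nz <- which(creads > 0L)
      if (length(nz)) {
        ent <- library[sel[nz], , drop = FALSE]
        reps <- creads[nz]
        idx <- rep(seq_along(nz), reps)
        off <- cfg$overhang + floor(runif(length(idx)) * (rl - 2 * cfg$overhang + 1))
        e <- ent[idx, , drop = FALSE]
        up <- substr(seqs[e$t1], e$b1 - off + 1L, e$b1)
        down_len <- rl - off
        down <- if (cfg$orientation == "antiparallel") {
          .revcomp(substr(seqs[e$t2], e$b2 - down_len + 1L, e$b2))
        } else {
          .comp(substr(seqs[e$t2], e$b2 + 1L, e$b2 + down_len))
        }
        posb <- if (cfg$orientation == "antiparallel") e$b2 else e$b2 + 1L
        cell_rec[[length(cell_rec) + 1L]] <- data.frame(
          chrom_a = "chrS", pos_a = .sim_genomic(ann, e$t1, e$b1),
          strand_a = "+",
          chrom_b = "chrS", pos_b = .sim_genomic(ann, e$t2, posb),
          strand_b = "-",
          jtype = 0L,
          read_name = sprintf("%s_c%d_%d", cells[j], sel[nz][idx], seq_along(idx)),
          cigar_a = sprintf("%dM", off), cigar_b = sprintf("%dM", rl - off),
          mapq_a = 255L, mapq_b = 255L,
          read_seq = paste0(up, down),
          junction_offset = as.integer(off),
          stringsAsFactors = FALSE)
        chim_truth[[j]] <- data.frame(cell_id = cells[j], entry = sel[nz],
                                      reads = as.integer(reps),
                                      stringsAsFactors = FALSE)
      }
      acct$chimeric[j] <- n_chim
    }
    rec[[j]] <- if (length(cell_rec)) {
      d <- do.call(rbind, cell_rec); d$cell_id <- cells[j]; d
    } else NULL
  }

  records <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  expr <- sweep(expr_counts, 2, pmax(colSums(expr_counts), 1), "/") * 1e6

  fus_truth <- NULL
  if (n_fus) {
    fus_truth <- fus
    fus_truth$pos5 <- .sim_genomic(ann, fus$gene5, fus$b5)
    fus_truth$pos3 <- .sim_genomic(ann, fus$gene3, fus$b3)
    fus_truth$cells <- apply(fus_reads > 0, 1, function(z) paste(cells[z], collapse = ","))
    fus_truth$n_cells <- rowSums(fus_reads > 0)
    fus_truth$junction_reads <- rowSums(fus_reads)
  }
  structure(list(records = records, expr = expr,
                 annotation = ann, seqs = seqs,
                 baseline = base, library = library,
                 truth = list(fusions = fus_truth,
                              chimeras = do.call(rbind, chim_truth[!vapply(chim_truth, is.null, logical(1))]),
                              accounting = acct),
                 cells = cells,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset: %d cells x %s reads, %d chimeric junction records, ",
                     "%d spiked fusions\n"),
              x$config$n_cells, format(x$config$reads_per_cell, big.mark = ","),
              if (is.null(x$records)) 0L else nrow(x$records),
              if (is.null(x$truth$fusions)) 0L else nrow(x$truth$fusions)))
  invisible(x)
}

#' Sample background (non-chimeric) read sequences
#'
#' Draws reads uniformly positioned on transcripts selected by the
#' baseline expression profile; used as the read pool of the classifier's
#' random-concatenation examples and by the FASTQ writer.
#'
#' @param x a `sim_dataset`.
#' @param n number of reads.
#' @param seed RNG seed.
#' @return character vector of read sequences.
#' @export
sample_background_reads <- function(x, n, seed = 1L) {
  set.seed(seed)
  rl <- x$config$read_length
  len <- nchar(x$seqs)
  ok <- len >= rl
  w <- x$baseline[ok] / sum(x$baseline[ok])
  tx <- sample(names(x$seqs)[ok], n, replace = TRUE, prob = w)
  st <- 1L + floor(runif(n) * (len[tx] - rl + 1))
  substr(x$seqs[tx], st, st + rl - 1L)
}

#' Write a simulated dataset to disk
#'
#' Writes per-cell chimeric-junction TSVs (the dialect
#' [read_chimeric_junctions()] reads), the expression matrix, the truth
#' tables, the chimera library and the transcript FASTA; optionally
#' per-cell gzipped FASTQ with background reads included.
#'
#' @param x a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @param fastq also write per-cell FASTQ (`.fastq.gz`)?
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(x, dir, fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- intersect(c(.junction_cols, "mapq_a", "mapq_b", "read_seq", "junction_offset"),
                    names(x$records))
  for (cl in x$cells) {
    sub <- x$records[x$records$cell_id == cl, cols, drop = FALSE]
    write.table(sub, file.path(dir, paste0(cl, ".junctions.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(data.frame(gene_id = rownames(x$expr), x$expr, check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$truth$fusions)) {
    write.table(x$truth$fusions, file.path(dir, "truth_fusions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$truth$chimeras)) {
    write.table(x$truth$chimeras, file.path(dir, "truth_chimeras.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$library)) {
    write.table(as.data.frame(x$library), file.path(dir, "chimera_library.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$seqs),
                              file.path(dir, "transcripts.fa"))
  if (fastq) {
    for (j in seq_along(x$cells)) {
      cl <- x$cells[j]
      nb <- x$truth$accounting$background[j]
      bg <- sample_background_reads(x, nb, seed = x$config$seed + 100L + j)
      jr <- x$records$read_seq[x$records$cell_id == cl]
      reads <- c(bg, jr[!is.na(jr)])
      names(reads) <- sprintf("%s_read%07d", cl, seq_along(reads))
      con <- gzfile(file.path(dir, paste0(cl, ".fastq.gz")), "w")
      writeLines(paste0("@", names(reads), "\n", reads, "\n+\n",
                        strrep("I", nchar(reads))), con)
      close(con)
    }
  }
  invisible(dir)
}
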