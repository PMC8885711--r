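## Evidence extraction: read per-cell chimeric alignment records, keep
## uniquely-mapped inter-gene reads in exonic regions, cluster breakpoints
## into fusion candidates, and tally per-cell support.

.junction_cols <- c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b",
                    "strand_b", "jtype", "read_name", "cigar_a", "cigar_b")

#' Read chimeric-junction files (STAR-style tab-separated dialect)
#'
#' One file per cell (cell identity from `cell_ids` or file names), columns:
#' chromA, posA, strandA, chromB, posB, strandB, junction-type, read-name,
#' cigarA, cigarB. Junction type >= 0 denotes a split-mapped read (the read
#' itself spans the junction); -1 denotes a discordant mate pair. Extra
#' columns `mapq_a`, `mapq_b`, `read_seq` and `junction_offset` are kept
#' when present.
#'
#' @param files character vector of file paths.
#' @param cell_ids cell identifiers, one per file (default: file base names).
#' @return data.frame of raw chimeric records with a `cell_id` column.
#' @export
read_chimeric_junctions <- function(files, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- sub("\\.[^.]*$", "", basename(files))
  stopifnot(length(files) == length(cell_ids))
  recs <- lapply(seq_along(files), function(i) {
    df <- read.delim(files[i], header = FALSE, stringsAsFactors = FALSE)
    extra <- c("mapq_a", "mapq_b", "read_seq", "junction_offset")
    names(df) <- c(.junction_cols, extra)[seq_len(ncol(df))]
    df$cell_id <- cell_ids[i]
    df
  })
  cols <- Reduce(union, lapply(recs, names))
  recs <- lapply(recs, function(d) { d[setdiff(cols, names(d))] <- NA; d[cols] })
  do.call(rbind, recs)
}

#' Read chimeric records from SAM/BAM alignments
#'
#' Extracts split-mapped chimeric reads from alignments carrying an `SA`
#' (supplementary alignment) tag and discordant pairs whose mates map to
#' different chromosomes or far apart, via [Rsamtools::scanBam()]. SAM text
#' files are converted with [Rsamtools::asBam()] first. Each primary
#' record with an SA tag becomes one split record whose side A is the
#' primary alignment (breakpoint at its 3' clip) and side B the first SA
#' entry; the aligned read sequence and junction offset are retained.
#'
#' @param files SAM or BAM files, one per cell.
#' @param cell_ids cell identifiers (default: file base names).
#' @param isize_limit minimum mate separation (same chromosome) for a pair
#'   to be called discordant.
#' @return data.frame in the same layout as [read_chimeric_junctions()].
#' @export
read_chimeric_sam <- function(files, cell_ids = NULL, isize_limit = 1e5) {
  if (is.null(cell_ids)) cell_ids <- sub("\\.(sam|bam)$", "", basename(files))
  stopifnot(length(files) == length(cell_ids))
  out <- lapply(seq_along(files), function(i) {
    f <- files[i]
    if (grepl("\\.sam$", f, ignore.case = TRUE)) {
      f <- Rsamtools::asBam(f, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    }
    prm <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq",
               "mapq", "mrnm", "mpos", "isize"),
      tag = "SA")
    b <- Rsamtools::scanBam(f, param = prm)[[1]]
    n <- length(b$qname)
    if (n == 0L) return(NULL)
    sup <- bitwAnd(b$flag, 2048L) > 0L
    sa <- b$tag$SA
    res <- list()
    take_split <- which(!sup & !is.na(sa))
    if (length(take_split)) {
      sa1 <- t(vapply(strsplit(sub(";.*$", "", sa[take_split]), ","),
                      function(x) x[1:5], character(5)))
      m <- .cigar_matched(b$cigar[take_split])
      res$split <- data.frame(
        chrom_a = as.character(b$rname[take_split]),
        pos_a = b$pos[take_split] + m$ref_len - 1L,
        strand_a = as.character(b$strand[take_split]),
        chrom_b = sa1[, 1],
        pos_b = as.integer(sa1[, 2]),
        strand_b = sa1[, 3],
        jtype = 0L,
        read_name = b$qname[take_split],
        cigar_a = b$cigar[take_split],
        cigar_b = sa1[, 4],
        mapq_a = b$mapq[take_split],
        mapq_b = as.integer(sa1[, 5]),
        read_seq = as.character(b$seq[take_split]),
        junction_offset = m$read_len,
        stringsAsFactors = FALSE
      )
    }
    disc <- which(!sup & is.na(sa) & !is.na(b$mrnm) & !is.na(b$mpos) &
                    bitwAnd(b$flag, 64L) > 0L &
                    (as.character(b$rname) != as.character(b$mrnm) |
                       abs(ifelse(is.na(b$isize), Inf, b$isize)) > isize_limit))
    if (length(disc)) {
      res$disc <- data.frame(
        chrom_a = as.character(b$rname[disc]),
        pos_a = b$pos[disc],
        strand_a = as.character(b$strand[disc]),
        chrom_b = as.character(b$mrnm[disc]),
        pos_b = b$mpos[disc],
        strand_b = as.character(b$strand[disc]),  # mate strand unknown from this record
        jtype = -1L,
        read_name = b$qname[disc],
        cigar_a = b$cigar[disc],
        cigar_b = "*",
        mapq_a = b$mapq[disc],
        mapq_b = NA_integer_,
        read_seq = NA_character_,
        junction_offset = 0L,
        stringsAsFactors = FALSE
      )
    }
    if (!length(res)) return(NULL)
    df <- do.call(rbind, res)
    df$cell_id <- cell_ids[i]
    df
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# reference and read lengths consumed by the aligned part of a CIGAR
.cigar_matched <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  ref_len <- vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]", "", o)); t <- sub("\\d+", "", o)
    sum(n[t %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
  read_len <- vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]", "", o)); t <- sub("\\d+", "", o)
    sum(n[t %in% c("M", "I", "=", "X")])
  }, numeric(1))
  list(ref_len = as.integer(ref_len), read_len = as.integer(read_len))
}

#' Identify chimeric reads between distinct genes
#'
#' Keeps records whose two sides fall in exonic regions of two distinct
#' annotated genes and that satisfy the unique-mapping contract: when a
#' `mappability` track is supplied both positions must lie in it; otherwise,
#' when mapping qualities are present, both must reach `min_mapq`. A side
#' overlapping several genes is assigned to all of them and a record is
#' emitted per gene-pair assignment. Malformed records and records on
#' unknown chromosomes are skipped with a warning; skip counts are attached
#' as the `"dropped"` attribute.
#'
#' @param records raw record data.frame from [read_chimeric_junctions()] or
#'   [read_chimeric_sam()].
#' @param annotation a [gene_annotation()].
#' @param mappability optional [GenomicRanges::GRanges] of uniquely
#'   mappable positions.
#' @param min_mapq mapping-quality threshold used when no mappability track
#'   is given (50 by default, i.e. STAR-style "unique").
#' @return data.frame of class `chimeric_reads`: one row per retained read
#'   and gene-pair assignment, with columns `cell_id`, `gene_a`, `chrom_a`,
#'   `pos_a`, `strand_a`, `gene_b`, `chrom_b`, `pos_b`, `strand_b`, `kind`
#'   ("split"/"discordant"), `junction_offset`, `read_seq`, `read_name`.
#' @export
parse_chimeric_alignments <- function(records, annotation, mappability = NULL,
                                      min_mapq = 50) {
  stopifnot(is(annotation, "gene_annotation"))
  records <- as.data.frame(records)
  n0 <- nrow(records)
  dropped <- c(malformed = 0L, unknown_chrom = 0L, not_unique = 0L,
               not_exonic = 0L, same_gene = 0L)

  ok <- !is.na(records$pos_a) & !is.na(records$pos_b) &
    records$pos_a >= 1 & records$pos_b >= 1 &
    records$strand_a %in% c("+", "-") & records$strand_b %in% c("+", "-")
  dropped["malformed"] <- sum(!ok)
  if (any(!ok)) warning(sprintf("skipped %d malformed record(s)", sum(!ok)))
  records <- records[ok, , drop = FALSE]

  chroms <- unique(annotation$genes$chrom)
  ok <- records$chrom_a %in% chroms & records$chrom_b %in% chroms
  dropped["unknown_chrom"] <- sum(!ok)
  if (any(!ok)) warning(sprintf("skipped %d record(s) on unknown chromosomes", sum(!ok)))
  records <- records[ok, , drop = FALSE]

  if (!is.null(mappability)) {
    qa <- GenomicRanges::GRanges(records$chrom_a, IRanges::IRanges(records$pos_a, records$pos_a))
    qb <- GenomicRanges::GRanges(records$chrom_b, IRanges::IRanges(records$pos_b, records$pos_b))
    ok <- GenomicRanges::countOverlaps(qa, mappability) > 0L &
      GenomicRanges::countOverlaps(qb, mappability) > 0L
  } else if (all(c("mapq_a", "mapq_b") %in% names(records))) {
    ok <- !is.na(records$mapq_a) & !is.na(records$mapq_b) &
      records$mapq_a >= min_mapq & records$mapq_b >= min_mapq
  } else {
    ok <- rep(TRUE, nrow(records))
  }
  dropped["not_unique"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  ga <- assign_genes(annotation, records$chrom_a, records$pos_a)
  gb <- assign_genes(annotation, records$chrom_b, records$pos_b)
  na_ <- lengths(ga); nb_ <- lengths(gb)
  dropped["not_exonic"] <- sum(na_ == 0L | nb_ == 0L)
  keep <- which(na_ > 0L & nb_ > 0L)

  if (length(keep)) {
    reps <- na_[keep] * nb_[keep]
    idx <- rep(keep, reps)
    gene_a <- unlist(lapply(keep, function(i) rep(ga[[i]], each = length(gb[[i]]))))
    gene_b <- unlist(lapply(keep, function(i) rep(gb[[i]], times = length(ga[[i]]))))
  } else {
    idx <- integer(0); gene_a <- gene_b <- character(0)
  }
  out <- data.frame(
    cell_id = records$cell_id[idx],
    gene_a = gene_a,
    chrom_a = records$chrom_a[idx], pos_a = as.integer(records$pos_a[idx]),
    strand_a = records$strand_a[idx],
    gene_b = gene_b,
    chrom_b = records$chrom_b[idx], pos_b = as.integer(records$pos_b[idx]),
    strand_b = records$strand_b[idx],
    kind = ifelse(!is.na(records$jtype[idx]) & records$jtype[idx] >= 0, "split", "discordant"),
    junction_offset = if ("junction_offset" %in% names(records))
      as.integer(ifelse(is.na(records$junction_offset[idx]), 0L, records$junction_offset[idx]))
    else 0L,
    read_seq = if ("read_seq" %in% names(records)) as.character(records$read_seq[idx])
    else NA_character_,
    read_name = if ("read_name" %in% names(records)) as.character(records$read_name[idx])
    else NA_character_,
    stringsAsFactors = FALSE
  )
  same <- out$gene_a == out$gene_b
  dropped["same_gene"] <- length(unique(idx[same]))
  out <- out[!same, , drop = FALSE]
  out$junction_offset[out$kind == "discordant"] <- 0L
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "n_input") <- n0
  class(out) <- c("chimeric_reads", "data.frame")
  out
}

# 1-D single-linkage clustering: sorted positions are split where the gap
# between neighbours exceeds `window`; returns cluster index per element
.linkage_1d <- function(pos, window) {
  o <- order(pos)
  g <- cumsum(c(1L, diff(pos[o]) > window))
  cl <- integer(length(pos))
  cl[o] <- g
  cl
}

# deterministic median for integer breakpoints: lower of the two central
# values when the member count is even
.median_lower <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Cluster chimeric reads into fusion candidates
#'
#' Split-mapped reads are clustered per (gene pair, orientation pair) by
#' single-linkage on each breakpoint side: two reads join when their
#' breakpoints are within `window` bp on side A and, within the resulting
#' groups, within `window` bp on side B. The consensus breakpoint of a
#' candidate is the median of its members' breakpoints (lower-middle value
#' for even counts). Discordant reads attach to the candidate of the same
#' gene pair whose consensus breakpoints are within `frag_size` bp on both
#' sides (nearest if several); unattached discordant reads form
#' discordant-only candidates clustered with `frag_size` linkage.
#'
#' @param reads a `chimeric_reads` data.frame from
#'   [parse_chimeric_alignments()].
#' @param window split-read clustering window (bp).
#' @param frag_size discordant attachment bound (bp).
#' @return object of class `fusion_candidates`: list with `candidates`
#'   (data.frame: id, gene5, gene3, chrom5, pos5, strand5, chrom3, pos3,
#'   strand3, n_split, n_discordant, n_cells), `support` (long data.frame:
#'   candidate_id, cell_id, split, discordant), `cells` (sorted cell ids),
#'   and `membership` (candidate id per input read row, NA for unassigned).
#' @export
cluster_breakpoints <- function(reads, window = 20L, frag_size = 500L) {
  stopifnot(window >= 0)
  empty <- function() {
    structure(list(
      candidates = data.frame(id = character(0), gene5 = character(0), gene3 = character(0),
                              chrom5 = character(0), pos5 = integer(0), strand5 = character(0),
                              chrom3 = character(0), pos3 = integer(0), strand3 = character(0),
                              n_split = integer(0), n_discordant = integer(0), n_cells = integer(0),
                              stringsAsFactors = FALSE),
      support = data.frame(candidate_id = character(0), cell_id = character(0),
                           split = integer(0), discordant = integer(0), stringsAsFactors = FALSE),
      cells = character(0), membership = character(0)),
      class = "fusion_candidates")
  }
  if (is.null(reads) || nrow(reads) == 0L) return(empty())
  reads <- as.data.frame(reads)
  membership <- rep(NA_character_, nrow(reads))
  gkey <- paste(reads$gene_a, reads$gene_b, reads$strand_a, reads$strand_b, sep = "\r")

  clus <- data.frame()
  is_split <- reads$kind == "split"
  for (k in unique(gkey[is_split])) {
    ridx <- which(gkey == k & is_split)
    ca <- .linkage_1d(reads$pos_a[ridx], window)
    lab <- ca * 0L
    for (a in unique(ca)) {
      sub <- which(ca == a)
      cb <- .linkage_1d(reads$pos_b[ridx[sub]], window)
      lab[sub] <- a * 1e6L + cb
    }
    for (cl in unique(lab)) {
      m <- ridx[lab == cl]
      clus <- rbind(clus, data.frame(
        gene5 = reads$gene_a[m[1]], gene3 = reads$gene_b[m[1]],
        chrom5 = reads$chrom_a[m[1]], pos5 = .median_lower(reads$pos_a[m]),
        strand5 = reads$strand_a[m[1]],
        chrom3 = reads$chrom_b[m[1]], pos3 = .median_lower(reads$pos_b[m]),
        strand3 = reads$strand_b[m[1]],
        members = I(list(m)), stringsAsFactors = FALSE))
    }
  }

  # discordant attachment: nearest split cluster of the same gene pair
  # within frag_size on both sides
  disc_members <- rep(list(integer(0)), nrow(clus))
  disc_left <- which(!is_split)
  if (length(disc_left) && nrow(clus)) {
    pair_of <- paste(clus$gene5, clus$gene3, sep = "\r")
    for (i in disc_left) {
      cand <- which(pair_of == paste(reads$gene_a[i], reads$gene_b[i], sep = "\r") &
                      abs(clus$pos5 - reads$pos_a[i]) <= frag_size &
                      abs(clus$pos3 - reads$pos_b[i]) <= frag_size)
      if (length(cand)) {
        d <- abs(clus$pos5[cand] - reads$pos_a[i]) + abs(clus$pos3[cand] - reads$pos_b[i])
        j <- cand[which.min(d)]
        disc_members[[j]] <- c(disc_members[[j]], i)
        disc_left <- setdiff(disc_left, i)
      }
    }
  }
  # discordant-only clusters from whatever remains
  if (length(disc_left)) {
    for (k in unique(gkey[disc_left])) {
      ridx <- disc_left[gkey[disc_left] == k]
      ca <- .linkage_1d(reads$pos_a[ridx], frag_size)
      lab <- ca * 0L
      for (a in unique(ca)) {
        sub <- which(ca == a)
        cb <- .linkage_1d(reads$pos_b[ridx[sub]], frag_size)
        lab[sub] <- a * 1e6L + cb
      }
      for (cl in unique(lab)) {
        m <- ridx[lab == cl]
        clus <- rbind(clus, data.frame(
          gene5 = reads$gene_a[m[1]], gene3 = reads$gene_b[m[1]],
          chrom5 = reads$chrom_a[m[1]], pos5 = .median_lower(reads$pos_a[m]),
          strand5 = reads$strand_a[m[1]],
          chrom3 = reads$chrom_b[m[1]], pos3 = .median_lower(reads$pos_b[m]),
          strand3 = reads$strand_b[m[1]],
          members = I(list(integer(0))), stringsAsFactors = FALSE))
        disc_members[[nrow(clus)]] <- m
      }
    }
  }
  if (!nrow(clus)) return(empty())

  # merge clusters that coincide on (gene5, gene3, consensus breakpoints)
  mkey <- paste(clus$gene5, clus$gene3, clus$chrom5, clus$pos5, clus$chrom3, clus$pos3, sep = "\r")
  if (anyDuplicated(mkey)) {
    keep <- !duplicated(mkey)
    for (d in which(duplicated(mkey))) {
      j <- match(mkey[d], mkey)
      clus$members[[j]] <- union(clus$members[[j]], clus$members[[d]])
      disc_members[[j]] <- union(disc_members[[j]], disc_members[[d]])
    }
    clus <- clus[keep, , drop = FALSE]
    disc_members <- disc_members[keep]
  }

  # deterministic ordering and ids
  o <- order(clus$gene5, clus$gene3, clus$chrom5, clus$pos5, clus$chrom3, clus$pos3)
  clus <- clus[o, , drop = FALSE]
  disc_members <- disc_members[o]
  ids <- sprintf("FC%05d", seq_len(nrow(clus)))

  cells <- sort(unique(reads$cell_id))
  sup <- vector("list", nrow(clus))
  for (i in seq_len(nrow(clus))) {
    ms <- clus$members[[i]]; md <- disc_members[[i]]
    membership[ms] <- ids[i]
    membership[md] <- ids[i]
    tb_s <- table(factor(reads$cell_id[ms], levels = cells))
    tb_d <- table(factor(reads$cell_id[md], levels = cells))
    nz <- which(tb_s + tb_d > 0)
    sup[[i]] <- data.frame(candidate_id = ids[i], cell_id = cells[nz],
                           split = as.integer(tb_s[nz]), discordant = as.integer(tb_d[nz]),
                           stringsAsFactors = FALSE)
  }
  support <- do.call(rbind, sup)
  rownames(support) <- NULL
  cand <- data.frame(
    id = ids, gene5 = clus$gene5, gene3 = clus$gene3,
    chrom5 = clus$chrom5, pos5 = as.integer(clus$pos5), strand5 = clus$strand5,
    chrom3 = clus$chrom3, pos3 = as.integer(clus$pos3), strand3 = clus$strand3,
    n_split = vapply(clus$members, length, integer(1)),
    n_discordant = lengths(disc_members),
    stringsAsFactors = FALSE
  )
  ncell <- tapply(rep(1L, nrow(support)), support$candidate_id, sum)
  cand$n_cells <- as.integer(ncell[cand$id])
  rownames(cand) <- NULL
  structure(list(candidates = cand, support = support, cells = cells,
                 membership = membership),
            class = "fusion_candidates")
}

#' @export
print.fusion_candidates <- function(x, ...) {
  cat(sprintf("fusion_candidates: %d candidates across %d cells (%d split, %d discordant reads)\n",
              nrow(x$candidates), length(x$cells),
              sum(x$candidates$n_split), sum(x$candidates$n_discordant)))
  invisible(x)
}

#' GC content near candidate junctions
#'
#' Fraction of G/C bases in the exonic sequence flanking the junction:
#' `window_bp / 2` bases ending at the 5'-side breakpoint plus
#' `window_bp / 2` bases starting at the 3'-side breakpoint (200 bp in
#' total by default). Candidates whose breakpoints cannot be resolved to
#' exonic sequence get `NA` (handled downstream by median imputation).
#'
#' @param candidates a `fusion_candidates` object.
#' @param annotation a [gene_annotation()].
#' @param seqs transcript sequences named by gene id.
#' @param window_bp total window width (split half-and-half).
#' @return numeric vector in \[0, 1\] (or `NA`), one per candidate.
#' @export
compute_gc_content <- function(candidates, annotation, seqs, window_bp = 200L) {
  half <- as.integer(window_bp / 2)
  w <- junction_window(candidates, annotation, seqs, flank = half)
  gc <- (nchar(gsub("[^GCgc]", "", w))) / nchar(w)
  ifelse(is.na(w), NA_real_, gc)
}

#' Build the candidate-by-cell support matrix
#'
#' Sparse integer matrix of per-cell supporting read counts
#' (\eqn{y_{ij}}), candidates in rows and cells in columns; absent
#' combinations are zero.
#'
#' @param candidates a `fusion_candidates` object.
#' @param cells cell ordering (default: the object's cells).
#' @param type `"split"` (default) or `"discordant"` counts.
#' @return a [Matrix::sparseMatrix()] (dgCMatrix) with candidate ids as row
#'   names and cell ids as column names.
#' @export
build_support_matrix <- function(candidates, cells = candidates$cells,
                                 type = c("split", "discordant")) {
  type <- match.arg(type)
  ids <- candidates$candidates$id
  if (anyDuplicated(ids)) stop("duplicate candidate ids")
  sup <- candidates$support
  sup <- sup[sup$cell_id %in% cells, , drop = FALSE]
  Matrix::sparseMatrix(
    i = match(sup$candidate_id, ids),
    j = match(sup$cell_id, cells),
    x = sup[[type]],
    dims = c(length(ids), length(cells)),
    dimnames = list(ids, cells)
  )
}

#' Write candidate tables to disk
#'
#' Writes the candidate summary as a TSV and the per-cell split-read
#' support in long TSV form (candidate_id, cell_id, split, discordant).
#'
#' @param candidates a `fusion_candidates` object.
#' @param file candidate table path; the support table is written next to
#'   it with suffix `.support.tsv`.
#' @return `file`, invisibly.
#' @export
write_candidates <- function(candidates, file) {
  write.table(candidates$candidates, file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(candidates$support, paste0(file, ".support.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
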