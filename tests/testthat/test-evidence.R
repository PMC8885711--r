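# Evidence extraction: record parsing, gene assignment, breakpoint
# clustering, GC windows and the support matrix.

test_that("parsing keeps inter-gene exonic records and drops the rest", {
  ann <- toy_annotation(n = 6)
  recs <- rbind(
    toy_record("c1", 1, 2),                       # split between two genes
    toy_record("c1", 3, 3),                       # both halves in one gene
    toy_record("c1", 1, 4, jtype = -1L))          # discordant pair
  out <- parse_chimeric_alignments(recs, ann)
  expect_s3_class(out, "chimeric_reads")
  expect_identical(nrow(out), 2L)
  expect_identical(out$kind, c("split", "discordant"))
  expect_identical(out$gene_a, c("T01", "T01"))
  expect_identical(out$gene_b, c("T02", "T04"))
  expect_identical(attr(out, "dropped")[["same_gene"]], 1L)
})

test_that("parsing drops malformed records, unknown chromosomes, and non-unique mappings", {
  ann <- toy_annotation(n = 4)
  bad_pos <- toy_record("c1", 1, 2); bad_pos$pos_a <- NA
  bad_chr <- toy_record("c1", 1, 2); bad_chr$chrom_b <- "chrZ"
  low_mapq <- toy_record("c1", 1, 2, mapq = 10L)
  intron <- toy_record("c1", 1, 2, pos_a = toy_exonic_pos(1, offset = 700L))
  recs <- rbind(toy_record("c1", 1, 2), bad_pos, bad_chr, low_mapq, intron)
  expect_warning(expect_warning(out <- parse_chimeric_alignments(recs, ann),
                                "malformed"), "unknown chromosome")
  expect_identical(nrow(out), 1L)
  d <- attr(out, "dropped")
  expect_identical(d[["malformed"]], 1L)
  expect_identical(d[["unknown_chrom"]], 1L)
  expect_identical(d[["not_unique"]], 1L)
  expect_identical(d[["not_exonic"]], 1L)
  # an explicit mappability track overrides the MAPQ contract
  mp <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 2000))
  out2 <- parse_chimeric_alignments(rbind(toy_record("c1", 1, 2, mapq = 10L)),
                                    ann, mappability = mp)
  expect_identical(nrow(out2), 0L)  # side B outside the track
  mp_all <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 1e6))
  out3 <- parse_chimeric_alignments(rbind(toy_record("c1", 1, 2, mapq = 10L)),
                                    ann, mappability = mp_all)
  expect_identical(nrow(out3), 1L)
})

test_that("a generated stream yields exactly its inter-gene records", {
  ann <- toy_annotation(n = 10)
  set.seed(3)
  inter <- do.call(rbind, lapply(1:60, function(i) {
    gg <- sample(10, 2)
    toy_record(sprintf("c%d", i %% 4), gg[1], gg[2])
  }))
  intra <- do.call(rbind, lapply(1:40, function(i) {
    g <- sample(10, 1)
    toy_record(sprintf("c%d", i %% 4), g, g,
               pos_a = toy_exonic_pos(g, 10L), pos_b = toy_exonic_pos(g, 400L))
  }))
  out <- parse_chimeric_alignments(rbind(inter, intra), ann)
  expect_identical(nrow(out), 60L)
})

test_that("positions overlapping several genes are assigned to all of them", {
  genes <- data.frame(
    gene_id = c("GA", "GB", "GC"), symbol = c("GA", "GB", "GC"),
    chrom = "chrT", start = c(1L, 501L, 5001L), end = c(1000L, 1500L, 6000L),
    strand = "+", biotype = "protein_coding", approved = TRUE)
  exons <- genes[, c("gene_id", "chrom", "start", "end")]
  ann <- gene_annotation(genes, exons)
  # side A at 700 overlaps GA and GB; side B in GC
  rec <- toy_record("c1", 1, 1, pos_a = 700L, pos_b = 5500L)
  out <- parse_chimeric_alignments(rec, ann)
  expect_identical(nrow(out), 2L)
  expect_setequal(out$gene_a, c("GA", "GB"))
  expect_identical(unique(out$gene_b), "GC")
})

test_that("clustering windows, medians, and boundaries behave as documented", {
  ann <- toy_annotation(n = 4)
  mk <- function(pa) toy_record("c1", 1, 2, pos_a = toy_exonic_pos(1) + pa)
  reads <- parse_chimeric_alignments(do.call(rbind, lapply(c(0, 15), mk)), ann)
  expect_identical(nrow(cluster_breakpoints(reads)$candidates), 1L)   # 15 <= 20
  reads <- parse_chimeric_alignments(do.call(rbind, lapply(c(0, 21), mk)), ann)
  expect_identical(nrow(cluster_breakpoints(reads)$candidates), 2L)   # 21 > 20
  reads <- parse_chimeric_alignments(do.call(rbind, lapply(c(0, 10, 20), mk)), ann)
  cl <- cluster_breakpoints(reads)
  expect_identical(cl$candidates$pos5, toy_exonic_pos(1) + 10L)       # median
  # even member count: lower of the two central values
  reads <- parse_chimeric_alignments(do.call(rbind, lapply(c(0, 6, 12, 18), mk)), ann)
  expect_identical(cluster_breakpoints(reads)$candidates$pos5, toy_exonic_pos(1) + 6L)
  expect_identical(nrow(cluster_breakpoints(reads[0, ])$candidates), 0L)
})

test_that("clustering is order-invariant and assigns each read once", {
  ann <- toy_annotation(n = 8)
  set.seed(14)
  recs <- do.call(rbind, lapply(1:120, function(i) {
    gg <- sample(8, 2)
    # jittered breakpoints around well-separated cluster centers
    toy_record(sprintf("c%d", i %% 5), gg[1], gg[2],
               pos_a = toy_exonic_pos(gg[1], offset = sample(c(50L, 400L), 1)) + sample(0:8, 1),
               pos_b = toy_exonic_pos(gg[2], offset = sample(c(60L, 420L), 1)) + sample(0:8, 1))
  }))
  reads <- parse_chimeric_alignments(recs, ann)
  cl <- cluster_breakpoints(reads)
  # every retained read contributes to exactly one candidate
  expect_false(anyNA(cl$membership))
  expect_identical(sum(cl$candidates$n_split), nrow(reads))
  # shuffled input gives identical candidates
  o <- sample(nrow(reads))
  cl2 <- cluster_breakpoints(reads[o, ])
  expect_identical(cl$candidates, cl2$candidates)
  expect_identical(cl$support, cl2$support)
  # members lie within the window of the consensus on each side
  for (i in seq_len(nrow(cl$candidates))) {
    m <- which(cl$membership == cl$candidates$id[i])
    expect_true(all(abs(reads$pos_a[m] - cl$candidates$pos5[i]) <= 20))
    expect_true(all(abs(reads$pos_b[m] - cl$candidates$pos3[i]) <= 20))
  }
})

test_that("discordant reads attach within the fragment bound or form their own candidates", {
  ann <- toy_annotation(n = 6)
  split1 <- toy_record("c1", 1, 2)
  near <- toy_record("c2", 1, 2, jtype = -1L,
                     pos_a = toy_exonic_pos(1) + 300L, pos_b = toy_exonic_pos(2) + 200L)
  far <- toy_record("c2", 3, 4, jtype = -1L)
  reads <- parse_chimeric_alignments(rbind(split1, near, far), ann)
  cl <- cluster_breakpoints(reads)
  expect_identical(nrow(cl$candidates), 2L)
  att <- cl$candidates[cl$candidates$gene5 == "T01", ]
  expect_identical(att$n_split, 1L)
  expect_identical(att$n_discordant, 1L)
  solo <- cl$candidates[cl$candidates$gene5 == "T03", ]
  expect_identical(solo$n_split, 0L)
  expect_identical(solo$n_discordant, 1L)
})

test_that("GC content counts G/C over the two exonic flanks", {
  genes <- data.frame(
    gene_id = c("GG", "CC", "MX"), symbol = c("GG", "CC", "MX"), chrom = "chrQ",
    start = c(1L, 1001L, 2001L), end = c(1000L, 2000L, 3000L),
    strand = "+", biotype = "protein_coding", approved = TRUE)
  ann <- gene_annotation(genes, genes[, c("gene_id", "chrom", "start", "end")])
  seqs <- c(GG = strrep("G", 1000), CC = strrep("C", 1000),
            MX = strrep("ACGT", 250))
  cand <- toy_candidates("GG", "CC", list(c(c1 = 1, c2 = 1)),
                         pos5 = 500L, pos3 = 1500L)
  cand$candidates$chrom5 <- cand$candidates$chrom3 <- "chrQ"
  expect_identical(compute_gc_content(cand, ann, seqs), 1)
  cand2 <- toy_candidates("MX", "MX", list(c(c1 = 1, c2 = 1)),
                          pos5 = 2500L, pos3 = 2600L)
  cand2$candidates$gene3 <- "MX"
  cand2$candidates$chrom5 <- cand2$candidates$chrom3 <- "chrQ"
  expect_identical(compute_gc_content(cand2, ann, seqs), 0.5)
  # independent character count on a random junction
  tx <- toy_transcriptome()
  cand3 <- toy_candidates("G010", "G020", list(c(c1 = 1, c2 = 1)),
                          pos5 = tx$annotation$genes$start[10] + 400L,
                          pos3 = tx$annotation$genes$start[20] + 300L)
  cand3$candidates$chrom5 <- cand3$candidates$chrom3 <- "chrS"
  got <- compute_gc_content(cand3, tx$annotation, tx$seqs)
  up <- substr(tx$seqs["G010"], 302L, 401L)
  down <- substr(tx$seqs["G020"], 301L, 400L)
  expected <- sum(strsplit(paste0(up, down), "")[[1]] %in% c("G", "C")) / 200
  expect_equal(got, expected, tolerance = 1e-12)
  # breakpoint too close to the transcript end: covariate flagged missing
  cand4 <- toy_candidates("G010", "G020", list(c(c1 = 1, c2 = 1)),
                          pos5 = tx$annotation$genes$start[10] + 10L,
                          pos3 = tx$annotation$genes$start[20] + 300L)
  cand4$candidates$chrom5 <- cand4$candidates$chrom3 <- "chrS"
  expect_true(is.na(compute_gc_content(cand4, tx$annotation, tx$seqs)))
})

test_that("support matrix reproduces per-cell tallies", {
  cand <- toy_candidates("T01", "T02",
                         list(c(cellA = 2, cellB = 1, cellD = 4)))
  m <- build_support_matrix(cand, cells = c("cellA", "cellB", "cellC", "cellD", "cellE"))
  expect_identical(as.vector(m), c(2, 1, 0, 4, 0))
  empty <- toy_candidates(character(0), character(0), list())
  m0 <- build_support_matrix(empty, cells = letters[1:4])
  expect_identical(dim(m0), c(0L, 4L))
  # random fixture: row sums equal per-candidate totals recounted from reads
  ann <- toy_annotation(n = 10)
  set.seed(4)
  recs <- do.call(rbind, lapply(1:300, function(i) {
    gg <- sample(10, 2)
    toy_record(sprintf("c%02d", sample(12, 1)), gg[1], gg[2])
  }))
  reads <- parse_chimeric_alignments(recs, ann)
  cl <- cluster_breakpoints(reads)
  m <- build_support_matrix(cl)
  recount <- table(cl$membership)
  expect_equal(unname(Matrix::rowSums(m)[names(recount)]), as.numeric(recount))
  expect_true(all(m >= 0))
  # duplicate candidate ids are rejected
  dup <- cl; dup$candidates <- rbind(dup$candidates, dup$candidates[1, ])
  expect_error(build_support_matrix(dup), "duplicate")
})

test_that("SAM split and discordant records are extracted through Rsamtools", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:100000",
    "@SQ\tSN:chrU\tLN:100000",
    # split read: primary on chrT with SA pointing at chrU
    paste("r1", 0, "chrT", 101, 60, "50M50S", "*", 0, 0,
          paste(rep("ACGT", 25), collapse = ""), "*",
          "SA:Z:chrU,201,+,50S50M,60,0;", sep = "\t"),
    # discordant pair: mates on different chromosomes (first mate flag 65)
    paste("r2", 65, "chrT", 301, 60, "100M", "chrU", 501, 0,
          paste(rep("ACGT", 25), collapse = ""), "*", sep = "\t")
  ), sam)
  out <- read_chimeric_sam(sam, cell_ids = "cellX")
  expect_identical(nrow(out), 2L)
  sp <- out[out$jtype == 0L, ]
  expect_identical(sp$chrom_a, "chrT")
  expect_identical(sp$pos_a, 150L)          # 101 + 50M - 1
  expect_identical(sp$chrom_b, "chrU")
  expect_identical(sp$junction_offset, 50L)
  dc <- out[out$jtype == -1L, ]
  expect_identical(dc$chrom_b, "chrU")
  expect_identical(unique(out$cell_id), "cellX")
})

test_that("junction TSV files round-trip through the per-cell reader", {
  ds <- simulate_dataset(sim_config(n_cells = 3, reads_per_cell = 3000,
                                    library_size = 1000, entries_per_cell = 50,
                                    seed = 9),
                         transcriptome = toy_transcriptome(),
                         library = toy_library()[1:1000, ])
  dir <- tempfile()
  write_sim_dataset(ds, dir)
  files <- file.path(dir, paste0(ds$cells, ".junctions.tsv"))
  recs <- read_chimeric_junctions(files, cell_ids = ds$cells)
  expect_identical(nrow(recs), nrow(ds$records))
  expect_setequal(unique(recs$cell_id), ds$cells)
  reads <- parse_chimeric_alignments(recs, ds$annotation)
  reads0 <- parse_chimeric_alignments(ds$records, ds$annotation)
  expect_identical(nrow(reads), nrow(reads0))
})
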