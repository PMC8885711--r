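# Shared fixtures, all generated in code. Heavier objects (transcriptome,
# chimera library) are built once per session and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small synthetic transcriptome shared by sequence-level tests
toy_transcriptome <- function() {
  fixture("txome", function() synthetic_transcriptome(n_genes = 60, seed = 101))
}

toy_library <- function() {
  fixture("library", function()
    build_chimera_library(toy_transcriptome()$seqs, size = 5000, seed = 202))
}

# hand-laid multi-exon annotation with mixed biotypes for filter tests:
# per gene, two 500 bp exons separated by a 500 bp intron
toy_annotation <- function(n = 12, biotypes = NULL, approved = NULL) {
  ids <- sprintf("T%02d", seq_len(n))
  if (is.null(biotypes)) biotypes <- rep("protein_coding", n)
  if (is.null(approved)) approved <- rep(TRUE, n)
  start <- seq(1L, by = 2000L, length.out = n)
  genes <- data.frame(
    gene_id = ids, symbol = ids, chrom = "chrT",
    start = start, end = start + 1499L, strand = "+",
    biotype = rep_len(biotypes, n), approved = rep_len(approved, n),
    stringsAsFactors = FALSE
  )
  exons <- rbind(
    data.frame(gene_id = ids, chrom = "chrT", start = start, end = start + 499L),
    data.frame(gene_id = ids, chrom = "chrT", start = start + 1000L, end = start + 1499L)
  )
  gene_annotation(genes, exons)
}

# exonic genomic position inside gene `i` of toy_annotation (first exon)
toy_exonic_pos <- function(i, offset = 100L) {
  as.integer((i - 1L) * 2000L + 1L + offset)
}

# raw junction record between two toy_annotation genes
toy_record <- function(cell, g1, g2, pos_a = toy_exonic_pos(g1),
                       pos_b = toy_exonic_pos(g2), jtype = 0L,
                       strand_a = "+", strand_b = "+", mapq = 255L) {
  data.frame(cell_id = cell, chrom_a = "chrT", pos_a = pos_a, strand_a = strand_a,
             chrom_b = "chrT", pos_b = pos_b, strand_b = strand_b,
             jtype = jtype, read_name = paste0("r", pos_a, "_", pos_b),
             cigar_a = "50M", cigar_b = "50M", mapq_a = mapq, mapq_b = mapq,
             read_seq = NA_character_, junction_offset = 50L,
             stringsAsFactors = FALSE)
}

# fusion_candidates object built from explicit per-candidate support lists
toy_candidates <- function(genes5, genes3, split_cells, discordant_cells = NULL,
                           pos5 = NULL, pos3 = NULL) {
  n <- length(genes5)
  if (is.null(discordant_cells)) discordant_cells <- rep(list(numeric(0)), n)
  if (is.null(pos5)) pos5 <- rep(150L, n)
  if (is.null(pos3)) pos3 <- rep(250L, n)
  ids <- sprintf("FC%05d", seq_len(n))
  cells <- sort(unique(c(unlist(lapply(split_cells, names)),
                         unlist(lapply(discordant_cells, names)))))
  sup <- do.call(rbind, lapply(seq_len(n), function(i) {
    sc <- split_cells[[i]]; dc <- discordant_cells[[i]]
    all_c <- union(names(sc), names(dc))
    d <- data.frame(candidate_id = ids[i], cell_id = all_c,
                    split = as.integer(sc[all_c] %coerce0% all_c),
                    discordant = as.integer(dc[all_c] %coerce0% all_c),
                    stringsAsFactors = FALSE)
    d[d$split + d$discordant > 0, , drop = FALSE]
  }))
  if (is.null(sup)) {
    sup <- data.frame(candidate_id = character(0), cell_id = character(0),
                      split = integer(0), discordant = integer(0),
                      stringsAsFactors = FALSE)
  }
  cand <- data.frame(
    id = ids, gene5 = genes5, gene3 = genes3,
    chrom5 = rep("chrT", n), pos5 = as.integer(pos5), strand5 = rep("+", n),
    chrom3 = rep("chrT", n), pos3 = as.integer(pos3), strand3 = rep("+", n),
    n_split = vapply(split_cells, sum, numeric(1)),
    n_discordant = vapply(discordant_cells, function(d) sum(unlist(d), 0), numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- table(sup$candidate_id)
  cand$n_cells <- as.integer(tab[cand$id])
  cand$n_cells[is.na(cand$n_cells)] <- 0L
  structure(list(candidates = cand, support = sup, cells = cells,
                 membership = character(0)),
            class = "fusion_candidates")
}

`%coerce0%` <- function(x, nm) {
  out <- x[nm]
  out[is.na(out)] <- 0
  out
}

# cell_covariates object assembled directly from matrices (for model tests)
manual_covariates <- function(gc, e1, e2, scale = "raw") {
  structure(list(gc = gc, gc_missing = rep(FALSE, length(gc)),
                 e1 = e1, e2 = e2,
                 ebar1 = rowMeans(e1), ebar2 = rowMeans(e2),
                 candidate_ids = as.character(seq_along(gc)),
                 cells = as.character(seq_len(ncol(e1))), scale = scale),
            class = "cell_covariates")
}

# desk-scale artifact classifier shared by the end-to-end checks: trained
# once on a fusion-free dataset simulated from the given transcriptome and
# library (so the artifact class contains technical chimeras only)
acceptance_classifier <- function(tx, lib, seed = 77) {
  ds <- simulate_dataset(sim_config(n_cells = 60, reads_per_cell = 3e4,
                                    library_size = nrow(lib), seed = seed),
                         transcriptome = tx, library = lib)
  reads <- parse_chimeric_alignments(ds$records, ds$annotation)
  run_train(reads, ds$seqs,
            config = fusion_config(
              seed = seed,
              classifier = list(layers = c(8L, 16L), seq2one = 16L, fc = 32L,
                                epochs = 30L, batch = 250L, lr = 5e-3,
                                n_examples = 18000L)))
}

# rank-based AUC (Mann-Whitney form), independent of any model code
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# random DNA of given length
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
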