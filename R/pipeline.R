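## End-to-end orchestration: configuration, the detect pipeline with its
## filter funnel, and thin wrappers for simulation, classifier training and
## scoring. A single master seed determines every stochastic stage.

.config_defaults <- function() {
  list(
    window = 20L,            # split-read clustering window (bp)
    frag_size = 500L,        # discordant attachment bound (bp)
    min_mapq = 50L,          # unique-mapping threshold without a track
    min_cells = 2L,          # minimum supporting cells
    K = 5L,                  # spline basis size
    restarts = 3L,           # background-fit random restarts
    B = 1000L,               # resamples per candidate
    alpha = 0.05,            # target FDR
    hq_cell_fraction = 0.01, # high-quality subset: cell fraction
    hq_mean_reads = 1.25,    # high-quality subset: reads per supporting cell
    artifact_threshold = 0.75,
    max_partners = 5L,
    discordant_ratio = 10,
    enable_lncrna = TRUE,
    enable_symbol = TRUE,
    expr_scale = "log1p",
    gc_window = 200L,
    classifier = list(layers = c(32L, 64L, 128L), seq2one = 64L, fc = 64L,
                      epochs = 200L, batch = 500L, lr = 1e-3,
                      n_examples = 2000L),
    seed = 1L
  )
}

#' Detection-run configuration
#'
#' Builds the run configuration from the documented defaults, overriding
#' any named setting. Unknown keys are rejected. The `classifier` entry is
#' itself a list (architecture and training settings) merged key-wise.
#'
#' @param ... named overrides of the defaults: `window` (20), `frag_size`
#'   (500), `min_mapq` (50), `min_cells` (2), `K` (5), `restarts` (3),
#'   `B` (1000), `alpha` (0.05), `hq_cell_fraction` (0.01),
#'   `hq_mean_reads` (1.25), `artifact_threshold` (0.75), `max_partners`
#'   (5), `discordant_ratio` (10), `enable_lncrna`, `enable_symbol`,
#'   `expr_scale` ("log1p"), `gc_window` (200), `classifier` (list),
#'   `seed`.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(over$classifier)) {
    badc <- setdiff(names(over$classifier), names(cfg$classifier))
    if (length(badc)) stop("unknown classifier key(s): ", paste(badc, collapse = ", "))
    cfg$classifier[names(over$classifier)] <- over$classifier
    over$classifier <- NULL
  }
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$B >= 2, cfg$min_cells >= 1,
            cfg$window >= 0, cfg$artifact_threshold >= 0, cfg$artifact_threshold <= 1,
            cfg$max_partners >= 1, cfg$discordant_ratio > 0,
            cfg$hq_cell_fraction > 0, cfg$hq_cell_fraction < 1,
            cfg$expr_scale %in% c("log1p", "raw"))
  structure(cfg, class = "fusion_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [fusion_config()] arguments.
#' @return a `fusion_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  do.call(fusion_config, yaml::read_yaml(path))
}

# random reference fragments used as the classifier's positive read pool
.reference_read_pool <- function(seqs, n, read_length, seed) {
  set.seed(seed)
  len <- nchar(seqs)
  ok <- which(len >= read_length)
  tx <- ok[sample.int(length(ok), n, replace = TRUE)]
  st <- 1L + floor(runif(n) * (len[tx] - read_length + 1))
  unname(substr(seqs[tx], st, st + read_length - 1L))
}

#' Train the artifact classifier on a detection input
#'
#' Builds the proxy-task training set from the observed chimeric reads
#' (negative/artifact class: junction windows of split reads) and random
#' concatenations of reference-derived reads (positive class, matched 1:1)
#' and trains the bi-LSTM.
#'
#' @param reads a `chimeric_reads` data.frame with `read_seq` and
#'   `junction_offset` populated for split reads.
#' @param seqs reference transcript sequences (for the random read pool).
#' @param config a [fusion_config()].
#' @return a [train_bilstm()] model.
#' @export
run_train <- function(reads, seqs, config = fusion_config()) {
  cc <- config$classifier
  sp <- reads[reads$kind == "split" & !is.na(reads$read_seq), , drop = FALSE]
  if (!nrow(sp)) stop("no split reads with sequences to train on")
  if (nrow(sp) > cc$n_examples) {
    set.seed(config$seed + 41L)
    sp <- sp[sample.int(nrow(sp), cc$n_examples), , drop = FALSE]
  }
  neg <- make_negative_examples(sp$read_seq, sp$junction_offset,
                                seed = config$seed + 42L)
  rl <- max(nchar(sp$read_seq))
  pool <- .reference_read_pool(seqs, max(1000L, nrow(neg)), rl,
                               seed = config$seed + 43L)
  pos <- make_positive_examples(pool, nrow(neg), seed = config$seed + 44L)
  train_bilstm(c(neg$window, pos$window),
               labels = c(rep(1L, nrow(neg)), rep(0L, nrow(pos))),
               epochs = cc$epochs, batch = cc$batch, seed = config$seed + 45L,
               lr = cc$lr, layers = cc$layers, seq2one = cc$seq2one, fc = cc$fc)
}

#' Score candidates with a trained artifact classifier
#'
#' Reconstructs each candidate's 60 bp junction window from the reference
#' (the same tokenization path as training) and returns the artifact
#' scores.
#'
#' @param model a `bilstm_model`.
#' @param candidates a `fusion_candidates` object.
#' @param annotation,seqs reference annotation and transcript sequences.
#' @return numeric artifact scores (`NA` where no window is resolvable).
#' @export
run_score <- function(model, candidates, annotation, seqs) {
  w <- junction_window(candidates, annotation, seqs, flank = 30L)
  off <- rep(30L, length(w))
  artifact_score(model, w, offset = off)
}

#' Run the full fusion-detection pipeline
#'
#' Executes evidence extraction, the annotation and minimum-cell filters,
#' the ZINB background fit, the resampling test with empirical-FDR cutoff
#' selection, artifact-classifier scoring, and the promiscuous-partner and
#' discordant-ratio filters, logging the candidate count after each layer.
#'
#' @param x input evidence: a `sim_dataset`, a raw junction-record
#'   data.frame (see [read_chimeric_junctions()]), or an already parsed
#'   `chimeric_reads` object.
#' @param annotation a [gene_annotation()] (taken from `x` for
#'   `sim_dataset` input).
#' @param seqs transcript sequences named by gene id (idem).
#' @param expr gene-by-cell expression matrix, TPM-like (idem).
#' @param config a [fusion_config()].
#' @param classifier `NULL` (skip artifact scoring), `"train"` (train on
#'   this input), or a pre-trained `bilstm_model`.
#' @param mappability optional mappability track passed to
#'   [parse_chimeric_alignments()].
#' @param output_dir when given, the call TSV, the funnel TSV and the
#'   resolved configuration (JSON) are written there.
#' @return list of class `fusion_run`: `calls` (final `fusion_calls`),
#'   `funnel`, `tests`, `fit`, `cutoff`, `model`, `config`, plus the
#'   intermediate candidate sets.
#' @export
run_detect <- function(x, annotation = NULL, seqs = NULL, expr = NULL,
                       config = fusion_config(), classifier = NULL,
                       mappability = NULL, output_dir = NULL) {
  if (is(x, "sim_dataset")) {
    annotation <- x$annotation; seqs <- x$seqs; expr <- x$expr
    records <- x$records
  } else {
    records <- x
  }
  stopifnot(!is.null(annotation), !is.null(seqs), !is.null(expr))

  reads <- if (is(records, "chimeric_reads")) records else
    parse_chimeric_alignments(records, annotation, mappability = mappability,
                              min_mapq = config$min_mapq)
  cand <- cluster_breakpoints(reads, window = config$window,
                              frag_size = config$frag_size)
  funnel <- c(candidates = nrow(cand$candidates))

  cand <- annotation_filter(cand, annotation,
                            enable_lncrna = config$enable_lncrna,
                            enable_symbol = config$enable_symbol)
  funnel <- c(funnel, annotation = nrow(cand$candidates))

  cand <- min_cell_filter(cand, min_cells = config$min_cells)
  funnel <- c(funnel, min_cells = nrow(cand$candidates))

  empty_run <- function() {
    calls <- finalize_calls(cand, data.frame(candidate_id = character(0),
                                             S = numeric(0), nu = numeric(0),
                                             sigma = numeric(0), pvalue = numeric(0)),
                            scores = NULL)
    list(calls = calls[0, ], funnel = filter_funnel(funnel), tests = NULL,
         fit = NULL, cutoff = 0, model = NULL, config = config)
  }
  if (nrow(cand$candidates) == 0L) {
    out <- empty_run()
    class(out) <- "fusion_run"
    return(out)
  }

  counts <- build_support_matrix(cand)
  covar <- candidate_covariates(cand, expr, annotation = annotation, seqs = seqs,
                                scale = config$expr_scale,
                                window_bp = config$gc_window)
  fit <- fit_background(counts, covar, K = config$K, restarts = config$restarts,
                        seed = config$seed + 17L)
  tests <- test_candidates(fit, covar, counts, B = config$B,
                           seed = config$seed + 29L)

  hq <- split_high_quality(counts, hq_cell_fraction = config$hq_cell_fraction,
                           hq_mean_reads = config$hq_mean_reads)
  sel <- tryCatch(select_fdr_cutoff(tests$pvalue, hq, alpha = config$alpha),
                  error = function(e) {
                    warning(conditionMessage(e), "; passing no candidate")
                    list(cutoff = 0, passed = rep(FALSE, nrow(tests)))
                  })
  stat_keep <- cand$candidates$id[sel$passed]
  after_stat <- length(stat_keep)
  funnel <- c(funnel, statistical = after_stat)

  model <- NULL
  scores <- NULL
  if (!is.null(classifier)) {
    model <- if (is(classifier, "bilstm_model")) classifier else
      run_train(reads, seqs, config)
    scores <- run_score(model, cand, annotation, seqs)
    names(scores) <- cand$candidates$id
    funnel <- c(funnel,
                artifact = sum(is.na(scores) | scores <= config$artifact_threshold))
  }

  # candidates passing both models
  keep <- cand$candidates$id %in% stat_keep
  if (!is.null(scores)) keep <- keep & (is.na(scores) | scores <= config$artifact_threshold)
  cand2 <- .drop_candidates(cand, cand$candidates$id[!keep], "models")
  funnel <- c(funnel, both_models = nrow(cand2$candidates))

  cand2 <- too_many_partner_filter(cand2, max_partners = config$max_partners)
  funnel <- c(funnel, partners = nrow(cand2$candidates))
  cand2 <- discordant_ratio_filter(cand2, ratio = config$discordant_ratio)
  funnel <- c(funnel, discordant = nrow(cand2$candidates))

  calls <- finalize_calls(cand2, tests,
                          scores = if (is.null(scores)) NULL else
                            scores[cand2$candidates$id])
  out <- list(calls = calls, funnel = filter_funnel(funnel), tests = tests,
              fit = fit, cutoff = sel$cutoff, model = model,
              candidates = cand, config = config)
  class(out) <- "fusion_run"

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_fusion_calls(calls, file.path(output_dir, "fusion_calls.tsv"))
    write.table(out$funnel, file.path(output_dir, "filter_funnel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_plain <- unclass(config)
    jsonlite::write_json(cfg_plain, file.path(output_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(fit)) write_background(fit, file.path(output_dir, "background_model.json"))
  }
  out
}

#' @export
print.fusion_run <- function(x, ...) {
  cat("fusion_run\n")
  print(x$funnel)
  cat(sprintf("p-value cutoff: %.4g; %d final call(s)\n", x$cutoff, nrow(x$calls)))
  invisible(x)
}

#' Simulate a dataset (pipeline wrapper)
#'
#' Thin wrapper over [simulate_dataset()] that optionally writes the
#' dataset to disk.
#'
#' @param cfg a [sim_config()].
#' @param transcriptome,library optional pre-built inputs.
#' @param output_dir when given, passed to [write_sim_dataset()].
#' @param fastq write FASTQ too?
#' @return the `sim_dataset`.
#' @export
run_simulate <- function(cfg = sim_config(), transcriptome = NULL,
                         library = NULL, output_dir = NULL, fastq = FALSE) {
  x <- simulate_dataset(cfg, transcriptome = transcriptome, library = library)
  if (!is.null(output_dir)) write_sim_dataset(x, output_dir, fastq = fastq)
  x
}
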