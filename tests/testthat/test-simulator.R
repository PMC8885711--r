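# Dataset simulator: configuration contracts, read accounting, chimeric
# calibration, fusion spiking, and reproducibility.

test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(chimeric_fraction = 1.2))
  expect_error(sim_config(fusion_cell_fraction = -0.1))
  expect_error(sim_config(read_length = 10))
  expect_error(sim_config(chimera_expression_range = c(10, 1)))
})

test_that("per-cell read totals are conserved across the three read classes", {
  tx <- toy_transcriptome()
  fus <- sample_true_fusions(tx, n = 5, expression = 2000, seed = 3)
  ds <- simulate_dataset(sim_config(n_cells = 8, reads_per_cell = 8000,
                                    entries_per_cell = 100, true_fusions = fus,
                                    seed = 21),
                         transcriptome = tx, library = toy_library())
  ac <- ds$truth$accounting
  expect_true(all(ac$background + ac$chimeric + ac$fusion == 8000))
  expect_true(all(ac$chimeric > 0))
})

test_that("realized chimeric read fraction matches its calibration", {
  tx <- toy_transcriptome()
  ds <- simulate_dataset(sim_config(n_cells = 1, reads_per_cell = 2e5,
                                    entries_per_cell = 500, seed = 77),
                         transcriptome = tx, library = toy_library())
  frac <- ds$truth$accounting$chimeric / 2e5
  expect_lt(abs(frac - 0.01), 0.002)
  # the emitted junction records agree with the accounting
  expect_identical(nrow(ds$records), as.integer(ds$truth$accounting$chimeric))
})

test_that("an infeasible chimeric fraction warns and emits nothing", {
  tx <- toy_transcriptome()
  expect_warning(
    ds <- simulate_dataset(sim_config(n_cells = 2, reads_per_cell = 50,
                                      chimeric_fraction = 0.001,
                                      entries_per_cell = 10, seed = 1),
                           transcriptome = tx, library = toy_library()),
    "chimeric")
  expect_lte(sum(ds$truth$accounting$chimeric), 1)
})

test_that("fusion spiking honours the cell fraction and records the truth", {
  tx <- toy_transcriptome()
  fus <- sample_true_fusions(tx, n = 10, expression = 4000, seed = 5)
  ds <- simulate_dataset(sim_config(n_cells = 30, reads_per_cell = 1e4,
                                    chimeric_fraction = 0, true_fusions = fus,
                                    fusion_cell_fraction = 0.2, seed = 9),
                         transcriptome = tx, library = NULL)
  tf <- ds$truth$fusions
  # bearing-cell counts binomial(30, 0.2): all within a generous band
  expect_true(all(tf$n_cells >= 0 & tf$n_cells <= 16))
  expect_gt(mean(tf$n_cells), 2)
  # at this expression nearly every bearing cell has a junction read
  expect_gt(sum(tf$junction_reads), 0)
  # every junction record corresponds to a spiked fusion breakpoint
  key <- paste(ds$records$pos_a, ds$records$pos_b)
  expect_true(all(key %in% paste(tf$pos5, tf$pos3)))
  # fraction 0: no fusion-bearing cells at all
  ds0 <- simulate_dataset(sim_config(n_cells = 10, reads_per_cell = 1e4,
                                     chimeric_fraction = 0, true_fusions = fus,
                                     fusion_cell_fraction = 0, seed = 9),
                          transcriptome = tx, library = NULL)
  expect_true(all(ds0$truth$fusions$n_cells == 0))
  expect_null(ds0$records)
})

test_that("high-expression fusions give junction reads in nearly all bearing cells", {
  tx <- toy_transcriptome()
  fus <- sample_true_fusions(tx, n = 8, expression = 6000, seed = 11)
  ds <- simulate_dataset(sim_config(n_cells = 25, reads_per_cell = 5e4,
                                    chimeric_fraction = 0, true_fusions = fus,
                                    fusion_cell_fraction = 0.4, seed = 13),
                         transcriptome = tx, library = NULL)
  # count bearing cells with at least one junction-spanning read
  tab <- table(ds$records$cell_id,
               factor(paste(ds$records$pos_a, ds$records$pos_b),
                      levels = paste(ds$truth$fusions$pos5, ds$truth$fusions$pos3)))
  covered <- sum(tab > 0)
  bearing <- sum(ds$truth$fusions$n_cells)
  expect_gt(bearing, 0)
  expect_gte(covered / bearing, 0.95)
})

test_that("simulation is reproducible under its seed", {
  tx <- toy_transcriptome()
  lib <- toy_library()
  cfg <- sim_config(n_cells = 4, reads_per_cell = 5000, entries_per_cell = 50,
                    seed = 31)
  d1 <- simulate_dataset(cfg, transcriptome = tx, library = lib)
  d2 <- simulate_dataset(cfg, transcriptome = tx, library = lib)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$expr, d2$expr)
})

test_that("expression matrix is TPM-scaled with fusion partners covered", {
  tx <- toy_transcriptome()
  fus <- sample_true_fusions(tx, n = 3, expression = 4000, seed = 7)
  ds <- simulate_dataset(sim_config(n_cells = 6, reads_per_cell = 2e4,
                                    entries_per_cell = 50, true_fusions = fus,
                                    fusion_cell_fraction = 1, seed = 15),
                         transcriptome = tx, library = toy_library())
  expect_equal(unname(colSums(ds$expr)), rep(1e6, 6), tolerance = 1e-6)
  # partner genes of ubiquitous high-expression fusions are well covered
  expect_true(all(ds$expr[fus$gene5, ] > 0))
})

test_that("background read sampler returns reads of the configured length", {
  tx <- toy_transcriptome()
  ds <- simulate_dataset(sim_config(n_cells = 2, reads_per_cell = 1000,
                                    entries_per_cell = 20, seed = 41),
                         transcriptome = tx, library = toy_library())
  rd <- sample_background_reads(ds, 200, seed = 8)
  expect_length(rd, 200)
  expect_true(all(nchar(rd) == ds$config$read_length))
  expect_true(all(grepl("^[ACGT]+$", rd)))
})

test_that("written datasets include FASTQ with conserved read counts when asked", {
  tx <- toy_transcriptome()
  ds <- simulate_dataset(sim_config(n_cells = 2, reads_per_cell = 800,
                                    entries_per_cell = 20, seed = 51),
                         transcriptome = tx, library = toy_library())
  dir <- tempfile()
  write_sim_dataset(ds, dir, fastq = TRUE)
  fq <- file.path(dir, paste0(ds$cells[1], ".fastq.gz"))
  expect_true(file.exists(fq))
  lines <- readLines(fq)
  expect_identical(length(lines) %% 4L, 0L)
  expect_identical(length(lines) / 4L,
                   ds$truth$accounting$background[1] + ds$truth$accounting$chimeric[1] +
                     ds$truth$accounting$fusion[1])
  expect_true(file.exists(file.path(dir, "transcripts.fa")))
  expect_true(file.exists(file.path(dir, "chimera_library.tsv")))
})
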