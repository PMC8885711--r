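# Artifact classifier: training-example construction, tokenization, the
# network's gradients against finite differences, training behaviour and
# threshold semantics.

test_that("negative examples place the junction at the sampled in-window offset", {
  set.seed(6)
  reads <- random_dna(50, 100)
  jo <- sample(20:80, 50, replace = TRUE)
  ex <- make_negative_examples(reads, jo, seed = 2)
  expect_true(all(ex$offset >= 15 & ex$offset <= 45))
  expect_true(all(nchar(ex$window) == 61))
  for (k in seq_len(nrow(ex))) {
    w <- ex$window[k]
    expect_identical(substr(w, ex$offset[k] + 1, ex$offset[k] + 1), "J")
    # window content is a verbatim substring of the source read
    naked <- paste0(substr(w, 1, ex$offset[k]), substr(w, ex$offset[k] + 2, 61))
    src <- reads[ex$source_id[k]]
    start <- jo[ex$source_id[k]] - ex$offset[k]
    expect_identical(naked, substr(src, start + 1, start + 60))
  }
})

test_that("reads that cannot host a valid window are skipped and counted", {
  ex <- make_negative_examples(random_dna(1, 59), 30, seed = 1)
  expect_identical(nrow(ex), 0L)
  expect_identical(attr(ex, "skipped"), 1L)
  # junction too close to the read end
  ex2 <- make_negative_examples(random_dna(1, 100), 5L, seed = 1)
  expect_identical(nrow(ex2), 0L)
  # exhaustive check over a large fixture
  set.seed(91)
  reads <- random_dna(1000, 100)
  jo <- sample(1:99, 1000, replace = TRUE)
  ex3 <- make_negative_examples(reads, jo, seed = 3)
  expect_true(all(ex3$offset >= 15 & ex3$offset <= 45))
  expect_identical(nrow(ex3) + attr(ex3, "skipped"), 1000L)
})

test_that("positive examples seam two reads at a uniform offset", {
  set.seed(17)
  pool <- random_dna(200, 100)
  ex <- make_positive_examples(pool, 10000, seed = 5)
  expect_true(all(nchar(ex$window) == 61))
  expect_true(all(vapply(gregexpr("J", ex$window), length, integer(1)) == 1L))
  # offsets approximately uniform on 15..45 (chi-square GOF)
  tab <- table(factor(ex$offset, levels = 15:45))
  gof <- chisq.test(tab)
  expect_gt(gof$p.value, 0.01)
  # deterministic under a fixed seed
  expect_identical(ex, make_positive_examples(pool, 10000, seed = 5))
  expect_error(make_positive_examples(character(0), 5), "pool")
})

test_that("tokenization inserts the junction symbol and maps N to its own token", {
  m <- tokenize_junctions("ACGTN", offset = NULL) |> try(silent = TRUE)
  expect_s3_class(m, "try-error")  # not a 60 bp window
  w <- paste0(strrep("A", 30), strrep("C", 30))
  tok <- tokenize_junctions(w, offset = 30)
  expect_identical(dim(tok), c(1L, 61L))
  expect_identical(tok[1, 31], 5L)             # J token
  expect_identical(tok[1, 1], 1L)              # A
  expect_identical(tok[1, 61], 2L)             # C
  wn <- paste0(strrep("N", 30), strrep("G", 30))
  expect_identical(tokenize_junctions(wn, offset = 15)[1, 1], 6L)  # N token
  expect_error(tokenize_junctions(substr(w, 1, 59), offset = 20), "60 bp")
  two_j <- paste0(substr(w, 1, 20), "J", substr(w, 21, 40), "J", substr(w, 41, 59))
  expect_error(tokenize_junctions(two_j), "exactly one")
})

test_that("backpropagated gradients match finite differences", {
  fw <- fusecell:::.model_fwd; bw <- fusecell:::.model_bwd
  flat <- fusecell:::.flatten_params; appl <- fusecell:::.apply_flat
  set.seed(2)
  prm <- fusecell:::.bilstm_init(layers = c(3L), seq2one = 2L, fc = 4L, seed = 2)
  ids <- matrix(sample(1:6, 5 * 9, replace = TRUE), 5, 9)
  labels <- c(1, 0, 1, 1, 0)
  loss_fn <- function(p) {
    pr <- fw(p, ids)$probs
    -mean(log(pmax(pr[cbind(1:5, labels + 1)], 1e-12)))
  }
  fo <- fw(prm, ids, keep_cache = TRUE)
  gr <- bw(prm, fo, labels)
  fp <- flat(prm); fg <- flat(gr)
  expect_setequal(names(fg), names(fp))
  eps <- 1e-6
  for (k in names(fp)) {
    idx <- sample(length(fp[[k]]), min(3, length(fp[[k]])))
    for (ii in idx) {
      p2 <- fp; p2[[k]][ii] <- p2[[k]][ii] + eps
      p3 <- fp; p3[[k]][ii] <- p3[[k]][ii] - eps
      num <- (loss_fn(appl(prm, p2)) - loss_fn(appl(prm, p3))) / (2 * eps)
      den <- max(abs(num), abs(fg[[k]][ii]), 1e-8)
      expect_lt(abs(num - fg[[k]][ii]) / den, 1e-4)
    }
  }
})

test_that("the compiled engine reproduces the reference implementation exactly", {
  set.seed(12)
  prm <- fusecell:::.bilstm_init(layers = c(4L, 5L), seq2one = 3L, fc = 6L, seed = 12)
  ids <- matrix(sample(1:6, 7 * 13, replace = TRUE), 7, 13)
  labels <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L)
  fo <- fusecell:::.model_fwd(prm, ids, keep_cache = TRUE)
  gr <- fusecell:::.model_bwd(prm, fo, labels)
  res <- fusecell:::.cpp_bilstm_fwdbwd(prm, ids, labels)
  expect_equal(res$probs, fo$probs, tolerance = 1e-12, ignore_attr = TRUE)
  fr <- fusecell:::.flatten_params(gr)
  fc <- fusecell:::.flatten_params(res$grads)
  expect_setequal(names(fr), names(fc))
  for (k in names(fr)) {
    expect_equal(fc[[k]], fr[[k]], tolerance = 1e-10, ignore_attr = TRUE)
  }
  # end-to-end: both engines trained on the same data agree on the loss path
  n <- 60
  x <- sprintf("%sJ%s", substr(random_dna(n, 60), 1, 30), strrep("A", 30))
  y <- rep(c(0L, 1L), n / 2)
  m_cpp <- train_bilstm(x, y, epochs = 2, batch = 30, seed = 5,
                        layers = c(4L), seq2one = 4L, fc = 6L, engine = "cpp")
  m_r <- train_bilstm(x, y, epochs = 2, batch = 30, seed = 5,
                      layers = c(4L), seq2one = 4L, fc = 6L, engine = "r")
  expect_equal(m_cpp$history, m_r$history, tolerance = 1e-8)
})

test_that("training decreases the loss, is seed-reproducible, and rejects one class", {
  set.seed(23)
  n <- 120
  neg <- random_dna(n, 60); pos <- random_dna(n, 60)
  off <- sample(15:45, n, replace = TRUE)
  # implant a signature straddling the junction in the negatives
  negJ <- sprintf("%sAAAJAAA%s", substr(neg, 1, off - 3), substr(neg, off + 4, 60))
  posJ <- sprintf("%sJ%s", substr(pos, 1, off), substr(pos, off + 1, 60))
  x <- c(negJ, posJ); y <- c(rep(1L, n), rep(0L, n))
  m <- train_bilstm(x, y, epochs = 6, batch = 60, seed = 9,
                    layers = c(6L), seq2one = 6L, fc = 8L, lr = 5e-3)
  expect_lt(tail(m$history, 1), m$history[1])
  m2 <- train_bilstm(x, y, epochs = 6, batch = 60, seed = 9,
                     layers = c(6L), seq2one = 6L, fc = 8L, lr = 5e-3)
  expect_equal(tail(m$history, 1), tail(m2$history, 1), tolerance = 1e-6)
  expect_error(train_bilstm(x, rep(1L, length(x)), epochs = 1), "both classes")
  # probabilities sum to one
  pr <- predict(m, x[1:10])
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0 & pr <= 1))
  # retraining from a pre-trained model runs retrain_epochs
  m3 <- train_bilstm(x, y, seed = 9, init = m, retrain_epochs = 2)
  expect_length(m3$history, 2)
  expect_true(m3$settings$retrained)
})

test_that("artifact filtering is strictly greater-than the threshold", {
  cand <- toy_candidates(sprintf("G%d", 1:4), sprintf("H%d", 1:4),
                         rep(list(c(cellA = 1, cellB = 1)), 4))
  out <- artifact_filter(cand, scores = c(0.75, 0.76, NA, 0.2), threshold = 0.75)
  # 0.75 retained (strict), 0.76 filtered, NA retained, 0.2 retained
  expect_identical(out$candidates$gene5, c("G1", "G3", "G4"))
  expect_identical(attr(out, "removed"), c(artifact_score = 1L))
})

test_that("a trained model survives JSON persistence", {
  set.seed(44)
  n <- 60
  x <- sprintf("%sJ%s", substr(random_dna(n, 60), 1, 30), strrep("A", 30))
  y <- rep(c(0L, 1L), n / 2)
  m <- train_bilstm(x, y, epochs = 2, batch = 30, seed = 1,
                    layers = c(4L), seq2one = 4L, fc = 6L)
  path <- tempfile(fileext = ".json")
  write_bilstm(m, path)
  back <- read_bilstm(path)
  expect_equal(predict(back, x[1:8]), predict(m, x[1:8]), tolerance = 1e-10)
})
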