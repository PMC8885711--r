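## Bi-directional LSTM junction-artifact classifier, implemented directly
## on matrix operations: an embedding layer over {A, C, G, T, J(unction),
## N}, a stack of sequence-to-sequence bi-LSTM layers, one sequence-to-one
## bi-LSTM layer, two fully connected layers and a softmax head, trained
## with Adam on binary cross-entropy. Training data come from a proxy
## task: junction windows of observed chimeric reads (artifact class)
## against random read concatenations (non-artifact class).

.VOCAB <- c("A", "C", "G", "T", "J", "N")
.EMB_DIM <- 5L
.WINDOW <- 60L
.OFF_RANGE <- c(15L, 45L)

#' Tokenize junction windows
#'
#' Converts 60 bp junction windows into integer token sequences of length
#' 61: the four nucleotides, a dedicated junction symbol `J` inserted after
#' `offset` bases, and `N` for degenerate bases. Windows already carrying a
#' single `J` may be passed with `offset = NULL`.
#'
#' @param windows character vector of 60 bp sequences (or 61-mers
#'   containing one `J`).
#' @param offset junction offsets (bases before the junction), recycled;
#'   ignored when the windows already contain `J`.
#' @return integer matrix (n x 61) of token ids with attribute `vocab`.
#' @export
tokenize_junctions <- function(windows, offset = NULL) {
  has_j <- grepl("J", windows, fixed = TRUE)
  if (!all(has_j)) {
    stopifnot(!is.null(offset))
    offset <- rep_len(offset, length(windows))
    windows[!has_j] <- paste0(
      substr(windows[!has_j], 1L, offset[!has_j]), "J",
      substr(windows[!has_j], offset[!has_j] + 1L, nchar(windows[!has_j])))
  }
  if (any(nchar(windows) != .WINDOW + 1L)) stop("windows must be 60 bp (+ junction)")
  if (any(vapply(gregexpr("J", windows, fixed = TRUE), length, integer(1)) != 1L)) {
    stop("each window must contain exactly one junction symbol")
  }
  ch <- matrix(unlist(strsplit(toupper(windows), "", fixed = TRUE), use.names = FALSE),
               nrow = length(windows), byrow = TRUE)
  ids <- match(ch, .VOCAB)
  ids[is.na(ids)] <- match("N", .VOCAB)
  m <- matrix(ids, nrow = length(windows))
  attr(m, "vocab") <- .VOCAB
  m
}

#' Negative (artifact-class) training examples from chimeric reads
#'
#' Cuts one 60 bp window out of each chimeric read so that the junction
#' lies at an offset drawn uniformly from the admissible range 15--45,
#' subject to the read boundaries, and marks the junction with the `J`
#' token. Reads that cannot host such a window (too short, or junction too
#' close to an end) are skipped and counted in the `"skipped"` attribute.
#'
#' @param sequences character vector of read sequences.
#' @param junction_offset integer vector: number of read bases before the
#'   junction.
#' @param seed RNG seed.
#' @return data.frame with columns `window` (61-token string including
#'   `J`), `offset`, `source_id` (input index), plus attribute `skipped`.
#' @export
make_negative_examples <- function(sequences, junction_offset, seed = 1L) {
  stopifnot(length(sequences) == length(junction_offset))
  set.seed(seed)
  len <- nchar(sequences)
  lo <- pmax(0L, junction_offset - .OFF_RANGE[2])
  hi <- pmin(len - .WINDOW, junction_offset - .OFF_RANGE[1])
  ok <- which(len >= .WINDOW & hi >= lo & junction_offset >= .OFF_RANGE[1] &
                (len - junction_offset) >= (.WINDOW - .OFF_RANGE[2]))
  if (!length(ok)) {
    out <- data.frame(window = character(0), offset = integer(0),
                      source_id = integer(0), stringsAsFactors = FALSE)
    attr(out, "skipped") <- length(sequences)
    return(out)
  }
  start <- lo[ok] + floor(runif(length(ok)) * (hi[ok] - lo[ok] + 1))
  win <- substr(sequences[ok], start + 1L, start + .WINDOW)
  off <- junction_offset[ok] - start
  out <- data.frame(
    window = paste0(substr(win, 1L, off), "J", substr(win, off + 1L, .WINDOW)),
    offset = as.integer(off),
    source_id = ok,
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- length(sequences) - length(ok)
  out
}

#' Positive (random-concatenation) training examples
#'
#' Builds 60 bp pseudo-junction windows by concatenating a suffix of one
#' randomly drawn read with a prefix of another, the seam at an offset
#' drawn uniformly from 15--45 and marked with `J`. Because the seams are
#' random, these windows carry no mis-priming signature and serve as the
#' non-artifact class of the proxy task.
#'
#' @param pool character vector of (non-chimeric) read sequences, each at
#'   least 45 bp.
#' @param count number of examples.
#' @param seed RNG seed.
#' @return data.frame with columns `window`, `offset`, `source_id`.
#' @export
make_positive_examples <- function(pool, count, seed = 1L) {
  pool <- pool[nchar(pool) >= .OFF_RANGE[2]]
  if (length(pool) < 2L) stop("read pool too small for positive examples")
  set.seed(seed)
  i1 <- sample.int(length(pool), count, replace = TRUE)
  i2 <- sample.int(length(pool), count, replace = TRUE)
  off <- .OFF_RANGE[1] + floor(runif(count) * (.OFF_RANGE[2] - .OFF_RANGE[1] + 1))
  l1 <- nchar(pool[i1]); l2 <- nchar(pool[i2])
  left <- substr(pool[i1], l1 - off + 1L, l1)
  right <- substr(pool[i2], 1L, .WINDOW - off)
  short <- nchar(right) < .WINDOW - off
  if (any(short)) {  # second read shorter than the needed prefix: resample offset cap
    off[short] <- .WINDOW - nchar(right[short])
    left[short] <- substr(pool[i1][short], l1[short] - off[short] + 1L, l1[short])
  }
  data.frame(window = paste0(left, "J", right),
             offset = as.integer(off),
             source_id = i1,
             stringsAsFactors = FALSE)
}

## ---- parameter initialization ------------------------------------------

.glorot <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

.lstm_params <- function(in_dim, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(W = .glorot(in_dim, 4 * H), U = .glorot(H, 4 * H), b = b)
}

.bilstm_init <- function(layers, seq2one, fc, seed) {
  set.seed(seed)
  prm <- list(emb = .glorot(length(.VOCAB), .EMB_DIM))
  in_dim <- .EMB_DIM
  prm$layers <- lapply(layers, function(H) {
    l <- list(fwd = .lstm_params(in_dim, H), bwd = .lstm_params(in_dim, H))
    in_dim <<- 2L * H
    l
  })
  prm$seq2one <- list(fwd = .lstm_params(in_dim, seq2one),
                      bwd = .lstm_params(in_dim, seq2one))
  prm$fc1 <- list(W = .glorot(2L * seq2one, fc), b = rep(0, fc))
  prm$fc2 <- list(W = .glorot(fc, 2L), b = rep(0, 2L))
  prm
}

## ---- forward / backward ------------------------------------------------

# forward pass of one LSTM direction over a list of B x in matrices;
# reverse = TRUE processes the sequence right-to-left. The input
# projection X_t W + b has no recurrence and is computed for all
# timesteps in one matrix product.
.lstm_fwd <- function(X, prm, reverse = FALSE) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- ncol(prm$U) / 4L
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  Xs <- do.call(rbind, X)                       # (B*T) x in
  P <- Xs %*% prm$W + rep(prm$b, each = B * T_) # (B*T) x 4H
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", T_); cache <- vector("list", T_)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (t in ord) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    a <- P[rows, , drop = FALSE] + h %*% prm$U
    i <- plogis(a[, i1, drop = FALSE])
    f <- plogis(a[, i2, drop = FALSE])
    g <- tanh(a[, i3, drop = FALSE])
    o <- plogis(a[, i4, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    hs[[t]] <- h
    cache[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  list(h = hs, cache = cache, ord = ord, last = h, Xs = Xs)
}

# backward pass; fwd$dh_ext: list of B x H external gradients per step
# (NULL entries allowed); returns dX (list) and parameter gradients. The
# non-recurrent products (dW, dX, db) are batched over timesteps.
.lstm_bwd <- function(X, fwd, prm) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- ncol(prm$U) / 4L
  dU <- prm$U * 0
  da_all <- matrix(0, B * T_, 4L * H)
  hp_all <- matrix(0, B * T_, H)
  dh_rec <- matrix(0, B, H); dc_rec <- matrix(0, B, H)
  for (t in rev(fwd$ord)) {
    cc <- fwd$cache[[t]]
    dh <- dh_rec
    if (!is.null(fwd$dh_ext[[t]])) dh <- dh + fwd$dh_ext[[t]]
    do_ <- dh * cc$tc
    dtc <- dh * cc$o * (1 - cc$tc^2) + dc_rec
    dc_rec <- dtc * cc$f
    di <- dtc * cc$g
    df <- dtc * cc$c_prev
    dg <- dtc * cc$i
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    rows <- ((t - 1L) * B + 1L):(t * B)
    da_all[rows, ] <- da
    hp_all[rows, ] <- cc$h_prev
    dh_rec <- da %*% t(prm$U)
  }
  dU <- crossprod(hp_all, da_all)
  dW <- crossprod(fwd$Xs, da_all)
  db <- colSums(da_all)
  dXs <- da_all %*% t(prm$W)
  dX <- lapply(seq_len(T_), function(t)
    dXs[((t - 1L) * B + 1L):(t * B), , drop = FALSE])
  list(dX = dX, dW = dW, dU = dU, db = db)
}

# gradient triple named like the parameter triple, so Adam matches them
.as_param_grad <- function(b) list(W = b$dW, U = b$dU, b = b$db)

# full forward; returns probabilities and (optionally) all caches
.model_fwd <- function(prm, ids, keep_cache = FALSE) {
  B <- nrow(ids); T_ <- ncol(ids)
  X <- lapply(seq_len(T_), function(t) prm$emb[ids[, t], , drop = FALSE])
  caches <- list()
  inp <- X
  for (li in seq_along(prm$layers)) {
    lp <- prm$layers[[li]]
    fw <- .lstm_fwd(inp, lp$fwd, reverse = FALSE)
    bw <- .lstm_fwd(inp, lp$bwd, reverse = TRUE)
    out <- lapply(seq_len(T_), function(t) cbind(fw$h[[t]], bw$h[[t]]))
    if (keep_cache) caches[[li]] <- list(fw = fw, bw = bw, inp = inp)
    inp <- out
  }
  fw1 <- .lstm_fwd(inp, prm$seq2one$fwd, reverse = FALSE)
  bw1 <- .lstm_fwd(inp, prm$seq2one$bwd, reverse = TRUE)
  feat <- cbind(fw1$last, bw1$last)
  z1 <- feat %*% prm$fc1$W + rep(prm$fc1$b, each = B)
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% prm$fc2$W + rep(prm$fc2$b, each = B)
  z2 <- z2 - apply(z2, 1, max)
  probs <- exp(z2) / rowSums(exp(z2))
  out <- list(probs = probs)
  if (keep_cache) {
    out <- c(out, list(caches = caches, s2o = list(fw = fw1, bw = bw1, inp = inp),
                       feat = feat, a1 = a1, X = X, ids = ids))
  }
  out
}

# backward from cross-entropy on labels (1 = artifact class column 2)
.model_bwd <- function(prm, fwdout, labels) {
  B <- nrow(fwdout$probs); T_ <- length(fwdout$X)
  y <- cbind(1 - labels, labels)
  dz2 <- (fwdout$probs - y) / B
  g <- list()
  g$fc2 <- list(W = crossprod(fwdout$a1, dz2), b = colSums(dz2))
  da1 <- dz2 %*% t(prm$fc2$W)
  dz1 <- da1 * (fwdout$a1 > 0)
  g$fc1 <- list(W = crossprod(fwdout$feat, dz1), b = colSums(dz1))
  dfeat <- dz1 %*% t(prm$fc1$W)
  Hs <- ncol(prm$seq2one$fwd$U) / 4L
  dlast_f <- dfeat[, 1:Hs, drop = FALSE]
  dlast_b <- dfeat[, (Hs + 1):(2 * Hs), drop = FALSE]
  # sequence-to-one layer: gradient enters only at the final step of each
  # direction (the last processed timestep)
  fw1 <- fwdout$s2o$fw; bw1 <- fwdout$s2o$bw
  fw1$dh_ext <- rep(list(NULL), T_); fw1$dh_ext[[T_]] <- dlast_f
  bw1$dh_ext <- rep(list(NULL), T_); bw1$dh_ext[[1L]] <- dlast_b
  bf <- .lstm_bwd(fwdout$s2o$inp, fw1, prm$seq2one$fwd)
  bb <- .lstm_bwd(fwdout$s2o$inp, bw1, prm$seq2one$bwd)
  g$seq2one <- list(fwd = .as_param_grad(bf), bwd = .as_param_grad(bb))
  dinp <- lapply(seq_len(T_), function(t) bf$dX[[t]] + bb$dX[[t]])
  g$layers <- vector("list", length(prm$layers))
  for (li in rev(seq_along(prm$layers))) {
    ca <- fwdout$caches[[li]]
    H <- ncol(prm$layers[[li]]$fwd$U) / 4L
    fwc <- ca$fw; bwc <- ca$bw
    fwc$dh_ext <- lapply(dinp, function(d) d[, 1:H, drop = FALSE])
    bwc$dh_ext <- lapply(dinp, function(d) d[, (H + 1):(2 * H), drop = FALSE])
    bf <- .lstm_bwd(ca$inp, fwc, prm$layers[[li]]$fwd)
    bb <- .lstm_bwd(ca$inp, bwc, prm$layers[[li]]$bwd)
    g$layers[[li]] <- list(fwd = .as_param_grad(bf), bwd = .as_param_grad(bb))
    dinp <- lapply(seq_len(T_), function(t) bf$dX[[t]] + bb$dX[[t]])
  }
  demb <- prm$emb * 0
  for (t in seq_len(T_)) {
    agg <- rowsum(dinp[[t]], group = fwdout$ids[, t])
    ridx <- as.integer(rownames(agg))
    demb[ridx, ] <- demb[ridx, , drop = FALSE] + agg
  }
  g$emb <- demb
  g
}

## ---- Adam on the nested parameter list ---------------------------------

.flatten_params <- function(p, path = "") {
  if (is.list(p)) {
    out <- list()
    nm <- names(p); if (is.null(nm)) nm <- as.character(seq_along(p))
    for (i in seq_along(p)) out <- c(out, .flatten_params(p[[i]], paste0(path, "/", nm[i])))
    out
  } else setNames(list(p), path)
}

.apply_flat <- function(p, fl, path = "") {
  if (is.list(p)) {
    nm <- names(p); if (is.null(nm)) nm <- as.character(seq_along(p))
    for (i in seq_along(p)) p[[i]] <- .apply_flat(p[[i]], fl, paste0(path, "/", nm[i]))
    p
  } else fl[[path]]
}

.adam_step <- function(prm, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip = 5) {
  fp <- .flatten_params(prm); fg <- .flatten_params(grad)
  # global gradient-norm clipping guards the BPTT against explosion
  gnorm <- sqrt(sum(vapply(fg, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip) fg <- lapply(fg, `*`, clip / gnorm)
  state$t <- state$t + 1L
  for (k in names(fp)) {
    if (is.null(fg[[k]])) next
    if (is.null(state$m[[k]])) { state$m[[k]] <- fg[[k]] * 0; state$v[[k]] <- fg[[k]] * 0 }
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * fg[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * fg[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    fp[[k]] <- fp[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(prm = .apply_flat(prm, fp), state = state)
}

## ---- training / scoring -------------------------------------------------

#' Train the bi-LSTM artifact classifier
#'
#' Trains the junction classifier on tokenized 61-symbol windows with
#' binary cross-entropy and the Adam optimizer. The default architecture
#' follows the published design — embedding dimension 5, three
#' sequence-to-sequence bi-LSTM layers of 32/64/128 units, one
#' sequence-to-one bi-LSTM layer, two fully connected layers and a softmax
#' head — and is fully configurable (the test suite and desk-scale runs
#' use smaller layers). An 80/20 stratified validation split is held out.
#' Supplying `init` (a previously trained model) switches to retraining
#' for `retrain_epochs` epochs.
#'
#' @param examples character vector of junction windows (with `J`) or an
#'   integer token matrix from [tokenize_junctions()].
#' @param labels 0/1 vector (1 = artifact class, i.e. chimeric-read
#'   origin). Both classes must be present.
#' @param epochs,batch training epochs and mini-batch size (defaults 200
#'   and 500).
#' @param seed RNG seed governing initialization, the split and shuffling.
#' @param init optional `bilstm_model` used as starting point.
#' @param retrain_epochs epochs used when `init` is given (default 30).
#' @param lr Adam learning rate.
#' @param layers integer vector of sequence-to-sequence bi-LSTM layer
#'   sizes.
#' @param seq2one units of the sequence-to-one bi-LSTM layer.
#' @param fc width of the first fully connected layer.
#' @param validation_split held-out fraction (stratified by label).
#' @param verbose print per-epoch losses?
#' @return object of class `bilstm_model`: parameters, architecture
#'   metadata, `history` (per-epoch training loss), `val` (validation
#'   indices) and the training call settings.
#' @export
train_bilstm <- function(examples, labels, epochs = 200L, batch = 500L,
                         seed = 1L, init = NULL, retrain_epochs = 30L,
                         lr = 1e-3, layers = c(32L, 64L, 128L),
                         seq2one = 64L, fc = 64L,
                         validation_split = 0.2, verbose = FALSE,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  ids <- if (is.matrix(examples)) examples else tokenize_junctions(examples)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(ids))
  if (length(unique(labels)) < 2L) stop("training data must contain both classes")
  if (!is.null(init)) {
    prm <- init$params
    layers <- init$arch$layers; seq2one <- init$arch$seq2one; fc <- init$arch$fc
    epochs <- retrain_epochs
  } else {
    prm <- .bilstm_init(layers, seq2one, fc, seed = seed)
  }
  set.seed(seed + 1L)
  val_idx <- unlist(lapply(unique(labels), function(l) {
    w <- which(labels == l)
    sample(w, max(1L, round(validation_split * length(w))))
  }))
  tr_idx <- setdiff(seq_len(nrow(ids)), val_idx)
  state <- list(t = 0L, m = list(), v = list())
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    set.seed(seed + 1000L + ep)
    ord <- sample(tr_idx)
    losses <- c()
    for (s in seq(1L, length(ord), by = batch)) {
      bi <- ord[s:min(s + batch - 1L, length(ord))]
      if (engine == "cpp") {
        res <- .cpp_bilstm_fwdbwd(prm, ids[bi, , drop = FALSE], labels[bi])
        losses <- c(losses, res$loss)
        gr <- res$grads
      } else {
        fo <- .model_fwd(prm, ids[bi, , drop = FALSE], keep_cache = TRUE)
        pr <- pmax(fo$probs[cbind(seq_along(bi), labels[bi] + 1L)], 1e-12)
        losses <- c(losses, -mean(log(pr)))
        gr <- .model_bwd(prm, fo, labels[bi])
      }
      up <- .adam_step(prm, gr, state, lr = lr)
      prm <- up$prm; state <- up$state
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  structure(list(params = prm,
                 arch = list(layers = as.integer(layers),
                             seq2one = as.integer(seq2one), fc = as.integer(fc),
                             emb_dim = .EMB_DIM, vocab = .VOCAB),
                 history = history,
                 val = val_idx,
                 settings = list(epochs = epochs, batch = batch, seed = seed,
                                 lr = lr, retrained = !is.null(init),
                                 engine = engine)),
            class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  cat(sprintf("bilstm_model: layers %s + seq2one %d + fc %d; %d epochs, final loss %.4f\n",
              paste(x$arch$layers, collapse = "/"), x$arch$seq2one, x$arch$fc,
              length(x$history), tail(x$history, 1)))
  invisible(x)
}

#' @export
predict.bilstm_model <- function(object, newdata, batch = 500L,
                                 engine = c("cpp", "r"), ...) {
  engine <- match.arg(engine)
  ids <- if (is.matrix(newdata)) newdata else tokenize_junctions(newdata)
  out <- matrix(NA_real_, nrow(ids), 2L, dimnames = list(NULL, c("random", "artifact")))
  for (s in seq(1L, nrow(ids), by = batch)) {
    bi <- s:min(s + batch - 1L, nrow(ids))
    out[bi, ] <- if (engine == "cpp") {
      .cpp_bilstm_fwd(object$params, ids[bi, , drop = FALSE])
    } else {
      .model_fwd(object$params, ids[bi, , drop = FALSE])$probs
    }
  }
  out
}

#' Artifact score of junction windows
#'
#' Softmax probability of the artifact class for each candidate junction
#' window, tokenized exactly as the training data.
#'
#' @param model a trained [train_bilstm()] model.
#' @param windows character vector of 60 bp windows with `J` (or 60 bp plus
#'   `offset`); `NA` windows score `NA`.
#' @param offset junction offsets for windows lacking `J` (default 30,
#'   centered).
#' @return numeric scores in \[0, 1\].
#' @export
artifact_score <- function(model, windows, offset = 30L) {
  out <- rep(NA_real_, length(windows))
  ok <- !is.na(windows)
  if (any(ok)) {
    out[ok] <- predict(model, tokenize_junctions(windows[ok], offset = offset))[, "artifact"]
  }
  out
}

#' Filter candidates by artifact score
#'
#' Removes candidates whose artifact score strictly exceeds `threshold`
#' (a score of exactly `threshold` is retained). Candidates without a
#' score (no resolvable junction window) are retained.
#'
#' @param candidates a `fusion_candidates` object.
#' @param scores numeric vector aligned with the candidates.
#' @param threshold filtering threshold (default 0.75).
#' @return filtered `fusion_candidates` (removal count in attribute
#'   `"removed"`).
#' @export
artifact_filter <- function(candidates, scores, threshold = 0.75) {
  cd <- candidates$candidates
  stopifnot(length(scores) == nrow(cd))
  drop <- cd$id[!is.na(scores) & scores > threshold]
  .drop_candidates(candidates, drop, "artifact_score")
}

#' Save / load a trained classifier
#'
#' JSON persistence of all weights and the architecture metadata.
#'
#' @param model a `bilstm_model`.
#' @param path file path.
#' @return `read_bilstm()` returns the restored model.
#' @export
write_bilstm <- function(model, path) {
  jsonlite::write_json(list(params = model$params, arch = model$arch,
                            history = model$history, settings = model$settings),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bilstm
#' @export
read_bilstm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  relist_lstm <- function(l) list(W = as.matrix(l$W), U = as.matrix(l$U), b = as.numeric(l$b))
  p <- x$params
  p$emb <- as.matrix(p$emb)
  p$layers <- lapply(x$params$layers, function(l)
    list(fwd = relist_lstm(l$fwd), bwd = relist_lstm(l$bwd)))
  p$seq2one <- list(fwd = relist_lstm(x$params$seq2one$fwd),
                    bwd = relist_lstm(x$params$seq2one$bwd))
  p$fc1 <- list(W = as.matrix(x$params$fc1$W), b = as.numeric(x$params$fc1$b))
  p$fc2 <- list(W = as.matrix(x$params$fc2$W), b = as.numeric(x$params$fc2$b))
  structure(list(params = p, arch = x$arch, history = as.numeric(x$history),
                 settings = x$settings),
            class = "bilstm_model")
}
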