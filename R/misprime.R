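## PCR mis-priming chimera model: 6-mer binding energy and the two sigmoids
## that govern library construction (A) and per-cell selection (W).

# position-wise pair energies: A-T/T-A = 12, G-C/C-G = 21, all else 0
.pair_energy <- local({
  m <- matrix(0L, 4L, 4L, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- 12L
  m["G", "C"] <- m["C", "G"] <- 21L
  m
})

.check_6mer <- function(s, arg) {
  if (!is.character(s)) stop(sprintf("'%s' must be a character vector", arg))
  if (any(nchar(s) != 6L)) stop(sprintf("'%s' must contain 6-mers", arg))
  if (any(grepl("[^ACGT]", s))) stop(sprintf("'%s' contains non-ACGT characters", arg))
  invisible(s)
}

#' Binding energy between two 6-mers
#'
#' Position-wise sum of pair energies between two hexamers, the "binding
#' energy" \eqn{\psi} of the mis-priming model. Complementary pairs
#' contribute A-T/T-A = 12 and G-C/C-G = 21; all other pairs contribute 0,
#' so \eqn{\psi \in \{0, \ldots, 126\}}.
#'
#' The first hexamer is read off the annealing (primer) strand and the
#' second off the template strand in pairing order, so position i of `s1`
#' faces position i of `s2`.
#'
#' @param s1,s2 character vectors of 6-mers over A/C/G/T (recycled to a
#'   common length).
#' @return integer vector of binding energies.
#' @examples
#' binding_energy("GGGGGG", "CCCCCC") # 126
#' binding_energy("AAAAAA", "AAAAAA") # 0
#' @export
binding_energy <- function(s1, s2) {
  .check_6mer(s1, "s1")
  .check_6mer(s2, "s2")
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n)
  s2 <- rep_len(s2, n)
  if (n == 0L) return(integer(0))
  c1 <- matrix(unlist(strsplit(s1, "", fixed = TRUE), use.names = FALSE), nrow = n, byrow = TRUE)
  c2 <- matrix(unlist(strsplit(s2, "", fixed = TRUE), use.names = FALSE), nrow = n, byrow = TRUE)
  psi <- integer(n)
  for (i in seq_len(6L)) {
    psi <- psi + .pair_energy[cbind(c1[, i], c2[, i])]
  }
  as.integer(psi)
}

#' Mis-priming likelihood of a binding energy
#'
#' The sigmoid \eqn{A(\psi) = 1 / (1 + \exp(180 - 3\psi))} used as the
#' weighting probability when building the chimera library. It is a sharp
#' threshold around \eqn{\psi = 60}: `misprime_likelihood(60)` is exactly
#' 0.5 and the function is non-decreasing in \eqn{\psi}.
#'
#' @param psi numeric vector of binding energies (>= 0).
#' @return numeric vector of likelihoods in (0, 1).
#' @export
misprime_likelihood <- function(psi) {
  stopifnot(is.numeric(psi), all(psi >= 0))
  1 / (1 + exp(180 - 3 * psi))
}

#' Per-cell sampling weight of a binding energy
#'
#' The weight \eqn{W(\psi) = \psi / (1 + \exp(195 - 3\psi))} with which
#' library entries are selected into an individual cell. `sampling_weight(65)`
#' is exactly 32.5; the function is non-decreasing in \eqn{\psi}.
#'
#' @inheritParams misprime_likelihood
#' @return numeric vector of non-negative weights.
#' @export
sampling_weight <- function(psi) {
  stopifnot(is.numeric(psi), all(psi >= 0))
  psi / (1 + exp(195 - 3 * psi))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.comp <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

#' Build a library of potential technical chimeras
#'
#' Samples tuples (T1, b1, T2, b2) of two transcripts and two breakpoints
#' with probability proportional to the mis-priming likelihood
#' \eqn{A(\psi)} of their local 6-mers, by rejection sampling of uniform
#' proposals. Each accepted entry records the two hexamers, the binding
#' energy \eqn{\psi}, the likelihood `A`, the per-cell sampling weight `W`,
#' and the junction construction needed to emit reads later.
#'
#' The annealing geometry (default `orientation = "antiparallel"`) takes
#' `s1` as the 6 bases of T1 ending at `b1` (5'→3') and `s2` as the 6 bases
#' of T2 ending at `b2` read 3'→5' — the antiparallel partner strand — and
#' the chimeric sequence is T1[1..b1] followed by the reverse complement of
#' T2[1..b2], so the read content immediately downstream of the junction is
#' the base-wise complement of `s2` (which matches `s1` at high-energy
#' positions, the artifact signature the classifier learns). With
#' `orientation = "parallel"` the hexamers are paired co-linearly
#' (`s2` = T2[b2+1..b2+6]) and the second segment is the base-wise
#' complement of the downstream sequence.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   transcript sequences.
#' @param size number of library entries (paper-scale runs use millions;
#'   the desk-scale default is 2e4).
#' @param seed integer RNG seed.
#' @param orientation `"antiparallel"` (default) or `"parallel"`; see
#'   Details.
#' @param margin minimum distance of a breakpoint from either transcript
#'   end, so that hexamers and read-length flanks exist. Transcripts shorter
#'   than `2 * margin` are excluded.
#' @param max_propose proposal budget for the rejection sampler.
#' @return a `data.frame` of class `chimera_library` with columns
#'   `t1, b1, t2, b2, s1, s2, psi, A, W`.
#' @export
build_chimera_library <- function(seqs, size = 2e4, seed = 1,
                                  orientation = c("antiparallel", "parallel"),
                                  margin = 110L, max_propose = 500 * size) {
  orientation <- match.arg(orientation)
  if (is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  len <- nchar(seqs)
  ok <- len >= 2L * margin
  if (sum(ok) < 2L) stop("need at least two transcripts longer than 2 * margin")
  seqs <- seqs[ok]
  len <- len[ok]
  ids <- names(seqs)

  set.seed(seed)
  out <- vector("list", 0L)
  got <- 0L
  proposed <- 0L
  chunk <- max(1000L, as.integer(min(size * 20, 2e5)))
  while (got < size && proposed < max_propose) {
    i1 <- sample.int(length(ids), chunk, replace = TRUE)
    i2 <- sample.int(length(ids), chunk, replace = TRUE)
    keep <- i1 != i2
    i1 <- i1[keep]; i2 <- i2[keep]
    # breakpoints at least `margin` from each end
    b1 <- margin + floor(runif(length(i1)) * (len[i1] - 2 * margin + 1))
    b2 <- margin + floor(runif(length(i2)) * (len[i2] - 2 * margin + 1))
    s1 <- substr(seqs[i1], b1 - 5L, b1)
    s2raw <- if (orientation == "antiparallel") {
      # partner strand read 3'->5': hexamer at b2 going leftward
      .rev_string(substr(seqs[i2], b2 - 5L, b2))
    } else {
      substr(seqs[i2], b2 + 1L, b2 + 6L)
    }
    psi <- binding_energy(s1, s2raw)
    acc <- runif(length(psi)) < misprime_likelihood(psi)
    proposed <- proposed + chunk
    if (any(acc)) {
      out[[length(out) + 1L]] <- data.frame(
        t1 = ids[i1][acc], b1 = as.integer(b1[acc]),
        t2 = ids[i2][acc], b2 = as.integer(b2[acc]),
        s1 = s1[acc], s2 = s2raw[acc], psi = psi[acc],
        stringsAsFactors = FALSE
      )
      got <- got + sum(acc)
    }
  }
  if (got < size) {
    warning(sprintf("proposal budget exhausted: %d of %d entries sampled", got, size))
  }
  lib <- do.call(rbind, out)
  if (got > size) lib <- lib[seq_len(size), , drop = FALSE]
  rownames(lib) <- NULL
  lib$A <- misprime_likelihood(lib$psi)
  lib$W <- sampling_weight(lib$psi)
  attr(lib, "orientation") <- orientation
  attr(lib, "margin") <- as.integer(margin)
  class(lib) <- c("chimera_library", "data.frame")
  lib
}

.rev_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Junction-spanning sequence of a chimera library entry
#'
#' Reconstructs `flank` bases on each side of the junction of a library
#' entry, in read orientation: the upstream flank is T1[(b1-flank+1)..b1]
#' and the downstream flank is the start of the second (complemented)
#' segment.
#'
#' @param library a [build_chimera_library()] result.
#' @param seqs the transcript sequences the library was built from.
#' @param flank bases per side.
#' @return character vector of `2 * flank`-length junction windows.
#' @export
chimera_junction_sequence <- function(library, seqs, flank = 30L) {
  if (is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  up <- substr(seqs[library$t1], library$b1 - flank + 1L, library$b1)
  down <- if (identical(attr(library, "orientation"), "parallel")) {
    .comp(substr(seqs[library$t2], library$b2 + 1L, library$b2 + flank))
  } else {
    .revcomp(substr(seqs[library$t2], library$b2 - flank + 1L, library$b2))
  }
  paste0(up, down)
}
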