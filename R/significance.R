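## Resampling-based significance against the fitted ZINB background and
## the two-subset empirical FDR cutoff selection.

#' Resampled null distribution of a candidate's total support
#'
#' Draws `B` replicates of the candidate's per-cell counts from its fitted
#' background law ZINB(p, mu_j, lambda), sums each replicate over cells,
#' and returns the sample mean and standard deviation of the resampled
#' totals. Reproducible for a given `seed`.
#'
#' @param p fitted zero probability of the candidate.
#' @param mu fitted per-cell NB means (length = number of cells).
#' @param lambda fitted shared overdispersion.
#' @param B number of resamples (default 1000).
#' @param seed integer seed.
#' @return named numeric vector `c(nu, sigma)`.
#' @export
resample_null_sum <- function(p, mu, lambda, B = 1000L, seed = 1L) {
  stopifnot(B >= 2L, p >= 0, p <= 1, all(mu > 0), lambda > 0)
  n <- length(mu)
  set.seed(seed)
  nz <- runif(B * n) >= p           # cells with a positive draw, by replicate
  k <- sum(nz)
  s <- numeric(B)
  if (k > 0) {
    cell <- rep(seq_len(n), times = B)[nz]
    repl <- rep(seq_len(B), each = n)[nz]
    m <- mu[cell]
    phi0 <- exp(.nb_logpmf(0, m, lambda))
    u <- pmin(phi0 + runif(k) * (1 - phi0), 1 - 1e-12)
    y <- pmax(1L, qnbinom(u, size = 1 / lambda, mu = m))
    s <- as.numeric(rowsum(y, factor(repl, levels = seq_len(B))))
  }
  c(nu = mean(s), sigma = sd(s))
}

#' Normal-approximation p-value of a candidate
#'
#' Upper-tail p-value \eqn{1 - \Phi((S - \nu) / \sigma)} of the observed
#' total support against the resampled null mean and SD. When the null is
#' degenerate (`sigma == 0`), the p-value is 1 if `S <= nu` and 0
#' otherwise.
#'
#' @param S observed total supporting reads of the candidate.
#' @param nu,sigma resampled mean and SD from [resample_null_sum()].
#' @return p-value in \[0, 1\] (vectorized).
#' @export
candidate_pvalue <- function(S, nu, sigma) {
  ifelse(sigma > 0,
         pnorm((S - nu) / sigma, lower.tail = FALSE),
         as.numeric(S <= nu))
}

#' Test all candidates against the fitted background
#'
#' Computes the resampled null mean/SD and the normal-approximation
#' p-value for every candidate row. Each candidate uses an RNG substream
#' derived from the master seed and its row index, so serial and subsetted
#' runs agree.
#'
#' @param fit a [fit_background()] result.
#' @param covariates a [candidate_covariates()] object.
#' @param counts candidate-by-cell support matrix aligned with
#'   `covariates`.
#' @param B resamples per candidate.
#' @param seed master seed.
#' @return data.frame: `candidate_id`, `S`, `nu`, `sigma`, `pvalue`.
#' @export
test_candidates <- function(fit, covariates, counts, B = 1000L, seed = 1L) {
  pred <- predict_background(fit, covariates)
  N <- nrow(counts)
  stopifnot(length(pred$p) == N)
  S <- as.numeric(Matrix::rowSums(counts))
  nu <- numeric(N); sig <- numeric(N)
  for (i in seq_len(N)) {
    ns <- resample_null_sum(pred$p[i], pred$mu[i, ], pred$lambda, B = B,
                            seed = (seed + i) %% .Machine$integer.max)
    nu[i] <- ns["nu"]; sig[i] <- ns["sigma"]
  }
  data.frame(candidate_id = covariates$candidate_ids,
             S = S, nu = nu, sigma = sig,
             pvalue = candidate_pvalue(S, nu, sig),
             stringsAsFactors = FALSE)
}

#' High-quality subset membership
#'
#' Splits candidates into the high-quality subset (used as subset 1 of the
#' empirical FDR procedure) and the rest: a candidate qualifies when at
#' least `hq_cell_fraction` of all cells support it and its supporting
#' cells carry at least `hq_mean_reads` reads each on average (the average
#' is over supporting cells).
#'
#' @param counts candidate-by-cell support matrix.
#' @param hq_cell_fraction minimum supporting-cell fraction (default 0.01).
#' @param hq_mean_reads minimum mean supporting reads per supporting cell
#'   (default 1.25).
#' @return logical vector, `TRUE` for high-quality candidates.
#' @export
split_high_quality <- function(counts, hq_cell_fraction = 0.01,
                               hq_mean_reads = 1.25) {
  n <- ncol(counts)
  k <- as.numeric(Matrix::rowSums(counts > 0))
  tot <- as.numeric(Matrix::rowSums(counts))
  mean_reads <- ifelse(k > 0, tot / k, 0)
  k >= hq_cell_fraction * n & mean_reads >= hq_mean_reads
}

#' Empirical FDR of a p-value cutoff
#'
#' \eqn{fdr(c) = (m_2(c) / n_2) \cdot (n_1 + n_2) / (m_1(c) + m_2(c))},
#' where subsets 1 and 2 are the high-quality and remaining candidates,
#' \eqn{n_k} their sizes and \eqn{m_k(c)} the number of their p-values at
#' or below `c`. Defined as 0 when no p-value is at or below `c`.
#'
#' @param cutoff p-value cutoff(s).
#' @param pvalues candidate p-values.
#' @param high_quality logical subset-1 membership (see
#'   [split_high_quality()]).
#' @return numeric vector of estimated FDRs.
#' @export
empirical_fdr <- function(cutoff, pvalues, high_quality) {
  n1 <- sum(high_quality); n2 <- sum(!high_quality)
  stopifnot(n2 > 0)
  vapply(cutoff, function(cc) {
    m1 <- sum(pvalues[high_quality] <= cc)
    m2 <- sum(pvalues[!high_quality] <= cc)
    if (m1 + m2 == 0) return(0)
    (m2 / n2) * (n1 + n2) / (m1 + m2)
  }, numeric(1))
}

#' Choose the p-value cutoff controlling the empirical FDR
#'
#' Evaluates [empirical_fdr()] at every observed p-value (the estimate is
#' a step function between observed values) and returns the largest cutoff
#' with estimated FDR at most `alpha`. If no cutoff qualifies, 0 is
#' returned with a warning and no candidate passes.
#'
#' @param pvalues candidate p-values.
#' @param high_quality logical subset-1 membership; the procedure requires
#'   at least one candidate outside subset 1.
#' @param alpha target FDR (default 0.05).
#' @return list with `cutoff`, `passed` (logical per candidate), and
#'   `table` (cutoff grid with `fdr` values).
#' @export
select_fdr_cutoff <- function(pvalues, high_quality, alpha = 0.05) {
  stopifnot(length(pvalues) == length(high_quality), alpha > 0, alpha < 1,
            !anyNA(pvalues))
  if (!any(!high_quality)) stop("empirical FDR undefined: no candidates outside the high-quality subset")
  grid <- sort(unique(pvalues))
  fdr <- empirical_fdr(grid, pvalues, high_quality)
  feasible <- grid[fdr <= alpha & vapply(grid, function(cc) any(pvalues <= cc), logical(1))]
  if (!length(feasible)) {
    warning("no p-value cutoff attains the target FDR; returning 0 (nothing passes)")
    cutoff <- 0
  } else {
    cutoff <- max(feasible)
  }
  list(cutoff = cutoff,
       passed = pvalues <= cutoff & cutoff > 0,
       table = data.frame(cutoff = grid, fdr = fdr))
}
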