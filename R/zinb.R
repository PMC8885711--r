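## Zero-inflated negative binomial background model for technical chimeric
## noise. The per-candidate zero probability p_i follows a logistic
## regression with a spline GC term and the candidate-level mean partner
## expressions; the NB mean mu_ij follows a log-linear regression with the
## same spline term and the per-cell partner expressions; the NB
## overdispersion lambda (Var = mu + lambda * mu^2) is shared by all
## candidates and cells. Fitting maximizes the product over candidates of
## the conditional likelihood given >= 2 supporting cells.

.CLAMP <- 30  # link-scale guard before exponentiation
# overdispersion box: beyond ~50 the zero-truncated NB is numerically
# indistinguishable from its logarithmic-series limit at these counts and
# the boundary destabilizes the resampling step
.LAMBDA_RANGE <- c(1e-3, 50)

#' Cubic B-spline basis on \[0, 1\]
#'
#' Evaluates `K` B-spline basis functions at GC fractions `t`. The basis is
#' a partition of unity (rows sum to 1). Interior knots default to
#' quantiles of `t`; for `K` below `degree + 1` the degree is reduced, and
#' `K = 1` gives the constant basis. Values outside \[0, 1\] are clamped
#' with a warning.
#'
#' @param t numeric vector of GC fractions.
#' @param K number of basis functions (default 5).
#' @param knots optional interior knots (length `K - degree - 1`).
#' @param degree spline degree (default 3, cubic).
#' @return numeric matrix (length(t) x K) with attributes `knots`,
#'   `degree`, `boundary`.
#' @export
spline_basis <- function(t, K = 5L, knots = NULL, degree = 3L) {
  stopifnot(K >= 1L)
  if (any(t < 0 | t > 1, na.rm = TRUE)) {
    warning("GC fractions outside [0, 1] clamped")
    t <- pmin(pmax(t, 0), 1)
  }
  if (K == 1L) {
    B <- matrix(1, length(t), 1L)
    attr(B, "knots") <- numeric(0); attr(B, "degree") <- 0L
    attr(B, "boundary") <- c(0, 1)
    return(B)
  }
  degree <- min(degree, K - 1L)
  n_int <- K - degree - 1L
  if (is.null(knots)) {
    knots <- if (n_int > 0L) {
      q <- quantile(t, probs = seq_len(n_int) / (n_int + 1), na.rm = TRUE, names = FALSE)
      pmin(pmax(q, 1e-6), 1 - 1e-6)
    } else numeric(0)
  }
  stopifnot(length(knots) == n_int)
  aug <- c(rep(0, degree + 1L), sort(knots), rep(1, degree + 1L))
  # evaluate at the right boundary by the left-limit convention
  x <- pmin(t, 1 - 1e-12)
  B <- splines::splineDesign(aug, x, ord = degree + 1L)
  at_one <- t >= 1 - 1e-12
  if (any(at_one)) B[at_one, K] <- B[at_one, K] + (1 - rowSums(B[at_one, , drop = FALSE]))
  attr(B, "knots") <- as.numeric(sort(knots)); attr(B, "degree") <- as.integer(degree)
  attr(B, "boundary") <- c(0, 1)
  B
}

# log NB density in (mu, lambda) parameterization; size = 1 / lambda
.nb_logpmf <- function(y, mu, lambda) {
  dnbinom(y, size = 1 / lambda, mu = mu, log = TRUE)
}

#' Log probability mass of the zero-inflated negative binomial
#'
#' Two-part law used for the background noise: \eqn{P(Y = 0) = p} exactly,
#' and conditional on \eqn{Y > 0}, \eqn{Y} follows a zero-truncated
#' negative binomial with mean `mu` and overdispersion `lambda`
#' (\eqn{Var = \mu + \lambda \mu^2}).
#'
#' @param y non-negative integer counts.
#' @param p zero probability in (0, 1).
#' @param mu positive NB mean (recycled with `y`).
#' @param lambda positive shared overdispersion.
#' @return numeric vector of log probabilities.
#' @export
zinb_logpmf <- function(y, p, mu, lambda) {
  stopifnot(all(p > 0 & p < 1), all(mu > 0), lambda > 0, all(y >= 0))
  n <- max(length(y), length(mu), length(p))
  y <- rep_len(y, n); mu <- rep_len(mu, n); p <- rep_len(p, n)
  out <- numeric(n)
  z <- y == 0
  out[z] <- log(p[z])
  if (any(!z)) {
    phi0 <- .nb_logpmf(0, mu[!z], lambda)
    out[!z] <- log1p(-p[!z]) + .nb_logpmf(y[!z], mu[!z], lambda) -
      log1p(-exp(phi0))
  }
  out
}

#' Draw from the zero-inflated negative binomial
#'
#' @param n number of draws.
#' @inheritParams zinb_logpmf
#' @return integer vector of counts.
#' @export
rzinb <- function(n, p, mu, lambda) {
  stopifnot(all(p > 0 & p < 1) || all(p >= 0 & p <= 1))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  y <- integer(n)
  nz <- runif(n) >= p
  if (any(nz)) {
    phi0 <- exp(.nb_logpmf(0, mu[nz], lambda))
    u <- pmin(phi0 + runif(sum(nz)) * (1 - phi0), 1 - 1e-12)
    y[nz] <- pmax(1L, qnbinom(u, size = 1 / lambda, mu = mu[nz]))
  }
  y
}

#' Conditional log-likelihood of one candidate row
#'
#' Log-likelihood of the per-cell counts of one candidate under the ZINB
#' background, conditional on the candidate being observed — i.e. on at
#' least two cells having a supporting read. The conditioning event has
#' probability \eqn{1 - p^n - n (1 - p) p^{n - 1}}, and the unconditional
#' term of each cell is \eqn{p} for a zero count and
#' \eqn{(1 - p)\,\phi(y;\mu_j,\lambda) / (1 - \phi(0;\mu_j,\lambda))} for a
#' positive count, where \eqn{\phi} is the NB density. Summing
#' `exp(conditional_candidate_loglik())` over all count vectors with at
#' least two positive entries gives 1.
#'
#' @param y integer vector of per-cell counts (length n, at least two
#'   positive entries).
#' @param p candidate zero probability in (0, 1).
#' @param mu NB means, scalar or per-cell vector.
#' @param lambda shared overdispersion.
#' @return scalar log-likelihood.
#' @export
conditional_candidate_loglik <- function(y, p, mu, lambda) {
  n <- length(y)
  if (sum(y > 0) < 2L) stop("conditioning event requires >= 2 cells with positive counts")
  stopifnot(p > 0, p < 1, all(mu > 0), lambda > 0)
  mu <- rep_len(mu, n)
  num <- sum(zinb_logpmf(y, p, mu, lambda))
  denom <- 1 - p^n - n * (1 - p) * p^(n - 1)
  num - log(max(denom, 1e-300))
}

#' Per-candidate and per-cell covariates for the background model
#'
#' Assembles the model covariates: the junction GC fraction \eqn{t_i}
#' (missing values are imputed with the median and flagged), and the
#' partner-gene expressions per cell sorted so that
#' \eqn{e_{1ij} \le e_{2ij}}, optionally log1p-transformed (the default;
#' supporting-read counts are close to linear in log expression).
#' Candidate-level means \eqn{\bar e_{1i} \le \bar e_{2i}} are the row
#' means of the sorted per-cell values.
#'
#' @param candidates a `fusion_candidates` object.
#' @param expr numeric gene-by-cell expression matrix (TPM-like), row names
#'   gene ids, column names cell ids covering `candidates$cells`.
#' @param annotation,seqs used to compute the GC covariate via
#'   [compute_gc_content()]; alternatively pass `gc` directly.
#' @param gc optional numeric vector of GC fractions per candidate.
#' @param scale `"log1p"` (default) or `"raw"` expression scale.
#' @param window_bp GC window width.
#' @return object of class `cell_covariates`: list with `gc`, `gc_missing`,
#'   `e1`, `e2` (candidate-by-cell matrices), `ebar1`, `ebar2`,
#'   `candidate_ids`, `cells`, `scale`.
#' @export
candidate_covariates <- function(candidates, expr, annotation = NULL, seqs = NULL,
                                 gc = NULL, scale = c("log1p", "raw"),
                                 window_bp = 200L) {
  scale <- match.arg(scale)
  cd <- candidates$candidates
  cells <- candidates$cells
  stopifnot(all(cells %in% colnames(expr)))
  missing_genes <- setdiff(unique(c(cd$gene5, cd$gene3)), rownames(expr))
  if (length(missing_genes)) {
    add <- matrix(0, length(missing_genes), ncol(expr),
                  dimnames = list(missing_genes, colnames(expr)))
    expr <- rbind(expr, add)
  }
  if (is.null(gc)) {
    gc <- if (!is.null(annotation) && !is.null(seqs)) {
      compute_gc_content(candidates, annotation, seqs, window_bp = window_bp)
    } else rep(NA_real_, nrow(cd))
  }
  gc_missing <- is.na(gc)
  if (all(gc_missing)) {
    gc[] <- 0.5
  } else if (any(gc_missing)) {
    gc[gc_missing] <- median(gc, na.rm = TRUE)
  }
  x5 <- as.matrix(expr[cd$gene5, cells, drop = FALSE])
  x3 <- as.matrix(expr[cd$gene3, cells, drop = FALSE])
  if (scale == "log1p") { x5 <- log1p(x5); x3 <- log1p(x3) }
  e1 <- pmin(x5, x3); e2 <- pmax(x5, x3)
  dimnames(e1) <- dimnames(e2) <- list(cd$id, cells)
  structure(list(gc = as.numeric(gc), gc_missing = gc_missing,
                 e1 = e1, e2 = e2,
                 ebar1 = rowMeans(e1), ebar2 = rowMeans(e2),
                 candidate_ids = cd$id, cells = cells, scale = scale),
            class = "cell_covariates")
}

# unpack the joint parameter vector used by the optimizer
.theta_unpack <- function(th, K) {
  list(beta1 = c(th[1], th[K + 2], th[K + 3]),
       beta_f = th[2:(K + 1)],
       beta2 = c(th[K + 4], th[2 * K + 5], th[2 * K + 6]),
       beta_g = th[(K + 5):(2 * K + 4)],
       lambda = exp(th[2 * K + 7]))
}

#' Fit the ZINB background-noise model
#'
#' Maximizes the product over candidates of
#' [conditional_candidate_loglik()] — the likelihood of all supporting-read
#' counts conditional on each retained candidate having at least two
#' supporting cells — over the regression coefficients and the shared
#' overdispersion, by quasi-Newton optimization of the joint parameter
#' vector (overdispersion on the log scale). One moment-based start plus
#' `restarts` seeded random perturbations are run and the best optimum is
#' kept. The spline basis is centered on the training candidates so the
#' intercepts are identified.
#'
#' Candidates with an imputed (originally missing) GC covariate are
#' excluded from fitting but can still be scored via
#' [predict_background()].
#'
#' @param counts candidate-by-cell count matrix (dense or
#'   [Matrix::sparseMatrix()]); every row must have at least two positive
#'   entries.
#' @param covariates a [candidate_covariates()] object aligned with
#'   `counts` rows.
#' @param K number of spline basis functions (default 5).
#' @param restarts number of random restarts on top of the moment start.
#' @param seed RNG seed for the restarts.
#' @param maxit optimizer iteration cap per start.
#' @return object of class `zinb_background`: coefficient blocks `beta1`
#'   (\eqn{\beta_{10},\beta_{11},\beta_{12}}), `beta2`
#'   (\eqn{\beta_{20},\beta_{21},\beta_{22}}), `beta_f`, `beta_g`,
#'   `lambda`, spline metadata (`knots`, `degree`, `basis_center`),
#'   `loglik`, `convergence`, `starts` (per-start initial/final
#'   objectives), `n_cells`, `expr_scale`.
#' @export
fit_background <- function(counts, covariates, K = 5L, restarts = 3L,
                           seed = 17L, maxit = 500L) {
  stopifnot(is(covariates, "cell_covariates"))
  Y <- as(counts, "CsparseMatrix")
  N <- nrow(Y); n <- ncol(Y)
  nz_per_row <- Matrix::rowSums(Y > 0)
  if (any(nz_per_row < 2)) {
    stop("all rows must have >= 2 supporting cells; apply min_cell_filter() first")
  }
  use <- which(!covariates$gc_missing)
  if (length(use) < 5L) use <- seq_len(N)  # too few complete rows: fit on all
  t_i <- covariates$gc[use]
  B <- spline_basis(t_i, K = K)
  ctr <- colMeans(B)
  Bc <- sweep(B, 2, ctr)
  Xp <- cbind(1, Bc, covariates$ebar1[use], covariates$ebar2[use])

  sm <- methods::as(Y[use, , drop = FALSE], "TsparseMatrix")
  ri <- sm@i + 1L; ci <- sm@j + 1L; y_nz <- sm@x
  e1_nz <- covariates$e1[use, , drop = FALSE][cbind(ri, ci)]
  e2_nz <- covariates$e2[use, , drop = FALSE][cbind(ri, ci)]
  Xmu <- cbind(1, Bc[ri, , drop = FALSE], e1_nz, e2_nz)
  z_i <- n - tabulate(ri, nbins = length(use))

  negll <- function(th) {
    pr <- .theta_unpack(th, K)
    eta_p <- drop(Xp %*% c(pr$beta1[1], pr$beta_f, pr$beta1[2], pr$beta1[3]))
    eta_p <- pmin(pmax(eta_p, -.CLAMP), .CLAMP)
    p <- plogis(eta_p)
    eta_mu <- drop(Xmu %*% c(pr$beta2[1], pr$beta_g, pr$beta2[2], pr$beta2[3]))
    mu <- exp(pmin(pmax(eta_mu, -.CLAMP), .CLAMP))
    lam <- pr$lambda
    phi0 <- exp(.nb_logpmf(0, mu, lam))
    num <- sum(z_i * log(p)) +
      sum(log1p(-p[ri]) + .nb_logpmf(y_nz, mu, lam) - log1p(-phi0))
    denom <- 1 - p^n - n * (1 - p) * p^(n - 1)
    ll <- num - sum(log(pmax(denom, 1e-300)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # moment start: overall zero fraction and mean positive count
  zfrac <- min(max(sum(z_i) / (length(use) * n), 1e-3), 1 - 1e-3)
  th0 <- c(qlogis(zfrac), rep(0, K), 0, 0,
           log(max(mean(y_nz), 0.2)), rep(0, K), 0, 0, 0)
  set.seed(seed)
  starts <- c(list(th0), lapply(seq_len(restarts), function(r)
    th0 + rnorm(length(th0), 0, 0.5)))
  lower <- rep(-Inf, length(th0)); upper <- rep(Inf, length(th0))
  lower[length(th0)] <- log(.LAMBDA_RANGE[1])
  upper[length(th0)] <- log(.LAMBDA_RANGE[2])
  fits <- lapply(starts, function(s) {
    f <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e7)),
      error = function(e) list(par = s, value = negll(s), convergence = 99L))
    f$init_value <- negll(s)
    f
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  if (all(vapply(fits, `[[`, numeric(1), "convergence") != 0)) {
    warning("optimizer did not report convergence from any start; returning best iterate")
  }
  pr <- .theta_unpack(best$par, K)
  structure(list(
    beta1 = pr$beta1, beta2 = pr$beta2,
    beta_f = pr$beta_f, beta_g = pr$beta_g,
    lambda = pr$lambda, K = as.integer(K),
    knots = attr(B, "knots"), degree = attr(B, "degree"),
    basis_center = ctr,
    loglik = -best$value,
    convergence = best$convergence,
    starts = data.frame(init = vapply(fits, `[[`, numeric(1), "init_value"),
                        final = vals),
    n_cells = n,
    fitted_rows = use,
    expr_scale = covariates$scale
  ), class = "zinb_background")
}

#' @export
print.zinb_background <- function(x, ...) {
  cat(sprintf(paste0(
    "zinb_background: K = %d spline basis, lambda = %.4g, loglik = %.2f\n",
    "  beta1 (zero part) = %s\n  beta2 (mean part) = %s\n"),
    x$K, x$lambda, x$loglik,
    paste(sprintf("%.3f", x$beta1), collapse = ", "),
    paste(sprintf("%.3f", x$beta2), collapse = ", ")))
  invisible(x)
}

#' Fitted background parameters for a set of candidates
#'
#' Evaluates the fitted regressions at the supplied covariates, returning
#' the per-candidate zero probability and the candidate-by-cell NB mean
#' matrix.
#'
#' @param fit a [fit_background()] result.
#' @param covariates a [candidate_covariates()] object (any candidates, not
#'   only those used in fitting; imputed GC values are used as-is).
#' @return list with `p` (vector in (0,1)), `mu` (matrix > 0), `lambda`.
#' @export
predict_background <- function(fit, covariates) {
  stopifnot(is(covariates, "cell_covariates"))
  B <- spline_basis(covariates$gc, K = fit$K, knots = fit$knots,
                    degree = if (fit$K > 1L) fit$degree else 3L)
  Bc <- sweep(B, 2, fit$basis_center)
  eta_p <- fit$beta1[1] + drop(Bc %*% fit$beta_f) +
    fit$beta1[2] * covariates$ebar1 + fit$beta1[3] * covariates$ebar2
  p <- plogis(pmin(pmax(eta_p, -.CLAMP), .CLAMP))
  f_gc <- drop(Bc %*% fit$beta_g)
  eta_mu <- fit$beta2[1] + f_gc +
    fit$beta2[2] * covariates$e1 + fit$beta2[3] * covariates$e2
  mu <- exp(pmin(pmax(eta_mu, -.CLAMP), .CLAMP))
  list(p = p, mu = mu, lambda = fit$lambda)
}

#' Save / load a fitted background model
#'
#' Plain-text JSON persistence of all coefficients, knots, the shared
#' overdispersion and covariate-scaling metadata.
#'
#' @param fit a `zinb_background` object.
#' @param path file path.
#' @return `read_background()` returns the restored `zinb_background`.
#' @export
write_background <- function(fit, path) {
  keep <- c("beta1", "beta2", "beta_f", "beta_g", "lambda", "K", "knots",
            "degree", "basis_center", "loglik", "n_cells", "expr_scale")
  jsonlite::write_json(fit[keep], path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$K <- as.integer(x$K); x$degree <- as.integer(x$degree)
  x$knots <- as.numeric(x$knots)
  structure(x, class = "zinb_background")
}
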