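# ZINB background model: spline basis against a hand-coded Cox-de Boor
# recursion, the two-part probability law, the conditional likelihood
# against an independent transcription of its formula, and the fit.

# independent oracle: textbook Cox-de Boor recursion
cox_de_boor <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- matrix(0, length(x), n_basis)
  for (j in seq_len(n_basis)) {
    B[, j] <- vapply(x, function(xx) .cdb_rec(xx, j, degree, knots), numeric(1))
  }
  B
}
.cdb_rec <- function(x, j, d, k) {
  if (d == 0) {
    # half-open intervals, closed at the right boundary
    return(as.numeric(x >= k[j] & (x < k[j + 1] ||
                                     (x == k[j + 1] && k[j + 1] == k[length(k)]))))
  }
  a <- if (k[j + d] > k[j]) (x - k[j]) / (k[j + d] - k[j]) * .cdb_rec(x, j, d - 1, k) else 0
  b <- if (k[j + d + 1] > k[j + 1])
    (k[j + d + 1] - x) / (k[j + d + 1] - k[j + 1]) * .cdb_rec(x, j + 1, d - 1, k) else 0
  a + b
}

test_that("spline basis is a partition of unity and matches Cox-de Boor", {
  t <- seq(0, 1, length.out = 101)
  B <- spline_basis(t, K = 5, knots = 0.4)
  expect_identical(dim(B), c(101L, 5L))
  expect_true(all(abs(rowSums(B) - 1) < 1e-12))
  aug <- c(rep(0, 4), 0.4, rep(1, 4))
  expect_equal(unclass(B)[, ], cox_de_boor(t, aug, 3L), tolerance = 1e-12,
               ignore_attr = TRUE)
  # K = 1 gives the constant basis
  expect_true(all(spline_basis(c(0, 0.5, 1), K = 1) == 1))
  # out-of-range values are clamped with a warning
  expect_warning(B2 <- spline_basis(c(-0.2, 1.3), K = 5, knots = 0.4), "clamped")
  expect_equal(B2[1, ], B[1, ], ignore_attr = TRUE)
})

test_that("zinb log-pmf is the two-part law and normalizes", {
  expect_identical(zinb_logpmf(0, 0.7, 2, 1), log(0.7))
  expect_equal(sum(exp(zinb_logpmf(0:500, 0.7, 2, 1.3))), 1, tolerance = 1e-8)
  # oracle composition: stock NB density with explicit zero truncation
  p <- 0.9; mu <- 2; lam <- 1; y <- 3
  ref <- log((1 - p) * dnbinom(y, size = 1 / lam, mu = mu) /
               (1 - dnbinom(0, size = 1 / lam, mu = mu)))
  expect_equal(zinb_logpmf(y, p, mu, lam), ref, tolerance = 1e-12)
  expect_error(zinb_logpmf(1, 1.2, 2, 1))
})

# independent transcription of the conditional likelihood: the per-cell
# two-part terms divided by the probability of >= 2 supporting cells
ref_conditional <- function(y, p, mu, lambda) {
  n <- length(y); mu <- rep_len(mu, n)
  phi <- function(x, m) dnbinom(x, size = 1 / lambda, mu = m)
  terms <- ifelse(y == 0, p, (1 - p) * phi(y, mu) / (1 - phi(0, mu)))
  log(prod(terms)) - log(1 - p^n - n * (1 - p) * p^(n - 1))
}

test_that("conditional likelihood matches an independent transcription on random draws", {
  set.seed(42)
  for (r in 1:100) {
    n <- sample(3:12, 1)
    p <- runif(1, 0.05, 0.95)
    mu <- runif(n, 0.2, 5)
    lam <- runif(1, 0.2, 3)
    y <- rzinb(n, p, mu, lam)
    while (sum(y > 0) < 2) y <- rzinb(n, p, mu, lam)
    expect_equal(conditional_candidate_loglik(y, p, mu, lam),
                 ref_conditional(y, p, mu, lam), tolerance = 1e-8)
  }
  expect_error(conditional_candidate_loglik(c(0, 0, 1), 0.5, 1, 1), ">= 2 cells")
})

test_that("conditional probabilities sum to one over the conditioning event", {
  p <- 0.6; mu <- c(0.8, 1.2, 0.5); lam <- 0.7
  tot <- 0
  for (y1 in 0:30) for (y2 in 0:30) for (y3 in 0:30) {
    y <- c(y1, y2, y3)
    if (sum(y > 0) >= 2) tot <- tot + exp(conditional_candidate_loglik(y, p, mu, lam))
  }
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("conditional likelihood approaches the unconditional one as p -> 0", {
  y <- c(2, 1, 3); mu <- c(1, 2, 1.5); lam <- 0.8
  p <- 1e-9
  uncond <- sum(zinb_logpmf(y, p, mu, lam))
  expect_equal(conditional_candidate_loglik(y, p, mu, lam), uncond, tolerance = 1e-6)
})

test_that("background fit recovers an intercept-only model found by a profile scan", {
  set.seed(31)
  N <- 200; n <- 60
  p0 <- 0.75; mu0 <- 1.6; lam0 <- 1
  Y <- matrix(rzinb(N * n, p0, mu0, lam0), N, n)
  keep <- rowSums(Y > 0) >= 2
  Y <- Y[keep, , drop = FALSE]
  gc <- rep(0.5, nrow(Y))
  e0 <- matrix(0, nrow(Y), n)
  cov <- manual_covariates(gc, e0, e0)
  fit <- fit_background(Matrix::Matrix(Y, sparse = TRUE), cov, K = 1,
                        restarts = 1)
  # constant covariates: fitted mu identical across cells
  pred <- predict_background(fit, cov)
  expect_lt(diff(range(pred$mu)), 1e-8)
  expect_lt(diff(range(pred$p)), 1e-8)
  # 1-D profile-likelihood scan over mu at the fitted (p, lambda)
  z <- sum(Y == 0); nz <- Y[Y > 0]
  prof <- function(m) {
    phat <- pred$p[1]
    z * log(phat) +
      sum(log(1 - phat) + dnbinom(nz, size = 1 / fit$lambda, mu = m, log = TRUE) -
            log(1 - dnbinom(0, size = 1 / fit$lambda, mu = m))) -
      nrow(Y) * log(1 - phat^n - n * (1 - phat) * phat^(n - 1))
  }
  grid <- seq(0.5 * pred$mu[1], 2 * pred$mu[1], length.out = 400)
  best <- grid[which.max(vapply(grid, prof, numeric(1)))]
  expect_equal(pred$mu[1], best, tolerance = 0.02)
  # and the recovered parameters are near the truth
  expect_equal(pred$p[1], p0, tolerance = 0.1)
  expect_equal(pred$mu[1], mu0, tolerance = 0.25)
})

test_that("fit is invariant to candidate order and never worsens its objective", {
  set.seed(77)
  N <- 80; n <- 40
  gc <- runif(N, 0.2, 0.8)
  e_a <- matrix(rexp(N * n), N, n); e_b <- matrix(rexp(N * n), N, n)
  e1 <- pmin(e_a, e_b); e2 <- pmax(e_a, e_b)
  B <- spline_basis(gc, K = 5); Bc <- sweep(B, 2, colMeans(B))
  p <- plogis(1.0 + drop(Bc %*% c(.3, -.2, .1, .2, -.3)) + 0.1 * rowMeans(e1))
  mu <- exp(-0.2 + 0.2 * e1 + 0.3 * e2)
  Y <- matrix(0L, N, n)
  for (i in seq_len(N)) Y[i, ] <- rzinb(n, p[i], mu[i, ], 0.8)
  keep <- rowSums(Y > 0) >= 2
  Y <- Y[keep, ]; gc <- gc[keep]; e1 <- e1[keep, ]; e2 <- e2[keep, ]
  cov <- manual_covariates(gc, e1, e2)
  fit <- fit_background(Matrix::Matrix(Y, sparse = TRUE), cov, restarts = 1)
  # optimizer improves on every start
  expect_true(all(fit$starts$final <= fit$starts$init + 1e-6))
  # permuted candidate order gives the same estimates
  o <- sample(nrow(Y))
  cov_o <- manual_covariates(gc[o], e1[o, , drop = FALSE], e2[o, , drop = FALSE])
  fit_o <- fit_background(Matrix::Matrix(Y[o, ], sparse = TRUE), cov_o, restarts = 1)
  expect_equal(fit_o$lambda, fit$lambda, tolerance = 1e-3)
  expect_equal(fit_o$beta2, fit$beta2, tolerance = 1e-3)
  # fitted p and mu stay in their domains
  pred <- predict_background(fit, cov)
  expect_true(all(pred$p > 0 & pred$p < 1))
  expect_true(all(pred$mu > 0 & is.finite(pred$mu)))
  # rows below the conditioning threshold are rejected
  Ybad <- Y; Ybad[1, ] <- 0
  expect_error(fit_background(Matrix::Matrix(Ybad, sparse = TRUE), cov), "min_cell_filter")
})

test_that("fitted model persists through its JSON file", {
  set.seed(15)
  N <- 60; n <- 30
  Y <- matrix(rzinb(N * n, 0.7, 1.5, 1), N, n)
  keep <- rowSums(Y > 0) >= 2
  Y <- Y[keep, , drop = FALSE]
  cov <- manual_covariates(runif(nrow(Y), 0.3, 0.7),
                           matrix(rexp(nrow(Y) * n), nrow(Y), n),
                           matrix(rexp(nrow(Y) * n) + 1, nrow(Y), n))
  fit <- suppressWarnings(
    fit_background(Matrix::Matrix(Y, sparse = TRUE), cov, restarts = 0))
  path <- tempfile(fileext = ".json")
  write_background(fit, path)
  back <- read_background(path)
  expect_equal(back$beta2, fit$beta2, tolerance = 1e-12)
  expect_equal(back$lambda, fit$lambda, tolerance = 1e-12)
  p1 <- predict_background(fit, cov); p2 <- predict_background(back, cov)
  expect_equal(p2$mu, p1$mu, tolerance = 1e-10)
})
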