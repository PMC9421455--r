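# Independent dense-matrix REML oracle.
#
# Used by the test-suite to cross-check the lme4 route: the restricted
# log-likelihood is evaluated from its textbook definition with dense
# linear algebra, and maximized by a general-purpose optimizer from random
# starts. Only suitable for small n.

#' Restricted log-likelihood, dense evaluation
#'
#' `l_R = -1/2 [(n - p) log 2pi + log|V| + log|X'V^-1 X| + r'V^-1 r]` with
#' `V = sigma^2 I + Z G Z'`, `G` block-diagonal per group with common
#' covariance `Psi`, and `r` the GLS residual.
#'
#' @param y Response vector.
#' @param X Fixed-effect design (n x p).
#' @param W Per-row random-effect covariates (n x q).
#' @param group Grouping factor (length n).
#' @param Psi q x q random-effect covariance.
#' @param sigma Residual SD.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik_dense <- function(y, X, W, group, Psi, sigma) {
  n <- length(y); p <- ncol(X)
  V <- diag(sigma^2, n)
  for (s in split(seq_len(n), group)) {
    Ws <- W[s, , drop = FALSE]
    V[s, s] <- V[s, s] + Ws %*% Psi %*% t(Ws)
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(-Inf)
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * ((n - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(ch2))) +
            drop(crossprod(r, Vi_r)))
}

# log-Cholesky parameterization: par = c(log-diag + offdiag of the lower
# Cholesky factor of Psi (column order), log sigma).
#' @keywords internal
par_to_psi <- function(par, q) {
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- par[seq_len(q * (q + 1) / 2)]
  diag(L) <- exp(diag(L))
  list(Psi = L %*% t(L), sigma = exp(par[q * (q + 1) / 2 + 1L]))
}

#' Maximize the dense REML criterion with a general-purpose optimizer
#'
#' Nelder-Mead/BFGS from `n_starts` random admissible starting points in a
#' log-Cholesky parameterization. Returns the best restricted log-likelihood
#' found and the corresponding parameters; an independent check on the
#' production REML route.
#'
#' @inheritParams reml_loglik_dense
#' @param n_starts Number of random restarts.
#' @param seed Seed for the random starts (local RNG).
#' @return List with `loglik`, `Psi`, `sigma`.
#' @export
fit_reml_oracle <- function(y, X, W, group, n_starts = 20L, seed = 1L) {
  q <- ncol(W)
  npar <- q * (q + 1) / 2 + 1L
  obj <- function(par) {
    pp <- par_to_psi(par, q)
    -reml_loglik_dense(y, X, W, group, pp$Psi, pp$sigma)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- stats::rnorm(npar, 0, 0.7)
    opt <- tryCatch(
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  pp <- par_to_psi(best$par, q)
  list(loglik = -best$value, Psi = pp$Psi, sigma = pp$sigma)
}
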