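# Normative modelling: robust covariate regression on healthy controls,
# z-scoring of every subject against the control residual distribution,
# and thresholding into binary abnormality masks.

#' Huber M-estimation by iteratively reweighted least squares
#'
#' Tuning constant `k = 1.345`, scale re-estimated each iteration as the MAD
#' (about zero) of the residuals, iterated to relative coefficient tolerance
#' `tol` or `maxit` iterations. An exact fit (MAD of residuals ~ 0) returns
#' the least-squares solution with unit weights.
#'
#' @param X Design matrix (with intercept column).
#' @param y Response vector.
#' @param k Huber tuning constant.
#' @param tol Relative convergence tolerance on coefficients.
#' @param maxit Maximum IRLS iterations.
#' @return List with `coefficients`, `residuals`, `weights`, `iterations`,
#'   `converged`.
#' @export
huber_lm <- function(X, y, k = 1.345, tol = 1e-8, maxit = 50L) {
  fit0 <- stats::lm.fit(X, y)
  beta <- fit0$coefficients
  conv <- TRUE; it <- 0L
  repeat {
    r <- drop(y - X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s < 1e-12 * max(1, stats::mad(y, center = stats::median(y)), abs(y))) {
      w <- rep(1, length(y)); break
    }
    w <- pmin(1, k / (abs(r) / s))
    w[!is.finite(w)] <- 1
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    it <- it + 1L
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    if (delta <= tol) break
    if (it >= maxit) { conv <- FALSE; break }
  }
  r <- drop(y - X %*% beta)
  list(coefficients = beta, residuals = r,
       weights = if (exists("w", inherits = FALSE)) w else rep(1, length(y)),
       iterations = it, converged = conv)
}

#' Fit per-feature normative models on healthy controls
#'
#' One robust (Huber) linear regression per feature of feature ~ covariates
#' on controls; the residual scale is the plain standard deviation of the
#' control residuals (set `robust_scale = TRUE` for 1.4826*MAD instead).
#'
#' @param control_features Controls x features numeric matrix (column names =
#'   feature names).
#' @param control_covariates Data frame of covariates for the same rows
#'   (e.g. age, sex, icv for volumes; age, sex for edges).
#' @param robust_scale Use a robust residual scale instead of the SD.
#' @return A `normative_model`: coefficient matrix (covariates+intercept x
#'   features), residual scale `sigma` per feature, covariate names.
#' @export
fit_normative <- function(control_features, control_covariates,
                          robust_scale = FALSE) {
  X <- cbind(`(Intercept)` = 1, as.matrix(control_covariates))
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient covariate design")
  if (nrow(X) < p + 9) stop("need at least p + 10 control subjects")
  feats <- as.matrix(control_features)
  coefs <- matrix(NA_real_, p, ncol(feats),
                  dimnames = list(colnames(X), colnames(feats)))
  sigma <- numeric(ncol(feats)); names(sigma) <- colnames(feats)
  for (j in seq_len(ncol(feats))) {
    f <- huber_lm(X, feats[, j])
    coefs[, j] <- f$coefficients
    sigma[j] <- if (robust_scale) stats::mad(f$residuals) else
      stats::sd(f$residuals)
  }
  # an exactly-fitted feature has no residual scale: z defined as 0
  degenerate <- sigma < 1e-10 * pmax(1, apply(abs(feats), 2L, max))
  if (any(degenerate))
    warning("constant or exactly-fitted feature(s): residual scale set to 1 for ",
            sum(degenerate), " feature(s)")
  sigma[degenerate] <- 1
  structure(list(coefficients = coefs, sigma = sigma,
                 covariates = colnames(control_covariates),
                 robust_scale = robust_scale),
            class = "normative_model")
}

#' Normative z-scores for a feature table
#'
#' `z = (observed - predicted) / sigma_f` per feature, applied to patients
#' and controls alike.
#'
#' @param features Subjects x features matrix (feature set must match the
#'   model).
#' @param covariates Data frame with the model's covariate columns.
#' @param model A [fit_normative()] model.
#' @return A `ztable`: list with `z` (subjects x features), `kind`
#'   (`"node"`/`"edge"`, inferred from feature names) and `frame`
#'   (`"anatomical"`).
#' @export
zscore <- function(features, covariates, model) {
  miss <- setdiff(model$covariates, colnames(covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  feats <- as.matrix(features)
  if (!identical(colnames(feats), colnames(model$coefficients)))
    feats <- feats[, colnames(model$coefficients), drop = FALSE]
  X <- cbind(1, as.matrix(covariates[, model$covariates, drop = FALSE]))
  pred <- X %*% model$coefficients
  z <- sweep(feats - pred, 2L, model$sigma, "/")
  kind <- if (any(grepl("--", colnames(z), fixed = TRUE))) "edge" else "node"
  structure(list(z = z, kind = kind, frame = "anatomical"), class = "ztable")
}

#' @export
print.ztable <- function(x, ...) {
  cat(sprintf("ztable: %d subjects x %d %s features (%s frame)\n",
              nrow(x$z), ncol(x$z), x$kind, x$frame))
  invisible(x)
}

#' Threshold a z-table into a binary abnormality mask
#'
#' @param ztable A [ztable].
#' @param tau Negative z threshold; abnormal where `z < tau`.
#' @return An `abn_mask`: list with logical `mask`, `tau`, `kind`, `frame`.
#' @export
threshold_abnormal <- function(ztable, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau < 0)
  structure(list(mask = ztable$z < tau, tau = tau, kind = ztable$kind,
                 frame = ztable$frame), class = "abn_mask")
}
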