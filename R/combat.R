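# Parametric empirical-Bayes ComBat harmonization (Johnson et al. 2007
# lineage): per-feature location/scale batch adjustment with normal /
# inverse-gamma priors, biological covariates preserved through the design.

#' Fit a ComBat harmonization model
#'
#' Standardizes each feature against a batch + covariate linear fit,
#' estimates per-(batch, feature) location and scale effects, and shrinks
#' them with the parametric empirical-Bayes priors (normal on locations,
#' inverse-gamma on scales). With a single batch the model short-circuits to
#' the identity transform. Constant features are passed through unadjusted
#' with a warning.
#'
#' @param features Subjects x features numeric matrix.
#' @param batch Batch labels, one per subject.
#' @param covariates Optional data frame of biological covariates to preserve
#'   (e.g. age, sex, ICV).
#' @param eb Use empirical-Bayes shrinkage (default). `FALSE` adjusts with the
#'   raw per-batch location/scale estimates (exact batch-moment equalisation).
#' @return A `combat_model`.
#' @export
combat_fit <- function(features, batch, covariates = NULL, eb = TRUE) {
  Y <- as.matrix(features)
  batch <- factor(batch)
  if (nlevels(batch) > 1 && any(table(batch) < 2))
    stop("every batch needs at least 2 subjects")
  Xcov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (nlevels(batch) == 1L) {
    return(structure(list(identity = TRUE, batches = levels(batch)),
                     class = "combat_model"))
  }
  B <- stats::model.matrix(~ 0 + batch)
  X <- cbind(B, Xcov)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient batch + covariate design")
  nb <- nlevels(batch); n <- nrow(Y)
  n_batch <- as.integer(table(batch))
  Bhat <- solve(crossprod(X), crossprod(X, Y))         # (nb + q) x p
  grand <- drop((n_batch / n) %*% Bhat[seq_len(nb), , drop = FALSE])
  cov_coef <- Bhat[-seq_len(nb), , drop = FALSE]
  fit_mean <- outer(rep(1, n), grand) +
    if (is.null(Xcov)) 0 else Xcov %*% cov_coef
  var_pooled <- colMeans((Y - X %*% Bhat)^2)
  const <- var_pooled < 1e-12 * pmax(1, colMeans(Y)^2)
  if (any(const)) {
    warning(sum(const), " constant feature(s): left unadjusted")
    var_pooled[const] <- 1
  }
  S <- sweep(Y - fit_mean, 2L, sqrt(var_pooled), "/")

  gamma_hat <- rowsum(S, batch) / n_batch                  # nb x p
  delta_hat <- rowsum(sweep(S, 2L, 0)^2, batch)            # placeholder
  for (b in seq_len(nb)) {
    rows <- which(as.integer(batch) == b)
    delta_hat[b, ] <- apply(S[rows, , drop = FALSE], 2L, stats::var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  a_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat; delta_star <- delta_hat
  if (eb) {
    for (b in seq_len(nb)) {
      rows <- which(as.integer(batch) == b)
      sol <- eb_iterate(S[rows, , drop = FALSE], gamma_hat[b, ], delta_hat[b, ],
                        gamma_bar[b], t2[b], a_prior[b], b_prior[b])
      gamma_star[b, ] <- sol$gamma
      delta_star[b, ] <- sol$delta
    }
  }
  gamma_star[, const] <- 0
  delta_star[, const] <- 1

  structure(list(identity = FALSE, batches = levels(batch),
                 grand_mean = grand, cov_coef = cov_coef,
                 covariate_names = colnames(Xcov),
                 var_pooled = var_pooled, gamma_star = gamma_star,
                 delta_star = delta_star, constant = const),
            class = "combat_model")
}

# Iterative EB posterior solution for one batch (standard parametric ComBat).
#' @keywords internal
eb_iterate <- function(S_b, g_hat, d_hat, g_bar, t2, a, b, conv = 1e-6,
                       maxit = 200L) {
  n <- nrow(S_b)
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums(sweep(S_b, 2L, g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = pmax(d_old, 1e-12))
}

#' Apply a fitted ComBat model
#'
#' @param model A [combat_fit()] model.
#' @param features,batch,covariates New data; every batch must have been seen
#'   at fit time and the covariate columns must match.
#' @return Harmonized matrix, same shape as `features`.
#' @export
combat_apply <- function(model, features, batch, covariates = NULL) {
  Y <- as.matrix(features)
  if (isTRUE(model$identity)) return(Y)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen)) stop("unseen batch: ", paste(unseen, collapse = ", "))
  bi <- match(batch, model$batches)
  Xcov <- if (is.null(model$covariate_names)) NULL else
    as.matrix(covariates[, model$covariate_names, drop = FALSE])
  fit_mean <- outer(rep(1, nrow(Y)), model$grand_mean) +
    if (is.null(Xcov)) 0 else Xcov %*% model$cov_coef
  S <- sweep(Y - fit_mean, 2L, sqrt(model$var_pooled), "/")
  adj <- (S - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star)[bi, , drop = FALSE]
  if (any(model$constant)) adj[, model$constant] <- S[, model$constant]
  out <- sweep(adj, 2L, sqrt(model$var_pooled), "*") + fit_mean
  dimnames(out) <- dimnames(Y)
  out
}

#' Serialize / load a ComBat model as JSON
#' @param model A `combat_model`.
#' @param path File path.
#' @name combat_io
#' @export
write_combat_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname combat_io
#' @export
read_combat_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!isTRUE(m$identity)) {
    m$gamma_star <- as.matrix(m$gamma_star)
    m$delta_star <- as.matrix(m$delta_star)
    m$cov_coef <- as.matrix(m$cov_coef)
    m$grand_mean <- as.numeric(m$grand_mean)
    m$var_pooled <- as.numeric(m$var_pooled)
  }
  structure(m, class = "combat_model")
}
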