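# Two-level hierarchical models linking node and edge abnormalities.
#
# Edge direction: connection z-score C_ijk modelled by whether the connection
# joins one (V') or two (V'') volumetrically abnormal regions, with random
# intercepts and slopes per subject:
#   Level one: C_ijk = a_k + b_k V'_ijk + c_k V''_ijk + e_ijk
#   Level two: a_k = alpha0 + u_k ; b_k = beta0 + v_k ; c_k = gamma0 + w_k
# Volume direction: mean endpoint volume z modelled by a binary
# edge-abnormality predictor, random intercept + slope.
# Fitted by REML via lme4::lmer with an unstructured random-effect
# covariance; Satterthwaite and normal-approximation p-values reported.

#' Build the edge-direction model frame
#'
#' One row per (subject, edge); `vprime` = exactly one abnormal endpoint,
#' `vdouble` = both endpoints abnormal (mutually exclusive).
#'
#' @param edge_z Edge-kind [ztable] for the subjects to model.
#' @param vol_mask Node-kind abnormality mask (same subjects, same frame).
#' @param edge_index Edge index matching the z-table columns.
#' @return A `model_frame` data frame with attribute `direction = "edge"` and
#'   per-category row counts in attribute `counts`.
#' @export
build_edge_model_frame <- function(edge_z, vol_mask, edge_index) {
  if (vol_mask$kind != "node") stop("vol_mask must be a node-kind mask")
  z <- edge_z$z
  subj <- intersect(rownames(z), rownames(vol_mask$mask))
  if (!length(subj)) stop("no shared subjects between z-table and mask")
  z <- z[subj, edge_index$edge, drop = FALSE]
  i <- match(edge_index$region_i, colnames(vol_mask$mask))
  j <- match(edge_index$region_j, colnames(vol_mask$mask))
  if (anyNA(i) || anyNA(j))
    stop("edge index references regions absent from the volume mask")
  mi <- vol_mask$mask[subj, i, drop = FALSE]
  mj <- vol_mask$mask[subj, j, drop = FALSE]
  n_abn <- mi + mj
  fr <- data.frame(
    subject = factor(rep(subj, times = ncol(z))),
    edge = rep(edge_index$edge, each = length(subj)),
    z = as.vector(z),
    vprime = as.integer(as.vector(n_abn == 1L)),
    vdouble = as.integer(as.vector(n_abn == 2L)),
    stringsAsFactors = FALSE)
  attr(fr, "direction") <- "edge"
  attr(fr, "counts") <- c(none = sum(n_abn == 0L), one = sum(n_abn == 1L),
                          two = sum(n_abn == 2L))
  class(fr) <- c("model_frame", "data.frame")
  fr
}

#' Build the volume-direction model frame
#'
#' Response = per-subject mean volume z of the two endpoints; single binary
#' predictor `abn` = the connection itself is abnormal.
#'
#' @param vol_z Node-kind [ztable].
#' @param edge_mask Edge-kind abnormality mask.
#' @param edge_index Edge index.
#' @return A `model_frame` with attribute `direction = "volume"`.
#' @export
build_volume_model_frame <- function(vol_z, edge_mask, edge_index) {
  if (edge_mask$kind != "edge") stop("edge_mask must be an edge-kind mask")
  m <- endpoint_mean_z(vol_z, edge_index)
  subj <- intersect(rownames(m), rownames(edge_mask$mask))
  if (!length(subj)) stop("no shared subjects between z-table and mask")
  m <- m[subj, , drop = FALSE]
  em <- edge_mask$mask[subj, edge_index$edge, drop = FALSE]
  fr <- data.frame(
    subject = factor(rep(subj, times = ncol(m))),
    edge = rep(edge_index$edge, each = length(subj)),
    z = as.vector(m),
    abn = as.integer(as.vector(em)),
    stringsAsFactors = FALSE)
  attr(fr, "direction") <- "volume"
  attr(fr, "counts") <- c(normal = sum(em == 0L), abnormal = sum(em == 1L))
  class(fr) <- c("model_frame", "data.frame")
  fr
}

#' Fit the two-level model by REML
#'
#' Random intercept and slope(s) per subject with unstructured covariance;
#' degenerate predictors (no variation at the chosen threshold) are dropped
#' from both fixed and random parts and reported. A single-subject frame
#' degrades to ordinary least squares with a warning.
#'
#' @param frame A [build_edge_model_frame()] / [build_volume_model_frame()]
#'   frame.
#' @param satterthwaite Also compute Satterthwaite degrees of freedom
#'   (slower; normal-approximation Wald p-values are always reported).
#' @param calc_derivs Passed to [lme4::lmerControl()]; `FALSE` speeds up
#'   large scans.
#' @return A `hier_fit`: fixed effects with SEs and p-values, variance
#'   components, per-subject random effects, REML criterion, convergence
#'   info, category counts.
#' @export
fit_reml <- function(frame, satterthwaite = TRUE, calc_derivs = TRUE) {
  direction <- attr(frame, "direction")
  preds <- switch(direction, edge = c("vprime", "vdouble"), volume = "abn",
                  stop("frame lacks a direction attribute"))
  active <- preds[vapply(preds, function(p) stats::var(frame[[p]]) > 0, TRUE)]
  dropped <- setdiff(preds, active)
  rhs <- if (length(active)) paste(active, collapse = " + ") else "1"
  n_subj <- length(unique(frame$subject))

  if (n_subj < 2L) {
    warning("single subject: degrading to ordinary least squares")
    fit <- stats::lm(stats::reformulate(active, response = "z",
                                        intercept = TRUE), data = frame)
    sm <- summary(fit)$coefficients
    fe <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                     p_wald = 2 * stats::pnorm(-abs(sm[, 1L] / sm[, 2L])),
                     df_satterthwaite = NA_real_, p_satterthwaite = NA_real_,
                     row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(direction = direction, fixed = fe, vcov_fixed = stats::vcov(fit),
                          varcomp = NULL, ranef = NULL, sigma = summary(fit)$sigma,
                          reml_criterion = NA_real_, converged = TRUE,
                          singular = NA, dropped = dropped,
                          counts = attr(frame, "counts"), n_subjects = n_subj,
                          lmer_fit = NULL),
                     class = "hier_fit"))
  }

  form <- stats::as.formula(paste0("z ~ ", rhs, " + (", rhs, " | subject)"))
  ctrl <- lme4::lmerControl(calc.derivs = calc_derivs,
                            check.conv.singular = "ignore")
  fit <- lme4::lmer(form, data = frame, REML = TRUE, control = ctrl)
  devfun <- lme4::lmer(form, data = frame, REML = TRUE, control = ctrl,
                       devFunOnly = TRUE)

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  zval <- beta / se
  vp <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  satt <- if (satterthwaite) {
    diag_l <- lapply(seq_along(beta), function(i) {
      L <- numeric(length(beta)); L[i] <- 1; L
    })
    satterthwaite_df(devfun, vp, diag_l)
  } else rep(NA_real_, length(beta))
  p_satt <- 2 * stats::pt(-abs(zval), satt)
  fe <- data.frame(term = names(beta), estimate = unname(beta),
                   se = unname(se),
                   p_wald = unname(2 * stats::pnorm(-abs(zval))),
                   df_satterthwaite = unname(satt),
                   p_satterthwaite = unname(p_satt),
                   row.names = NULL, stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)$subject
  structure(list(direction = direction, fixed = fe, vcov_fixed = V,
                 varcomp = vc, ranef = re, sigma = stats::sigma(fit),
                 reml_criterion = lme4::REMLcrit(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = length(fit@optinfo$conv$lme4$messages) == 0L,
                 singular = lme4::isSingular(fit), dropped = dropped,
                 counts = attr(frame, "counts"), n_subjects = n_subj,
                 lmer_fit = fit, devfun = devfun, varpar = vp),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("hier_fit (%s direction, %d subjects, REML criterion %.3f)\n",
              x$direction, x$n_subjects,
              if (is.null(x$reml_criterion)) NA else x$reml_criterion))
  print(x$fixed, digits = 4)
  invisible(x)
}

# Satterthwaite df for contrasts L'beta of an lmer fit: finite-difference
# Hessian of the REML deviance in (theta, sigma) and gradient of L'C(vp)L,
# as in the lmerTest approach. `devfun` is the lmer deviance function
# (devFunOnly = TRUE), `vp = c(theta, sigma)` the fitted variance parameters.
# Returns NA (caller falls back to the normal approximation) when the
# variance-parameter Hessian is not positive definite.
#' @keywords internal
satterthwaite_df <- function(devfun, vp, contrasts) {
  np <- length(vp) - 1L
  env <- environment(devfun)
  n <- nrow(env$pp$X); p <- ncol(env$pp$X)

  dev_vp <- function(v) {
    if (v[np + 1] <= 0) return(NA_real_)
    s2 <- v[np + 1]^2
    devfun(v[seq_len(np)])
    env$pp$ldL2() + (env$resp$wrss() + env$pp$sqrL(1)) / s2 +
      (n - p) * log(2 * pi * s2) + env$pp$ldRX2()
  }
  vcov_vp <- function(v) {
    devfun(v[seq_len(np)])
    v[np + 1]^2 * as.matrix(env$pp$unsc())
  }

  h <- pmax(abs(vp) * 1e-4, 1e-7)
  k <- np + 1L
  H <- matrix(NA_real_, k, k)
  f0 <- dev_vp(vp)
  for (a in seq_len(k)) for (b in a:k) {
    ea <- eb <- numeric(k); ea[a] <- h[a]; eb[b] <- h[b]
    if (a == b) {
      H[a, a] <- (dev_vp(vp + ea) - 2 * f0 + dev_vp(vp - ea)) / h[a]^2
    } else {
      H[a, b] <- H[b, a] <-
        (dev_vp(vp + ea + eb) - dev_vp(vp + ea - eb) -
           dev_vp(vp - ea + eb) + dev_vp(vp - ea - eb)) / (4 * h[a] * h[b])
    }
  }
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  devfun(vp[seq_len(np)])  # restore
  if (is.null(A) || anyNA(A)) return(rep(NA_real_, length(contrasts)))

  vapply(contrasts, function(L) {
    fvar <- function(v) drop(t(L) %*% vcov_vp(v) %*% L)
    g <- vapply(seq_len(k), function(a) {
      ea <- numeric(k); ea[a] <- h[a]
      (fvar(vp + ea) - fvar(vp - ea)) / (2 * h[a])
    }, 0)
    denom <- drop(t(g) %*% A %*% g)
    f0v <- fvar(vp)
    if (!is.finite(denom) || denom <= 0) return(NA_real_)
    df <- 2 * f0v^2 / denom
    if (df <= 0) NA_real_ else df
  }, 0)
}

#' Wald test of "one abnormal endpoint" vs "two abnormal endpoints"
#'
#' Tests beta0 = gamma0 (the `vprime` and `vdouble` fixed effects) in an
#' edge-direction fit, using the fixed-effect covariance; Satterthwaite df
#' when available, normal approximation otherwise.
#'
#' @param fit An edge-direction `hier_fit`.
#' @return List with `estimate` (gamma0 - beta0), `se`, `statistic`, `df`,
#'   `p_value`, `p_wald`.
#' @export
contrast_one_vs_two <- function(fit) {
  if (fit$direction != "edge")
    stop("contrast requires an edge-direction fit")
  terms <- fit$fixed$term
  iv <- match("vprime", terms); iw <- match("vdouble", terms)
  if (is.na(iv) || is.na(iw))
    stop("fit lacks one of the vprime/vdouble effects (degenerate threshold)")
  L <- numeric(length(terms)); L[iw] <- 1; L[iv] <- -1
  est <- sum(L * fit$fixed$estimate)
  se <- sqrt(drop(t(L) %*% fit$vcov_fixed %*% L))
  if (se < 1e-12) {
    p <- if (abs(est) < 1e-12) 1 else 0
    return(list(estimate = est, se = se, statistic = NA_real_, df = NA_real_,
                p_value = p, p_wald = p))
  }
  stat <- est / se
  df <- if (!is.null(fit$devfun))
    satterthwaite_df(fit$devfun, fit$varpar, list(L)) else NA_real_
  p_wald <- 2 * stats::pnorm(-abs(stat))
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else p_wald
  list(estimate = est, se = se, statistic = stat, df = df, p_value = p,
       p_wald = p_wald)
}

#' Shuffle null: permute responses within each subject
#'
#' Predictors untouched; the multiset of responses per subject is preserved.
#'
#' @param frame A `model_frame`.
#' @param seed Integer seed (local RNG; the caller's stream is untouched).
#' @return A permuted `model_frame`.
#' @export
shuffle_null <- function(frame, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- frame
  for (s in split(seq_len(nrow(frame)), frame$subject)) {
    out$z[s] <- frame$z[s][sample.int(length(s))]
  }
  out
}

#' Refit the model over a grid of abnormality thresholds
#'
#' @param edge_z,vol_z Edge- and node-kind [ztable]s (patients).
#' @param edge_index Edge index.
#' @param taus Grid of negative thresholds (default the scan
#'   `seq(-1.0, -2.5, by = -0.1)`).
#' @param direction `"edge"` or `"volume"`.
#' @param satterthwaite,calc_derivs Passed to [fit_reml()]; defaults favour
#'   speed.
#' @return Data frame with one row per (tau, term): estimates, SEs, Wald
#'   p-values, category counts and a degeneracy flag.
#' @export
threshold_scan <- function(edge_z, vol_z, edge_index,
                           taus = seq(-1.0, -2.5, by = -0.1),
                           direction = c("edge", "volume"),
                           satterthwaite = FALSE, calc_derivs = FALSE) {
  direction <- match.arg(direction)
  stopifnot(all(taus < 0))
  out <- lapply(taus, function(tau) {
    fr <- if (direction == "edge")
      build_edge_model_frame(edge_z, threshold_abnormal(vol_z, tau), edge_index)
    else
      build_volume_model_frame(vol_z, threshold_abnormal(edge_z, tau), edge_index)
    fit <- fit_reml(fr, satterthwaite = satterthwaite,
                    calc_derivs = calc_derivs)
    cnt <- attr(fr, "counts")
    data.frame(tau = tau, term = fit$fixed$term,
               estimate = fit$fixed$estimate, se = fit$fixed$se,
               p_wald = fit$fixed$p_wald,
               degenerate = length(fit$dropped) > 0L,
               t(cnt), row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
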