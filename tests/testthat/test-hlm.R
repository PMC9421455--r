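test_that("model frames encode V'/V'' per the coefficient definitions", {
  ei <- toy_edge_index(c("a", "a", "b"), c("b", "c", "c"))
  z <- matrix(rnorm(6), 2, 3, dimnames = list(c("s1", "s2"), ei$edge))
  mask <- matrix(c(FALSE, TRUE, FALSE,   # s1: b abnormal
                   TRUE, TRUE, FALSE),   # s2: a, b abnormal
                 2, 3, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  fr <- build_edge_model_frame(as_ztable(z, "edge"),
                               as_mask(mask, -1.96, "node"), ei)
  get <- function(s, e) fr[fr$subject == s & fr$edge == e, c("vprime", "vdouble")]
  expect_equal(unlist(get("s1", "a--b")), c(vprime = 1L, vdouble = 0L))
  expect_equal(unlist(get("s1", "a--c")), c(vprime = 0L, vdouble = 0L))
  expect_equal(unlist(get("s2", "a--b")), c(vprime = 0L, vdouble = 1L))
  expect_equal(unlist(get("s2", "a--c")), c(vprime = 1L, vdouble = 0L))
  expect_true(all(fr$vprime * fr$vdouble == 0))
  expect_equal(sum(attr(fr, "counts")), nrow(fr))   # partition
  expect_error(build_edge_model_frame(as_ztable(z, "edge"),
                                      as_mask(mask[, 1:2], -1.96, "node"), ei),
               "absent")

  # volume direction: response is the endpoint mean z
  vz <- matrix(c(-2, 0, 1, 0, 0, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  emask <- matrix(FALSE, 2, 3, dimnames = list(c("s1", "s2"), ei$edge))
  frv <- build_volume_model_frame(as_ztable(vz, "node"),
                                  as_mask(emask, -1.96, "edge"), ei)
  expect_equal(frv$z[frv$subject == "s1" & frv$edge == "a--b"], -1)
  expect_true(all(frv$abn == 0L))
})

test_that("noiseless data is recovered exactly with ~zero variance", {
  fr <- simulate_edge_frame(12, 30, fixed = c(-0.4, -0.1, -0.2),
                            re_sd = c(0, 0, 0), resid_sd = 0, seed = 5)
  fit <- fit_reml(fr, satterthwaite = FALSE)
  expect_equal(fit$fixed$estimate, c(-0.4, -0.1, -0.2), tolerance = 1e-6)
  expect_lt(sum(fit$varcomp$vcov[fit$varcomp$grp == "subject"]), 1e-8)
})

test_that("balanced random-intercept fit equals ANOVA method-of-moments", {
  set.seed(6)
  a <- 10L; n <- 20L
  u <- rnorm(a, 0, 0.7)
  y <- rep(u, each = n) + rnorm(a * n, 0, 1) + 2
  fr <- data.frame(subject = factor(rep(seq_len(a), each = n)), z = y,
                   abn = 0L)
  attr(fr, "direction") <- "volume"
  class(fr) <- c("model_frame", "data.frame")
  fit <- fit_reml(fr, satterthwaite = FALSE)
  gm <- tapply(y, rep(seq_len(a), each = n), mean)
  msb <- n * var(gm)
  mse <- sum((y - rep(gm, each = n))^2) / (a * (n - 1))
  tau2 <- (msb - mse) / n
  vc <- fit$varcomp
  expect_equal(vc$vcov[vc$grp == "subject"], tau2, tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], mse, tolerance = 1e-6)
  expect_identical(fit$dropped, "abn")     # degenerate predictor dropped
})

test_that("REML optimum beats random admissible parameter points", {
  fr <- simulate_edge_frame(8, 15, seed = 7)
  fit <- fit_reml(fr, satterthwaite = FALSE)
  W <- cbind(1, fr$vprime, fr$vdouble)
  Psi_hat <- as.matrix(Matrix::bdiag(lme4::VarCorr(fit$lmer_fit)$subject))
  ll_hat <- reml_loglik_dense(fr$z, W, W, fr$subject, Psi_hat,
                              fit$sigma)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)  # dense oracle agrees
  set.seed(8)
  for (i in 1:20) {
    L <- matrix(rnorm(9, 0, 0.5), 3); Psi <- L %*% t(L)
    ll <- reml_loglik_dense(fr$z, W, W, fr$subject, Psi, exp(rnorm(1, 0, 0.3)))
    expect_lte(ll, ll_hat + 1e-6)
  }
})

test_that("fixed effects invariant to subject and row reordering", {
  fr <- simulate_edge_frame(10, 20, seed = 9)
  fit1 <- fit_reml(fr, satterthwaite = FALSE)
  set.seed(10)
  fr2 <- fr[sample.int(nrow(fr)), ]
  attr(fr2, "direction") <- "edge"
  class(fr2) <- c("model_frame", "data.frame")
  fit2 <- fit_reml(fr2, satterthwaite = FALSE)
  expect_equal(fit1$fixed$estimate, fit2$fixed$estimate, tolerance = 1e-4)
})

test_that("single subject degrades to least squares with a warning", {
  fr <- simulate_edge_frame(1, 40, seed = 11)
  expect_warning(fit <- fit_reml(fr), "single subject")
  expect_s3_class(fit, "hier_fit")
  expect_true(is.null(fit$varcomp))
})

test_that("Satterthwaite df are plausible and p-values consistent", {
  fr <- simulate_edge_frame(25, 40, seed = 12)
  fit <- fit_reml(fr, satterthwaite = TRUE)
  expect_true(all(is.finite(fit$fixed$df_satterthwaite)))
  # df bounded by total rows, of the order of the subject count
  expect_true(all(fit$fixed$df_satterthwaite < nrow(fr)))
  expect_true(all(fit$fixed$df_satterthwaite > 2))
  expect_true(all(fit$fixed$p_satterthwaite >= fit$fixed$p_wald))
})

test_that("contrast of one vs two abnormal endpoints behaves", {
  fr <- simulate_edge_frame(20, 40, fixed = c(-0.4, -0.3, -0.3), seed = 13)
  fit <- fit_reml(fr, satterthwaite = FALSE)
  ct <- contrast_one_vs_two(fit)
  expect_equal(ct$estimate,
               fit$fixed$estimate[3L] - fit$fixed$estimate[2L],
               tolerance = 1e-12)
  expect_true(ct$p_value > 0 && ct$p_value <= 1)
  # zero-variance degenerate case: p = 1 when the difference is 0
  frz <- simulate_edge_frame(6, 20, fixed = c(-0.4, -0.2, -0.2),
                             re_sd = c(0, 0, 0), resid_sd = 0, seed = 14)
  fitz <- fit_reml(frz, satterthwaite = FALSE)
  ctz <- contrast_one_vs_two(fitz)
  expect_true(ctz$p_value %in% c(1) || ctz$p_value > 0.99 ||
                is.na(ctz$statistic))
  # volume-direction fit rejected
  frv <- data.frame(subject = factor(rep(1:4, each = 5)), z = rnorm(20),
                    abn = rbinom(20, 1, 0.3))
  attr(frv, "direction") <- "volume"
  class(frv) <- c("model_frame", "data.frame")
  expect_error(contrast_one_vs_two(fit_reml(frv, satterthwaite = FALSE)),
               "edge-direction")
})

test_that("shuffle null permutes within subject, deterministically", {
  fr <- simulate_edge_frame(6, 25, seed = 15)
  sh1 <- shuffle_null(fr, seed = 99)
  sh2 <- shuffle_null(fr, seed = 99)
  expect_identical(sh1, sh2)
  expect_false(identical(sh1$z, fr$z))
  for (s in levels(fr$subject)) {
    expect_equal(sort(sh1$z[sh1$subject == s]), sort(fr$z[fr$subject == s]))
  }
  expect_identical(sh1$vprime, fr$vprime)
})

test_that("threshold scan returns one fit per tau with monotone counts", {
  space <- default_ipsi_space()
  set.seed(16)
  n_s <- 15L
  keep <- space$ei_ic[1:60, ]; class(keep) <- class(space$ei_ic)
  regions <- unique(c(keep$region_i, keep$region_j))
  ids <- sprintf("p%02d", 1:n_s)
  vz <- matrix(rnorm(n_s * length(regions)), n_s,
               dimnames = list(ids, regions))
  ez <- matrix(rnorm(n_s * 60, -0.3), n_s, dimnames = list(ids, keep$edge))
  taus <- seq(-1.0, -2.5, by = -0.1)
  scan <- threshold_scan(as_ztable(ez, "edge", "ipsicontra"),
                         as_ztable(vz, "node", "ipsicontra"),
                         keep, taus, "edge")
  expect_equal(length(unique(scan$tau)), 16L)
  ones <- tapply(scan$one, scan$tau, unique)[as.character(taus)]
  expect_true(all(diff(ones) <= 0))   # stricter tau, fewer abnormal rows
  twos <- tapply(scan$two, scan$tau, unique)[as.character(taus)]
  expect_true(all(diff(twos) <= 0))
})

test_that("planted coupling gives a negative edge-abnormality coefficient", {
  # volume-direction analogue on generator ground truth, kappa = 1
  space <- default_ipsi_space()
  set.seed(17)
  cfg <- cohort_config(n_controls = 40L, n_patients = 40L, kappa = 1,
                       batch_delta = c(0, 0), batch_lambda = c(1, 1),
                       seed = 171L)
  tb <- generate_cohort(cfg, space$parc, space$ei)
  sub <- tb$subjects
  covs <- data.frame(age = sub$age, sex = sub$sex,
                     icv = (sub$icv - mean(sub$icv)) / sd(sub$icv))
  ctrl <- sub$group == "control"
  nmv <- fit_normative(tb$volumes[ctrl, ], covs[ctrl, ])
  nme <- fit_normative(tb$edges[ctrl, ], covs[ctrl, c("age", "sex")])
  zv <- flip_to_ipsicontra(zscore(tb$volumes, covs, nmv), sub, space$parc)
  ze <- flip_to_ipsicontra(zscore(tb$edges, covs[, c("age", "sex")], nme),
                           sub, space$parc)
  pat <- !ctrl
  zv_p <- as_ztable(zv$z[pat, , drop = FALSE], "node", "ipsicontra")
  ze_p <- as_ztable(ze$z[pat, , drop = FALSE], "edge", "ipsicontra")
  frv <- build_volume_model_frame(zv_p, threshold_abnormal(ze_p, -1.96),
                                  space$ei_ic)
  fit <- fit_reml(frv, satterthwaite = FALSE, calc_derivs = FALSE)
  est <- fit$fixed$estimate[fit$fixed$term == "abn"]
  se <- fit$fixed$se[fit$fixed$term == "abn"]
  expect_lt(est, 0)
  expect_lt(est + 2 * se, 0)          # significantly negative
})
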