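test_that("noiseless controls on a known plane are recovered exactly", {
  set.seed(1)
  n <- 60
  covs <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5))
  y <- 3 + 0.2 * covs$age - 1.5 * covs$sex
  feats <- cbind(f1 = y, f2 = -y)
  expect_warning(m <- fit_normative(feats, covs), "constant|residual scale")
  expect_equal(unname(m$coefficients[, "f1"]), c(3, 0.2, -1.5),
               tolerance = 1e-8)
  zt <- zscore(feats, covs, m)
  expect_equal(max(abs(zt$z)), 0, tolerance = 1e-8)  # z = 0 at the prediction
})

test_that("Huber regression resists one-sided gross outliers where OLS fails", {
  set.seed(2)
  n <- 300
  x <- sort(runif(n, 0, 10))
  sigma <- 0.5
  y <- 2 + 1.5 * x + rnorm(n, 0, sigma)
  out_idx <- (n - n / 10 + 1):n             # 10% at highest leverage
  y[out_idx] <- y[out_idx] + 10 * sigma * 10
  X <- cbind(1, x)
  hb <- huber_lm(X, y)
  ols <- lm.fit(X, y)$coefficients
  expect_lt(abs(hb$coefficients[2L] / 1.5 - 1), 0.10)
  expect_gt(abs(ols[2L] / 1.5 - 1), 0.10)
  # agrees with the independent M-estimation route
  rl <- MASS::rlm(y ~ x, k = 1.345, scale.est = "MAD", maxit = 50)
  expect_equal(unname(hb$coefficients), unname(coef(rl)), tolerance = 1e-3)
})

test_that("held-out controls are calibrated; linearity; self-consistency", {
  set.seed(3)
  n <- 1000; p <- 50
  covs <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5))
  B <- rbind(runif(p, -1, 1), runif(p, -0.05, 0.05), runif(p, -0.5, 0.5))
  feats <- cbind(1, as.matrix(covs)) %*% B + matrix(rnorm(n * p), n)
  colnames(feats) <- paste0("f", 1:p)
  fit_rows <- 1:900
  m <- fit_normative(feats[fit_rows, ], covs[fit_rows, ])
  expect_true(all(m$sigma > 0))
  zt <- zscore(feats, covs, m)
  held <- zt$z[-fit_rows, ]
  expect_lt(abs(mean(colMeans(held))), 0.15)
  expect_true(mean(apply(held, 2, sd)) > 0.85 && mean(apply(held, 2, sd)) < 1.15)
  # z-scoring the fit controls: per-feature SD = 1 by construction
  expect_equal(unname(apply(zt$z[fit_rows, ], 2, sd)), rep(1, p),
               tolerance = 1e-8)
  # linearity: +2 sigma_f on one feature raises its z by exactly 2
  feats2 <- feats; feats2[1L, 1L] <- feats2[1L, 1L] + 2 * m$sigma[1L]
  zt2 <- zscore(feats2, covs, m)
  expect_equal(unname(zt2$z[1L, 1L] - zt$z[1L, 1L]), 2, tolerance = 1e-10)
})

test_that("fit_normative validates its preconditions", {
  covs <- data.frame(age = 1:20, age2 = 2 * (1:20))
  feats <- matrix(rnorm(40), 20, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_normative(feats, covs), "rank-deficient")
  expect_error(fit_normative(feats[1:8, ], data.frame(age = 1:8)),
               "p \\+ 10")
  m <- fit_normative(feats, data.frame(age = rnorm(20)))
  expect_error(zscore(feats, data.frame(sex = rep(0, 20)), m),
               "missing covariate")
})

test_that("thresholding matches the normal tail and is monotone in tau", {
  set.seed(4)
  z <- matrix(rnorm(200 * 100), 200, dimnames = list(NULL, paste0("f", 1:100)))
  zt <- as_ztable(z, "node")
  for (tau in c(-1.96, -1.645)) {
    mk <- threshold_abnormal(zt, tau)
    p_expect <- pnorm(tau)
    se <- sqrt(p_expect * (1 - p_expect) / length(z))
    expect_lt(abs(mean(mk$mask) - p_expect), 3 * se)
  }
  m1 <- threshold_abnormal(zt, -2.5)$mask
  m2 <- threshold_abnormal(zt, -1.0)$mask
  expect_true(all(m2[m1]))                  # mask(-2.5) subset of mask(-1.0)
  expect_false(any(threshold_abnormal(as_ztable(matrix(0, 2, 2,
    dimnames = list(NULL, c("a", "b"))), "node"), -1)$mask))
  expect_error(threshold_abnormal(zt, 1.5))
})

test_that("hemisphere flip: relabel semantics, involution, mirrored edges", {
  parc <- load_default_parcellation()
  ei <- default_edge_index(parc)
  subj <- data.frame(subject_id = c("L1", "R1", "C1"),
                     group = c("patient", "patient", "control"),
                     laterality = c("L", "R", NA), stringsAsFactors = FALSE)
  zv <- matrix(rnorm(3 * 82), 3, dimnames = list(subj$subject_id, parc$name))
  zv["R1", "rh_hippocampus"] <- -3
  ztv <- as_ztable(zv, "node")
  ic <- flip_to_ipsicontra(ztv, subj, parc)
  expect_identical(ic$frame, "ipsicontra")
  # LTLE and controls: values identical, labels renamed left -> ipsi
  expect_equal(unname(ic$z["L1", "ipsi_hippocampus"]),
               unname(zv["L1", "lh_hippocampus"]))
  expect_equal(unname(ic$z["C1", "contra_thalamus"]),
               unname(zv["C1", "rh_thalamus"]))
  # RTLE: right maps to ipsi
  expect_equal(unname(ic$z["R1", "ipsi_hippocampus"]), -3)
  # involution
  back <- flip_to_ipsicontra(ic, subj, parc)
  expect_identical(back$frame, "anatomical")
  expect_equal(back$z[, colnames(zv)], zv)
  # edges: mirrored remap, involution on the mirror-symmetric fixture
  ze <- matrix(rnorm(3 * nrow(ei)), 3,
               dimnames = list(subj$subject_id, ei$edge))
  zte <- as_ztable(ze, "edge")
  ice <- flip_to_ipsicontra(zte, subj, parc)
  expect_equal(ncol(ice$z), nrow(ei))       # nothing dropped
  backe <- flip_to_ipsicontra(ice, subj, parc)
  expect_equal(backe$z[, colnames(ze)], ze)
  # RTLE edge values come from the mirrored anatomical edge
  e1 <- ei$edge[1L]
  ends <- strsplit(e1, "--", fixed = TRUE)[[1L]]
  mir <- epicoloc:::edge_name(epicoloc:::homologue_names(ends[1L]),
                              epicoloc:::homologue_names(ends[2L]))
  ipsi_name <- epicoloc:::edge_name(
    epicoloc:::rename_to_ipsi(ends[1L]), epicoloc:::rename_to_ipsi(ends[2L]))
  expect_equal(unname(ice$z["R1", ipsi_name]), unname(ze["R1", mir]))
  expect_equal(unname(ice$z["L1", ipsi_name]), unname(ze["L1", e1]))
})

test_that("edges without a mirror are dropped with a message", {
  parc <- load_default_parcellation()
  ei <- build_edge_index(parc, rbind(
    c("lh_hippocampus", "lh_thalamus"),
    c("rh_hippocampus", "rh_thalamus"),
    c("lh_insula", "lh_amygdala")))     # no rh mirror
  subj <- data.frame(subject_id = "P1", group = "patient", laterality = "L",
                     stringsAsFactors = FALSE)
  z <- matrix(rnorm(3), 1, dimnames = list("P1", ei$edge))
  expect_message(ic <- flip_to_ipsicontra(as_ztable(z, "edge"), subj, parc),
                 "without mirror")
  expect_equal(ncol(ic$z), 2L)
})
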