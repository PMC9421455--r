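test_that("Dice similarity reproduces the worked 4-edge example", {
  fx <- table2_fixture()
  ds <- dice_similarity(fx$vol, fx$edge, fx$ei)
  expect_equal(ds$ds_i, 0)        # 0 / (0 + 2)
  expect_equal(ds$ds_j, 0.25)     # 1 / (2 + 2)
  expect_equal(ds$ds, 0.125)
  # all-abnormal saturates at 0.5 (as-printed formula, no factor 2)
  all_v <- setNames(rep(TRUE, length(fx$vol)), names(fx$vol))
  ds2 <- dice_similarity(all_v, rep(TRUE, 4), fx$ei)
  expect_equal(ds2$ds, 0.5)
  # empty masks: 0/0 -> 0 policy
  none <- setNames(rep(FALSE, length(fx$vol)), names(fx$vol))
  expect_equal(dice_similarity(none, rep(FALSE, 4), fx$ei)$ds, 0)
  expect_error(dice_similarity(fx$vol, fx$edge[1:2], fx$ei), "length")
})

test_that("swapping endpoint roles swaps DS_i/DS_j and keeps DS", {
  set.seed(1)
  ei <- toy_edge_index(paste0("r", 1:8), paste0("r", c(2:8, 1)))
  vm <- setNames(runif(8) < 0.4, paste0("r", 1:8))
  em <- runif(nrow(ei)) < 0.4
  ds <- dice_similarity(vm, em, ei)
  ei_sw <- ei
  ei_sw$region_i <- ei$region_j; ei_sw$region_j <- ei$region_i
  ds_sw <- dice_similarity(vm, em, ei_sw)
  expect_equal(ds_sw$ds_i, ds$ds_j)
  expect_equal(ds_sw$ds_j, ds$ds_i)
  expect_equal(ds_sw$ds, ds$ds)
})

test_that("moving an abnormal edge onto an abnormal region never lowers DS", {
  set.seed(2)
  for (rep_i in 1:20) {
    n_r <- 10; n_e <- 16
    ends <- t(replicate(n_e, sample.int(n_r, 2)))
    ei <- toy_edge_index(paste0("r", pmin(ends[, 1], ends[, 2])),
                         paste0("r", pmax(ends[, 1], ends[, 2])))
    vm <- setNames(runif(n_r) < 0.3, paste0("r", 1:n_r))
    if (!any(vm)) next
    em <- runif(n_e) < 0.3
    inc <- vm[ei$region_i] | vm[ei$region_j]
    from <- which(em & !inc); to <- which(!em & inc)
    if (!length(from) || !length(to)) next
    em2 <- em; em2[from[1L]] <- FALSE; em2[to[1L]] <- TRUE
    expect_gte(dice_similarity(vm, em2, ei)$ds,
               dice_similarity(vm, em, ei)$ds)
  }
})

test_that("Monte-Carlo score matches exhaustive enumeration and edge cases", {
  set.seed(3)
  nm <- paste0("r", 1:6)
  pairs <- t(utils::combn(nm, 2))[sample.int(15, 10), ]
  ei <- toy_edge_index(pairs[, 1L], pairs[, 2L])
  vm <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), nm)
  em <- rep(FALSE, 10); em[c(2, 5)] <- TRUE
  ex <- colocalisation_exact(vm, em, ei)
  mc <- colocalisation_score(vm, em, ei, n_perm = 5000, seed = 4)
  se <- sqrt(max(ex * (1 - ex), 1e-12) / 5000)
  expect_lt(abs(mc$score - ex), 3 * se + 1e-9)
  # determinism
  expect_identical(colocalisation_score(vm, em, ei, 500, seed = 9)$score,
                   colocalisation_score(vm, em, ei, 500, seed = 9)$score)
  # all edges abnormal: permutations identical, strict inequality -> 0
  expect_equal(colocalisation_score(vm, rep(TRUE, 10), ei, 200, 1)$score, 0)
  # undefined policies
  expect_false(colocalisation_score(vm, rep(FALSE, 10), ei, 100, 1)$defined)
  none <- setNames(rep(FALSE, 6), nm)
  expect_false(colocalisation_score(none, em, ei, 100, 1)$defined)
})

test_that("scores do not disturb the caller's RNG stream", {
  fx <- table2_fixture()
  set.seed(5); x1 <- runif(1)
  set.seed(5)
  invisible(colocalisation_score(fx$vol, fx$edge, fx$ei, 100, 2))
  expect_identical(runif(1), x1)
})

test_that("hemispheric restriction partitions edges and scores sides", {
  space <- default_ipsi_space()
  labs <- classify_edges(space$ei_ic, space$parc_ic, "ipsi")
  expect_equal(sum(labs == "ipsilateral-only") +
                 sum(labs == "contralateral-only") +
                 sum(labs == "interhemispheric"), nrow(space$ei_ic))
  set.seed(6)
  vm <- setNames(runif(82) < 0.1, space$parc_ic$name)
  em <- runif(nrow(space$ei_ic)) < 0.05
  hs <- hemispheric_scores(vm, em, space$ei_ic, space$parc_ic,
                           n_perm = 300, seed = 7)
  expect_named(hs, c("ipsi", "contra"))
  # mirror-symmetric masks give identical ipsi and contra scores
  stems_v <- sub("^(ipsi|contra)_", "", names(vm))
  vm_sym <- vm | vm[match(paste0(ifelse(grepl("^ipsi_", names(vm)),
                                        "contra_", "ipsi_"), stems_v),
                          names(vm))]
  names(vm_sym) <- names(vm)
  mir <- epicoloc:::edge_name(
    epicoloc:::homologue_names(space$ei_ic$region_i),
    epicoloc:::homologue_names(space$ei_ic$region_j))
  em_sym <- em | em[match(mir, space$ei_ic$edge)]
  hs2 <- hemispheric_scores(vm_sym, em_sym, space$ei_ic, space$parc_ic,
                            n_perm = 400, seed = 8)
  # same inputs on both sides -> same DS and near-identical score
  expect_equal(hs2$ipsi$ds$ds, hs2$contra$ds$ds)
  if (hs2$ipsi$defined && hs2$contra$defined)
    expect_lt(abs(hs2$ipsi$score - hs2$contra$score), 0.1)
})

test_that("compare_hemispheres handles ties, direction, and eligibility", {
  x <- c(0.99, 0.97, 0.98, 1.0, 0.96, 0.99)
  expect_equal(compare_hemispheres(rep(1, 6), x, x)$p_value, 1)
  res <- compare_hemispheres(rep(1, 6), x, x - 0.3)
  swapped <- compare_hemispheres(rep(1, 6), x - 0.3, x)
  expect_equal(res$p_value, swapped$p_value)
  expect_identical(res$direction, "ipsi > contra")
  expect_identical(swapped$direction, "contra > ipsi")
  expect_error(compare_hemispheres(c(1, 1, 0.2, 0.1), x[1:4], x[1:4]),
               "fewer than 5")
})

test_that("qualitative coupling conclusions hold across coloc thresholds", {
  # threshold scan mirror: uniform null and kappa=1 elevation at several taus
  space <- default_ipsi_space()
  for (tau in c(-1.3, -1.645, -2.0)) {
    set.seed(round(-tau * 100))
    p_abn <- pnorm(tau)
    # null: independent masks at the tau-implied rate
    sc_null <- replicate(40, {
      vm <- setNames(runif(82) < p_abn, space$parc_ic$name)
      m <- max(1L, rbinom(1, nrow(space$ei_ic), p_abn))
      em <- rep(FALSE, nrow(space$ei_ic)); em[sample.int(length(em), m)] <- TRUE
      if (!any(vm)) return(NA_real_)
      colocalisation_score(vm, em, space$ei_ic, 400,
                           sample.int(1e6, 1))$score
    })
    expect_lt(abs(mean(sc_null, na.rm = TRUE) - 0.5), 0.2)
    # coupled: abnormal edges incident to abnormal regions
    sc_c <- replicate(15, {
      vm <- setNames(rep(FALSE, 82), space$parc_ic$name)
      vm[sample.int(82, 6)] <- TRUE
      inc <- which(vm[space$ei_ic$region_i] | vm[space$ei_ic$region_j])
      em <- rep(FALSE, nrow(space$ei_ic))
      em[inc[sample.int(length(inc), min(30, length(inc)))]] <- TRUE
      colocalisation_score(vm, em, space$ei_ic, 400,
                           sample.int(1e6, 1))$score
    })
    expect_gt(mean(sc_c), 0.9)
  }
})

test_that("coupling in the generator raises co-localisation monotonically", {
  # scaled down: 6 seeds x 25 patients on planted truth masks
  space <- default_ipsi_space()
  means <- vapply(c(0, 0.5, 1), function(kap) {
    sc <- unlist(lapply(1:6, function(s) {
      cfg <- cohort_config(n_controls = 0L, n_patients = 25L, kappa = kap,
                           region_penetrance = 1, seed = 900L + s)
      tr <- planted_truth(cfg, space$parc, space$ei)
      vapply(seq_len(25), function(k)
        colocalisation_score(tr$node_mask[k, ], tr$edge_mask[k, ], space$ei,
                             n_perm = 300, seed = 17L * k + s)$score, 0)
    }))
    mean(sc, na.rm = TRUE)
  }, 0)
  expect_true(means[1] <= means[2] && means[2] <= means[3])
  expect_gt(means[3], 0.95)
  expect_lt(means[1], 0.7)
})
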