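# End-to-end orchestration: simulate -> validate -> harmonize -> zscore ->
# group stats -> hierarchical models -> co-localisation -> associations.
# Every tabular artifact is TSV with one header row; models and the final
# report are JSON. All randomness flows from named seeds in the config.

.pipeline_stages <- c("simulate", "validate", "harmonize", "zscore",
                      "group_stats", "hlm", "coloc", "associations")

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] for simulation, or `NULL` with
#'   `input_dir` pointing at `subjects.tsv`/`volumes.tsv`/`edges.tsv`.
#' @param input_dir Directory of pre-existing cohort tables (used when
#'   `cohort` is NULL).
#' @param outdir Output directory.
#' @param tau_hlm Abnormality threshold for the hierarchical models
#'   (default -1.96, the 2.5th percentile).
#' @param tau_coloc Threshold for the co-localisation analysis
#'   (default -1.645, the 5th percentile).
#' @param n_perm Permutations per co-localisation score (default 5000).
#' @param seed Analysis seed (shuffle null, permutations).
#' @param stages Stages to run; must be a prefix of the dependency order
#'   `r paste(.pipeline_stages, collapse = ", ")`.
#' @param satterthwaite Compute Satterthwaite p-values in model fits.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), input_dir = NULL,
                       outdir = tempfile("epicoloc_run_"),
                       tau_hlm = -1.96, tau_coloc = -1.645,
                       n_perm = 5000L, seed = 17L,
                       stages = .pipeline_stages, satterthwaite = TRUE) {
  stopifnot(tau_hlm < 0, tau_coloc < 0, n_perm >= 1)
  if (!identical(stages, .pipeline_stages[seq_along(stages)]))
    stop("stages must be a prefix of: ",
         paste(.pipeline_stages, collapse = ", "))
  structure(list(cohort = cohort, input_dir = input_dir, outdir = outdir,
                 tau_hlm = tau_hlm, tau_coloc = tau_coloc, n_perm = n_perm,
                 seed = seed, stages = stages, satterthwaite = satterthwaite),
            class = "run_config")
}

#' Validate cohort tables
#'
#' Checks ID agreement across the three tables, volume positivity, FA range,
#' covariate completeness and laterality presence for patients.
#'
#' @param subjects,volumes,edges Cohort tables (see [generate_cohort()]).
#' @return List with character vectors `errors` and `warnings`.
#' @export
validate_tables <- function(subjects, volumes, edges) {
  errors <- character(0); warnings <- character(0)
  ids <- subjects$subject_id
  if (!identical(sort(ids), sort(rownames(volumes))))
    errors <- c(errors, "subject ids of subjects.tsv and volumes.tsv differ")
  if (!identical(sort(ids), sort(rownames(edges))))
    errors <- c(errors, "subject ids of subjects.tsv and edges.tsv differ")
  bad_vol <- which(volumes <= 0, arr.ind = TRUE)
  if (nrow(bad_vol))
    errors <- c(errors, sprintf("non-positive volume at [%s, %s]",
                                rownames(volumes)[bad_vol[1L, 1L]],
                                colnames(volumes)[bad_vol[1L, 2L]]))
  bad_fa <- which(edges <= 0 | edges >= 1, arr.ind = TRUE)
  if (nrow(bad_fa))
    errors <- c(errors, sprintf("FA out of (0,1) at [%s, %s]",
                                rownames(edges)[bad_fa[1L, 1L]],
                                colnames(edges)[bad_fa[1L, 2L]]))
  for (cv in c("age", "sex", "icv")) {
    if (anyNA(subjects[[cv]]))
      errors <- c(errors, paste0("missing covariate ", cv))
  }
  pat <- subjects$group == "patient"
  no_lat <- pat & (is.na(subjects$laterality) |
                     !subjects$laterality %in% c("L", "R"))
  if (any(no_lat))
    errors <- c(errors, paste0("patient without laterality: ",
                               paste(ids[no_lat], collapse = ", ")))
  if (any(!pat & !is.na(subjects$laterality)))
    warnings <- c(warnings, "controls carry laterality labels (ignored)")
  list(errors = errors, warnings = warnings)
}

#' @keywords internal
log_msg <- function(level, ...) {
  message(format(Sys.time(), "%H:%M:%OS1"), " [", level, "] ", ...)
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @keywords internal
mat_tsv <- function(m, path) {
  write_tsv(data.frame(subject_id = rownames(m), m, check.names = FALSE), path)
}

#' @keywords internal
fit_summary <- function(fit) {
  list(fixed = fit$fixed[, c("term", "estimate", "se", "p_wald",
                             "df_satterthwaite", "p_satterthwaite")],
       varcomp = fit$varcomp, sigma = fit$sigma,
       reml_criterion = fit$reml_criterion, converged = fit$converged,
       singular = fit$singular, counts = as.list(fit$counts),
       n_subjects = fit$n_subjects)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stage prefix; writes TSV/JSON artifacts into
#' `config$outdir` plus a machine-readable `report.json` stamped with a
#' config hash and seeds. Deterministic: rerunning the same config rewrites
#' identical results.
#'
#' @param config A [run_config()].
#' @return The report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  parc <- load_default_parcellation()
  ei <- default_edge_index(parc)
  report <- list(package_version = as.character(utils::packageVersion("epicoloc")),
                 seed = config$seed,
                 config_hash = sum(utf8ToInt(paste(
                   deparse(config[setdiff(names(config), "outdir")]),
                   collapse = ""))))

  ## simulate / load -------------------------------------------------------
  if (is.null(config$cohort)) {
    if (is.null(config$input_dir)) stop("missing stage input: need a cohort config or input_dir")
    tables <- read_cohort(config$input_dir)
    log_msg("INFO", "loaded cohort from ", config$input_dir)
  } else {
    tables <- generate_cohort(config$cohort, parc, ei)
    log_msg("INFO", "simulated cohort: ", nrow(tables$subjects), " subjects, ",
            "FA clip rate ", signif(tables$fa_clip_rate, 2))
  }
  if ("simulate" %in% stages) write_cohort(tables, config$outdir)
  report$n_subjects <- nrow(tables$subjects)
  if (identical(stages, "simulate")) {
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }

  ## validate --------------------------------------------------------------
  val <- validate_tables(tables$subjects, tables$volumes, tables$edges)
  for (w in val$warnings) log_msg("WARN", w)
  if (length(val$errors))
    stop("validation failed: ", paste(val$errors, collapse = "; "))
  report$validation <- val
  if (!"harmonize" %in% stages) return(.finish(report, config))

  ## harmonize -------------------------------------------------------------
  subj <- tables$subjects
  cov_vol <- data.frame(age = subj$age, sex = subj$sex,
                        icv = (subj$icv - mean(subj$icv)) / stats::sd(subj$icv))
  cov_edge <- cov_vol[, c("age", "sex")]
  cb_vol <- combat_fit(tables$volumes, subj$batch, cov_vol)
  cb_edge <- combat_fit(tables$edges, subj$batch, cov_edge)
  vol_h <- combat_apply(cb_vol, tables$volumes, subj$batch, cov_vol)
  edge_h <- combat_apply(cb_edge, tables$edges, subj$batch, cov_edge)
  write_combat_model(cb_vol, file.path(config$outdir, "combat_volumes.json"))
  write_combat_model(cb_edge, file.path(config$outdir, "combat_edges.json"))
  log_msg("INFO", "harmonized ", ncol(vol_h), " volumes and ", ncol(edge_h),
          " edges across ", length(unique(subj$batch)), " batches")
  if (!"zscore" %in% stages) return(.finish(report, config))

  ## zscore + flip + masks -------------------------------------------------
  ctrl <- subj$group == "control"
  nm_vol <- fit_normative(vol_h[ctrl, , drop = FALSE], cov_vol[ctrl, ])
  nm_edge <- fit_normative(edge_h[ctrl, , drop = FALSE], cov_edge[ctrl, ])
  z_vol <- zscore(vol_h, cov_vol, nm_vol)
  z_edge <- zscore(edge_h, cov_edge, nm_edge)
  z_vol_ic <- flip_to_ipsicontra(z_vol, subj, parc)
  z_edge_ic <- flip_to_ipsicontra(z_edge, subj, parc)
  mat_tsv(z_vol_ic$z, file.path(config$outdir, "z_volumes.tsv"))
  mat_tsv(z_edge_ic$z, file.path(config$outdir, "z_edges.tsv"))
  parc_ic <- ipsicontra_parcellation(parc)
  ei_ic <- build_edge_index(parc_ic, do.call(rbind, strsplit(
    colnames(z_edge_ic$z), "--", fixed = TRUE)))
  sub_z <- function(zt, rows) {
    out <- zt; out$z <- zt$z[rows, , drop = FALSE]; out
  }
  pat <- subj$group == "patient"
  log_msg("INFO", "z-scored; ", ncol(z_edge_ic$z), " edges in ipsi/contra frame")
  if (!"group_stats" %in% stages) return(.finish(report, config))

  ## group stats ------------------------------------------------------------
  d_region <- cohens_d(sub_z(z_vol_ic, pat), sub_z(z_vol_ic, ctrl))
  d_edge <- cohens_d(sub_z(z_edge_ic, pat), sub_z(z_edge_ic, ctrl))
  lobes <- lobe_summary(sub_z(z_vol_ic, pat), sub_z(z_vol_ic, ctrl), d_edge,
                        parc_ic, ei_ic)
  write_tsv(d_region, file.path(config$outdir, "region_d.tsv"))
  write_tsv(d_edge, file.path(config$outdir, "edge_d.tsv"))
  write_tsv(lobes, file.path(config$outdir, "lobe_summary.tsv"))
  report$group_stats <- list(
    most_atrophied = d_region$feature[which.min(d_region$d)],
    min_region_d = min(d_region$d, na.rm = TRUE),
    min_edge_d = min(d_edge$d, na.rm = TRUE))
  if (!"hlm" %in% stages) return(.finish(report, config))

  ## hierarchical models ----------------------------------------------------
  mask_vol_hlm <- threshold_abnormal(z_vol_ic, config$tau_hlm)
  mask_edge_hlm <- threshold_abnormal(z_edge_ic, config$tau_hlm)
  sub_mask <- function(mk, rows) {
    out <- mk; out$mask <- mk$mask[rows, , drop = FALSE]; out
  }
  hlm <- list()
  for (who in c("patients", "controls")) {
    rows <- if (who == "patients") pat else ctrl
    fr_e <- build_edge_model_frame(sub_z(z_edge_ic, rows),
                                   sub_mask(mask_vol_hlm, rows), ei_ic)
    fr_v <- build_volume_model_frame(sub_z(z_vol_ic, rows),
                                     sub_mask(mask_edge_hlm, rows), ei_ic)
    hlm[[paste0("edge_", who)]] <- fit_reml(fr_e,
                                            satterthwaite = config$satterthwaite,
                                            calc_derivs = FALSE)
    hlm[[paste0("volume_", who)]] <- fit_reml(fr_v,
                                              satterthwaite = config$satterthwaite,
                                              calc_derivs = FALSE)
    if (who == "patients") {
      hlm$edge_shuffle <- fit_reml(shuffle_null(fr_e, config$seed),
                                   satterthwaite = config$satterthwaite,
                                   calc_derivs = FALSE)
      hlm$volume_shuffle <- fit_reml(shuffle_null(fr_v, config$seed + 1L),
                                     satterthwaite = config$satterthwaite,
                                     calc_derivs = FALSE)
      hlm$edge_contrast <- contrast_one_vs_two(hlm$edge_patients)
    }
    log_msg("INFO", "hlm (", who, "): edge counts ",
            paste(attr(fr_e, "counts"), collapse = "/"))
  }
  report$hlm <- lapply(hlm[setdiff(names(hlm), "edge_contrast")], fit_summary)
  report$hlm$edge_contrast <- hlm$edge_contrast
  jsonlite::write_json(report$hlm, file.path(config$outdir, "hlm.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  if (!"coloc" %in% stages) return(.finish(report, config))

  ## co-localisation --------------------------------------------------------
  mask_vol_c <- sub_mask(threshold_abnormal(z_vol_ic, config$tau_coloc), pat)
  mask_edge_c <- sub_mask(threshold_abnormal(z_edge_ic, config$tau_coloc), pat)
  coloc <- cohort_colocalisation(mask_vol_c, mask_edge_c, ei_ic, parc_ic,
                                 n_perm = config$n_perm, seed = config$seed,
                                 hemispheres = TRUE)
  write_tsv(coloc, file.path(config$outdir, "coloc.tsv"))
  hemi <- tryCatch(
    compare_hemispheres(coloc$score, coloc$score_ipsi, coloc$score_contra),
    error = function(e) list(error = conditionMessage(e)))
  defined <- coloc$score[!is.na(coloc$score)]
  report$coloc <- list(
    n_defined = length(defined),
    frac_colocalised = mean(defined >= 0.95),
    frac_not_colocalised = mean(defined <= 0.05),
    hemisphere_test = hemi)
  log_msg("INFO", "coloc: ", length(defined), " defined scores; ",
          round(100 * mean(defined >= 0.95)), "% co-localised")
  if (!"associations" %in% stages) return(.finish(report, config))

  ## clinical associations --------------------------------------------------
  burden <- abnormality_burden(mask_vol_c, mask_edge_c)
  measures <- merge(burden, coloc[, c("subject_id", "score")], by = "subject_id")
  names(measures)[names(measures) == "score"] <- "coloc"
  assoc <- association_table(subj[pat, ], measures)
  write_tsv(assoc, file.path(config$outdir, "associations.tsv"))
  report$associations <- assoc
  .finish(report, config)
}

#' @keywords internal
.finish <- function(report, config) {
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  log_msg("INFO", "report written to ",
          file.path(config$outdir, "report.json"))
  invisible(report)
}
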