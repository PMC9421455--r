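# Group-level effect-size cartography: per-feature Cohen's d between
# patients and controls, and lobe-level aggregation relating region-volume
# and edge-FA abnormality.

#' Cohen's d per feature between patients and controls
#'
#' `d = (mean_P - mean_C) / s` with the classical pooled standard deviation
#' (weights n1-1, n2-1; no small-sample correction). Negative d = reduced in
#' patients.
#'
#' @param patient_z,control_z [ztable]s (or plain matrices) with matching
#'   feature columns.
#' @return An `effect_size` data frame: `feature`, `d`, `mean_patient`,
#'   `mean_control`, `pooled_sd`, `n_patient`, `n_control`. Features with
#'   zero pooled SD get `d = NA`.
#' @export
cohens_d <- function(patient_z, control_z) {
  P <- if (inherits(patient_z, "ztable")) patient_z$z else as.matrix(patient_z)
  C <- if (inherits(control_z, "ztable")) control_z$z else as.matrix(control_z)
  if (!identical(colnames(P), colnames(C)))
    stop("patient and control feature columns do not match")
  n1 <- nrow(P); n2 <- nrow(C)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  m1 <- colMeans(P); m2 <- colMeans(C)
  v1 <- apply(P, 2L, stats::var); v2 <- apply(C, 2L, stats::var)
  s <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- ifelse(s > 0, (m1 - m2) / s, NA_real_)
  structure(data.frame(feature = colnames(P), d = d, mean_patient = m1,
                       mean_control = m2, pooled_sd = s, n_patient = n1,
                       n_control = n2, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("effect_size", "data.frame"))
}

#' Per-subject mean volume z-score of the two endpoints of each edge
#'
#' @param vol_z Node-kind [ztable].
#' @param edge_index Edge index whose endpoint names are columns of `vol_z`.
#' @return Subjects x edges matrix.
#' @export
endpoint_mean_z <- function(vol_z, edge_index) {
  z <- if (inherits(vol_z, "ztable")) vol_z$z else as.matrix(vol_z)
  i <- match(edge_index$region_i, colnames(z))
  j <- match(edge_index$region_j, colnames(z))
  if (anyNA(i) || anyNA(j))
    stop("edge index references regions absent from the volume z-table")
  m <- (z[, i, drop = FALSE] + z[, j, drop = FALSE]) / 2
  colnames(m) <- edge_index$edge
  m
}

#' Lobe-level summary relating edge and endpoint-volume effect sizes
#'
#' For every within-lobe connection (both endpoints in the same hemisphere
#' and lobe), pairs the connection's Cohen's d with the Cohen's d of the
#' per-subject mean volume z-score of its two endpoints, then averages by
#' lobe. Intended for the ipsi/contra frame.
#'
#' @param vol_z_patients,vol_z_controls Node-kind [ztable]s.
#' @param edge_d [cohens_d()] result for edge features.
#' @param parcellation,edge_index Feature space (same frame as the z-tables).
#' @return Data frame: `lobe` (hemisphere.lobe), `n_edges`, `mean_edge_d`,
#'   `mean_vol_d`, plus per-edge pairs as attribute `"edges"`. Lobes with no
#'   within-lobe edges are omitted (message).
#' @export
lobe_summary <- function(vol_z_patients, vol_z_controls, edge_d,
                         parcellation, edge_index) {
  hemi <- parcellation$hemisphere[match(edge_index$region_i, parcellation$name)]
  hemj <- parcellation$hemisphere[match(edge_index$region_j, parcellation$name)]
  lobi <- parcellation$lobe[match(edge_index$region_i, parcellation$name)]
  lobj <- parcellation$lobe[match(edge_index$region_j, parcellation$name)]
  within <- which(hemi == hemj & lobi == lobj)
  vol_d <- cohens_d(endpoint_mean_z(vol_z_patients, edge_index),
                    endpoint_mean_z(vol_z_controls, edge_index))
  ed <- edge_d$d[match(edge_index$edge, edge_d$feature)]
  pairs <- data.frame(edge = edge_index$edge[within],
                      lobe = paste(hemi[within], lobi[within], sep = "."),
                      edge_d = ed[within], vol_d = vol_d$d[within],
                      stringsAsFactors = FALSE)
  all_lobes <- unique(paste(parcellation$hemisphere, parcellation$lobe,
                            sep = "."))
  empty <- setdiff(all_lobes, unique(pairs$lobe))
  if (length(empty))
    message("lobes without within-lobe edges omitted: ",
            paste(empty, collapse = ", "))
  agg <- do.call(rbind, lapply(split(pairs, pairs$lobe), function(g)
    data.frame(lobe = g$lobe[1L], n_edges = nrow(g),
               mean_edge_d = mean(g$edge_d, na.rm = TRUE),
               mean_vol_d = mean(g$vol_d, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  attr(agg, "edges") <- pairs
  agg
}
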