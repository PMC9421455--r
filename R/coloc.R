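# Within-patient co-localisation of node and edge abnormalities.
#
# The Dice-style statistic is implemented exactly as printed in the source
# analysis, WITHOUT the conventional factor 2 (its maximum is therefore 0.5);
# the permutation percentile is invariant to that choice. For each edge the
# alphabetically-first endpoint is "region one".

#' Dice similarity of node and incident edge abnormalities for one subject
#'
#' With `V'_i` the region-one abnormality vector over edges, `C'` the edge
#' abnormality vector and `V'_j` the region-two vector:
#' `DS_i = |V'_i & C'| / (|V'_i| + |C'|)`, `DS_j` symmetrically, and
#' `DS = (DS_i + DS_j)/2`. Components with denominator 0 are defined as 0.
#'
#' @param vol_mask_row Named logical vector over regions (one subject).
#' @param edge_mask_row Logical vector over edges, ordered as `edge_index`.
#' @param edge_index Edge index.
#' @return A `dice_result` list: `ds_i`, `ds_j`, `ds`, and the cardinalities.
#' @export
dice_similarity <- function(vol_mask_row, edge_mask_row, edge_index) {
  if (length(edge_mask_row) != nrow(edge_index))
    stop("edge mask length does not match the edge index")
  vi <- vol_mask_row[edge_index$region_i]
  vj <- vol_mask_row[edge_index$region_j]
  if (anyNA(vi) || anyNA(vj))
    stop("node mask is missing regions referenced by the edge index")
  cc <- as.logical(edge_mask_row)
  n_vi <- sum(vi); n_vj <- sum(vj); n_c <- sum(cc)
  ds_i <- if (n_vi + n_c > 0) sum(vi & cc) / (n_vi + n_c) else 0
  ds_j <- if (n_vj + n_c > 0) sum(vj & cc) / (n_vj + n_c) else 0
  structure(list(ds_i = ds_i, ds_j = ds_j, ds = (ds_i + ds_j) / 2,
                 n_region_one = n_vi, n_region_two = n_vj, n_edges_abn = n_c,
                 inter_i = sum(vi & cc), inter_j = sum(vj & cc)),
            class = "dice_result")
}

# Vectorized DS over count-preserving permutations of the edge abnormality
# labels: `idx` is an m x n_perm matrix of sampled edge indices.
#' @keywords internal
dice_null <- function(vi, vj, idx) {
  m <- nrow(idx); n_perm <- ncol(idx)
  ii <- matrix(as.numeric(vi[idx]), m, n_perm)
  jj <- matrix(as.numeric(vj[idx]), m, n_perm)
  si <- sum(vi); sj <- sum(vj)
  di <- if (si + m > 0) colSums(ii) / (si + m) else rep(0, n_perm)
  dj <- if (sj + m > 0) colSums(jj) / (sj + m) else rep(0, n_perm)
  (di + dj) / 2
}

#' Permutation-based co-localisation score for one subject
#'
#' Permutes which edges are abnormal (uniformly over edges, preserving the
#' abnormal-edge count; node masks never permuted), recomputes the Dice
#' statistic `n_perm` times, and returns the strict-inequality percentile
#' `mean(DS_actual > DS_null)`. Subjects with zero abnormal regions or zero
#' abnormal edges have an undefined (NA) score.
#'
#' @inheritParams dice_similarity
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed; deterministic given it (caller's RNG untouched).
#' @param scope Label stored with the result.
#' @return A `coloc_result` list: `score`, `defined`, `ds` (a `dice_result`),
#'   `null` (the permuted DS values), `n_perm`, `seed`, `scope`.
#' @export
colocalisation_score <- function(vol_mask_row, edge_mask_row, edge_index,
                                 n_perm = 5000L, seed = 1L,
                                 scope = "whole-brain") {
  stopifnot(n_perm >= 1)
  ds <- dice_similarity(vol_mask_row, edge_mask_row, edge_index)
  n_edges <- nrow(edge_index)
  m <- ds$n_edges_abn
  any_region <- any(vol_mask_row[unique(c(edge_index$region_i,
                                          edge_index$region_j))])
  if (m == 0L || !any_region) {
    return(structure(list(score = NA_real_, defined = FALSE, ds = ds,
                          null = NULL, n_perm = n_perm, seed = seed,
                          scope = scope), class = "coloc_result"))
  }
  vi <- as.logical(vol_mask_row[edge_index$region_i])
  vj <- as.logical(vol_mask_row[edge_index$region_j])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n_edges, m),
                integer(m))
  idx <- matrix(idx, nrow = m)
  null <- dice_null(vi, vj, idx)
  structure(list(score = mean(ds$ds > null), defined = TRUE, ds = ds,
                 null = null, n_perm = n_perm, seed = seed, scope = scope),
            class = "coloc_result")
}

#' Exact co-localisation percentile by exhaustive enumeration
#'
#' Enumerates all count-preserving edge masks (use only for small edge sets);
#' the test-suite oracle for [colocalisation_score()].
#' @inheritParams colocalisation_score
#' @return Exact `mean(DS_actual > DS_null)` over all C(n_edges, m) masks.
#' @export
colocalisation_exact <- function(vol_mask_row, edge_mask_row, edge_index) {
  ds <- dice_similarity(vol_mask_row, edge_mask_row, edge_index)
  m <- ds$n_edges_abn
  n_edges <- nrow(edge_index)
  if (m == 0L) return(NA_real_)
  vi <- as.logical(vol_mask_row[edge_index$region_i])
  vj <- as.logical(vol_mask_row[edge_index$region_j])
  combos <- utils::combn(n_edges, m)
  null <- dice_null(vi, vj, matrix(combos, nrow = m))
  mean(ds$ds > null)
}

#' Hemisphere-restricted co-localisation scores
#'
#' Recomputes the score separately on ipsilateral-only and contralateral-only
#' connections (interhemispheric edges excluded from both); node masks are
#' restricted to the corresponding hemisphere. Expects the ipsi/contra frame.
#'
#' @inheritParams colocalisation_score
#' @param parcellation Ipsi/contra-frame catalogue.
#' @return List with elements `ipsi` and `contra`, each a `coloc_result`
#'   (undefined when the restricted subset has no abnormalities).
#' @export
hemispheric_scores <- function(vol_mask_row, edge_mask_row, edge_index,
                               parcellation, n_perm = 5000L, seed = 1L) {
  labels <- classify_edges(edge_index, parcellation, "ipsi")
  out <- list()
  for (side in c("ipsi", "contra")) {
    lab <- paste0(if (side == "ipsi") "ipsilateral" else "contralateral",
                  "-only")
    keep <- which(labels == lab)
    sub_ei <- edge_index[keep, , drop = FALSE]
    class(sub_ei) <- c("edge_index", "data.frame")
    regions <- parcellation$name[parcellation$hemisphere == side]
    vm <- vol_mask_row[intersect(names(vol_mask_row), regions)]
    out[[side]] <- colocalisation_score(vm, edge_mask_row[keep], sub_ei,
                                        n_perm = n_perm,
                                        seed = seed + (side == "contra"),
                                        scope = paste0(lab))
  }
  out
}

#' Paired ipsi-vs-contra comparison in strongly co-localised patients
#'
#' Restricted to patients whose whole-brain co-localisation score is at least
#' `cutoff` and whose hemispheric scores are both defined; Wilcoxon
#' signed-rank test (the paired analogue of the Mann-Whitney U test), exact
#' for n <= 25, normal approximation with continuity/tie correction
#' otherwise.
#'
#' @param whole,ipsi,contra Numeric score vectors, aligned by patient.
#' @param cutoff Eligibility threshold on the whole-brain score.
#' @return List with `p_value`, `statistic`, `n`, `median_ipsi`,
#'   `median_contra`, `direction`.
#' @export
compare_hemispheres <- function(whole, ipsi, contra, cutoff = 0.95) {
  ok <- !is.na(whole) & !is.na(ipsi) & !is.na(contra) & whole >= cutoff
  n <- sum(ok)
  if (n < 5) stop("fewer than 5 eligible patients with both sides defined (",
                  n, ")")
  x <- ipsi[ok]; y <- contra[ok]
  d <- x - y
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, n = n,
                median_ipsi = stats::median(x), median_contra = stats::median(y),
                direction = "none"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = n <= 25, correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), n = n,
       median_ipsi = stats::median(x), median_contra = stats::median(y),
       direction = if (stats::median(d) > 0) "ipsi > contra"
       else if (stats::median(d) < 0) "contra > ipsi" else "none")
}

#' Co-localisation over a cohort
#'
#' Runs [colocalisation_score()] (and optionally [hemispheric_scores()]) for
#' every subject of a mask pair.
#'
#' @param vol_mask,edge_mask `abn_mask` objects over the same subjects.
#' @param edge_index Edge index matching the edge-mask columns.
#' @param parcellation Needed when `hemispheres = TRUE` (ipsi/contra frame).
#' @param n_perm,seed Permutation settings; subject i uses `seed + 7 i`.
#' @param hemispheres Also compute hemisphere-restricted scores.
#' @return Data frame: subject, score, ds, counts, and when requested
#'   `score_ipsi`/`score_contra`.
#' @export
cohort_colocalisation <- function(vol_mask, edge_mask, edge_index,
                                  parcellation = NULL, n_perm = 5000L,
                                  seed = 1L, hemispheres = FALSE) {
  subj <- intersect(rownames(vol_mask$mask), rownames(edge_mask$mask))
  rows <- lapply(seq_along(subj), function(k) {
    s <- subj[k]
    vm <- vol_mask$mask[s, ]; em <- edge_mask$mask[s, edge_index$edge]
    cs <- colocalisation_score(vm, em, edge_index, n_perm = n_perm,
                               seed = seed + 7L * k)
    row <- data.frame(subject_id = s, scope = cs$scope, score = cs$score,
                      ds = cs$ds$ds, n_regions_abn = sum(vm),
                      n_edges_abn = cs$ds$n_edges_abn, n_perm = n_perm,
                      seed = seed + 7L * k, stringsAsFactors = FALSE)
    if (hemispheres) {
      hs <- hemispheric_scores(vm, em, edge_index, parcellation,
                               n_perm = n_perm, seed = seed + 7L * k + 3L)
      row$score_ipsi <- hs$ipsi$score
      row$score_contra <- hs$contra$score
    }
    row
  })
  do.call(rbind, rows)
}
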