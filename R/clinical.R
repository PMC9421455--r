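# Clinical associations: abnormality burden and co-localisation vs epilepsy
# duration, surgical outcome (ILAE 1 vs 2+) and secondary generalisation.

#' Per-subject abnormality burden
#'
#' @param node_mask,edge_mask `abn_mask` objects over the same subjects.
#' @return Data frame: `subject_id`, `prop_regions`, `prop_edges`,
#'   `n_regions_abn`, `n_edges_abn`.
#' @export
abnormality_burden <- function(node_mask, edge_mask) {
  subj <- intersect(rownames(node_mask$mask), rownames(edge_mask$mask))
  nm <- node_mask$mask[subj, , drop = FALSE]
  em <- edge_mask$mask[subj, , drop = FALSE]
  data.frame(subject_id = subj,
             prop_regions = rowSums(nm) / ncol(nm),
             prop_edges = rowSums(em) / ncol(em),
             n_regions_abn = rowSums(nm), n_edges_abn = rowSums(em),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation of a per-patient measure with epilepsy duration
#'
#' Two-sided test; incomplete pairs dropped with a message.
#'
#' @param values Per-patient measure.
#' @param duration Duration in years, aligned with `values`.
#' @return List with `r`, `p_value`, `n`, `defined`.
#' @export
duration_correlation <- function(values, duration) {
  ok <- is.finite(values) & is.finite(duration)
  if (sum(!ok)) message(sum(!ok), " incomplete pair(s) dropped")
  x <- values[ok]; y <- duration[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Two-group comparison: Cohen's d and Mann-Whitney U p-value
#'
#' Unpaired pooled-SD Cohen's d (first level minus second level) and
#' two-sided Mann-Whitney (Wilcoxon rank-sum) p-value, exact for small
#' tie-free samples.
#'
#' @param values Numeric measure.
#' @param groups Binary labels (factor or coercible; first level is the
#'   reference reported first in the difference).
#' @return List with `d`, `p_value`, `n1`, `n2`, `levels`.
#' @export
group_comparison <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  x <- values[groups == levels(groups)[1L]]
  y <- values[groups == levels(groups)[2L]]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 subjects per group")
  s <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
              (length(x) + length(y) - 2))
  d <- if (s > 0) (mean(x) - mean(y)) / s else NA_real_
  p <- if (identical(x, y)) 1 else
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(d = d, p_value = p, n1 = length(x), n2 = length(y),
       levels = levels(groups))
}

#' Clinical association grid
#'
#' The 3 x 3 grid of clinical variables (duration, surgical outcome,
#' secondary generalisation) against measures (co-localisation score,
#' proportion of abnormal regions, proportion of abnormal connections).
#' Pearson r for duration; Cohen's d + Mann-Whitney p for binary groups.
#' Outcome is dichotomised ILAE 1 vs ILAE 2+.
#'
#' @param patients Patient metadata (columns `subject_id`, `duration`,
#'   `outcome`, `secondary_generalisation`).
#' @param measures Data frame with `subject_id`, `coloc`, `prop_regions`,
#'   `prop_edges`.
#' @param bh_adjust Apply Benjamini-Hochberg across the 9 cells (off by
#'   default; raw p-values mirror the source analysis).
#' @return An `association_table` data frame: clinical variable, measure,
#'   effect size, test name, p-value (optionally `p_adj`), n.
#' @export
association_table <- function(patients, measures, bh_adjust = FALSE) {
  m <- merge(patients, measures, by = "subject_id")
  meas <- c(coloc = "coloc", regions = "prop_regions", edges = "prop_edges")
  rows <- list()
  for (nm in names(meas)) {
    v <- m[[meas[nm]]]
    dc <- duration_correlation(v, m$duration)
    rows[[length(rows) + 1L]] <- data.frame(
      clinical = "duration", measure = nm, effect = dc$r, test = "pearson",
      p_value = dc$p_value, n = dc$n, stringsAsFactors = FALSE)
    gc_out <- group_comparison(v, factor(m$outcome, c("ILAE1", "ILAE2+")))
    rows[[length(rows) + 1L]] <- data.frame(
      clinical = "surgical_outcome", measure = nm, effect = gc_out$d,
      test = "cohens_d+mann_whitney", p_value = gc_out$p_value,
      n = gc_out$n1 + gc_out$n2, stringsAsFactors = FALSE)
    gc_sg <- group_comparison(v, factor(m$secondary_generalisation,
                                        c(TRUE, FALSE)))
    rows[[length(rows) + 1L]] <- data.frame(
      clinical = "secondary_generalisation", measure = nm, effect = gc_sg$d,
      test = "cohens_d+mann_whitney", p_value = gc_sg$p_value,
      n = gc_sg$n1 + gc_sg$n2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (bh_adjust) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  class(out) <- c("association_table", "data.frame")
  out
}
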