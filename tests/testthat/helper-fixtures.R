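# Shared fixtures, built in code at test time.

# Tiny edge index over arbitrary region names (no parcellation validation).
toy_edge_index <- function(region_i, region_j) {
  a <- pmin(region_i, region_j); b <- pmax(region_i, region_j)
  ei <- data.frame(edge_id = seq_along(a), region_i = a, region_j = b,
                   edge = paste0(a, "--", b), stringsAsFactors = FALSE)
  class(ei) <- c("edge_index", "data.frame")
  ei
}

# Worked 4-edge toy subject: two abnormal volumes (hippocampus, temporal
# pole), two abnormal connections (thalamus-amygdala, thalamus-temporalpole).
# The "a_"/"b_"/"c_" prefixes keep the thalamus as the nominal region one
# under canonical (alphabetical) endpoint ordering.
table2_fixture <- function() {
  ei <- toy_edge_index(
    c("a_thalamus", "a_thalamus", "a_thalamus", "c_insula"),
    c("b_hippocampus", "b_amygdala", "b_temporalpole",
      "c_transversetemporal"))
  vol <- c(a_thalamus = FALSE, b_amygdala = FALSE, b_hippocampus = TRUE,
           b_temporalpole = TRUE, c_insula = FALSE,
           c_transversetemporal = FALSE)
  edge <- ei$edge %in% c("a_thalamus--b_amygdala",
                         "a_thalamus--b_temporalpole")
  list(ei = ei, vol = vol, edge = edge)
}

# Simulate an edge-direction model frame straight from the two-level model.
simulate_edge_frame <- function(n_subj, n_edge, fixed = c(-0.38, -0.45, -0.49),
                                re_sd = c(0.3, 0.15, 0.15), resid_sd = 1,
                                p_one = 0.15, p_two = 0.05, seed = 1) {
  set.seed(seed)
  re <- matrix(MASS::mvrnorm(n_subj, c(0, 0, 0), diag(re_sd^2)), n_subj)
  vp <- matrix(stats::rbinom(n_subj * n_edge, 1, p_one), n_subj)
  vd <- matrix(stats::rbinom(n_subj * n_edge, 1, p_two), n_subj) * (1 - vp)
  z <- (fixed[1] + re[, 1]) + (fixed[2] + re[, 2]) * vp +
    (fixed[3] + re[, 3]) * vd +
    matrix(stats::rnorm(n_subj * n_edge, 0, resid_sd), n_subj)
  fr <- data.frame(subject = factor(rep(sprintf("P%03d", seq_len(n_subj)),
                                        n_edge)),
                   z = as.vector(z), vprime = as.vector(vp),
                   vdouble = as.vector(vd))
  attr(fr, "direction") <- "edge"
  attr(fr, "counts") <- c(none = sum(vp == 0 & vd == 0), one = sum(vp),
                          two = sum(vd))
  class(fr) <- c("model_frame", "data.frame")
  fr
}

# ztable / abn_mask constructors for hand-built matrices.
as_ztable <- function(z, kind, frame = "anatomical") {
  structure(list(z = z, kind = kind, frame = frame), class = "ztable")
}
as_mask <- function(mask, tau, kind, frame = "anatomical") {
  structure(list(mask = mask, tau = tau, kind = kind, frame = frame),
            class = "abn_mask")
}

# Ipsi/contra-frame feature space of the default fixture.
default_ipsi_space <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      parc <- load_default_parcellation()
      ei <- default_edge_index(parc)
      parc_ic <- ipsicontra_parcellation(parc)
      maps <- epicoloc:::ipsi_column_maps(ei$edge)
      ei_ic <- build_edge_index(parc_ic, do.call(rbind, strsplit(
        maps$ipsi, "--", fixed = TRUE)))
      cache <<- list(parc = parc, ei = ei, parc_ic = parc_ic, ei_ic = ei_ic)
    }
    cache
  }
})
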