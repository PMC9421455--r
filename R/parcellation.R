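# Region catalogue and edge-index machinery.
#
# All other modules reference features by name: regions as "lh_<name>" /
# "rh_<name>" (or "ipsi_<name>" / "contra_<name>" after flipping) and edges
# as "<name_a>--<name_b>" with the two endpoint names in alphabetical order.

# Desikan-Killiany cortical regions and their lobar assignment (34 per
# hemisphere) plus seven subcortical structures per hemisphere: 82 regions.
.dk_cortical <- c(
  bankssts = "temporal", caudalanteriorcingulate = "cingulate",
  caudalmiddlefrontal = "frontal", cuneus = "occipital",
  entorhinal = "temporal", fusiform = "temporal",
  inferiorparietal = "parietal", inferiortemporal = "temporal",
  isthmuscingulate = "cingulate", lateraloccipital = "occipital",
  lateralorbitofrontal = "frontal", lingual = "occipital",
  medialorbitofrontal = "frontal", middletemporal = "temporal",
  parahippocampal = "temporal", paracentral = "frontal",
  parsopercularis = "frontal", parsorbitalis = "frontal",
  parstriangularis = "frontal", pericalcarine = "occipital",
  postcentral = "parietal", posteriorcingulate = "cingulate",
  precentral = "frontal", precuneus = "parietal",
  rostralanteriorcingulate = "cingulate", rostralmiddlefrontal = "frontal",
  superiorfrontal = "frontal", superiorparietal = "parietal",
  superiortemporal = "temporal", supramarginal = "parietal",
  frontalpole = "frontal", temporalpole = "temporal",
  transversetemporal = "temporal", insula = "insula")

.dk_subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                     "hippocampus", "amygdala", "accumbens")

#' Load the default 82-region parcellation
#'
#' Returns the packaged catalogue of 34 Desikan-Killiany cortical regions plus
#' 7 subcortical structures per hemisphere (82 regions in total), each with a
#' lobar label. Regions come in left/right homologous pairs with `lh_`/`rh_`
#' name prefixes, matching FreeSurfer naming conventions.
#'
#' @return A `parcellation` object: a data frame with columns `region_id`
#'   (0-based integer), `name`, `hemisphere` (`"left"`/`"right"`), `lobe`
#'   (frontal, temporal, parietal, occipital, cingulate, insula, subcortical)
#'   and `subcortical` (logical).
#' @examples
#' parc <- load_default_parcellation()
#' nrow(parc)            # 82
#' table(parc$hemisphere)
#' @export
load_default_parcellation <- function() {
  base <- c(.dk_cortical,
            stats::setNames(rep("subcortical", length(.dk_subcortical)),
                            .dk_subcortical))
  df <- data.frame(
    name = c(paste0("lh_", names(base)), paste0("rh_", names(base))),
    hemisphere = rep(c("left", "right"), each = length(base)),
    lobe = rep(unname(base), 2L),
    subcortical = rep(base == "subcortical", 2L),
    stringsAsFactors = FALSE)
  df <- df[order(df$name), ]
  df <- data.frame(region_id = seq_len(nrow(df)) - 1L, df,
                   row.names = NULL, stringsAsFactors = FALSE)
  class(df) <- c("parcellation", "data.frame")
  validate_parcellation(df)
  df
}

#' @keywords internal
validate_parcellation <- function(parc) {
  stopifnot(is.data.frame(parc),
            all(c("region_id", "name", "hemisphere", "lobe",
                  "subcortical") %in% names(parc)))
  if (anyDuplicated(parc$name))
    stop("parcellation: duplicated region names")
  if (!all(parc$hemisphere %in% c("left", "right", "ipsi", "contra")))
    stop("parcellation: hemisphere must be left/right (or ipsi/contra)")
  lobes <- c("frontal", "temporal", "parietal", "occipital", "cingulate",
             "insula", "subcortical")
  if (!all(parc$lobe %in% lobes))
    stop("parcellation: unknown lobe label")
  if (nrow(parc) %% 2L != 0L)
    stop("parcellation: regions must come in homologous pairs")
  homol <- homologue_names(parc$name)
  if (!all(homol %in% parc$name))
    stop("parcellation: missing homologue for some regions")
  invisible(parc)
}

# Name of the opposite-hemisphere homologue ("lh_x" <-> "rh_x",
# "ipsi_x" <-> "contra_x").
#' @keywords internal
homologue_names <- function(names) {
  out <- names
  out <- sub("^lh_", "LH@", out); out <- sub("^rh_", "lh_", out)
  out <- sub("^LH@", "rh_", out)
  out <- sub("^ipsi_", "IP@", out); out <- sub("^contra_", "ipsi_", out)
  out <- sub("^IP@", "contra_", out)
  out
}

#' @keywords internal
edge_name <- function(a, b) {
  swap <- a > b
  ai <- ifelse(swap, b, a); bi <- ifelse(swap, a, b)
  paste0(ai, "--", bi)
}

#' Build a canonical edge index from an adjacency relation
#'
#' @param parcellation A [load_default_parcellation()]-style catalogue.
#' @param adjacency Either a symmetric logical matrix with region names as
#'   dimnames, or a two-column character matrix/data frame of region-name
#'   pairs.
#' @return An `edge_index` data frame with columns `edge_id` (1-based),
#'   `region_i`, `region_j` (region names, alphabetically ordered within each
#'   pair) and `edge` (the canonical `"i--j"` label). Duplicate pairs are
#'   collapsed; self-loops or unknown regions are an error.
#' @export
build_edge_index <- function(parcellation, adjacency) {
  validate_parcellation(parcellation)
  if (is.matrix(adjacency) && (is.logical(adjacency) || is.numeric(adjacency))) {
    if (is.null(rownames(adjacency)) || is.null(colnames(adjacency)))
      stop("adjacency matrix must carry region names as dimnames")
    if (!isTRUE(all.equal(adjacency, t(adjacency))))
      stop("adjacency matrix must be symmetric")
    idx <- which(adjacency != 0, arr.ind = TRUE)
    pairs <- cbind(rownames(adjacency)[idx[, 1L]],
                   colnames(adjacency)[idx[, 2L]])
  } else {
    pairs <- as.matrix(as.data.frame(adjacency)[, 1:2])
    storage.mode(pairs) <- "character"
  }
  if (nrow(pairs) == 0L) {
    ei <- data.frame(edge_id = integer(0), region_i = character(0),
                     region_j = character(0), edge = character(0),
                     stringsAsFactors = FALSE)
    class(ei) <- c("edge_index", "data.frame")
    return(ei)
  }
  unknown <- setdiff(unique(c(pairs)), parcellation$name)
  if (length(unknown))
    stop("edge index references unknown regions: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  selfloop <- pairs[, 1L] == pairs[, 2L]
  if (any(selfloop))
    stop("self-loop edge rejected: ", pairs[which(selfloop)[1L], 1L])
  a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
  key <- paste0(a, "--", b)
  keep <- !duplicated(key)
  ord <- order(a[keep], b[keep])
  ei <- data.frame(edge_id = seq_len(sum(keep)),
                   region_i = a[keep][ord], region_j = b[keep][ord],
                   edge = key[keep][ord], stringsAsFactors = FALSE)
  class(ei) <- c("edge_index", "data.frame")
  ei
}

#' Default pseudo-anatomical edge fixture (1289 edges)
#'
#' The study-scale tractography-atlas edge set is atlas-version dependent and
#' not shipped; this deterministic stand-in reproduces its scale (1,289 edges
#' over 82 regions, density ~0.39) with enrichment of within-lobe and
#' within-hemisphere pairs, and is built mirror-symmetric across hemispheres
#' so the ipsi/contra flip loses no edges. Seeded internally: identical on
#' every call, regardless of the caller's RNG state.
#'
#' @param parcellation Region catalogue; defaults to the packaged 82-region
#'   one.
#' @param n_edges Total edge count (default 1289).
#' @return An `edge_index`.
#' @export
default_edge_index <- function(parcellation = load_default_parcellation(),
                               n_edges = 1289L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(820L)

  left <- parcellation$name[parcellation$hemisphere %in% c("left", "ipsi")]
  stem <- sub("^(lh|ipsi)_", "", left)
  n <- length(left)
  # candidate left-intra pairs with affinity weights
  li <- t(utils::combn(n, 2L))
  lobe <- parcellation$lobe[match(left, parcellation$name)]
  w_li <- 1 + 3 * (lobe[li[, 1L]] == lobe[li[, 2L]])
  # interhemispheric non-homotopic pairs (i on left, j on right, stems differ)
  ih <- expand.grid(i = seq_len(n), j = seq_len(n))
  ih <- ih[ih$i != ih$j & ih$i < ih$j, ]          # one of each mirror pair
  w_ih <- 0.4 + 1.2 * (lobe[ih$i] == lobe[ih$j])

  n_homotopic <- if (n_edges %% 2L == 1L) 7L else 6L
  n_intra <- round(0.70 * (n_edges - n_homotopic) / 2)
  n_inter_pairs <- (n_edges - n_homotopic - 2L * n_intra) / 2L
  stopifnot(n_intra <= nrow(li), n_inter_pairs <= nrow(ih))

  pick_li <- sample.int(nrow(li), n_intra, prob = w_li)
  pick_ih <- sample.int(nrow(ih), n_inter_pairs, prob = w_ih)
  # homotopic edges: prefer subcortical + temporal stems
  homo_pref <- order(!(parcellation$subcortical[match(left, parcellation$name)] |
                         lobe == "temporal"), stem)
  pick_ho <- homo_pref[seq_len(n_homotopic)]

  rname <- homologue_names(left)
  pairs <- rbind(
    cbind(left[li[pick_li, 1L]], left[li[pick_li, 2L]]),
    cbind(rname[li[pick_li, 1L]], rname[li[pick_li, 2L]]),
    cbind(left[ih$i[pick_ih]], rname[ih$j[pick_ih]]),
    cbind(rname[ih$i[pick_ih]], left[ih$j[pick_ih]]),
    cbind(left[pick_ho], rname[pick_ho]))
  build_edge_index(parcellation, pairs)
}

#' Classify edges by endpoint hemispheres
#'
#' @param edge_index An `edge_index`.
#' @param parcellation Matching region catalogue.
#' @param ipsi_side Which anatomical hemisphere plays the ipsilateral role:
#'   `"left"`, `"right"`, or `"ipsi"` for tables already in the
#'   ipsi/contra frame (the default).
#' @return Character vector (one per edge) in
#'   `{"ipsilateral-only", "contralateral-only", "interhemispheric"}`.
#' @export
classify_edges <- function(edge_index, parcellation, ipsi_side = "ipsi") {
  stopifnot(ipsi_side %in% c("left", "right", "ipsi"))
  hemi <- parcellation$hemisphere[match(edge_index$region_i, parcellation$name)]
  hemj <- parcellation$hemisphere[match(edge_index$region_j, parcellation$name)]
  if (anyNA(hemi) || anyNA(hemj))
    stop("edge index references regions absent from the parcellation")
  ipsi_lab <- ipsi_side
  contra_lab <- switch(ipsi_side, left = "right", right = "left", ipsi = "contra")
  ifelse(hemi != hemj, "interhemispheric",
         ifelse(hemi == ipsi_lab, "ipsilateral-only", "contralateral-only"))
}

#' Write / read parcellation and edge-index TSVs
#'
#' Plain TSV round-trip with a single header row.
#' @param x Object to write.
#' @param path File path.
#' @name parcellation_io
#' @export
write_parcellation <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname parcellation_io
#' @export
read_parcellation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("parcellation", "data.frame")
  validate_parcellation(df)
  df
}

#' @rdname parcellation_io
#' @export
write_edge_index <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("edge_id", "region_i", "region_j")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname parcellation_io
#' @param parcellation Catalogue used to validate region names on read.
#' @export
read_edge_index <- function(path, parcellation) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_edge_index(parcellation, df[, c("region_i", "region_j")])
}
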