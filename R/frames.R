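# Anatomical <-> ipsilateral/contralateral frame machinery.
#
# Patients are lateralised (L or R temporal lobe onset). Analyses pool
# hemispheres by relabelling each patient's onset side "ipsi" and the other
# side "contra" AFTER z-scoring against the same anatomical hemisphere in
# controls. Controls (and left-lateralised patients) keep their values and
# are only renamed, with left as the reference pseudo-ipsilateral side;
# right-lateralised patients have homologous columns swapped.

#' @keywords internal
rename_to_ipsi <- function(names, ipsi_side = "left") {
  if (ipsi_side == "right") names <- homologue_names(names)
  out <- sub("^lh_", "ipsi_", names)
  sub("^rh_", "contra_", out)
}

#' @keywords internal
rename_to_anat <- function(names, ipsi_side = "left") {
  out <- sub("^ipsi_", "lh_", names)
  out <- sub("^contra_", "rh_", out)
  if (ipsi_side == "right") out <- homologue_names(out)
  out
}

#' Parcellation in the ipsi/contra frame
#'
#' Renames regions with left as the reference ipsilateral side.
#' @param parcellation Anatomical-frame catalogue.
#' @return A `parcellation` with `ipsi_`/`contra_` names and hemispheres.
#' @export
ipsicontra_parcellation <- function(parcellation) {
  p <- parcellation
  p$name <- rename_to_ipsi(p$name)
  p$hemisphere <- ifelse(p$hemisphere == "left", "ipsi", "contra")
  p <- p[order(p$name), ]
  p$region_id <- seq_len(nrow(p)) - 1L
  rownames(p) <- NULL
  class(p) <- c("parcellation", "data.frame")
  p
}

# For a set of anatomical feature (column) names, build the ipsi/contra
# column set and, for each laterality, the anatomical source column of each
# ipsi/contra column. Edge features whose mirror edge is absent from the
# anatomical set cannot be flipped and are dropped (count returned).
#' @keywords internal
ipsi_column_maps <- function(feature_names) {
  is_edge <- grepl("--", feature_names, fixed = TRUE)
  if (any(is_edge) && !all(is_edge))
    stop("mixed node and edge feature columns")
  if (!any(is_edge)) {
    ipsi <- rename_to_ipsi(feature_names, "left")
    src_L <- feature_names
    src_R <- homologue_names(feature_names)
    missing_R <- !(src_R %in% feature_names)
    if (any(missing_R))
      stop("regions without homologues cannot be flipped: ",
           paste(utils::head(feature_names[missing_R], 3L), collapse = ", "))
    ord <- order(ipsi)
    return(list(ipsi = ipsi[ord], src_L = src_L[ord], src_R = src_R[ord],
                dropped = character(0)))
  }
  ends <- strsplit(feature_names, "--", fixed = TRUE)
  e1 <- vapply(ends, `[`, "", 1L); e2 <- vapply(ends, `[`, "", 2L)
  mirror <- edge_name(homologue_names(e1), homologue_names(e2))
  has_mirror <- mirror %in% feature_names
  keep <- which(has_mirror)
  ipsi <- edge_name(rename_to_ipsi(e1[keep], "left"),
                    rename_to_ipsi(e2[keep], "left"))
  src_L <- feature_names[keep]
  src_R <- mirror[keep]
  ord <- order(ipsi)
  list(ipsi = ipsi[ord], src_L = src_L[ord], src_R = src_R[ord],
       dropped = feature_names[!has_mirror])
}

#' Flip a z-table between anatomical and ipsi/contra frames
#'
#' In the anatomical-to-ipsi direction, right-lateralised patients have
#' homologous region columns swapped and edge columns remapped to their
#' mirrored edges; left-lateralised patients and controls (reference side:
#' left) keep their values and are only relabelled. Applying the function to
#' an ipsi/contra table inverts the mapping. Edges without a mirror in the
#' edge set are dropped from the ipsi/contra frame for all subjects (a
#' message reports the count).
#'
#' @param ztable A [ztable] (also works on an abnormality mask).
#' @param subjects Subject metadata with `subject_id`, `group`, `laterality`.
#' @param parcellation Region catalogue (anatomical frame).
#' @return A `ztable` in the opposite frame.
#' @export
flip_to_ipsicontra <- function(ztable, subjects, parcellation) {
  x <- ztable$z
  if (is.null(x)) x <- ztable$mask
  subj <- subjects[match(rownames(x), subjects$subject_id), ]
  if (anyNA(subj$subject_id))
    stop("z-table rows missing from the subject table")
  lat <- ifelse(subj$group == "patient", subj$laterality, "L")
  if (anyNA(lat) || !all(lat %in% c("L", "R")))
    stop("every patient needs laterality L or R")
  to_ipsi <- ztable$frame == "anatomical"

  if (to_ipsi) {
    maps <- ipsi_column_maps(colnames(x))
    if (length(maps$dropped))
      message(length(maps$dropped),
              " edge(s) without mirror dropped from ipsi/contra frame")
    iL <- match(maps$src_L, colnames(x))
    iR <- match(maps$src_R, colnames(x))
    out <- x[, iL, drop = FALSE]
    right <- which(lat == "R")
    if (length(right)) out[right, ] <- x[right, iR, drop = FALSE]
    colnames(out) <- maps$ipsi
  } else {
    # invert: anatomical column set is the union of L-sources; reconstruct
    ends_edge <- grepl("--", colnames(x)[1L], fixed = TRUE)
    if (ends_edge) {
      ends <- strsplit(colnames(x), "--", fixed = TRUE)
      e1 <- vapply(ends, `[`, "", 1L); e2 <- vapply(ends, `[`, "", 2L)
      anat_L <- edge_name(rename_to_anat(e1, "left"), rename_to_anat(e2, "left"))
      anat_R <- edge_name(rename_to_anat(e1, "right"), rename_to_anat(e2, "right"))
    } else {
      anat_L <- rename_to_anat(colnames(x), "left")
      anat_R <- rename_to_anat(colnames(x), "right")
    }
    all_anat <- sort(unique(c(anat_L, anat_R)))
    out <- matrix(NA_real_, nrow(x), length(all_anat),
                  dimnames = list(rownames(x), all_anat))
    mode(out) <- mode(x)
    iL <- match(anat_L, all_anat); iR <- match(anat_R, all_anat)
    for (s in seq_len(nrow(x))) {
      cols <- if (lat[s] == "R") iR else iL
      out[s, cols] <- x[s, ]
    }
    # columns never sourced for any subject would be all-NA; drop them
    keep <- colSums(!is.na(out)) == nrow(out)
    out <- out[, keep, drop = FALSE]
  }

  res <- ztable
  if (!is.null(res$z)) res$z <- out else res$mask <- out
  res$frame <- if (to_ipsi) "ipsicontra" else "anatomical"
  res
}
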