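#' Euclidean distances between family presence/absence profiles
#'
#' @param matrix Family-by-species matrix.
#' @param family_subset Optional family IDs to restrict to.
#' @param binarize_profiles Use 0/1 presence (default) rather than copy
#'   numbers.
#' @return A `dist` object over families.
#' @export
profile_distances <- function(matrix, family_subset = NULL,
                              binarize_profiles = TRUE) {
  m <- matrix
  if (!is.null(family_subset)) m <- m[family_subset, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two families")
  if (binarize_profiles) m <- binarize(m)
  stats::dist(m, method = "euclidean")
}

#' Hierarchically cluster phylogenetic profiles
#'
#' Agglomerative clustering of the profile distance matrix; flat clusters
#' are cut at a height or a cluster count. Ties in merge order follow the
#' deterministic behaviour of `stats::hclust` on the family-ID-ordered
#' distance matrix.
#'
#' @param distances A `dist` from [profile_distances()].
#' @param linkage Agglomeration method (default `"average"`).
#' @param k Number of flat clusters, or
#' @param h Cut height (one of `k`/`h` required).
#' @return A `ProfileClustering` list: `dendrogram` (`hclust`), `clusters`
#'   (named membership vector), `k`.
#' @export
cluster_profiles <- function(distances, linkage = "average", k = NULL,
                             h = NULL) {
  hc <- stats::hclust(distances, method = linkage)
  if (is.null(k) && is.null(h)) stop("supply a cluster count `k` or height `h`")
  cl <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  structure(list(dendrogram = hc, clusters = cl, k = length(unique(cl))),
            class = "ProfileClustering")
}

#' Propose annotations for unannotated families by profile clustering
#'
#' Within each flat cluster, if at least `majority_fraction` of the
#' annotated members share one functional category, every unannotated
#' member is proposed that category, with the supporting annotated members
#' listed.
#'
#' @param clustering A `ProfileClustering`.
#' @param category_of Named character vector family -> functional category;
#'   families absent from it (or mapped to `""`/`NA`) count as unannotated.
#' @param majority_fraction Required share of annotated members agreeing.
#' @return Data frame `(family_id, proposed_category, n_supporting,
#'   n_annotated, supporting)`; zero rows when nothing qualifies.
#' @export
propose_annotations <- function(clustering, category_of,
                                majority_fraction = 0.8) {
  cl <- clustering$clusters
  rows <- list()
  for (g in sort(unique(cl))) {
    members <- sort(names(cl)[cl == g])
    cats <- category_of[members]
    annotated <- !is.na(cats) & nzchar(cats)
    if (!any(annotated) || all(annotated)) next
    tab <- table(cats[annotated])
    top <- names(tab)[which.max(tab)]
    if (max(tab) / sum(annotated) < majority_fraction) next
    supporters <- members[annotated & cats == top]
    for (f in members[!annotated]) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = f, proposed_category = top,
        n_supporting = length(supporters), n_annotated = sum(annotated),
        supporting = paste(supporters, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(0), proposed_category = character(0),
               n_supporting = integer(0), n_annotated = integer(0),
               supporting = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
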