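#' Edge filter thresholds for homology graphs
#'
#' Reciprocal-coverage, relative-length and E-value cutoffs applied to
#' similarity edges before clustering (`max_evalue` 1e-10) or during
#' targeted homolog screens (1e-20).
#'
#' @param min_bidir_coverage Minimum of query and subject coverage.
#' @param min_length_ratio Minimum shorter/longer sequence length ratio.
#' @param max_evalue Maximum E-value retained.
#' @export
edge_filter_thresholds <- function(min_bidir_coverage = 0.80,
                                   min_length_ratio = 0.75,
                                   max_evalue = 1e-10) {
  stopifnot(min_bidir_coverage > 0, min_bidir_coverage <= 1,
            min_length_ratio > 0, min_length_ratio <= 1, max_evalue > 0)
  structure(list(min_bidir_coverage = min_bidir_coverage,
                 min_length_ratio = min_length_ratio,
                 max_evalue = max_evalue),
            class = "edge_filter_thresholds")
}

#' Filter similarity edges for homology clustering
#'
#' Keeps an edge iff `min(qcov, scov) >= min_bidir_coverage`,
#' `min(qlen, slen)/max(qlen, slen) >= min_length_ratio`, and
#' `evalue <= max_evalue`. Self-edges are removed, and reciprocal duplicates
#' (A->B and B->A) are merged keeping the best E-value.
#'
#' @param edges Similarity edge data frame.
#' @param thresholds An [edge_filter_thresholds()] object.
#' @return Filtered edge data frame, one row per unordered pair.
#' @export
filter_edges <- function(edges, thresholds = edge_filter_thresholds()) {
  stopifnot(inherits(thresholds, "edge_filter_thresholds"))
  if (nrow(edges) == 0) return(edges)
  keep <- pmin(edges$qcov, edges$scov) >= thresholds$min_bidir_coverage &
    pmin(edges$qlen, edges$slen) / pmax(edges$qlen, edges$slen) >=
      thresholds$min_length_ratio &
    edges$evalue <= thresholds$max_evalue &
    edges$query_id != edges$subject_id
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) return(edges)
  a <- pmin(edges$query_id, edges$subject_id)
  b <- pmax(edges$query_id, edges$subject_id)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, edges$evalue, -edges$bitscore)
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Markov clustering configuration
#'
#' @param inflation Entrywise inflation exponent (granularity control;
#'   must exceed 1).
#' @param expansion_power Matrix power used in the expansion step.
#' @param prune_threshold Entries below this are zeroed after inflation.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Maximum absolute matrix change declaring
#'   convergence.
#' @param edge_weight_transform `"neg_log10_evalue_capped"` (the classical
#'   TRIBE-style weight, capped at 200 with E-value 0 mapping to 200) or
#'   `"bitscore"`.
#' @export
mcl_config <- function(inflation = 2.5, expansion_power = 2L,
                       prune_threshold = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-8,
                       edge_weight_transform = c("neg_log10_evalue_capped",
                                                 "bitscore")) {
  stopifnot(inflation > 1, expansion_power >= 2, prune_threshold >= 0)
  structure(list(inflation = inflation,
                 expansion_power = as.integer(expansion_power),
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 edge_weight_transform = match.arg(edge_weight_transform)),
            class = "mcl_config")
}

edge_weight <- function(edges, transform) {
  switch(transform,
         neg_log10_evalue_capped = pmin(200, -log10(pmax(edges$evalue, 1e-200))),
         bitscore = edges$bitscore)
}

#' Cluster a similarity graph into protein families by Markov clustering
#'
#' Builds a column-stochastic transition matrix from transformed edge
#' weights with self-loops, then iterates expansion (matrix power) and
#' inflation (entrywise power followed by column renormalization) with
#' pruning until the matrix change drops below `convergence_tol`. Clusters
#' are read off as connected components of the limit matrix's non-zero
#' structure. Proteins named in `universe` but absent from the kept edges
#' become singleton families. The protein universe is sorted
#' lexicographically before matrix construction, so the result is
#' deterministic.
#'
#' @param edges Filtered similarity edges (see [filter_edges()]).
#' @param config An [mcl_config()].
#' @param universe Optional character vector of all protein IDs (isolated
#'   proteins become singletons).
#' @return A `FamilySet`: list with `families` (named list of protein ID
#'   vectors, ordered by decreasing size), `membership` (named family-ID
#'   vector over proteins), and `converged` flag.
#' @export
mcl_cluster <- function(edges, config = mcl_config(), universe = NULL) {
  stopifnot(inherits(config, "mcl_config"))
  ids <- sort(unique(c(edges$query_id, edges$subject_id, universe)))
  n <- length(ids)
  if (n == 0) return(family_set(list()))
  idx <- seq_len(n); names(idx) <- ids
  w <- edge_weight(edges, config$edge_weight_transform)
  i <- idx[edges$query_id]; j <- idx[edges$subject_id]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), use.last.ij = FALSE)
  A <- (A + Matrix::t(A)) / 2  # symmetrize duplicate accumulation
  # self-loops at the maximum incident weight (unit for isolated nodes)
  loop <- apply_max_col(A)
  loop[loop == 0] <- 1
  Matrix::diag(A) <- loop
  M <- normalize_cols(A)
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    Mexp <- M
    for (k in seq_len(config$expansion_power - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^config$inflation
    Minf <- Matrix::drop0(Minf, tol = config$prune_threshold)
    Minf <- normalize_cols(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < config$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Markov clustering did not converge in ", config$max_iterations,
            " iterations; returning current clustering")
  }
  S <- M + Matrix::t(M)
  comp <- graph_components(S)
  fams <- split(ids, comp)
  fams <- fams[order(-lengths(fams), vapply(fams, `[`, character(1), 1))]
  fs <- family_set(unname(fams))
  fs$converged <- converged
  fs
}

apply_max_col <- function(A) {
  x <- numeric(nrow(A))
  T <- methods::as(A, "TsparseMatrix")
  if (length(T@x)) {
    agg <- tapply(T@x, T@j, max)
    x[as.integer(names(agg)) + 1L] <- agg
  }
  x
}

normalize_cols <- function(A) {
  cs <- Matrix::colSums(A)
  cs[cs == 0] <- 1
  A %*% Matrix::Diagonal(x = 1 / cs)
}

graph_components <- function(S) {
  n <- nrow(S)
  T <- methods::as(S, "TsparseMatrix")
  adj <- split(T@i + 1L, T@j + 1L)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- adj[[as.character(v)]]
      if (!is.null(nb)) stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

#' Construct a family set from a membership list
#'
#' @param families List of character vectors of protein IDs (disjoint).
#' @param family_ids Optional family names; default `fam00001` style, in
#'   decreasing size order.
#' @return A `FamilySet` list with `families` and `membership`.
#' @export
family_set <- function(families, family_ids = NULL) {
  if (is.null(family_ids)) {
    family_ids <- sprintf("fam%05d", seq_along(families))
  }
  names(families) <- family_ids
  all_ids <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("families must be disjoint; duplicated protein(s): ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  membership <- rep(family_ids, lengths(families))
  names(membership) <- all_ids
  structure(list(families = families, membership = membership,
                 converged = TRUE),
            class = "FamilySet")
}

#' @export
print.FamilySet <- function(x, ...) {
  cat("FamilySet:", length(x$families), "families,",
      length(x$membership), "proteins;",
      sum(lengths(x$families) == 1L), "singletons\n")
  invisible(x)
}

#' Per-family membership counts
#'
#' @param families A `FamilySet`.
#' @param species_of Named character vector protein ID -> species ID.
#' @param genus_of Optional named character vector species -> genus.
#' @return Data frame with `family_id`, `n_members`, `n_species`, `n_genera`,
#'   `singleton`.
#' @export
family_counts <- function(families, species_of, genus_of = NULL) {
  fam_ids <- names(families$families)
  n_members <- lengths(families$families)
  n_species <- vapply(families$families, function(p) {
    length(unique(species_of[p]))
  }, integer(1))
  n_genera <- if (is.null(genus_of)) NA_integer_ else
    vapply(families$families, function(p) {
      length(unique(genus_of[unique(species_of[p])]))
    }, integer(1))
  data.frame(family_id = fam_ids, n_members = n_members,
             n_species = n_species, n_genera = n_genera,
             singleton = n_members == 1L, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benchmark the inflation parameter against curated families
#'
#' Clusters the edge set at each inflation value and scores agreement with a
#' manually curated family set by the adjusted Rand index restricted to the
#' curated proteins.
#'
#' @param edges Filtered similarity edges.
#' @param curated A `FamilySet` covering a subset of the protein universe.
#' @param inflation_grid Numeric vector of inflation values.
#' @param config Base [mcl_config()]; its inflation is overridden.
#' @return Data frame `(inflation, ari)` with attribute `best` holding the
#'   argmax inflation.
#' @export
benchmark_inflation <- function(edges, curated,
                                inflation_grid = c(1.4, 2, 2.5, 3, 4, 5, 6, 8),
                                config = mcl_config()) {
  if (length(curated$membership) == 0) stop("curated family set is empty")
  curated_ids <- names(curated$membership)
  ari <- vapply(inflation_grid, function(I) {
    cfg <- config; cfg$inflation <- I
    fs <- mcl_cluster(edges, cfg)
    common <- intersect(curated_ids, names(fs$membership))
    if (length(common) < 2) return(NA_real_)
    mclust::adjustedRandIndex(fs$membership[common],
                              curated$membership[common])
  }, numeric(1))
  out <- data.frame(inflation = inflation_grid, ari = ari)
  attr(out, "best") <- inflation_grid[which.max(ari)]
  out
}

#' Screen query proteins for homologs across species
#'
#' Applies the strict screen thresholds (default E-value cutoff 1e-20 with
#' the reciprocal 80% coverage / 75% length filters) to query-vs-proteome
#' similarity results and reports a query-by-species presence/absence
#' matrix. Queries with no surviving match in any species are dropped; the
#' number dropped is recorded in the `dropped_queries` attribute.
#'
#' @param queries Protein record data frame of query sequences.
#' @param species Character vector of species IDs (matrix columns).
#' @param edges Similarity edges from queries to species proteins; subject
#'   IDs must be resolvable to species via `species_of`.
#' @param species_of Named character vector subject protein ID -> species.
#' @param thresholds Screen thresholds (default `max_evalue = 1e-20`).
#' @return Binary matrix (queries x species) with attributes
#'   `dropped_queries` (count) and `dropped_ids`.
#' @export
screen_homologs <- function(queries, species, edges, species_of,
                            thresholds = edge_filter_thresholds(max_evalue = 1e-20)) {
  unknown <- setdiff(unique(edges$query_id), queries$protein_id)
  if (length(unknown)) {
    stop("edges reference queries missing from the query list: ",
         paste(unknown, collapse = ", "))
  }
  kept <- filter_edges(edges, thresholds)
  m <- matrix(0L, nrow = nrow(queries), ncol = length(species),
              dimnames = list(queries$protein_id, species))
  if (nrow(kept)) {
    sp <- species_of[kept$subject_id]
    ok <- !is.na(sp) & sp %in% species
    for (r in which(ok)) m[kept$query_id[r], sp[r]] <- 1L
  }
  hit <- rowSums(m) > 0
  out <- m[hit, , drop = FALSE]
  attr(out, "dropped_queries") <- sum(!hit)
  attr(out, "dropped_ids") <- rownames(m)[!hit]
  out
}

#' Write a family membership file, one family per line, largest first
#'
#' @param families A `FamilySet`.
#' @param path Output path.
#' @export
write_family_set <- function(families, path) {
  fams <- families$families[order(-lengths(families$families),
                                  names(families$families))]
  writeLines(vapply(fams, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Read a family membership file written by [write_family_set()]
#'
#' @param path Input path.
#' @export
read_family_set <- function(path) {
  family_set(strsplit(readLines(path), "\t", fixed = TRUE))
}
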