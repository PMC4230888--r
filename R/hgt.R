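#' Extract domain tags from gene-tree tip labels
#'
#' Tips follow the convention of a single-letter domain tag prepended to the
#' gene ID: `H` haloarchaea, `A` (other) archaea, `E` (eu)bacteria.
#'
#' @param tree An `ape::phylo` tree.
#' @return Character vector of tags, one per tip.
#' @export
tip_tags <- function(tree) {
  tags <- substr(tree$tip.label, 1, 1)
  bad <- !tags %in% c("H", "A", "E")
  if (any(bad)) {
    stop("tip(s) without a valid H/A/E tag: ",
         paste(tree$tip.label[bad], collapse = ", "))
  }
  tags
}

#' Test unrooted monophyly of a tagged tip set
#'
#' A tag is monophyletic on an unrooted tree iff some edge bipartitions the
#' tips into exactly the tagged set versus all others. A single tagged tip,
#' or a tree whose tips all carry the tag, is monophyletic trivially.
#'
#' @param tree An `ape::phylo` tree (interpreted as unrooted).
#' @param tag Domain tag (`"H"`, `"A"`, or `"E"`).
#' @return Logical flag.
#' @export
test_monophyly <- function(tree, tag = "H") {
  tags <- tip_tags(tree)
  k <- sum(tags == tag)
  if (k == 0) stop("no tip carries tag ", tag)
  n <- length(tags)
  # a single tagged tip, its complement, or the whole tip set is always
  # separated by a (possibly terminal) edge
  if (k == 1 || k >= n - 1) return(TRUE)
  target <- sort(tree$tip.label[tags == tag])
  bips <- tree_bipartitions(tree)
  for (b in bips) {
    if (identical(b, target) ||
        identical(sort(setdiff(tree$tip.label, b)), target)) return(TRUE)
  }
  FALSE
}

# all non-trivial bipartitions of an unrooted tree, each as the sorted tip
# set on one side of an internal edge
tree_bipartitions <- function(tree) {
  tr <- tree
  if (!ape::is.rooted(tr)) tr <- ape::root(tr, outgroup = tr$tip.label[1],
                                           resolve.root = TRUE)
  n <- length(tr$tip.label)
  desc <- tips_below(tr)
  internal <- setdiff(unique(tr$edge[, 2]), seq_len(n))
  out <- lapply(internal, function(nd) sort(tr$tip.label[desc[[nd]]]))
  out[vapply(out, length, integer(1)) < n - 1L]
}

# list indexed by node id giving tip indices below each node (rooted tree)
tips_below <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  # accumulate children into parents in postorder
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

# undirected adjacency list of the unrooted tree, degree-2 (artificial
# root) nodes collapsed
unrooted_adjacency <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  repeat {
    deg2 <- which(lengths(adj) == 2 & seq_len(nn) > n)
    if (length(deg2) == 0) break
    v <- deg2[1]
    nb <- adj[[v]]
    adj[[nb[1]]] <- c(setdiff(adj[[nb[1]]], v), nb[2])
    adj[[nb[2]]] <- c(setdiff(adj[[nb[2]]], v), nb[1])
    adj[[v]] <- integer(0)
  }
  adj
}

# tip indices reachable from `from` without crossing the edge (from, blocked)
tips_beyond <- function(adj, from, blocked, n_tips) {
  seen <- rep(FALSE, length(adj))
  seen[blocked] <- TRUE
  stack <- from
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v <= n_tips) tips <- c(tips, v)
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  tips
}

#' Classify a tagged gene tree as basal bacterial import or not
#'
#' If the haloarchaeal (`H`) tips are not monophyletic the verdict is
#' `non_monophyly`. Otherwise the tree is rooted on the H-separating edge
#' and the composition of the neighbor clades on the non-H side is
#' collected: starting at the node adjacent to the H clade, tip children are
#' collected and internal children expanded up to `neighbor_depth` levels.
#' Under the strict `all_bacterial` rule the verdict is `basal_import` iff
#' the collected tips contain at least one bacterial (`E`) tip and no
#' archaeal (`A`) tip; the lenient `majority_bacterial` rule requires only
#' that bacterial tips outnumber archaeal ones.
#'
#' @param tree An `ape::phylo` gene tree with tagged tips.
#' @param neighbor_depth Levels of internal-node expansion on the non-H
#'   side.
#' @param sister_rule `"all_bacterial"` (strict, default) or
#'   `"majority_bacterial"`.
#' @param family_id Optional family identifier carried into the call.
#' @return An `HgtCall` list: `family_id`, `verdict`, `h_monophyletic`,
#'   `neighbor_composition` (table over tags).
#' @export
classify_tree <- function(tree, neighbor_depth = 1L,
                          sister_rule = c("all_bacterial", "majority_bacterial"),
                          family_id = NA_character_) {
  sister_rule <- match.arg(sister_rule)
  tags <- tip_tags(tree)
  if (all(tags == "H")) {
    return(hgt_call(family_id, "untestable", TRUE, character(0)))
  }
  if (!any(tags == "H")) stop("tree has no haloarchaeal (H) tip")
  mono <- test_monophyly(tree, "H")
  if (!mono) return(hgt_call(family_id, "non_monophyly", FALSE, character(0)))
  nb <- neighbor_tips(tree, neighbor_depth)
  nb_tags <- substr(nb, 1, 1)
  basal <- switch(sister_rule,
                  all_bacterial = any(nb_tags == "E") && !any(nb_tags == "A"),
                  majority_bacterial = sum(nb_tags == "E") > sum(nb_tags == "A"))
  hgt_call(family_id, if (basal) "basal_import" else "non_monophyly",
           TRUE, nb_tags)
}

hgt_call <- function(family_id, verdict, h_monophyletic, neighbor_tags) {
  structure(list(family_id = family_id, verdict = verdict,
                 h_monophyletic = h_monophyletic,
                 neighbor_composition = table(factor(neighbor_tags,
                                                     levels = c("A", "E")))),
            class = "HgtCall")
}

# tips collected on the non-H side of the H-separating edge: starting at
# the node adjacent to the (monophyletic) H clade, tip neighbors are
# collected and internal neighbor subtrees expanded while depth remains
neighbor_tips <- function(tree, neighbor_depth) {
  tags <- tip_tags(tree)
  n <- length(tags)
  h_idx <- which(tags == "H")
  adj <- unrooted_adjacency(tree)
  # locate the H-separating edge (u = non-H side, v = H side)
  u <- v <- NA_integer_
  if (length(h_idx) == 1) {
    v <- h_idx
    u <- adj[[v]][1]
  } else {
    found <- FALSE
    for (a in seq_along(adj)) {
      if (found || length(adj[[a]]) == 0) next
      for (b in adj[[a]]) {
        if (a < b) {
          side <- tips_beyond(adj, b, a, n)
          if (setequal(side, h_idx)) { u <- a; v <- b; found <- TRUE; break }
          if (setequal(side, setdiff(seq_len(n), h_idx))) {
            u <- b; v <- a; found <- TRUE; break
          }
        }
      }
    }
    if (!found) stop("H tips are not monophyletic; no separating edge")
  }
  collected <- integer(0)
  visit <- function(nd, depth, from) {
    for (k in setdiff(adj[[nd]], from)) {
      if (k <= n) {
        collected <<- c(collected, k)
      } else if (depth >= 1L) {
        visit(k, depth - 1L, from = nd)
      }
    }
  }
  visit(u, neighbor_depth, from = v)
  sort(tree$tip.label[collected])
}

#' Recruitment thresholds for family extension
#'
#' @param max_evalue Maximum E-value of a recruiting edge.
#' @param min_identity Minimum percent identity of a recruiting edge.
#' @param max_family_size Families growing beyond this many members are
#'   flagged infeasible for tree building.
#' @export
recruitment_thresholds <- function(max_evalue = 1e-10, min_identity = 30,
                                   max_family_size = 200L) {
  stopifnot(max_evalue > 0, min_identity > 0, min_identity <= 100)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 max_family_size = as.integer(max_family_size)),
            class = "recruitment_thresholds")
}

#' Extend a protein family with homologs from an additional proteome pool
#'
#' A pool protein is recruited iff it has at least one similarity edge to a
#' current family member with E-value at most `max_evalue` and percent
#' identity at least `min_identity`.
#'
#' @param members Character vector of current family member protein IDs.
#' @param pool Character vector of candidate protein IDs.
#' @param edges Similarity edges between family members and pool proteins
#'   (either direction).
#' @param thresholds A [recruitment_thresholds()] object.
#' @return List with `members` (extended ID set), `recruited`, and
#'   `excluded_too_large` flag.
#' @export
extend_family <- function(members, pool, edges,
                          thresholds = recruitment_thresholds()) {
  ok <- edges$evalue <= thresholds$max_evalue &
    edges$pct_identity >= thresholds$min_identity
  e <- edges[ok, , drop = FALSE]
  hit <- (e$query_id %in% members & e$subject_id %in% pool) |
    (e$subject_id %in% members & e$query_id %in% pool)
  recruited <- unique(c(e$subject_id[hit & e$subject_id %in% pool],
                        e$query_id[hit & e$query_id %in% pool]))
  extended <- union(members, recruited)
  list(members = extended, recruited = recruited,
       excluded_too_large = length(extended) > thresholds$max_family_size)
}

#' Summarize gene-tree classifications in two-way table form
#'
#' Percentages are computed over the assessed trees (calls flagged
#' `excluded_too_large` are removed from the denominator) and rounded to one
#' decimal.
#'
#' @param calls List of `HgtCall` objects, or a data frame with a `verdict`
#'   column, or a named count pair via `assessed`/`basal` below.
#' @param dataset_label Label for the summary row.
#' @param assessed,basal Optional printed count pair: when given, `calls`
#'   is ignored and the row is recomputed from the counts.
#' @return One-row data frame `(dataset, assessed, basal_imports, basal_pct,
#'   non_monophylies, non_monophyly_pct)`.
#' @export
summarize_calls <- function(calls = NULL, dataset_label = "dataset",
                            assessed = NULL, basal = NULL) {
  if (is.null(assessed)) {
    verdicts <- if (is.data.frame(calls)) calls$verdict else
      vapply(calls, function(cl) cl$verdict, character(1))
    if (length(verdicts) == 0) stop("no calls to summarize")
    verdicts <- verdicts[verdicts != "excluded_too_large" &
                           verdicts != "untestable"]
    assessed <- length(verdicts)
    basal <- sum(verdicts == "basal_import")
  }
  stopifnot(assessed >= 1, basal >= 0, basal <= assessed)
  non <- assessed - basal
  data.frame(dataset = dataset_label, assessed = assessed,
             basal_imports = basal,
             basal_pct = round(100 * basal / assessed, 1),
             non_monophylies = non,
             non_monophyly_pct = round(100 * non / assessed, 1),
             stringsAsFactors = FALSE)
}

#' Bootstrap clade support by bipartition counting
#'
#' For every non-trivial bipartition (internal edge) of the guide tree,
#' support is the fraction of replicate trees containing that bipartition.
#' Replicates whose tip set differs from the guide's are skipped; they are
#' counted in the denominator when `denominator = "all"`.
#'
#' @param guide Guide tree (`ape::phylo`).
#' @param replicates List of replicate trees (or `ape::multiPhylo`).
#' @param denominator `"used"` (replicates with matching tip sets) or
#'   `"all"`.
#' @return Data frame `(bipartition, support)`, one row per internal edge
#'   of the guide; bipartitions are `|`-joined sorted tip subsets.
#' @export
clade_support <- function(guide, replicates, denominator = c("used", "all")) {
  denominator <- match.arg(denominator)
  if (length(replicates) < 1) stop("need at least one replicate tree")
  gtips <- sort(guide$tip.label)
  gb <- tree_bipartitions(guide)
  gb <- lapply(gb, canonical_bipartition, all_tips = gtips)
  # a degree-2 newick root describes one unrooted edge twice
  keys <- unique(vapply(gb, paste, character(1), collapse = "|"))
  counts <- stats::setNames(numeric(length(keys)), keys)
  used <- 0L
  for (rep in replicates) {
    if (!identical(sort(rep$tip.label), gtips)) next
    used <- used + 1L
    rb <- tree_bipartitions(rep)
    rkeys <- unique(vapply(rb, function(b) {
      paste(canonical_bipartition(b, gtips), collapse = "|")
    }, character(1)))
    hit <- keys %in% rkeys
    counts[hit] <- counts[hit] + 1
  }
  if (used == 0L) stop("no replicate shares the guide's tip set")
  denom <- if (denominator == "all") length(replicates) else used
  data.frame(bipartition = keys, support = unname(counts) / denom,
             stringsAsFactors = FALSE)
}

# represent a bipartition by the side not containing the alphabetically
# first tip, so each split has a unique key
canonical_bipartition <- function(side, all_tips) {
  if (all_tips[1] %in% side) sort(setdiff(all_tips, side)) else sort(side)
}
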