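# shared in-code fixtures for the suite

AA20_test <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# a planted k-block similarity graph with uniform in-block edge probability
planted_block_graph <- function(n_per_block = 20L, k = 3L, p_in = 0.9,
                                p_out = 0.02, seed = 1L) {
  set.seed(seed)
  n <- n_per_block * k
  ids <- sprintf("p%03d", seq_len(n))
  blk <- rep(seq_len(k), each = n_per_block)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- blk[i] == blk[j]
    if (stats::runif(1) < (if (same) p_in else p_out)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = ids[i], subject_id = ids[j], pct_identity = 50,
        aln_length = 100, evalue = if (same) 1e-60 else 1e-12,
        bitscore = 100, qlen = 100, slen = 100, qcov = 0.95, scov = 0.95,
        self = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(edges = do.call(rbind, rows),
       truth = stats::setNames(paste0("b", blk), ids))
}

# random similarity edge table with values straddling all filter thresholds
random_edge_table <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("q%03d", 1:60)
  data.frame(query_id = sample(ids, n, replace = TRUE),
             subject_id = sample(ids, n, replace = TRUE),
             pct_identity = stats::runif(n, 10, 100),
             aln_length = sample(50:500, n, replace = TRUE),
             evalue = 10^stats::runif(n, -80, 0),
             bitscore = stats::runif(n, 30, 900),
             qlen = sample(50:500, n, replace = TRUE),
             slen = sample(50:500, n, replace = TRUE),
             qcov = stats::runif(n), scov = stats::runif(n),
             self = FALSE, stringsAsFactors = FALSE)
}

# toy 6-genome presence/absence matrix used by the rarefaction oracle tests
toy_matrix <- function(seed = 5L, n_fam = 40L, n_sp = 6L) {
  set.seed(seed)
  m <- matrix(stats::rbinom(n_fam * n_sp, 2, 0.4), nrow = n_fam,
              dimnames = list(sprintf("f%02d", seq_len(n_fam)),
                              sprintf("s%d", seq_len(n_sp))))
  m[rowSums(m) == 0, 1] <- 1L  # every family exists somewhere
  m
}

random_tagged_tree <- function(n_tips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tags <- sample(c("H", "A", "E"), n_tips, replace = TRUE)
  # ensure at least one H and one non-H
  tags[1] <- "H"
  if (all(tags == "H")) tags[2] <- "E"
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0(tags, seq_len(n_tips))
  tr
}

# brute-force monophyly: scan every edge of the unrooted tree and test
# whether one side's tips are exactly the tagged set
monophyly_bruteforce <- function(tree, tag = "H") {
  tags <- substr(tree$tip.label, 1, 1)
  target <- sort(tree$tip.label[tags == tag])
  n <- length(tree$tip.label)
  if (length(target) %in% c(1L, n)) return(TRUE)
  tr <- ape::unroot(tree)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    side <- if (child <= n) tr$tip.label[child] else
      ape::extract.clade(tr, child)$tip.label
    if (identical(sort(side), target) ||
        identical(sort(setdiff(tr$tip.label, side)), target)) return(TRUE)
  }
  FALSE
}
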