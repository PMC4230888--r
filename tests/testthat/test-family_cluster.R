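test_that("edge filtering applies the coverage, length-ratio and E-value rules", {
  e <- similarity_edges(
    query_id = c("a", "b", "c", "d"),
    subject_id = c("b", "c", "d", "d"),
    pct_identity = 50, aln_length = 100,
    evalue = c(1e-30, 1e-9, 1e-30, 1e-30), bitscore = 100,
    qlen = c(200, 200, 100, 100), slen = c(210, 200, 140, 100),
    qcov = c(0.85, 0.9, 0.9, 0.9), scov = c(0.90, 0.9, 0.9, 0.9))
  kept <- filter_edges(e)
  # a-b passes everything; b-c fails E-value (1e-9 > 1e-10);
  # c-d fails the length ratio (100/140 < 0.75); d-d is a self-edge
  expect_equal(kept$query_id, "a")
  expect_equal(kept$subject_id, "b")
})

test_that("reciprocal duplicates are merged keeping the best E-value", {
  e <- similarity_edges(c("a", "b"), c("b", "a"), 50, 100,
                        evalue = c(1e-30, 1e-50), bitscore = c(90, 100),
                        qlen = 100, slen = 100, qcov = 0.9, scov = 0.9)
  kept <- filter_edges(e)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$evalue, 1e-50)
})

test_that("edge filtering is monotone: relaxing thresholds never drops edges", {
  edges <- random_edge_table(300, seed = 11)
  strict <- edge_filter_thresholds(0.85, 0.8, 1e-20)
  key <- function(df) paste(pmin(df$query_id, df$subject_id),
                            pmax(df$query_id, df$subject_id))
  kept_strict <- key(filter_edges(edges, strict))
  for (relax in list(edge_filter_thresholds(0.70, 0.8, 1e-20),
                     edge_filter_thresholds(0.85, 0.6, 1e-20),
                     edge_filter_thresholds(0.85, 0.8, 1e-5))) {
    expect_true(all(kept_strict %in% key(filter_edges(edges, relax))))
  }
  # brute-force reapplication of the stated thresholds agrees
  th <- edge_filter_thresholds()
  manual <- edges[pmin(edges$qcov, edges$scov) >= th$min_bidir_coverage &
                    pmin(edges$qlen, edges$slen) /
                      pmax(edges$qlen, edges$slen) >= th$min_length_ratio &
                    edges$evalue <= th$max_evalue &
                    edges$query_id != edges$subject_id, ]
  expect_setequal(key(filter_edges(edges, th)), unique(key(manual)))
})

test_that("Markov clustering keeps disjoint cliques apart and yields a partition", {
  ids <- c(paste0("x", 1:5), paste0("y", 1:5))
  prs <- rbind(t(utils::combn(ids[1:5], 2)), t(utils::combn(ids[6:10], 2)))
  e <- similarity_edges(prs[, 1], prs[, 2], 50, 100, evalue = 1e-50,
                        bitscore = 100, qlen = 100, slen = 100,
                        qcov = 0.95, scov = 0.95)
  fs <- mcl_cluster(e, universe = c(ids, "lonely"))
  sizes <- sort(lengths(fs$families))
  expect_equal(unname(sizes), c(1L, 5L, 5L))
  expect_setequal(names(fs$membership), c(ids, "lonely"))
  expect_false(anyDuplicated(names(fs$membership)) > 0)
  expect_setequal(unlist(fs$families["fam00001"]),
                  if ("x1" %in% fs$families[["fam00001"]]) paste0("x", 1:5)
                  else paste0("y", 1:5))
})

test_that("Markov clustering recovers a planted 3-block graph", {
  g <- planted_block_graph(seed = 9)
  fs <- mcl_cluster(filter_edges(g$edges), universe = names(g$truth))
  ari <- mclust::adjustedRandIndex(fs$membership[names(g$truth)], g$truth)
  expect_gte(ari, 0.95)
})

test_that("inflation benchmarking scores curated agreement by restricted ARI", {
  g <- planted_block_graph(seed = 21)
  curated <- family_set(split(names(g$truth), g$truth))
  res <- benchmark_inflation(g$edges, curated, inflation_grid = c(1.4, 2.5, 8))
  # a grid point reproducing the curated partition scores exactly 1
  expect_equal(max(res$ari), 1)
  expect_true(attr(res, "best") %in% c(1.4, 2.5))
  # argmax beats the extreme endpoint that shatters the blocks
  expect_lt(res$ari[res$inflation == 8], max(res$ari))
  # all-singleton curated set against one giant cluster scores <= 0
  singles <- family_set(as.list(names(g$truth)))
  giant <- family_set(list(names(g$truth)))
  expect_lte(mclust::adjustedRandIndex(
    singles$membership[names(g$truth)], giant$membership[names(g$truth)]), 0)
  expect_error(benchmark_inflation(g$edges, family_set(list())), "empty")
})

test_that("the homolog screen matches a brute-force double loop", {
  set.seed(14)
  queries <- protein_records(sprintf("q%02d", 1:10), "querydb",
                             replicate(10, paste(sample(LETTERS[1:20], 30,
                                                        TRUE), collapse = "")))
  species <- sprintf("sp%d", 1:4)
  subj <- sprintf("t%03d", 1:40)
  species_of <- stats::setNames(rep(species, each = 10), subj)
  n <- 80
  edges <- data.frame(query_id = sample(queries$protein_id, n, TRUE),
                      subject_id = sample(subj, n, TRUE),
                      pct_identity = 50, aln_length = 100,
                      evalue = 10^runif(n, -40, 0), bitscore = 100,
                      qlen = sample(80:120, n, TRUE),
                      slen = sample(80:120, n, TRUE),
                      qcov = runif(n, 0.5, 1), scov = runif(n, 0.5, 1),
                      self = FALSE, stringsAsFactors = FALSE)
  th <- edge_filter_thresholds(max_evalue = 1e-20)
  m <- screen_homologs(queries, species, edges, species_of, th)
  # brute force over (query, species, edge)
  for (q in queries$protein_id) for (s in species) {
    hit <- FALSE
    for (r in seq_len(n)) {
      ok <- edges$query_id[r] == q &&
        species_of[edges$subject_id[r]] == s &&
        min(edges$qcov[r], edges$scov[r]) >= 0.80 &&
        min(edges$qlen[r], edges$slen[r]) /
          max(edges$qlen[r], edges$slen[r]) >= 0.75 &&
        edges$evalue[r] <= 1e-20
      if (ok) hit <- TRUE
    }
    got <- if (q %in% rownames(m)) m[q, s] else 0L
    expect_identical(got, as.integer(hit))
  }
  expect_equal(attr(m, "dropped_queries") + nrow(m), 10L)
})

test_that("screen boundary cases follow the E-value cutoff and drop rule", {
  queries <- protein_records(c("qa", "qb"), "db", c("MKL", "MNP"))
  species_of <- c(t1 = "sp1")
  mk <- function(q, ev) similarity_edges(q, "t1", 60, 100, ev, 100,
                                         100, 100, qcov = 0.9, scov = 0.9)
  m <- screen_homologs(queries, "sp1", rbind(mk("qa", 1e-21), mk("qb", 1e-19)),
                       species_of)
  expect_identical(rownames(m), "qa")
  expect_identical(unname(m["qa", "sp1"]), 1L)
  expect_identical(attr(m, "dropped_ids"), "qb")
  expect_error(screen_homologs(queries[1, ], "sp1", mk("qb", 1e-30),
                               species_of), "missing")
})

test_that("family membership files round-trip in size order", {
  fs <- family_set(list(c("a", "b", "c"), c("d", "e"), "f"))
  tf <- tempfile()
  write_family_set(fs, tf)
  back <- read_family_set(tf)
  expect_identical(lapply(back$families, sort),
                   lapply(fs$families, sort))
})
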