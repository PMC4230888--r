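test_that("unrooted monophyly finds (or refutes) a separating edge", {
  t1 <- ape::read.tree(text = "((H1,H2),(E1,(E2,A1)));")
  expect_true(test_monophyly(t1, "H"))
  t2 <- ape::read.tree(text = "((H1,E1),(H2,A1),E2);")
  expect_false(test_monophyly(t2, "H"))
  # single tagged tip and all-same-tag trees are trivially monophyletic
  t3 <- ape::read.tree(text = "((H1,E1),(E2,E3));")
  expect_true(test_monophyly(t3, "H"))
  expect_error(test_monophyly(t3, "X"), "tag")
})

test_that("monophyly agrees with the exhaustive edge-scan oracle", {
  set.seed(99)
  for (i in 1:500) {
    tr <- random_tagged_tree(sample(8:12, 1))
    expect_identical(test_monophyly(tr, "H"), monophyly_bruteforce(tr, "H"),
                     info = paste("tree", i, ape::write.tree(tr)))
  }
})

test_that("monophyly is invariant to newick rotation and re-rooting", {
  set.seed(7)
  for (i in 1:25) {
    tr <- random_tagged_tree(10)
    ref <- test_monophyly(tr, "H")
    rot <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_identical(test_monophyly(rot, "H"), ref)
    rer <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                     resolve.root = TRUE)
    expect_identical(test_monophyly(rer, "H"), ref)
  }
})

test_that("classification separates basal imports from archaeal sisters", {
  basal <- ape::read.tree(text = "(((H1,H2),(E1,E2)),(E3,(A1,A2)));")
  call <- classify_tree(basal)
  expect_equal(call$verdict, "basal_import")
  expect_true(call$h_monophyletic)
  expect_equal(unname(call$neighbor_composition["A"]), 0L)
  expect_gte(unname(call$neighbor_composition["E"]), 1L)

  sister_a <- ape::read.tree(text = "(((H1,H2),(A1,A2)),(E1,E2));")
  call2 <- classify_tree(sister_a)
  expect_equal(call2$verdict, "non_monophyly")
  expect_true(call2$h_monophyletic)

  scattered <- ape::read.tree(text = "((H1,E1),(H2,A1),E2);")
  expect_equal(classify_tree(scattered)$verdict, "non_monophyly")

  all_h <- ape::read.tree(text = "((H1,H2),(H3,H4));")
  expect_equal(classify_tree(all_h)$verdict, "untestable")
})

test_that("the lenient majority rule counts mixed neighborhoods differently", {
  # depth-1 neighborhood holds two E tips and one A tip
  tr <- ape::read.tree(text = "(((H1,H2),(A1,E1)),(E2,(E3,E4)));")
  strict <- classify_tree(tr, sister_rule = "all_bacterial")
  lenient <- classify_tree(tr, sister_rule = "majority_bacterial")
  expect_equal(strict$verdict, "non_monophyly")
  expect_equal(lenient$verdict, "basal_import")
})

test_that("classification never calls basal import on non-monophyletic trees", {
  set.seed(12)
  for (i in 1:100) {
    tr <- random_tagged_tree(sample(6:12, 1))
    if (all(substr(tr$tip.label, 1, 1) == "H")) next
    call <- classify_tree(tr)
    if (!call$h_monophyletic) expect_equal(call$verdict, "non_monophyly")
  }
})

test_that("noise-free synthetic scenarios classify with perfect accuracy", {
  n_per <- 50L
  for (sc in c("basal_transfer", "multiple_transfer", "no_transfer",
               "scattered")) {
    g <- gen_gene_trees(sc, n_trees = n_per, seed = 5L)
    verdicts <- vapply(g$trees, function(t) classify_tree(t)$verdict,
                       character(1))
    expect_identical(verdicts, g$truth$verdict, info = sc)
  }
})

test_that("family extension recruits by E-value and identity only", {
  members <- c("m1", "m2")
  pool <- c("x1", "x2", "x3")
  e <- similarity_edges(c("m1", "m1", "x3"), c("x1", "x2", "m2"),
                        pct_identity = c(45, 25, 45), aln_length = 100,
                        evalue = c(1e-12, 1e-12, 1e-30), bitscore = 100,
                        qlen = 100, slen = 100, qcov = 0.5, scov = 0.5)
  ext <- extend_family(members, pool, e)
  expect_setequal(ext$recruited, c("x1", "x3"))  # x2 fails identity
  expect_false(ext$excluded_too_large)
  small <- extend_family(members, pool, e,
                         recruitment_thresholds(max_family_size = 3))
  expect_true(small$excluded_too_large)
})

test_that("planted-family recruitment is exact at the stated thresholds", {
  pg <- gen_pangenome(n_genomes = 6, n_core = 4, n_accessory = 8,
                      n_noise_edges = 30, seed = 55)
  fam <- pg$truth$families$families[[1]]
  seedset <- fam[1]
  pool <- setdiff(pg$proteins$protein_id, seedset)
  ext <- extend_family(seedset, pool, pg$edges)
  # recruited = exactly the rest of the planted family (noise edges fail
  # the E-value cutoff)
  expect_setequal(ext$recruited, setdiff(fam, seedset))
})

test_that("call summaries reproduce the printed two-way percentages", {
  s1 <- summarize_calls(dataset_label = "Original", assessed = 1479,
                        basal = 1089)
  expect_equal(s1$basal_pct, 73.6)
  expect_equal(s1$non_monophyly_pct, 26.4)
  s2 <- summarize_calls(dataset_label = "Re-analysis", assessed = 1479,
                        basal = 656)
  expect_equal(s2$basal_pct, 44.4)
  s3 <- summarize_calls(dataset_label = "Extended", assessed = 543,
                        basal = 178)
  expect_equal(s3$basal_pct, 32.8)
  expect_equal(s3$non_monophyly_pct, 67.2)
  # percentages always close to 100 in the two-way split
  expect_equal(s1$basal_pct + s1$non_monophyly_pct, 100, tolerance = 0.101)
  s0 <- summarize_calls(dataset_label = "none", assessed = 10, basal = 0)
  expect_equal(s0$basal_pct, 0)
})

test_that("summaries drop infeasible families from the denominator", {
  calls <- data.frame(verdict = c("basal_import", "non_monophyly",
                                  "excluded_too_large"))
  s <- summarize_calls(calls, "mix")
  expect_equal(s$assessed, 2)
  expect_equal(s$basal_pct, 50)
})

test_that("clade support matches the ape bipartition-count oracle", {
  set.seed(61)
  for (i in 1:10) {
    g <- ape::unroot(ape::rtree(8))
    reps <- lapply(1:40, function(j) ape::rtree(8))
    cs <- clade_support(g, reps)
    pc <- ape::prop.clades(g, reps, rooted = FALSE)
    pc[is.na(pc)] <- 0
    # drop ape's trivial clades (full tip set / n-1 sets)
    sizes <- vapply(ape::prop.part(g), length, integer(1))
    keep <- sizes < 7 & sizes > 1
    expect_equal(sort(cs$support * 40), sort(pc[keep]), info = i)
  }
})

test_that("replicates identical to the guide give full support", {
  g <- ape::rtree(10)
  cs <- clade_support(g, list(g, g, g))
  expect_true(all(cs$support == 1))
  expect_error(clade_support(g, list()), "replicate")
  # a bipartition in half the replicates scores 0.5
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  cs2 <- clade_support(t1, list(t1, t2))
  expect_equal(cs2$support, 0.5)
  # replicates on a different tip set are skipped
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  cs3 <- clade_support(t1, list(t1, t3))
  expect_equal(cs3$support, 1)
  cs4 <- clade_support(t1, list(t1, t3), denominator = "all")
  expect_equal(cs4$support, 0.5)
})
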