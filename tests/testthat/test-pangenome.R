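test_that("the copy-number matrix reflects family membership exactly", {
  fs <- family_set(list(c("p1", "p2", "p3"), c("p4")),
                   family_ids = c("famA", "famB"))
  species_of <- c(p1 = "X", p2 = "X", p3 = "Y", p4 = "Y")
  m <- build_matrix(fs, species_of, c("X", "Y", "Z"))
  expect_equal(m["famA", "X"], 2L)
  expect_equal(m["famA", "Y"], 1L)
  expect_equal(m["famB", "X"], 0L)
  expect_equal(unname(m[, "Z"]), c(0L, 0L))
  expect_error(build_matrix(fs, species_of, c("X")), "unknown species")
})

test_that("the synthetic pangenome matrix equals the planted truth", {
  pg <- gen_pangenome(n_genomes = 8, seed = 19)
  fs <- mcl_cluster(filter_edges(pg$edges),
                    universe = pg$proteins$protein_id)
  m <- build_matrix(fs, pg$species_of, pg$species)
  # same partition => identical matrix up to family relabeling
  ari <- mclust::adjustedRandIndex(
    fs$membership[names(pg$truth$families$membership)],
    pg$truth$families$membership)
  expect_equal(ari, 1)
  expect_equal(sort(unname(colSums(m))),
               sort(unname(colSums(pg$truth$matrix))))
})

test_that("rarefaction closed form equals exhaustive enumeration on a toy matrix", {
  m <- toy_matrix()
  rc <- rarefy(m, replicates = 100, seed = 3)
  for (n in 0:6) {
    expect_equal(rc$expected[rc$n == n], rarefy_enumerate(m, n),
                 tolerance = 1e-12)
  }
  expect_equal(rc$expected[rc$n == 0], 0)
  expect_equal(rc$expected[rc$n == 6], nrow(m))
  expect_true(all(diff(rc$expected) >= 0))
})

test_that("the Monte-Carlo rarefaction mean converges on the closed form", {
  m <- toy_matrix()
  for (reps in c(100L, 10000L)) {
    rc <- rarefy(m, replicates = reps, seed = 11)
    se <- rc$sd_unique / sqrt(reps)
    mid <- rc$n > 0 & rc$n < 6
    expect_true(all(abs(rc$mean_unique - rc$expected)[mid] <=
                      3 * se[mid] + 1e-9))
    expect_equal(rc$mean_unique[rc$n == 0], 0)
    expect_equal(rc$mean_unique[rc$n == 6], nrow(m))
  }
  # identical seed, identical curve
  expect_identical(rarefy(m, 50, seed = 4)$mean_unique,
                   rarefy(m, 50, seed = 4)$mean_unique)
})

test_that("singleton exclusion drops single-member families from rarefaction", {
  m <- rbind(big = c(2L, 1L, 0L), single = c(1L, 0L, 0L))
  colnames(m) <- c("a", "b", "c")
  full <- rarefy(m, 10, seed = 1)
  nosing <- rarefy(m, 10, seed = 1, family_definition = "mcl_no_singletons")
  expect_equal(full$expected[full$n == 3], 2)
  expect_equal(nosing$expected[nosing$n == 3], 1)
})

test_that("core extraction matches the column-set intersection oracle", {
  pg <- gen_pangenome(n_genomes = 8, n_core = 25, seed = 23)
  m <- pg$truth$matrix
  core <- core_families(m)
  expect_setequal(core, pg$truth$core_ids)
  expect_length(core, 25)
  # set-algebra oracle: intersect per-column present sets
  sets <- lapply(seq_len(ncol(m)), function(j) rownames(m)[m[, j] > 0])
  expect_setequal(core, Reduce(intersect, sets))
  # dropping one occurrence of a core family excludes it
  m2 <- m
  m2[core[1], 1] <- 0L
  expect_false(core[1] %in% core_families(m2))
})

test_that("genus-specific families and markers obey their criteria", {
  pg <- gen_pangenome(n_genomes = 9, n_genera = 3, seed = 31)
  m <- pg$truth$matrix
  for (g in names(pg$truth$private_ids)) {
    gs <- genus_specific_families(m, g)
    expect_true(all(pg$truth$private_ids[[g]] %in% gs))
    # brute-force check of exclusivity
    outside <- colnames(m)[attr(m, "genus") != g]
    expect_true(all(rowSums(m[gs, outside, drop = FALSE]) == 0))
    mk <- discover_markers(m, marker_criteria(g))
    expect_true(all(mk %in% gs))  # markers nest in genus-specific families
    inside <- colnames(m)[attr(m, "genus") == g]
    if (length(mk)) {
      expect_true(all(m[mk, inside, drop = FALSE] == 1L))
    }
  }
  expect_error(genus_specific_families(m, "nope"), "unknown genus")
})

test_that("marker discovery rejects multi-copy and non-universal families", {
  m <- rbind(marker = c(1L, 1L, 0L, 0L),
             twocopy = c(2L, 1L, 0L, 0L),
             patchy = c(1L, 0L, 0L, 0L),
             shared = c(1L, 1L, 1L, 0L))
  colnames(m) <- c("g1a", "g1b", "g2a", "g2b")
  genus_of <- c(g1a = "G1", g1b = "G1", g2a = "G2", g2b = "G2")
  mk <- discover_markers(m, marker_criteria("G1"), genus_of = genus_of)
  expect_identical(mk, "marker")
})

test_that("genus reports compute interpolated quartiles", {
  df <- data.frame(species_id = sprintf("s%d", 1:6),
                   genome_size = c(1, 2, 3, 4, 5, 10))
  genus_of <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "A", s5 = "A", s6 = "B")
  rep_ <- genus_report(df, genus_of)
  a <- rep_[rep_$genus == "A", ]
  expect_equal(a$median, 3)
  expect_equal(a$q25, 2)
  expect_equal(a$q75, 4)
  b <- rep_[rep_$genus == "B", ]
  expect_equal(c(b$q25, b$median, b$q75), c(10, 10, 10))
  # reference oracle on random data: manual type-7 interpolation
  set.seed(8)
  x <- runif(11)
  df2 <- data.frame(species_id = sprintf("t%d", 1:11), v = x)
  r2 <- genus_report(df2, stats::setNames(rep("G", 11), df2$species_id))
  xs <- sort(x)
  manual <- function(p) {
    h <- (11 - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  expect_equal(r2$q25, manual(0.25))
  expect_equal(r2$median, manual(0.5))
  expect_equal(r2$q75, manual(0.75))
})

test_that("rescue recovers a planted deleted gene at its exact coordinates", {
  mg <- gen_missed_gene_case(n_species = 5, deleted_species = 2, seed = 41)
  res <- rescue_missed_genes("famA", "famB", "famT", mg$families,
                             mg$genomes, mg$features, mg$proteins)
  expect_gte(nrow(res), 1)
  top <- res[1, ]
  planted <- mg$truth$planted
  expect_equal(top$species_id, planted$species_id)
  expect_equal(top$start, planted$start)
  expect_equal(top$end, planted$end)
  expect_equal(top$identity, 100)
  expect_equal(top$protein, planted$protein)
})

test_that("rescue reports nothing when the gene is called or too diverged", {
  mg <- gen_missed_gene_case(n_species = 4, deleted_species = integer(0),
                             seed = 43)
  res <- rescue_missed_genes("famA", "famB", "famT", mg$families,
                             mg$genomes, mg$features, mg$proteins)
  expect_equal(nrow(res), 0L)
  # heavy degradation pushes identity below the cutoff
  mg2 <- gen_missed_gene_case(n_species = 4, deleted_species = 1,
                              identity_degradation = 0.8, seed = 47)
  res2 <- rescue_missed_genes("famA", "famB", "famT", mg2$families,
                              mg2$genomes, mg2$features, mg2$proteins,
                              min_identity = 30)
  # anything reported must genuinely clear the identity bar
  expect_true(all(res2$identity >= 30))
  realized <- 100 * mean(strsplit(mg2$truth$planted$protein, "")[[1]] ==
                           strsplit(mg2$proteins$sequence[1], "")[[1]])
  if (realized < 30) {
    # the planted (too-diverged) ORF itself must not be reported
    expect_false(any(res2$start == mg2$truth$planted$start &
                       res2$species_id == mg2$truth$planted$species_id))
  }
})
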