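test_that("window %G+C arithmetic and counts are exact", {
  cfg <- gc_scan_config(window_bp = 100, step_bp = 20)
  cs <- contig_set("x", c("allG", "at", "mix"),
                   c(strrep("G", 100), strrep("AT", 50), strrep("ATGC", 25)))
  prof <- gc_windows(cs, cfg)
  w <- prof$windows
  expect_equal(w$gc[w$contig_id == "allG"], 100)
  expect_equal(w$gc[w$contig_id == "at"], 0)
  expect_equal(w$gc[w$contig_id == "mix"], 50)
  # window count per contig: floor((L - window)/step) + 1
  set.seed(2)
  for (L in c(100, 119, 120, 1000, 1013)) {
    cs2 <- contig_set("y", "c", paste(sample(c("A", "C", "G", "T"), L,
                                             TRUE), collapse = ""))
    expect_equal(nrow(gc_windows(cs2, cfg)$windows),
                 floor((L - 100) / 20) + 1)
  }
  # short contigs contribute no windows
  cs3 <- contig_set("z", c("tiny", "ok"), c(strrep("G", 99), strrep("G", 100)))
  p3 <- gc_windows(cs3, cfg)
  expect_identical(p3$skipped_contigs, "tiny")
  expect_equal(nrow(p3$windows), 1L)
})

test_that("ambiguous windows are imputed to the contig mean and flagged", {
  # window 1: pure G; append Ns so a later window crosses the 10% rule
  seq_ <- paste0(strrep("G", 100), strrep("N", 15), strrep("A", 100),
                 strrep("G", 25))
  cs <- contig_set("x", "c", seq_)
  prof <- gc_windows(cs)
  w <- prof$windows
  expect_true(any(w$imputed))
  imp <- w[w$imputed, ]
  expect_true(all(imp$gc == prof$contig_means["c"]))
  # contig mean excludes the imputed windows
  expect_equal(unname(prof$contig_means["c"]), mean(w$gc[!w$imputed]))
  # sub-threshold ambiguity: denominator excludes the Ns
  cs2 <- contig_set("x", "c", paste0(strrep("G", 50), strrep("N", 5),
                                     strrep("A", 45)))
  w2 <- gc_windows(cs2, gc_scan_config(window_bp = 100, step_bp = 20))$windows
  expect_false(w2$imputed[1])
  expect_equal(w2$gc[1], 100 * 50 / 95)
})

test_that("the profile of a reverse complement is the original reversed", {
  set.seed(77)
  seq_ <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_)))
  cfg <- gc_scan_config(window_bp = 100, step_bp = 100)  # non-overlapping
  p1 <- gc_windows(contig_set("x", "c", seq_), cfg)
  p2 <- gc_windows(contig_set("x", "c", rc), cfg)
  expect_equal(p2$windows$gc, rev(p1$windows$gc))
})

test_that("a noiseless single jump yields exactly one changepoint at the jump", {
  x <- c(rep(60, 200), rep(45, 200))
  seg <- segment_gc(gc_profile_from_values(x))
  expect_identical(seg$changepoints[[1]], 200L)
  expect_equal(sort(seg$segments$mean_gc), c(45, 60))
  # constant series: no changepoints
  segc <- segment_gc(gc_profile_from_values(rep(52.5, 400)))
  expect_length(segc$changepoints[[1]], 0)
  # the exact dynamic-programming mode agrees
  segd <- segment_gc(gc_profile_from_values(x), method = "exact")
  expect_identical(segd$changepoints[[1]], 200L)
})

test_that("segmentation is invariant to adding a constant level", {
  set.seed(13)
  x <- c(rnorm(150, 60, 2), rnorm(150, 52, 2))
  s1 <- segment_gc(gc_profile_from_values(x))
  s2 <- segment_gc(gc_profile_from_values(x + 7))
  expect_identical(s1$changepoints, s2$changepoints)
})

test_that("planted shifted segments are recovered with tight boundaries", {
  set.seed(29)
  recovered <- 0L; n_sim <- 25L
  for (i in seq_len(n_sim)) {
    n <- 500L; t0 <- sample(100:300, 1); len <- 100L  # 2 kb at 20 bp steps
    x <- rnorm(n, 60, 3)
    x[(t0 + 1):(t0 + len)] <- rnorm(len, 68, 3)
    seg <- segment_gc(gc_profile_from_values(x))
    cps <- seg$changepoints[[1]]
    if (any(abs(cps - t0) <= 3) && any(abs(cps - (t0 + len)) <= 3)) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered / n_sim, 0.95)
})

test_that("an end-to-end genome scan localizes the planted G+C island", {
  gg <- gen_genome(contig_lengths = c(contig_1 = 40000L),
                   background_gc = 0.62,
                   segments = data.frame(contig = "contig_1", start = 15000L,
                                         length = 5000L, gc = 0.45),
                   seed = 83)
  seg <- segment_gc(gc_windows(gg$contigs))
  dv <- seg$divergent_regions
  expect_gte(nrow(dv), 1)
  # a divergent region overlaps the planted island by > 80% of its length
  ov <- sum(pmax(0, pmin(dv$end, 20000) - pmax(dv$start, 15000)))
  expect_gt(ov, 4000)
  expect_true(all(dv$delta[dv$start < 20000 & dv$end > 15000] < 0))
})

test_that("realized G+C of a planted segment is near its target", {
  gg <- gen_genome(seed = 5)
  seq_ <- gg$contigs$sequence[1]
  seg <- substr(seq_, 20001, 25000)
  base <- strsplit(seg, "")[[1]]
  p_hat <- mean(base %in% c("G", "C"))
  se <- sqrt(0.45 * 0.55 / 5000)
  expect_lt(abs(p_hat - 0.45), 3 * se)
  # no ambiguous bases at n_fraction 0
  expect_false(grepl("N", seq_))
  gg2 <- gen_genome(n_fraction = 0.01, seed = 5)
  expect_true(grepl("N", gg2$contigs$sequence[1]))
})

test_that("region feature extraction matches a brute-force interval scan", {
  x <- c(rep(60, 100), rep(45, 100), rep(60, 100))
  seg <- segment_gc(gc_profile_from_values(x))  # divergent mid region
  expect_gte(nrow(seg$divergent_regions), 1)
  set.seed(17)
  n <- 60
  starts <- sample(0:5800, n)
  feats <- feature_table(rep("contig_1", n), sprintf("f%02d", 1:n),
                         starts, starts + sample(50:200, n, TRUE), "+")
  got <- extract_region_features(seg, feats)
  regions <- seg$divergent_regions
  manual <- vapply(seq_len(n), function(i) {
    mid <- (feats$start[i] + feats$end[i]) / 2
    any(mid >= regions$start & mid < regions$end)
  }, logical(1))
  expect_setequal(got$feature_id, feats$feature_id[manual])
  bad <- feature_table("elsewhere", "g1", 0, 10, "+")
  expect_error(extract_region_features(seg, bad), "absent")
})

test_that("fold enrichment follows the frequency-ratio definition", {
  # 5 of a family's 10 members among 100 region features, 10,000 total
  fams <- family_set(list(sprintf("m%02d", 1:10)), family_ids = "famX")
  region <- c(sprintf("m%02d", 1:5), sprintf("bg%03d", 1:95))
  all_feats <- c(sprintf("m%02d", 1:10), sprintf("bg%03d", 1:9990))
  rows <- enrich(region, all_feats, fams)
  fx <- rows[rows$family_id == "famX", ]
  expect_equal(fx$fold, 50)
  expect_true(fx$reported)
  # fewer than five members: excluded no matter the fold
  fams4 <- family_set(list(sprintf("m%02d", 1:4)), family_ids = "famS")
  rows4 <- enrich(c(sprintf("m%02d", 1:4), sprintf("bg%03d", 1:96)),
                  c(sprintf("m%02d", 1:4), sprintf("bg%03d", 1:9996)), fams4)
  expect_false(rows4$reported[rows4$family_id == "famS"])
  # fold below 8: not reported
  fams2 <- family_set(list(sprintf("m%02d", 1:10)), family_ids = "famW")
  region2 <- c(sprintf("m%02d", 1:5), sprintf("bg%03d", 1:95))
  all2 <- c(sprintf("m%02d", 1:10), sprintf("bg%03d", 1:600))
  r2 <- enrich(region2, all2, fams2)
  expect_lt(r2$fold[r2$family_id == "famW"], 8)
  expect_false(r2$reported[r2$family_id == "famW"])
  expect_error(enrich(character(0), all2, fams2), "no features")
  # totals: region counts can never exceed the region feature total
  expect_true(all(rows$count_in_regions <= rows$region_feature_total))
})
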