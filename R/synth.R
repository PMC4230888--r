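AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, weights = NULL) {
  paste(sample(AA20, len, replace = TRUE, prob = weights), collapse = "")
}

mutate_protein <- function(seq_, rate) {
  if (rate <= 0) return(seq_)
  res <- strsplit(seq_, "")[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) res[i] <- sample(setdiff(AA20, res[i]), 1)
  paste(res, collapse = "")
}

#' Simulate a pangenome with planted family structure
#'
#' Each family descends from a random ancestral sequence; members are
#' point-mutated copies. Core families are present in every genome,
#' accessory families in each genome independently with `presence_prob`,
#' and genus-private families only within one genus. Paralogs arise with
#' probability `paralog_prob` per occupied cell. The emitted similarity
#' edge table contains all within-family edges (passing the clustering
#' thresholds) and, optionally, sub-threshold noise edges between families.
#'
#' @param n_genomes,n_genera Genome and genus counts.
#' @param n_core,n_accessory Core and accessory family counts.
#' @param presence_prob Per-genome presence probability of an accessory
#'   family.
#' @param n_private_per_genus Genus-private families planted per genus.
#' @param paralog_prob Probability of a second copy in an occupied genome.
#' @param mean_len Mean protein length (lengths drawn 0.5-1.5x).
#' @param mutation_rate Per-site substitution probability from the family
#'   ancestor.
#' @param n_noise_edges Between-family edges with E-value above the
#'   clustering cutoff.
#' @param seed RNG seed.
#' @return List: `proteins` (record data frame), `edges`, `species`,
#'   `species_of`, `genus_of`, and `truth` (scenario, seed, `families`
#'   (`FamilySet`), `matrix`, `core_ids`, `private_ids` per genus, params).
#' @export
gen_pangenome <- function(n_genomes = 12L, n_genera = 3L, n_core = 25L,
                          n_accessory = 60L, presence_prob = 0.4,
                          n_private_per_genus = 3L, paralog_prob = 0.05,
                          mean_len = 300L, mutation_rate = 0.05,
                          n_noise_edges = 0L, seed = 1L) {
  stopifnot(n_core >= 0, n_accessory >= 0,
            presence_prob > 0, presence_prob <= 1,
            paralog_prob >= 0, paralog_prob <= 1)
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_genomes))
  genus_of <- stats::setNames(
    sprintf("genus%s", LETTERS[rep(seq_len(n_genera), length.out = n_genomes)]),
    species)
  genera <- unique(unname(genus_of))
  n_private <- n_private_per_genus * length(genera)
  n_fam <- n_core + n_accessory + n_private
  fam_kind <- c(rep("core", n_core), rep("accessory", n_accessory),
                rep("private", n_private))
  fam_genus <- c(rep(NA, n_core + n_accessory),
                 rep(genera, each = n_private_per_genus))
  anc <- vapply(seq_len(n_fam), function(i) {
    random_protein(max(50L, round(stats::runif(1, 0.5, 1.5) * mean_len)))
  }, character(1))

  prot_rows <- list(); members <- vector("list", n_fam)
  counter <- stats::setNames(integer(n_genomes), species)
  for (f in seq_len(n_fam)) {
    present <- switch(fam_kind[f],
      core = species,
      accessory = {
        p <- species[stats::runif(n_genomes) < presence_prob]
        while (length(p) == 0) p <- species[stats::runif(n_genomes) < presence_prob]
        p
      },
      private = {
        g <- species[genus_of[species] == fam_genus[f]]
        p <- g[stats::runif(length(g)) < 0.8]
        if (length(p) == 0) p <- g[sample.int(length(g), 1)]
        p
      })
    for (sp in present) {
      copies <- 1L + stats::rbinom(1, 1, paralog_prob)
      for (cp in seq_len(copies)) {
        counter[sp] <- counter[sp] + 1L
        pid <- sprintf("%s_p%04d", sp, counter[sp])
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          protein_id = pid, species_id = sp,
          sequence = mutate_protein(anc[f], mutation_rate),
          annotation = "", stringsAsFactors = FALSE)
        members[[f]] <- c(members[[f]], pid)
      }
    }
  }
  proteins <- do.call(rbind, prot_rows)
  proteins$length_aa <- nchar(proteins$sequence)
  fam_ids <- sprintf("fam%05d", seq_len(n_fam))
  fams <- family_set(members, family_ids = fam_ids)
  species_of <- stats::setNames(proteins$species_id, proteins$protein_id)

  # within-family edges: one row per unordered member pair, passing the
  # clustering thresholds by construction
  er <- list()
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  for (f in seq_len(n_fam)) {
    mem <- members[[f]]
    if (length(mem) < 2) next
    prs <- utils::combn(mem, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      idp <- pct_identity_pair(seqs[[a]], seqs[[b]])
      er[[length(er) + 1L]] <- data.frame(
        query_id = a, subject_id = b, pct_identity = idp,
        aln_length = nchar(seqs[[a]]),
        evalue = 10^-stats::runif(1, 50, 180),
        bitscore = round(2 * nchar(seqs[[a]]) * idp / 100),
        qlen = nchar(seqs[[a]]), slen = nchar(seqs[[b]]),
        qcov = stats::runif(1, 0.9, 1), scov = stats::runif(1, 0.9, 1),
        self = FALSE, stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, er)
  if (n_noise_edges > 0) {
    nr <- list()
    for (k in seq_len(n_noise_edges)) {
      fp <- sample.int(n_fam, 2)
      a <- sample(members[[fp[1]]], 1); b <- sample(members[[fp[2]]], 1)
      nr[[k]] <- data.frame(
        query_id = a, subject_id = b, pct_identity = stats::runif(1, 15, 25),
        aln_length = 50, evalue = 10^-stats::runif(1, 5, 9),
        bitscore = 40, qlen = nchar(seqs[[a]]), slen = nchar(seqs[[b]]),
        qcov = stats::runif(1, 0.2, 0.5), scov = stats::runif(1, 0.2, 0.5),
        self = FALSE, stringsAsFactors = FALSE)
    }
    edges <- rbind(edges, do.call(rbind, nr))
  }
  mat <- build_matrix(fams, species_of, species, genus_of = genus_of)
  truth <- list(scenario = "pangenome", seed = seed, families = fams,
                matrix = mat, core_ids = fam_ids[fam_kind == "core"],
                private_ids = split(fam_ids[fam_kind == "private"],
                                    fam_genus[fam_kind == "private"]),
                params = list(n_genomes = n_genomes, n_genera = n_genera,
                              n_core = n_core, n_accessory = n_accessory,
                              presence_prob = presence_prob,
                              n_private_per_genus = n_private_per_genus,
                              paralog_prob = paralog_prob,
                              mutation_rate = mutation_rate))
  list(proteins = proteins, edges = edges, species = species,
       species_of = species_of, genus_of = genus_of, truth = truth)
}

#' Simulate a contig set with planted G+C-shifted segments
#'
#' Bases are drawn i.i.d. at the local target G+C (background elsewhere,
#' the planted level inside each segment); ambiguous `N`s are sprinkled at
#' `n_fraction`.
#'
#' @param contig_lengths Named or unnamed integer vector of contig lengths.
#' @param background_gc Background G+C fraction.
#' @param segments Data frame `(contig, start, length, gc)` of planted
#'   segments (`start` 0-based; `gc` a fraction).
#' @param n_fraction Fraction of positions replaced by `N`.
#' @param species_id Species label.
#' @param seed RNG seed.
#' @return List: `contigs` (`ContigSet`) and `truth` (segment table with
#'   realized coordinates, params, seed).
#' @export
gen_genome <- function(contig_lengths = c(contig_1 = 50000L),
                       background_gc = 0.62,
                       segments = data.frame(contig = "contig_1",
                                             start = 20000L, length = 5000L,
                                             gc = 0.45),
                       n_fraction = 0, species_id = "synth", seed = 1L) {
  set.seed(seed)
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- sprintf("contig_%d", seq_along(contig_lengths))
  }
  seqs <- character(length(contig_lengths))
  for (i in seq_along(contig_lengths)) {
    L <- contig_lengths[i]
    p <- rep(background_gc, L)
    segs <- segments[segments$contig == names(contig_lengths)[i], , drop = FALSE]
    for (k in seq_len(nrow(segs))) {
      idx <- (segs$start[k] + 1L):(segs$start[k] + segs$length[k])
      p[idx] <- segs$gc[k]
    }
    gc <- stats::runif(L) < p
    base <- ifelse(gc, sample(c("G", "C"), L, replace = TRUE),
                   sample(c("A", "T"), L, replace = TRUE))
    if (n_fraction > 0) base[stats::runif(L) < n_fraction] <- "N"
    seqs[i] <- paste(base, collapse = "")
  }
  contigs <- contig_set(species_id, names(contig_lengths), seqs)
  list(contigs = contigs,
       truth = list(scenario = "gc_segments", seed = seed,
                    segments = segments, background_gc = background_gc,
                    n_fraction = n_fraction))
}

ACIDIC_COMPOSITION <- local({
  w <- rep(1, 20); names(w) <- AA20
  w["D"] <- 6; w["E"] <- 6; w["K"] <- 0.3; w["R"] <- 0.3; w["H"] <- 0.5
  w / sum(w)
})

BASIC_COMPOSITION <- local({
  w <- rep(1, 20); names(w) <- AA20
  w["K"] <- 5; w["R"] <- 5; w["D"] <- 0.4; w["E"] <- 0.4
  w / sum(w)
})

#' Simulate a proteome with a bimodal isoelectric-point composition
#'
#' A fraction `acidic_fraction` of proteins are drawn from a D/E-enriched
#' composition (the acidic mode) and the rest from a K/R-enriched one (the
#' basic mode), emulating the acid-shifted proteomes of salt-in halophiles
#' with a minority basic mode.
#'
#' @param n Number of proteins (must be positive).
#' @param acidic_fraction Fraction drawn from the acidic mode.
#' @param len_range Protein length range (uniform).
#' @param species_id Species label.
#' @param seed RNG seed.
#' @return List: `proteins` (record data frame) and `truth` (per-protein
#'   mode, params, seed).
#' @export
gen_proteome <- function(n = 500L, acidic_fraction = 0.8,
                         len_range = c(100L, 400L), species_id = "synth",
                         seed = 1L) {
  if (n <= 0) stop("n must be positive")
  stopifnot(acidic_fraction >= 0, acidic_fraction <= 1)
  set.seed(seed)
  mode <- ifelse(stats::runif(n) < acidic_fraction, "acidic", "basic")
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    random_protein(lens[i], if (mode[i] == "acidic") ACIDIC_COMPOSITION
                   else BASIC_COMPOSITION)
  }, character(1))
  proteins <- protein_records(sprintf("%s_p%04d", species_id, seq_len(n)),
                              species_id, seqs)
  list(proteins = proteins,
       truth = list(scenario = "bimodal_proteome", seed = seed, mode = mode,
                    acidic_fraction = acidic_fraction))
}

caterpillar_newick <- function(labels) {
  if (length(labels) == 1) return(labels)
  out <- labels[length(labels)]
  for (l in rev(labels[-length(labels)])) out <- sprintf("(%s,%s)", l, out)
  out
}

#' Simulate tagged gene trees under known transfer scenarios
#'
#' Scenarios: `basal_transfer` attaches the haloarchaeal clade deep inside
#' the bacterial subtree (truth verdict `basal_import`);
#' `multiple_transfer` splits the haloarchaeal tips across two bacterial
#' attachment points; `no_transfer` nests them inside the archaea;
#' `scattered` attaches each haloarchaeal tip at its own point. All three
#' latter scenarios have truth verdict `non_monophyly`. `nni_noise` random
#' nearest-neighbor interchanges are applied after construction; the truth
#' verdict records the pre-noise topology.
#'
#' @param scenario One of the four scenario names.
#' @param n_H,n_A,n_E Tip counts per domain (`n_E >= 2`, `n_A >= 2`).
#' @param nni_noise Number of random NNI moves applied per tree.
#' @param seed RNG seed.
#' @param n_trees Number of trees generated.
#' @return List: `trees` (list of `phylo`) and `truth` (data frame
#'   `tree_id`, `scenario`, `verdict`).
#' @export
gen_gene_trees <- function(scenario = c("basal_transfer", "multiple_transfer",
                                        "no_transfer", "scattered"),
                           n_H = 6L, n_A = 6L, n_E = 8L, nni_noise = 0L,
                           seed = 1L, n_trees = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_H >= 1, n_A >= 2, n_E >= 2)
  if (scenario %in% c("multiple_transfer", "scattered")) stopifnot(n_H >= 2)
  if (scenario == "multiple_transfer") stopifnot(n_E >= 3)
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    h <- sprintf("H%03d_%d", seq_len(n_H), t)
    a <- sprintf("A%03d_%d", seq_len(n_A), t)
    e <- sprintf("E%03d_%d", seq_len(n_E), t)
    nwk <- switch(scenario,
      basal_transfer = {
        hclade <- caterpillar_newick(h)
        ecat <- caterpillar_newick(c(e[-n_E], sprintf("(%s,%s)", e[n_E], hclade)))
        sprintf("(%s,%s);", caterpillar_newick(a), ecat)
      },
      no_transfer = {
        hclade <- caterpillar_newick(h)
        acat <- caterpillar_newick(c(a[-n_A], sprintf("(%s,%s)", a[n_A], hclade)))
        sprintf("(%s,%s);", caterpillar_newick(e), acat)
      },
      multiple_transfer = {
        k <- max(1L, n_H %/% 2L)
        h1 <- caterpillar_newick(h[seq_len(k)])
        h2 <- caterpillar_newick(h[-seq_len(k)])
        ecat <- caterpillar_newick(c(sprintf("(%s,%s)", e[1], h1), e[2:(n_E - 1)],
                                     sprintf("(%s,%s)", e[n_E], h2)))
        sprintf("(%s,%s);", caterpillar_newick(a), ecat)
      },
      scattered = {
        hosts <- c(e, a)
        pick <- sample(seq_along(hosts), min(n_H, length(hosts)))
        for (i in seq_along(pick)) {
          hosts[pick[i]] <- sprintf("(%s,%s)", hosts[pick[i]], h[i])
        }
        extra <- if (n_H > length(pick)) h[-seq_along(pick)] else character(0)
        sprintf("(%s,%s);", caterpillar_newick(c(hosts[seq_len(n_E)], extra)),
                caterpillar_newick(hosts[-seq_len(n_E)]))
      })
    tr <- ape::read.tree(text = nwk)
    if (nni_noise > 0) tr <- phangorn::rNNI(tr, moves = nni_noise, n = 1)
    trees[[t]] <- tr
  }
  verdict <- if (scenario == "basal_transfer") "basal_import" else "non_monophyly"
  list(trees = trees,
       truth = data.frame(tree_id = seq_len(n_trees), scenario = scenario,
                          verdict = verdict, stringsAsFactors = FALSE))
}

CODON_OF <- local({
  # one unambiguous codon per amino acid (no stop-prone wobble needed)
  c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
    H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
    P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
    W = "TGG", Y = "TAT")
})

backtranslate <- function(protein) {
  paste(c("ATG", CODON_OF[strsplit(protein, "")[[1]]], "TAA"), collapse = "")
}

random_noncoding <- function(len, gc = 0.6) {
  # spacer free of ATG/GTG/TTG start codons on both strands so planted ORFs
  # stay unambiguous
  paste(sample(c("C", "G", "A"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, 1 - gc)), collapse = "")
}

#' Simulate a conserved anchorA-target-anchorB neighborhood with a missed
#' gene call
#'
#' Emits `n_species` genomes sharing the synteny anchorA - target - anchorB.
#' In the species listed in `deleted_species` the target gene is removed
#' from the feature table but kept in the sequence; `identity_degradation`
#' optionally mutates that hidden copy. The truth records its coordinates
#' and frame.
#'
#' @param n_species Number of species.
#' @param deleted_species Indices of species with the planted missed call.
#' @param target_len_aa Target protein length (amino acids, without stop).
#' @param anchor_len_aa Anchor protein length.
#' @param spacer_bp Intergenic spacer length.
#' @param identity_degradation Fraction of target residues mutated in the
#'   deleted species' hidden copy.
#' @param seed RNG seed.
#' @return List: `genomes` (named list of `ContigSet`), `features` (named
#'   list of feature tables), `families` (`FamilySet` with `famA`, `famB`,
#'   `famT`), `proteins` (record data frame), and `truth` (planted
#'   coordinates per deleted species, params, seed).
#' @export
gen_missed_gene_case <- function(n_species = 5L, deleted_species = 1L,
                                 target_len_aa = 39L, anchor_len_aa = 100L,
                                 spacer_bp = 150L, identity_degradation = 0,
                                 seed = 1L) {
  set.seed(seed)
  target_aa <- random_protein(target_len_aa - 1L)  # leading M added below
  anchorA_aa <- random_protein(anchor_len_aa - 1L)
  anchorB_aa <- random_protein(anchor_len_aa - 1L)
  species <- sprintf("sp%02d", seq_len(n_species))
  genomes <- list(); feats <- list(); prot_rows <- list()
  memA <- memB <- memT <- character(0)
  truth_rows <- list()
  for (i in seq_len(n_species)) {
    sp <- species[i]
    t_aa <- target_aa
    if (i %in% deleted_species && identity_degradation > 0) {
      t_aa <- mutate_protein(t_aa, identity_degradation)
    }
    cdsA <- backtranslate(anchorA_aa)
    cdsB <- backtranslate(anchorB_aa)
    cdsT <- backtranslate(t_aa)
    flank1 <- random_noncoding(200L); flank2 <- random_noncoding(200L)
    sp1 <- random_noncoding(spacer_bp); sp2 <- random_noncoding(spacer_bp)
    seq_ <- paste0(flank1, cdsA, sp1, cdsT, sp2, cdsB, flank2)
    a_start <- nchar(flank1)
    a_end <- a_start + nchar(cdsA)
    t_start <- a_end + spacer_bp
    t_end <- t_start + nchar(cdsT)
    b_start <- t_end + spacer_bp
    b_end <- b_start + nchar(cdsB)
    genomes[[sp]] <- contig_set(sp, paste0(sp, "_c1"), seq_)
    idA <- paste0(sp, "_anchorA"); idB <- paste0(sp, "_anchorB")
    idT <- paste0(sp, "_target")
    fid <- c(idA, idB); fst <- c(a_start, b_start); fen <- c(a_end, b_end)
    if (!(i %in% deleted_species)) {
      fid <- c(fid, idT); fst <- c(fst, t_start); fen <- c(fen, t_end)
      memT <- c(memT, idT)
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        protein_id = idT, species_id = sp, sequence = paste0("M", t_aa),
        annotation = "", stringsAsFactors = FALSE)
    } else {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        species_id = sp, contig_id = paste0(sp, "_c1"),
        start = t_start, end = t_end, strand = "+",
        frame = t_start %% 3L, protein = paste0("M", t_aa),
        stringsAsFactors = FALSE)
    }
    ord <- order(fst)
    feats[[sp]] <- feature_table(paste0(sp, "_c1"), fid[ord], fst[ord],
                                 fen[ord], "+")
    memA <- c(memA, idA); memB <- c(memB, idB)
  }
  proteins <- do.call(rbind, prot_rows)
  proteins$length_aa <- nchar(proteins$sequence)
  fams <- family_set(list(memA, memB, memT),
                     family_ids = c("famA", "famB", "famT"))
  list(genomes = genomes, features = feats, families = fams,
       proteins = proteins,
       truth = list(scenario = "missed_gene", seed = seed,
                    planted = do.call(rbind, truth_rows),
                    params = list(n_species = n_species,
                                  deleted_species = deleted_species,
                                  target_len_aa = target_len_aa,
                                  identity_degradation = identity_degradation)))
}

#' Write a truth bundle as JSON
#'
#' Serializes the machine-readable ground truth shipped with a synthetic
#' dataset (`FamilySet`s become membership lists, matrices become row-named
#' tables).
#'
#' @param truth A generator `truth` list.
#' @param path Output path.
#' @export
write_truth_bundle <- function(truth, path) {
  enc <- function(x) {
    if (inherits(x, "FamilySet")) return(lapply(x$families, as.character))
    if (is.matrix(x)) {
      return(list(rows = rownames(x), cols = colnames(x),
                  values = unname(apply(x, 1, as.integer, simplify = FALSE))))
    }
    if (is.list(x)) return(lapply(x, enc))
    x
  }
  jsonlite::write_json(enc(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
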