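#' Build a family-by-species copy-number matrix
#'
#' @param families A `FamilySet`.
#' @param species_of Named character vector protein ID -> species ID.
#' @param species_list Character vector of analyzed species (matrix
#'   columns); every protein must map into it.
#' @param genus_of Optional named character vector species -> genus, stored
#'   as the `genus` attribute.
#' @return Integer matrix of per-species copy numbers, families as rows.
#' @export
build_matrix <- function(families, species_of, species_list,
                         genus_of = NULL) {
  prot <- names(families$membership)
  sp <- species_of[prot]
  if (anyNA(sp) || !all(sp %in% species_list)) {
    bad <- prot[is.na(sp) | !sp %in% species_list]
    stop("protein(s) with unknown species: ", paste(bad, collapse = ", "))
  }
  m <- table(factor(families$membership, levels = names(families$families)),
             factor(sp, levels = species_list))
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  names(dimnames(m)) <- NULL
  if (!is.null(genus_of)) attr(m, "genus") <- genus_of[species_list]
  m
}

binarize <- function(matrix) (matrix > 0) * 1L

matrix_under_definition <- function(matrix, family_definition) {
  if (family_definition == "mcl_no_singletons") {
    matrix[rowSums(matrix) > 1L, , drop = FALSE]
  } else {
    matrix
  }
}

#' Pangenome rarefaction curve
#'
#' For each sample size `n` in `0..N` genomes, draws `replicates` uniform
#' subsets of `n` distinct genomes and averages the number of families
#' present in at least one sampled genome. Alongside the Monte-Carlo curve,
#' the exact expectation is returned in closed form:
#' `E[U(n)] = sum_f (1 - choose(N - m_f, n) / choose(N, n))`, where `m_f`
#' is the number of genomes containing family `f`.
#'
#' @param matrix Family-by-species copy-number matrix.
#' @param replicates Random subsets per sample size.
#' @param seed RNG seed.
#' @param family_definition `"mcl_all"` counts every family;
#'   `"mcl_no_singletons"` drops single-member families (total copy number
#'   one) first; `"cog"` is an alternative labelling of a caller-supplied
#'   matrix and is treated as `"mcl_all"`.
#' @param sample_sizes Sizes to evaluate (default `0:N`).
#' @return Data frame with `n`, `mean_unique`, `sd_unique`, `expected`
#'   (closed form), plus attributes `replicates`, `family_definition`,
#'   `seed`.
#' @export
rarefy <- function(matrix, replicates = 10000L, seed = 1L,
                   family_definition = c("mcl_all", "mcl_no_singletons", "cog"),
                   sample_sizes = NULL) {
  family_definition <- match.arg(family_definition)
  stopifnot(replicates >= 1)
  m <- binarize(matrix_under_definition(matrix, family_definition))
  N <- ncol(m)
  if (is.null(sample_sizes)) sample_sizes <- 0:N
  if (any(sample_sizes > N)) stop("sample size exceeds number of genomes")
  mf <- rowSums(m)
  expected <- vapply(sample_sizes, function(n) {
    sum(1 - choose(N - mf, n) / choose(N, n))
  }, numeric(1))
  set.seed(seed)
  mc <- vapply(sample_sizes, function(n) {
    if (n == 0) return(c(0, 0))
    u <- vapply(seq_len(replicates), function(r) {
      cols <- sample.int(N, n)
      sum(rowSums(m[, cols, drop = FALSE]) > 0)
    }, numeric(1))
    c(mean(u), stats::sd(u))
  }, numeric(2))
  out <- data.frame(n = sample_sizes, mean_unique = mc[1, ],
                    sd_unique = mc[2, ], expected = expected)
  attr(out, "replicates") <- replicates
  attr(out, "family_definition") <- family_definition
  attr(out, "seed") <- seed
  out
}

#' Exact rarefaction expectation by exhaustive subset enumeration
#'
#' Independent of the closed form: enumerates all `choose(N, n)` genome
#' subsets and averages the unique-family count. Intended for small `N`.
#'
#' @param matrix Family-by-species matrix.
#' @param n Sample size.
#' @export
rarefy_enumerate <- function(matrix, n) {
  m <- binarize(matrix)
  N <- ncol(m)
  stopifnot(n >= 0, n <= N)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(cols) {
    sum(rowSums(m[, cols, drop = FALSE]) > 0)
  }))
}

#' Core families: present in every analyzed genome
#'
#' @param matrix Family-by-species matrix.
#' @return Character vector of family IDs.
#' @export
core_families <- function(matrix) {
  rownames(matrix)[rowSums(matrix > 0) == ncol(matrix)]
}

#' Families confined to one genus (any copy number, any spread)
#'
#' @param matrix Family-by-species matrix carrying a `genus` attribute, or
#'   pass `genus_of` explicitly.
#' @param genus Genus of interest.
#' @param genus_of Optional named character vector species -> genus.
#' @return Character vector of family IDs found only within `genus`.
#' @export
genus_specific_families <- function(matrix, genus, genus_of = NULL) {
  g <- genus_vector(matrix, genus_of)
  if (!genus %in% g) stop("unknown genus: ", genus)
  inside <- g == genus
  rn <- rownames(matrix)
  present <- matrix > 0
  rn[rowSums(present[, inside, drop = FALSE]) > 0 &
       rowSums(present[, !inside, drop = FALSE]) == 0]
}

genus_vector <- function(matrix, genus_of) {
  g <- if (is.null(genus_of)) attr(matrix, "genus") else genus_of[colnames(matrix)]
  if (is.null(g) || anyNA(g)) stop("no genus assignment for the matrix columns")
  unname(g)
}

#' Marker criteria for genus-diagnostic families
#'
#' @param genus Genus of interest.
#' @param require_universal Family must be present in every genus member.
#' @param require_exclusive Family must be absent outside the genus.
#' @param require_single_copy Family must be single copy in every genus
#'   member.
#' @export
marker_criteria <- function(genus, require_universal = TRUE,
                            require_exclusive = TRUE,
                            require_single_copy = TRUE) {
  structure(list(genus = genus, require_universal = require_universal,
                 require_exclusive = require_exclusive,
                 require_single_copy = require_single_copy),
            class = "marker_criteria")
}

#' Discover genus marker families
#'
#' Under the default criteria a marker family is (1) universal to the genus,
#' (2) not found in any other species, and (3) single copy in every genus
#' member.
#'
#' @param matrix Family-by-species matrix with genus assignment.
#' @param criteria A [marker_criteria()] object.
#' @param genus_of Optional named character vector species -> genus.
#' @return Character vector of marker family IDs.
#' @export
discover_markers <- function(matrix, criteria, genus_of = NULL) {
  stopifnot(inherits(criteria, "marker_criteria"))
  g <- genus_vector(matrix, genus_of)
  if (!criteria$genus %in% g) stop("unknown genus: ", criteria$genus)
  inside <- g == criteria$genus
  stopifnot(sum(inside) >= 1)
  inm <- matrix[, inside, drop = FALSE]
  outm <- matrix[, !inside, drop = FALSE]
  ok <- rep(TRUE, nrow(matrix))
  if (criteria$require_universal) ok <- ok & rowSums(inm > 0) == sum(inside)
  if (criteria$require_exclusive) ok <- ok & rowSums(outm > 0) == 0
  if (criteria$require_single_copy) {
    ok <- ok & apply(inm, 1, function(v) all(v[v > 0] == 1L)) &
      rowSums(inm > 0) > 0
  }
  rownames(matrix)[ok]
}

#' Per-genus quartile report of genome statistics
#'
#' Quartiles use linear interpolation between closest ranks
#' (`stats::quantile` type 7).
#'
#' @param stats_df Data frame with a `species_id` column and numeric genome
#'   statistics (genome size, CDS count, %G+C, mean pI, contig count,
#'   %coding, ...).
#' @param genus_of Named character vector species -> genus.
#' @return Long-format data frame `(genus, statistic, q25, median, q75,
#'   n_genomes)`.
#' @export
genus_report <- function(stats_df, genus_of) {
  stopifnot("species_id" %in% names(stats_df))
  genus <- unname(genus_of[stats_df$species_id])
  if (anyNA(genus)) stop("species without genus assignment")
  stat_cols <- setdiff(names(stats_df), "species_id")
  rows <- list()
  for (g in sort(unique(genus))) {
    sub <- stats_df[genus == g, , drop = FALSE]
    for (s in stat_cols) {
      q <- stats::quantile(sub[[s]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        genus = g, statistic = s, q25 = q[1], median = q[2], q75 = q[3],
        n_genomes = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rescue missed gene calls between conserved anchors
#'
#' For each species in which both anchor families are called within
#' `max_span_bp` of each other on the same contig but the target family has
#' no call between them, scans the inter-anchor sequence in all six reading
#' frames for open reading frames (start codon `ATG`/`GTG`/`TTG`, stop
#' `TAA`/`TAG`/`TGA`) whose encoded length is within `length_tolerance` of
#' the target family's median member length, and reports candidates whose
#' identity to a family member reaches `min_identity`.
#'
#' @param anchor_a,anchor_b,target Family IDs; features are linked to
#'   families through `families$membership[feature_id]`.
#' @param families A `FamilySet` over the called protein/feature IDs.
#' @param genomes Named list of `ContigSet`s by species.
#' @param features Named list of feature tables by species.
#' @param proteins Protein record data frame for target-family members
#'   (provides lengths and sequences for identity scoring).
#' @param max_span_bp Maximum anchor separation considered a conserved
#'   neighborhood.
#' @param length_tolerance Allowed relative deviation from the target
#'   family's median protein length.
#' @param min_identity Minimum percent identity to a family member.
#' @param fixed_length Optional integer: instead of the ORF scan, translate
#'   every contiguous window of this many nucleotides in all six frames
#'   (the fixed-window variant; e.g. 117).
#' @return Data frame of candidates `(species_id, contig_id, start, end,
#'   strand, frame, protein, identity)`, best identity first; zero rows when
#'   nothing qualifies. Species skipped because the anchors sit on different
#'   contigs are listed in the `skipped` attribute.
#' @export
rescue_missed_genes <- function(anchor_a, anchor_b, target, families,
                                genomes, features, proteins,
                                max_span_bp = 5000L, length_tolerance = 0.2,
                                min_identity = 30, fixed_length = NULL) {
  member_ids <- families$families[[target]]
  member_seqs <- proteins$sequence[match(member_ids, proteins$protein_id)]
  member_seqs <- member_seqs[!is.na(member_seqs)]
  if (length(member_seqs) == 0) stop("no sequences available for target family")
  med_len <- stats::median(nchar(member_seqs))
  out <- list(); skipped <- character(0)
  for (sp in names(genomes)) {
    ft <- features[[sp]]
    if (is.null(ft)) next
    fam_of <- families$membership[ft$feature_id]
    ia <- which(fam_of == anchor_a)
    ib <- which(fam_of == anchor_b)
    if (length(ia) == 0 || length(ib) == 0) next
    # closest qualifying anchor pair
    best <- NULL
    for (a in ia) for (b in ib) {
      if (ft$contig_id[a] != ft$contig_id[b]) next
      gap_start <- min(ft$end[a], ft$end[b])
      gap_end <- max(ft$start[a], ft$start[b])
      if (gap_end - gap_start < 0) next
      span <- gap_end - gap_start
      if (span <= max_span_bp && (is.null(best) || span < best$span)) {
        best <- list(contig = ft$contig_id[a], start = gap_start,
                     end = gap_end, span = span)
      }
    }
    if (is.null(best)) {
      if (any(outer(ft$contig_id[ia], ft$contig_id[ib], `!=`))) {
        skipped <- c(skipped, sp)
      }
      next
    }
    # target already called in the gap?
    it <- which(fam_of == target & ft$contig_id == best$contig &
                  ft$start >= best$start & ft$end <= best$end)
    if (length(it) > 0) next
    g <- genomes[[sp]]
    seqrow <- which(g$contig_id == best$contig)
    if (length(seqrow) == 0) next
    gap_seq <- substr(g$sequence[seqrow], best$start + 1L, best$end)
    cands <- if (is.null(fixed_length)) {
      scan_orfs(gap_seq, med_len, length_tolerance)
    } else {
      scan_fixed_windows(gap_seq, fixed_length)
    }
    for (cand in cands) {
      idp <- max(vapply(member_seqs, function(ms) {
        pct_identity_pair(cand$protein, ms)
      }, numeric(1)))
      if (idp >= min_identity) {
        out[[length(out) + 1L]] <- data.frame(
          species_id = sp, contig_id = best$contig,
          start = best$start + cand$start, end = best$start + cand$end,
          strand = cand$strand, frame = cand$frame, protein = cand$protein,
          identity = idp, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), protein = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(-res$identity), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")
ORF_STARTS <- c("ATG", "GTG", "TTG")

translate_nt <- function(nt) {
  aa <- Biostrings::translate(Biostrings::DNAString(nt), if.fuzzy.codon = "X")
  as.character(aa)
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# coordinates returned 0-based half-open relative to `seq_` on the + strand
scan_orfs <- function(seq_, target_len_aa, length_tolerance) {
  L <- nchar(seq_)
  cands <- list()
  lo <- target_len_aa * (1 - length_tolerance)
  hi <- target_len_aa * (1 + length_tolerance)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_ else revcomp(seq_)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1L, frame + 3L * ((L - frame) %/% 3L))
      n_cod <- nchar(sub) %/% 3L
      if (n_cod < 2) next
      codons <- substring(sub, 3L * (seq_len(n_cod) - 1L) + 1L,
                          3L * seq_len(n_cod))
      starts <- which(codons %in% ORF_STARTS)
      stops <- which(codons %in% GENETIC_CODE_STOPS)
      for (st in starts) {
        nxt <- stops[stops > st]
        if (length(nxt) == 0) next
        sp <- nxt[1]
        if (any(stops > st & stops < sp)) sp <- min(stops[stops > st])
        aa_len <- sp - st  # codons excluding the stop
        if (aa_len < lo || aa_len > hi) next
        nt0 <- frame + 3L * (st - 1L)        # 0-based on strand s
        nt1 <- frame + 3L * sp               # includes stop codon
        prot <- translate_nt(substr(s, nt0 + 1L, nt1 - 3L))
        coords <- if (strand == "+") c(nt0, nt1) else c(L - nt1, L - nt0)
        cands[[length(cands) + 1L]] <- list(start = coords[1], end = coords[2],
                                            strand = strand, frame = frame,
                                            protein = prot)
      }
    }
  }
  cands
}

scan_fixed_windows <- function(seq_, window_nt) {
  L <- nchar(seq_)
  cands <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_ else revcomp(seq_)
    for (off in seq_len(max(0L, L - window_nt + 1L)) - 1L) {
      nt <- substr(s, off + 1L, off + window_nt)
      if (grepl("[^ACGT]", nt)) next
      prot <- translate_nt(nt)
      if (grepl("\\*", prot)) next
      coords <- if (strand == "+") c(off, off + window_nt) else
        c(L - off - window_nt, L - off)
      cands[[length(cands) + 1L]] <- list(start = coords[1], end = coords[2],
                                          strand = strand,
                                          frame = off %% 3L, protein = prot)
    }
  }
  cands
}

# ungapped identity when lengths match; otherwise global alignment identity
pct_identity_pair <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    return(100 * mean(va == vb))
  }
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}
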