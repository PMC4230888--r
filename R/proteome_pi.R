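#' pKa table for protein charge calculations
#'
#' Dissociation constants for the ionizable groups considered by the
#' Henderson-Hasselbalch charge model: the two termini and the side chains
#' of D, E, C, Y (acidic, contributing negative charge above their pKa) and
#' H, K, R (basic, positive below their pKa). The default preset uses the
#' EMBOSS-style constants.
#'
#' @param preset Currently `"emboss"`.
#' @param overrides Named numeric vector of pKa overrides (names among
#'   `Nterm`, `Cterm`, `C`, `D`, `E`, `Y`, `H`, `K`, `R`).
#' @return A `pka_table` list with `acidic` and `basic` named pKa vectors.
#' @export
pka_table <- function(preset = "emboss", overrides = NULL) {
  stopifnot(preset == "emboss")
  acidic <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  basic <- c(Nterm = 8.6, H = 6.5, K = 10.8, R = 12.5)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (nm %in% names(acidic)) acidic[nm] <- overrides[nm]
      else if (nm %in% names(basic)) basic[nm] <- overrides[nm]
      else stop("unknown ionizable group: ", nm)
    }
  }
  stopifnot(all(acidic > 0 & acidic < 14), all(basic > 0 & basic < 14))
  structure(list(preset = preset, acidic = acidic, basic = basic),
            class = "pka_table")
}

ionizable_counts <- function(sequence, pka) {
  res <- strsplit(toupper(sequence), "")[[1]]
  groups <- c(names(pka$acidic), names(pka$basic))
  side <- setdiff(groups, c("Nterm", "Cterm"))
  cnt <- vapply(side, function(a) sum(res == a), numeric(1))
  c(cnt, Nterm = 1, Cterm = 1)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: each basic group contributes
#' `1 / (1 + 10^(pH - pKa))` and each acidic group `-1 / (1 + 10^(pKa - pH))`,
#' termini counted once and side chains per occurrence. Residues outside
#' the ionizable set (including B/Z/X ambiguity codes) contribute no
#' charge.
#'
#' @param sequence Amino-acid sequence.
#' @param pH pH value (vectorized).
#' @param pka A [pka_table()].
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(sequence, pH, pka = pka_table()) {
  stopifnot(nchar(sequence) > 0)
  cnt <- ionizable_counts(sequence, pka)
  charge_from_counts(cnt, pH, pka)
}

charge_from_counts <- function(cnt, pH, pka) {
  pos <- rep(0, length(pH)); neg <- rep(0, length(pH))
  for (g in names(pka$basic)) {
    k <- if (g %in% names(cnt)) cnt[[g]] else 0
    if (k > 0) pos <- pos + k / (1 + 10^(pH - pka$basic[[g]]))
  }
  for (g in names(pka$acidic)) {
    k <- if (g %in% names(cnt)) cnt[[g]] else 0
    if (k > 0) neg <- neg + k / (1 + 10^(pka$acidic[[g]] - pH))
  }
  pos - neg
}

#' Isoelectric point by bisection
#'
#' The net charge is strictly decreasing in pH, so the pH at which it
#' vanishes is unique; it is bracketed on `[0, 14]` and found by bisection
#' to within `tol`.
#'
#' @param sequence Amino-acid sequence (termini guarantee at least one
#'   acidic and one basic group).
#' @param pka A [pka_table()].
#' @param tol Convergence tolerance on the charge-neutral pH.
#' @return The isoelectric point.
#' @export
isoelectric_point <- function(sequence, pka = pka_table(), tol = 1e-4) {
  cnt <- ionizable_counts(sequence, pka)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge_from_counts(cnt, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Isoelectric point by exhaustive grid scan (reference method)
#'
#' Evaluates the net charge on a uniform pH grid and returns the grid point
#' with the smallest absolute charge. Slower than [isoelectric_point()];
#' intended as an independent cross-check.
#'
#' @param sequence Amino-acid sequence.
#' @param pka A [pka_table()].
#' @param resolution Grid spacing in pH units.
#' @export
isoelectric_point_grid <- function(sequence, pka = pka_table(),
                                   resolution = 1e-4) {
  cnt <- ionizable_counts(sequence, pka)
  grid <- seq(0, 14, by = resolution)
  ch <- charge_from_counts(cnt, grid, pka)
  grid[which.min(abs(ch))]
}

#' Isoelectric-point profile of a proteome
#'
#' Computes per-protein pIs, a histogram over 100 equal bins spanning pI
#' 2.0 to 13.0 (bin `k` covers `[2 + 0.11 k, 2 + 0.11 (k+1))`, last bin
#' closed), the set of high-pI proteins (pI >= 7.5), and a per-annotation
#' tally of total instances versus high-pI instances sorted by high-pI
#' frequency.
#'
#' @param proteins Protein record data frame.
#' @param pka A [pka_table()].
#' @return A `PiProfile` list: `pi` (named per-protein vector), `histogram`
#'   (data frame `bin_lo`, `bin_hi`, `count`), `high_pi_ids`,
#'   `annotation_tally` (data frame `annotation`, `n_total`, `n_high_pi`),
#'   `summary` (mean pI, modal bin midpoints, out-of-range count).
#' @export
profile_proteome <- function(proteins, pka = pka_table()) {
  stopifnot(nrow(proteins) >= 1)
  pis <- vapply(proteins$sequence, isoelectric_point, numeric(1), pka = pka,
                USE.NAMES = FALSE)
  names(pis) <- proteins$protein_id
  edges <- seq(2, 13, length.out = 101)
  inside <- pis >= 2 & pis <= 13
  bin <- pmin(floor((pis[inside] - 2) / 0.11), 99)
  counts <- tabulate(bin + 1L, nbins = 100L)
  hist_df <- data.frame(bin_lo = edges[1:100], bin_hi = edges[2:101],
                        count = counts)
  high <- names(pis)[pis >= 7.5]
  ann <- proteins$annotation
  tal <- NULL
  if (any(nzchar(ann))) {
    ann_tot <- table(ann[nzchar(ann)])
    ann_high <- table(ann[nzchar(ann) & proteins$protein_id %in% high])
    tal <- data.frame(annotation = names(ann_tot),
                      n_total = as.integer(ann_tot),
                      n_high_pi = as.integer(ann_high[names(ann_tot)]),
                      stringsAsFactors = FALSE)
    tal$n_high_pi[is.na(tal$n_high_pi)] <- 0L
    tal <- tal[order(-tal$n_high_pi, tal$annotation), , drop = FALSE]
    rownames(tal) <- NULL
  }
  mids <- (hist_df$bin_lo + hist_df$bin_hi) / 2
  left <- c(-1, counts[-length(counts)])
  right <- c(counts[-1], -1)
  local_max <- which(counts > 0 & counts >= left & counts >= right)
  structure(list(pi = pis, histogram = hist_df, high_pi_ids = high,
                 annotation_tally = tal,
                 summary = list(mean_pi = mean(pis),
                                mode_bins = mids[local_max],
                                n_out_of_range = sum(!inside))),
            class = "PiProfile")
}

#' Classify protein families by prevalence of high isoelectric points
#'
#' For each family, computes the fraction of members with pI above the
#' cutoff and labels the family `high` when at least `rule_fraction` of
#' members exceed it, `low` when at least `rule_fraction` fall below, and
#' `variable` otherwise.
#'
#' @param families A `FamilySet`.
#' @param pis Named per-protein pI vector (as from [profile_proteome()]).
#' @param cutoff pI cutoff (default 7.5).
#' @param rule_fraction Majority fraction (default 0.6).
#' @return Data frame `(family_id, n_members, frac_high, label)`.
#' @export
pi_family_report <- function(families, pis, cutoff = 7.5,
                             rule_fraction = 0.6) {
  rows <- lapply(names(families$families), function(f) {
    p <- pis[families$families[[f]]]
    p <- p[!is.na(p)]
    if (length(p) == 0) return(NULL)
    frac_high <- mean(p > cutoff)
    label <- if (frac_high >= rule_fraction) "high"
    else if (1 - frac_high >= rule_fraction) "low"
    else "variable"
    data.frame(family_id = f, n_members = length(p), frac_high = frac_high,
               label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
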