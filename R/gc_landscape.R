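#' Sliding-window G+C scan configuration
#'
#' @param window_bp Window length in bp.
#' @param step_bp Step between window starts in bp.
#' @param ambiguity_fraction_max Windows with a larger fraction of ambiguous
#'   bases are imputed to the contig mean.
#' @export
gc_scan_config <- function(window_bp = 100L, step_bp = 20L,
                           ambiguity_fraction_max = 0.10) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 ambiguity_fraction_max = ambiguity_fraction_max),
            class = "gc_scan_config")
}

#' Sliding-window %G+C profile of a contig set
#'
#' %G+C is computed per window as `100 * (G + C) / (window - ambiguous)`,
#' so sub-threshold ambiguity does not bias the composition. Windows never
#' span contig boundaries and the terminal sub-window residue of each
#' contig is omitted. Windows whose ambiguous fraction exceeds the
#' configured maximum are assigned the contig mean and flagged as imputed;
#' contig and genome means are computed over non-imputed windows. All
#' non-`ACGT` IUPAC codes count as ambiguous.
#'
#' @param contigs A `ContigSet`.
#' @param config A [gc_scan_config()].
#' @return A `GcProfile` list: `windows` (data frame `contig_id`, `start`,
#'   `end`, `gc`, `imputed`), `contig_means`, `genome_mean`, `config`.
#'   Contigs shorter than one window contribute no windows (recorded in
#'   `skipped_contigs`).
#' @export
gc_windows <- function(contigs, config = gc_scan_config()) {
  stopifnot(nrow(contigs) > 0)
  w <- config$window_bp; s <- config$step_bp
  all_windows <- list(); contig_means <- numeric(0); skipped <- character(0)
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    seq_ <- contigs$sequence[i]
    L <- nchar(seq_)
    if (L < w) { skipped <- c(skipped, cid); next }
    nwin <- (L - w) %/% s + 1L
    starts <- s * (seq_len(nwin) - 1L)
    base <- strsplit(seq_, "")[[1]]
    is_gc <- base %in% c("G", "C")
    is_at <- base %in% c("A", "T")
    cum_gc <- c(0, cumsum(is_gc))
    cum_known <- c(0, cumsum(is_gc | is_at))
    gc_cnt <- cum_gc[starts + w + 1L] - cum_gc[starts + 1L]
    known <- cum_known[starts + w + 1L] - cum_known[starts + 1L]
    ambig_frac <- (w - known) / w
    gc <- ifelse(known > 0, 100 * gc_cnt / known, NA_real_)
    imputed <- ambig_frac > config$ambiguity_fraction_max | is.na(gc)
    cmean <- if (all(imputed)) NA_real_ else mean(gc[!imputed])
    gc[imputed] <- cmean
    contig_means[cid] <- cmean
    all_windows[[cid]] <- data.frame(contig_id = cid, start = starts,
                                     end = starts + w, gc = gc,
                                     imputed = imputed,
                                     stringsAsFactors = FALSE)
  }
  windows <- if (length(all_windows)) do.call(rbind, all_windows) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), gc = numeric(0), imputed = logical(0))
  rownames(windows) <- NULL
  structure(list(windows = windows, contig_means = contig_means,
                 genome_mean = mean(windows$gc[!windows$imputed]),
                 skipped_contigs = skipped, config = config),
            class = "GcProfile")
}

#' Build a G+C profile directly from window values
#'
#' Convenience constructor for simulation studies of the segmentation step:
#' wraps a numeric series of window %G+C values as a single-contig
#' `GcProfile` with the given scan geometry.
#'
#' @param values Numeric vector of window %G+C values.
#' @param contig_id Contig label.
#' @param config A [gc_scan_config()] supplying window/step geometry.
#' @export
gc_profile_from_values <- function(values, contig_id = "contig_1",
                                   config = gc_scan_config()) {
  starts <- config$step_bp * (seq_along(values) - 1L)
  windows <- data.frame(contig_id = contig_id, start = starts,
                        end = starts + config$window_bp, gc = values,
                        imputed = FALSE, stringsAsFactors = FALSE)
  structure(list(windows = windows,
                 contig_means = stats::setNames(mean(values), contig_id),
                 genome_mean = mean(values), skipped_contigs = character(0),
                 config = config),
            class = "GcProfile")
}

#' Segment a G+C profile into regions of shifted mean
#'
#' Per contig, changepoints in the window series are found by penalized
#' change-in-mean segmentation: binary segmentation under a BIC-style
#' penalty (default), or exact penalized dynamic programming
#' (`method = "exact"`, quadratic time, for short series). The noise scale
#' is estimated robustly from first differences (MAD / sqrt(2)). Divergent
#' regions are the segments whose mean differs from the contig mean by at
#' least `divergence_min` percentage points, reported as genomic bp
#' intervals.
#'
#' @param profile A `GcProfile`.
#' @param penalty Penalty multiplier on `sigma^2 * log(n)`; larger is more
#'   conservative.
#' @param min_segment_windows Minimum windows per segment.
#' @param divergence_min Minimum |segment mean - contig mean| (percentage
#'   points) for a segment to be called divergent.
#' @param method `"binseg"` (default) or `"exact"`.
#' @return A `Segmentation` list: `changepoints` (named list per contig of
#'   last-window-indices before each change), `segments` (data frame
#'   `contig_id`, `first_window`, `last_window`, `mean_gc`, `divergent`),
#'   `divergent_regions` (data frame with bp intervals, 0-based half-open).
#' @export
segment_gc <- function(profile, penalty = 2, min_segment_windows = 10L,
                       divergence_min = 5, method = c("binseg", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "GcProfile"))
  w <- profile$config$window_bp; s <- profile$config$step_bp
  cps <- list(); seg_rows <- list(); div_rows <- list()
  for (cid in unique(profile$windows$contig_id)) {
    win <- profile$windows[profile$windows$contig_id == cid, , drop = FALSE]
    x <- win$gc
    n <- length(x)
    if (n < 2L * min_segment_windows) {
      cps[[cid]] <- integer(0)
    } else {
      # overlapping windows are serially correlated: estimate noise from
      # full-window-lag differences and penalize per effective observation
      lag <- max(1L, ceiling(w / s))
      sigma2 <- robust_sigma2(x, lag)
      beta <- penalty * sigma2 * log(n) * lag
      cps[[cid]] <- if (method == "binseg") {
        sort(binseg_mean(x, beta, min_segment_windows))
      } else {
        sort(dp_mean(x, beta, min_segment_windows))
      }
    }
    bounds <- c(0L, cps[[cid]], length(x))
    cmean <- mean(x)
    for (k in seq_len(length(bounds) - 1L)) {
      i0 <- bounds[k] + 1L; i1 <- bounds[k + 1L]
      m <- mean(x[i0:i1])
      divergent <- abs(m - cmean) >= divergence_min
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        contig_id = cid, first_window = i0, last_window = i1,
        mean_gc = m, divergent = divergent, stringsAsFactors = FALSE)
      if (divergent) {
        div_rows[[length(div_rows) + 1L]] <- data.frame(
          contig_id = cid, start = win$start[i0], end = win$end[i1],
          mean_gc = m, delta = m - cmean, stringsAsFactors = FALSE)
      }
    }
  }
  segments <- do.call(rbind, seg_rows)
  divergent_regions <- if (length(div_rows)) do.call(rbind, div_rows) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), mean_gc = numeric(0), delta = numeric(0))
  rownames(segments) <- rownames(divergent_regions) <- NULL
  structure(list(changepoints = cps, segments = segments,
                 divergent_regions = divergent_regions,
                 penalty = penalty, divergence_min = divergence_min),
            class = "Segmentation")
}

robust_sigma2 <- function(x, lag = 1L) {
  d <- diff(x, lag = lag)
  s <- stats::mad(d) / sqrt(2)
  if (s == 0) s <- stats::sd(x) / sqrt(2)
  if (is.na(s) || s == 0) s <- 1e-8
  s^2
}

segment_sse <- function(cum, cum2, i, j) {
  # SSE of x[i..j] from cumulative sums (1-based inclusive)
  n <- j - i + 1
  sx <- cum[j + 1] - cum[i]
  sxx <- cum2[j + 1] - cum2[i]
  sxx - sx^2 / n
}

# binary segmentation: recursively accept the best split while the SSE
# reduction exceeds the penalty; returns last-window indices before changes
binseg_mean <- function(x, beta, min_seg) {
  n <- length(x)
  cum <- c(0, cumsum(x)); cum2 <- c(0, cumsum(x^2))
  out <- integer(0)
  recurse <- function(i, j) {
    if (j - i + 1 < 2 * min_seg) return()
    whole <- segment_sse(cum, cum2, i, j)
    ks <- (i + min_seg - 1L):(j - min_seg)
    red <- vapply(ks, function(k) {
      whole - segment_sse(cum, cum2, i, k) - segment_sse(cum, cum2, k + 1, j)
    }, numeric(1))
    kbest <- ks[which.max(red)]
    if (max(red) > beta) {
      out <<- c(out, kbest)
      recurse(i, kbest)
      recurse(kbest + 1L, j)
    }
  }
  recurse(1L, length(x))
  refine_changepoints(sort(out), cum, cum2, n)
}

# local re-optimization: move each changepoint to the SSE-optimal position
# between its neighbors (repairs greedy placement error of binary
# segmentation); iterate to a fixed point
refine_changepoints <- function(cps, cum, cum2, n, max_pass = 5L) {
  if (length(cps) == 0) return(cps)
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    bounds <- c(0L, cps, n)
    for (i in seq_along(cps)) {
      lo <- bounds[i] + 1L; hi <- bounds[i + 2L] - 1L
      ks <- lo:hi
      sse <- vapply(ks, function(k) {
        segment_sse(cum, cum2, bounds[i] + 1L, k) +
          segment_sse(cum, cum2, k + 1L, bounds[i + 2L])
      }, numeric(1))
      kbest <- ks[which.min(sse)]
      if (kbest != cps[i]) { cps[i] <- kbest; moved <- TRUE }
      bounds[i + 1L] <- cps[i]
    }
    if (!moved) break
  }
  cps
}

# exact penalized partitioning (optimal in the sum of segment SSEs plus
# beta per changepoint); O(n^2)
dp_mean <- function(x, beta, min_seg) {
  n <- length(x)
  cum <- c(0, cumsum(x)); cum2 <- c(0, cumsum(x^2))
  F <- rep(Inf, n + 1); F[1] <- -beta
  last <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < min_seg) next
    ts <- c(0L, seq_len(j - min_seg))
    ts <- ts[ts == 0L | ts >= min_seg]
    seg_len <- j - ts
    sse <- (cum2[j + 1] - cum2[ts + 1]) - (cum[j + 1] - cum[ts + 1])^2 / seg_len
    vals <- F[ts + 1] + sse + beta
    b <- which.min(vals)
    F[j + 1] <- vals[b]
    last[j + 1] <- ts[b]
  }
  out <- integer(0)
  j <- n
  while (j > 0) {
    t <- last[j + 1]
    if (t == 0) break
    out <- c(t, out)
    j <- t
  }
  out
}

#' Extract annotated features lying in divergent G+C regions
#'
#' @param segmentation A `Segmentation`.
#' @param features Feature table (0-based half-open coordinates).
#' @param mode `"midpoint"` (feature midpoint inside a region, default) or
#'   `"overlap"` (any overlap).
#' @return The qualifying subset of `features`.
#' @export
extract_region_features <- function(segmentation, features,
                                    mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  regions <- segmentation$divergent_regions
  profiled <- names(segmentation$changepoints)
  unknown <- setdiff(unique(features$contig_id), profiled)
  if (length(unknown)) {
    stop("feature contig(s) absent from the segmentation: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(regions) == 0 || nrow(features) == 0) {
    return(features[0, , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(features)), function(i) {
    r <- regions[regions$contig_id == features$contig_id[i], , drop = FALSE]
    if (nrow(r) == 0) return(FALSE)
    if (mode == "midpoint") {
      mid <- (features$start[i] + features$end[i]) / 2
      any(mid >= r$start & mid < r$end)
    } else {
      any(features$start[i] < r$end & features$end[i] > r$start)
    }
  }, logical(1))
  features[keep, , drop = FALSE]
}

#' Fold enrichment of protein families in divergent-G+C regions
#'
#' For each family, fold enrichment is the family's frequency among
#' region features divided by its frequency among all features:
#' `(count_in_regions / region_feature_total) /
#' (count_total / genome_feature_total)`. Families are reported iff they
#' have at least `min_members` features overall and reach `min_fold`.
#'
#' @param region_feature_ids Feature/protein IDs found in divergent regions
#'   (across genomes).
#' @param all_feature_ids All feature/protein IDs in the analyzed genomes.
#' @param families A `FamilySet` mapping feature IDs to families.
#' @param min_members Families with fewer total members are excluded.
#' @param min_fold Minimum fold enrichment to report.
#' @param annotated Optional named logical vector family -> has annotation,
#'   carried through as an `unannotated` column.
#' @return Data frame of `EnrichmentRow`s: `family_id`, `count_in_regions`,
#'   `count_total`, `region_feature_total`, `genome_feature_total`, `fold`,
#'   `reported`, `unannotated`; only computed rows with
#'   `count_in_regions > 0` appear, sorted by fold.
#' @export
enrich <- function(region_feature_ids, all_feature_ids, families,
                   min_members = 5L, min_fold = 8, annotated = NULL) {
  if (length(region_feature_ids) == 0) {
    stop("no features in divergent regions (region_feature_total = 0)")
  }
  fam_region <- families$membership[region_feature_ids]
  fam_all <- families$membership[all_feature_ids]
  region_total <- length(region_feature_ids)
  genome_total <- length(all_feature_ids)
  tab_r <- table(fam_region[!is.na(fam_region)])
  tab_a <- table(fam_all[!is.na(fam_all)])
  fam_ids <- names(tab_r)
  count_in <- as.integer(tab_r)
  count_tot <- as.integer(tab_a[fam_ids])
  fold <- (count_in / region_total) / (count_tot / genome_total)
  out <- data.frame(family_id = fam_ids, count_in_regions = count_in,
                    count_total = count_tot,
                    region_feature_total = region_total,
                    genome_feature_total = genome_total, fold = fold,
                    reported = count_tot >= min_members & fold >= min_fold,
                    stringsAsFactors = FALSE)
  out$unannotated <- if (is.null(annotated)) NA else !annotated[out$family_id]
  out <- out[order(-out$fold, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
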