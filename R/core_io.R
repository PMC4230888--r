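#' Read a FASTA file into a contig set or protein record table
#'
#' Sequences are uppercased and line wrapping is removed; record order is
#' preserved. Nucleotide alphabets are validated against the IUPAC codes
#' (including `N`); protein records get their `length_aa` computed from the
#' sequence.
#'
#' @param path Path to a FASTA file.
#' @param type `"nucleotide"` for a contig set, `"protein"` for protein
#'   records.
#' @param species_id Species label attached to every record.
#' @param annotations Optional named character vector mapping record IDs to
#'   free-text functional annotations (protein input only).
#' @return For `type = "nucleotide"`, a `ContigSet`: a data frame with
#'   columns `species_id`, `contig_id`, `sequence`. For `type = "protein"`,
#'   a data frame with columns `protein_id`, `species_id`, `sequence`,
#'   `annotation`, `length_aa`.
#' @export
read_fasta <- function(path, type = c("nucleotide", "protein"),
                       species_id = "unknown", annotations = NULL) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  ss <- if (type == "nucleotide") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) {
    stop("empty FASTA record(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  if (type == "nucleotide") {
    ok <- grepl("^[ACGTUNRYSWKMBDHV]+$", seqs)
    if (!all(ok)) {
      stop("non-IUPAC nucleotide characters in record(s): ",
           paste(ids[!ok], collapse = ", "))
    }
    contig_set(species_id, ids, unname(seqs))
  } else {
    ann <- rep("", length(ids))
    if (!is.null(annotations)) {
      hit <- ids %in% names(annotations)
      ann[hit] <- unname(annotations[ids[hit]])
    }
    protein_records(ids, species_id, unname(seqs), ann)
  }
}

#' Construct a contig set
#'
#' @param species_id Single species label.
#' @param contig_id Character vector of unique contig IDs.
#' @param sequence Character vector of nucleotide sequences.
#' @return A `ContigSet` data frame.
#' @export
contig_set <- function(species_id, contig_id, sequence) {
  stopifnot(length(contig_id) == length(sequence))
  if (anyDuplicated(contig_id)) stop("contig IDs must be unique within a species")
  if (any(nchar(sequence) == 0)) stop("contig sequences must be non-empty")
  out <- data.frame(species_id = species_id, contig_id = contig_id,
                    sequence = toupper(sequence), stringsAsFactors = FALSE)
  class(out) <- c("ContigSet", "data.frame")
  out
}

#' Construct a protein record table
#'
#' @param protein_id,species_id,sequence,annotation Field vectors (recycled
#'   where length one).
#' @return Data frame with a derived `length_aa` column.
#' @export
protein_records <- function(protein_id, species_id, sequence, annotation = "") {
  if (anyDuplicated(protein_id)) {
    stop("protein IDs must be globally unique; duplicated: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  data.frame(protein_id = protein_id, species_id = species_id,
             sequence = toupper(sequence), annotation = annotation,
             length_aa = nchar(sequence), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x A `ContigSet` or protein record data frame.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  ids <- if ("contig_id" %in% names(x)) x$contig_id else x$protein_id
  ss <- Biostrings::BStringSet(x$sequence)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a tabular all-vs-all similarity search result
#'
#' Accepts the standard 12-column tabular dialect
#' (`query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore`), optionally extended with `qlen` and
#' `slen` as columns 13 and 14. Query/subject alignment coverages are
#' computed from the alignment spans and full sequence lengths when not
#' given directly.
#'
#' @param path Path to the tabular file (no header; `#` comments allowed).
#' @param length_map Optional named integer vector of sequence lengths, used
#'   when the table lacks `qlen`/`slen` columns.
#' @return A data frame of similarity edges with columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `evalue`, `bitscore`,
#'   `qlen`, `slen`, `qcov`, `scov`, `self` (logical flag for self-edges).
#' @export
read_similarity_table <- function(path, length_map = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_edges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 12)) {
    stop("rows with fewer than 12 columns at line(s): ",
         paste(which(ncols < 12), collapse = ", "))
  }
  get <- function(i) vapply(parts, `[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) {
      stop("unparsable ", what, " at line(s): ",
           paste(which(is.na(v)), collapse = ", "))
    }
    v
  }
  qid <- get(1); sid <- get(2)
  pident <- num(3, "pct_identity"); alen <- num(4, "aln_length")
  qstart <- num(7, "qstart"); qend <- num(8, "qend")
  sstart <- num(9, "sstart"); send <- num(10, "send")
  evalue <- num(11, "evalue"); bits <- num(12, "bitscore")
  if (any(evalue < 0)) stop("negative E-value(s)")
  if (all(ncols >= 14)) {
    qlen <- num(13, "qlen"); slen <- num(14, "slen")
  } else if (!is.null(length_map)) {
    qlen <- unname(length_map[qid]); slen <- unname(length_map[sid])
    if (anyNA(qlen) || anyNA(slen)) {
      stop("length map is missing IDs: ",
           paste(unique(c(qid[is.na(qlen)], sid[is.na(slen)])), collapse = ", "))
    }
  } else {
    stop("table has no qlen/slen columns; pass a named `length_map` of ",
         "sequence lengths")
  }
  similarity_edges(qid, sid, pident, alen, evalue, bits, qlen, slen,
                   qspan = abs(qend - qstart) + 1,
                   sspan = abs(send - sstart) + 1)
}

#' Construct a similarity edge table
#'
#' @param query_id,subject_id,pct_identity,aln_length,evalue,bitscore,qlen,slen
#'   Edge fields.
#' @param qspan,sspan Alignment spans on query/subject; default the alignment
#'   length.
#' @param qcov,scov Coverages in `[0,1]`; computed from spans when `NULL`.
#' @export
similarity_edges <- function(query_id, subject_id, pct_identity, aln_length,
                             evalue, bitscore, qlen, slen,
                             qspan = aln_length, sspan = aln_length,
                             qcov = NULL, scov = NULL) {
  if (is.null(qcov)) qcov <- pmin(1, qspan / qlen)
  if (is.null(scov)) scov <- pmin(1, sspan / slen)
  stopifnot(all(qcov >= 0 & qcov <= 1), all(scov >= 0 & scov <= 1),
            all(evalue >= 0))
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_length = aln_length,
             evalue = evalue, bitscore = bitscore,
             qlen = qlen, slen = slen, qcov = qcov, scov = scov,
             self = query_id == subject_id, stringsAsFactors = FALSE)
}

empty_edges <- function() {
  similarity_edges(character(0), character(0), numeric(0), numeric(0),
                   numeric(0), numeric(0), numeric(0), numeric(0))
}

#' Write a similarity edge table in the 14-column tabular dialect
#'
#' @param edges Edge data frame from [similarity_edges()].
#' @param path Output path.
#' @export
write_similarity_table <- function(edges, path) {
  qspan <- round(edges$qcov * edges$qlen)
  sspan <- round(edges$scov * edges$slen)
  fmt <- function(x) sub("e([+-])0(\\d)$", "e\\1\\2",
                         format(x, digits = 17, scientific = NA, trim = TRUE))
  tab <- data.frame(edges$query_id, edges$subject_id, fmt(edges$pct_identity),
                    fmt(edges$aln_length), 0L, 0L, 1, qspan, 1, sspan,
                    fmt(edges$evalue), fmt(edges$bitscore),
                    fmt(edges$qlen), fmt(edges$slen))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GFF3 feature table
#'
#' Coordinates are converted from GFF3 1-based closed to the package's
#' internal 0-based half-open convention at this boundary.
#'
#' @param path Path to an (uncompressed) GFF3 file.
#' @return A feature table: data frame with `contig_id`, `feature_id`,
#'   `start`, `end` (0-based half-open), `strand`, `annotation`.
#' @export
read_features <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  id <- sub(";.*$", "", sub("^.*?ID=", "", g$attributes))
  ann <- ifelse(grepl("product=", g$attributes),
                sub(";.*$", "", sub("^.*?product=", "", g$attributes)), "")
  feature_table(contig_id = as.character(g$seqid), feature_id = id,
                start = g$start - 1L, end = g$end,
                strand = as.character(g$strand), annotation = ann)
}

#' Construct a feature table (internal 0-based half-open coordinates)
#'
#' @param contig_id,feature_id,start,end,strand,annotation Field vectors.
#' @export
feature_table <- function(contig_id, feature_id, start, end, strand,
                          annotation = "") {
  stopifnot(all(start >= 0), all(start < end), all(strand %in% c("+", "-")))
  data.frame(contig_id = contig_id, feature_id = feature_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, annotation = annotation,
             stringsAsFactors = FALSE)
}

#' Write a feature table as GFF3
#'
#' @param features Feature table (internal 0-based half-open coordinates).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_features <- function(features, path, source = "halopan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    rows <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s%s",
                    features$contig_id, source,
                    features$start + 1L, features$end, features$strand,
                    features$feature_id,
                    ifelse(nzchar(features$annotation),
                           paste0(";product=", features$annotation), ""))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Contamination screening thresholds
#'
#' Significance, coverage and length cutoffs for flagging assembly
#' contamination from hits against a contaminant database: hits with
#' E-value at or below `significant_evalue_max` count; contigs whose
#' significant hits cover at least `contig_coverage_min` of their length are
#' removed, as are contigs of at most `short_contig_max_bp` with any
#' significant hit.
#'
#' @param significant_evalue_max Maximum E-value of a significant hit.
#' @param contig_coverage_min Fraction of contig length that must be covered
#'   for coverage-based removal.
#' @param short_contig_max_bp Length at or below which any significant hit
#'   removes the contig.
#' @param contaminant_taxa Substrings identifying contaminant annotations on
#'   long contigs (case-insensitive).
#' @export
contamination_rules <- function(significant_evalue_max = 1e-20,
                                contig_coverage_min = 0.80,
                                short_contig_max_bp = 1000L,
                                contaminant_taxa = c("Escherichia coli", "E. coli")) {
  stopifnot(significant_evalue_max > 0, is.finite(significant_evalue_max),
            contig_coverage_min > 0, contig_coverage_min <= 1,
            short_contig_max_bp > 0)
  structure(list(significant_evalue_max = significant_evalue_max,
                 contig_coverage_min = contig_coverage_min,
                 short_contig_max_bp = as.integer(short_contig_max_bp),
                 contaminant_taxa = contaminant_taxa),
            class = "contamination_rules")
}

#' Remove contaminated contigs from an assembly
#'
#' Applies significance filtering to the hit table, then removes contigs
#' whose significant hits cover at least the coverage threshold of the
#' contig, and short contigs (at most `short_contig_max_bp`) with any
#' significant hit. Long contigs with only a small-portion significant hit
#' are removed when they carry no annotated features or only
#' contaminant-annotated features, and flagged for manual review otherwise.
#'
#' @param contigs A `ContigSet`.
#' @param hits Similarity edges of contigs against a contaminant database
#'   (`query_id` = contig ID; `qcov` = fraction of contig covered).
#' @param features Feature table for the species, or `NULL`.
#' @param rules A [contamination_rules()] object.
#' @return List with `kept` (`ContigSet`), `removed` (data frame of
#'   `contig_id`, `reason`), `flagged` (character vector), and `summary`
#'   (removed contig and bp totals).
#' @export
filter_contamination <- function(contigs, hits = empty_edges(), features = NULL,
                                 rules = contamination_rules()) {
  stopifnot(inherits(rules, "contamination_rules"))
  unknown <- setdiff(unique(hits$query_id), contigs$contig_id)
  if (length(unknown)) {
    warning("hits reference unknown contig(s), skipped: ",
            paste(unknown, collapse = ", "))
    hits <- hits[!hits$query_id %in% unknown, , drop = FALSE]
  }
  hits <- hits[hits$evalue <= rules$significant_evalue_max, , drop = FALSE]
  len <- nchar(contigs$sequence)
  names(len) <- contigs$contig_id

  # best single-hit coverage of each contig by a significant match
  cov <- rep(0, nrow(contigs))
  names(cov) <- contigs$contig_id
  if (nrow(hits)) {
    agg <- tapply(hits$qcov, hits$query_id, max)
    cov[names(agg)] <- agg
  }
  has_hit <- cov > 0

  removed_id <- character(0); reason <- character(0); flagged <- character(0)
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    if (!has_hit[cid]) next
    if (cov[cid] >= rules$contig_coverage_min) {
      removed_id <- c(removed_id, cid)
      reason <- c(reason, "coverage>=threshold")
    } else if (len[cid] <= rules$short_contig_max_bp) {
      removed_id <- c(removed_id, cid)
      reason <- c(reason, "short_contig_any_hit")
    } else {
      feat <- if (is.null(features)) {
        character(0)
      } else {
        features$annotation[features$contig_id == cid]
      }
      native <- feat[!contaminant_annotation(feat, rules$contaminant_taxa)]
      if (length(feat) == 0 || length(native) == 0) {
        removed_id <- c(removed_id, cid)
        reason <- c(reason, "long_contig_no_native_features")
      } else {
        flagged <- c(flagged, cid)
      }
    }
  }
  kept <- contigs[!contigs$contig_id %in% removed_id, , drop = FALSE]
  class(kept) <- class(contigs)
  list(kept = kept,
       removed = data.frame(contig_id = removed_id, reason = reason,
                            stringsAsFactors = FALSE),
       flagged = flagged,
       summary = list(n_removed = length(removed_id),
                      bp_removed = sum(len[removed_id])))
}

contaminant_annotation <- function(annotation, taxa) {
  if (length(annotation) == 0) return(logical(0))
  hit <- rep(FALSE, length(annotation))
  for (t in taxa) hit <- hit | grepl(t, annotation, ignore.case = TRUE, fixed = FALSE)
  hit
}
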