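# Core specificity engine: mismatch profiles, specificity matrices,
# hybridization-spectrum prediction and exhaustive low-stringency screening.
#
# Orientation contract: probes are stored 5'->3' complementary to the rRNA.
# All comparisons are made between the probe's target-site sense sequence
# (reverse complement of the probe) and subject residues read in rRNA sense
# orientation. A probe "hits" a subject window when that window matches the
# probe's sense target pattern within the allowed Hamming distance.

#' Mismatch profile of a probe against panel records
#'
#' Maps the probe's target site onto the alignment through the reference
#' coordinate map and compares the site's sense sequence to each record's
#' residues over those columns. Gaps in a record count as mismatches (tracked
#' separately via `n_gap`/`has_gap`); IUPAC ambiguity codes mismatch unless
#' their set contains the expected base. `mismatch_positions` are probe-local
#' 1-based positions (5'->3' along the probe) of substitution mismatches.
#'
#' @param probe A one-row `probe_set`.
#' @param panel An `aligned_panel`.
#' @param ids Record ids to profile (default: all records).
#' @return Data frame with one row per record: `probe_name`, `sequence_id`,
#'   `taxon`, `group`, `n_mismatches`, `n_gap`, `has_gap`,
#'   `mismatch_positions` (comma-separated).
#' @export
mismatch_profile <- function(probe, panel, ids = panel$records$id) {
  stopifnot(is.data.frame(probe), nrow(probe) == 1,
            inherits(panel, "aligned_panel"))
  cmap <- build_coordinate_map(panel)
  if (probe$target_start < 1 || probe$target_end > nrow(cmap))
    stop("probe site [", probe$target_start, ", ", probe$target_end,
         "] outside the reference coordinate map (length ", nrow(cmap), ")")
  cols <- ref_to_column(cmap, probe$target_start:probe$target_end)
  sense <- strsplit(revcomp(probe$sequence), "", fixed = TRUE)[[1]]
  L <- length(sense)
  unknown <- setdiff(ids, panel$records$id)
  if (length(unknown)) stop("unknown sequence id(s): ", paste(unknown, collapse = ", "))
  rec <- panel$records[match(ids, panel$records$id), ]
  rows <- lapply(seq_along(ids), function(i) {
    obs <- substring(panel$seqs[[ids[i]]], cols, cols)
    gap <- obs == "-"
    sub_mm <- !gap & !residue_matches(sense, obs)
    # probe-local coordinates run antiparallel to the sense site
    pos <- sort((L + 1L) - which(sub_mm))
    data.frame(probe_name = probe$name, sequence_id = ids[i],
               taxon = rec$taxon[i], group = rec$group[i],
               n_mismatches = sum(sub_mm) + sum(gap),
               n_gap = sum(gap), has_gap = any(gap),
               mismatch_positions = paste(pos, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full probes-by-panel specificity matrix
#'
#' Computes the mismatch profile of every probe against every panel sequence.
#' The per-probe minimum mismatch count over off-target records
#' (`non_target` and `outgroup` groups) is attached as attribute
#' `"min_offtarget"`.
#'
#' @param probes A `probe_set`.
#' @param panel An `aligned_panel` with group metadata.
#' @return A `specificity_matrix`: long data frame of mismatch profiles.
#' @export
specificity_matrix <- function(probes, panel) {
  stopifnot(nrow(probes) >= 1)
  mat <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i)
    mismatch_profile(probes[i, ], panel)))
  off <- mat$group %in% offtarget_groups
  mo <- c(tapply(mat$n_mismatches[off], mat$probe_name[off], min))  # drop 1d dim
  structure(mat, class = c("specificity_matrix", "data.frame"),
            min_offtarget = mo[unique(mat$probe_name)])
}

#' Per-probe minimum off-target mismatch distance
#'
#' The minimum number of probe-sequence mismatches over all off-target panel
#' records — the "SNPs differentiating" count used to grade probe specificity.
#'
#' @param probe A one-row `probe_set`.
#' @param panel An `aligned_panel` with at least one off-target record.
#' @return Integer scalar.
#' @export
min_offtarget_distance <- function(probe, panel) {
  off_ids <- panel$records$id[panel$records$group %in% offtarget_groups]
  if (length(off_ids) == 0)
    stop("panel has no off-target (non_target/outgroup) records")
  prof <- mismatch_profile(probe, panel, ids = off_ids)
  min(prof$n_mismatches)
}

#' Extract per-probe minimum off-target distances from a matrix
#' @param matrix A `specificity_matrix`.
#' @return Named integer vector.
#' @export
min_offtarget <- function(matrix) {
  attr(matrix, "min_offtarget")
}

#' Predict per-taxon hybridization spectrum
#'
#' Aggregates a specificity matrix to taxon level by the minimum mismatch
#' count over that taxon's sequences (any matching strain can light up) and
#' calls each (probe, taxon) pair: `positive` when min mismatches <=
#' `positive_max`, `weak` when <= `weak_max`, otherwise `negative`. Defaults
#' (0/1) reproduce the observed behavior that a single SNP can still yield a
#' weak signal.
#'
#' @param matrix A `specificity_matrix`.
#' @param positive_max Maximum mismatches for a `positive` call (default 0).
#' @param weak_max Maximum mismatches for a `weak` call (default 1); must be
#'   >= `positive_max`.
#' @return Data frame: `probe`, `taxon`, `group`, `min_mismatches`, `call`,
#'   ordered by probe then taxon.
#' @export
predict_spectrum <- function(matrix, positive_max = 0L, weak_max = 1L) {
  stopifnot(weak_max >= positive_max)
  mm <- stats::aggregate(n_mismatches ~ probe_name + taxon + group,
                         data = as.data.frame(matrix), FUN = min)
  names(mm) <- c("probe", "taxon", "group", "min_mismatches")
  mm$call <- ifelse(mm$min_mismatches <= positive_max, "positive",
                    ifelse(mm$min_mismatches <= weak_max, "weak", "negative"))
  mm <- mm[order(mm$probe, mm$taxon), , drop = FALSE]
  rownames(mm) <- NULL
  mm
}

#' Exhaustive low-stringency screening of a sequence collection
#'
#' Scans every window of probe length in every subject for matches to the
#' probe's sense target pattern within `max_mismatches` (Hamming distance;
#' deterministic exhaustive scanning rather than seeded heuristics). Subjects
#' are read in rRNA sense orientation; with `both_strands = TRUE` the reverse
#' strand is scanned too, hits reported with `strand == "-"` and
#' `subject_start` giving the leftmost base on the given strand's coordinates.
#'
#' @param probe A one-row `probe_set`.
#' @param subjects Named character vector of subject sequences, a
#'   `Biostrings::XStringSet`, or a path to a FASTA file.
#' @param max_mismatches Maximum Hamming distance (< probe length).
#' @param both_strands Also scan the reverse complement strand.
#' @return Data frame of hits: `probe_name`, `subject_id`, `subject_start`,
#'   `strand`, `n_mismatches`, sorted by subject then start.
#' @export
screen_collection <- function(probe, subjects, max_mismatches = 0L,
                              both_strands = FALSE) {
  stopifnot(is.data.frame(probe), nrow(probe) == 1)
  if (is.character(subjects) && length(subjects) == 1 && is.null(names(subjects)) &&
      file.exists(subjects))
    subjects <- Biostrings::readBStringSet(subjects)
  if (methods::is(subjects, "XStringSet")) {
    nm <- vapply(strsplit(names(subjects), "\\s+"), `[[`, "", 1L)
    subjects <- stats::setNames(toupper(as.character(subjects)), nm)
  }
  stopifnot(is.character(subjects), !is.null(names(subjects)))
  subjects <- chartr("U", "T", toupper(subjects))
  L <- nchar(probe$sequence)
  if (max_mismatches >= L)
    stop("max_mismatches must be smaller than the probe length (", L, ")")
  pattern <- strsplit(revcomp(probe$sequence), "", fixed = TRUE)[[1]]
  hits <- list()
  for (id in names(subjects)) {
    s <- subjects[[id]]
    if (nchar(s) < L) {
      warning("subject '", id, "' shorter than probe; skipped")
      next
    }
    hits[[length(hits) + 1L]] <- scan_one(pattern, s, id, max_mismatches, "+")
    if (both_strands) {
      h <- scan_one(pattern, revcomp(s), id, max_mismatches, "-")
      if (nrow(h)) h$subject_start <- nchar(s) - (h$subject_start + L - 1L) + 1L
      hits[[length(hits) + 1L]] <- h
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(subject_id = character(0), subject_start = integer(0),
               strand = character(0), n_mismatches = integer(0))
  out <- cbind(probe_name = rep(probe$name, nrow(out)), out)
  out <- out[order(out$subject_id, out$subject_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hamming scan of one subject string against an unambiguous sense pattern.
# Vectorized over windows: one pass per pattern position.
scan_one <- function(pattern, subject, id, max_mm, strand) {
  ch <- strsplit(subject, "", fixed = TRUE)[[1]]
  L <- length(pattern)
  n_win <- length(ch) - L + 1L
  mm <- integer(n_win)
  for (i in seq_len(L)) {
    obs <- ch[i:(i + n_win - 1L)]
    mm <- mm + !residue_matches(rep(pattern[i], n_win), obs)
  }
  keep <- which(mm <= max_mm)
  data.frame(subject_id = rep(id, length(keep)), subject_start = keep,
             strand = rep(strand, length(keep)), n_mismatches = mm[keep],
             stringsAsFactors = FALSE)
}
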