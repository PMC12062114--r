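# Column profiling and variable-domain discovery.
#
# A column is "discriminative" when the target group is monomorphic there
# (one base, no gap; a configurable fraction of target records may deviate)
# and at least one off-target sequence (group non_target or outgroup) carries
# a different residue. Runs of windows enriched in discriminative columns are
# merged into candidate regions, the in-silico analog of the variable domains
# retained for probe design.

offtarget_groups <- c("non_target", "outgroup")

#' Per-column discrimination profile of a panel
#'
#' For every alignment column, tallies residues by group, determines the
#' target-group consensus (monomorphism up to `target_tolerance`), and counts
#' how many off-target sequences differ from that consensus (the
#' discrimination margin). Gaps in off-target records count as differing;
#' ambiguity codes are compared literally at this stage.
#'
#' @param panel An `aligned_panel` with at least one `target` and one
#'   off-target (`non_target`/`outgroup`) record.
#' @param target_tolerance Fraction of target records allowed to deviate from
#'   the target consensus while the column still counts as monomorphic
#'   (default 0: strict).
#' @return A data frame with one row per column: `column`, `target_consensus`
#'   (`NA` when the target group is polymorphic or gapped), `target_has_gap`,
#'   `is_discriminative`, `discrimination_margin`. Per-group residue counts
#'   are attached as attribute `"counts"`.
#' @export
column_profiles <- function(panel, target_tolerance = 0) {
  stopifnot(inherits(panel, "aligned_panel"))
  grp <- panel$records$group
  if (!any(grp == "target"))
    stop("panel has no target-group records; attach metadata first")
  if (!any(grp %in% offtarget_groups))
    stop("panel has no off-target (non_target/outgroup) records")
  m <- seq_char_matrix(panel$seqs)
  tm <- m[grp == "target", , drop = FALSE]
  om <- m[grp %in% offtarget_groups, , drop = FALSE]
  n_t <- nrow(tm)

  cons <- character(ncol(m)); cons[] <- NA_character_
  has_gap <- logical(ncol(m))
  margin <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    tc <- tm[, j]
    has_gap[j] <- any(tc == "-")
    tab <- table(tc)
    top <- names(tab)[which.max(tab)]
    # monomorphic (up to tolerance) on a base, never on a gap
    if (top != "-" && (n_t - max(tab)) <= target_tolerance * n_t) {
      cons[j] <- top
      margin[j] <- sum(om[, j] != top)
    }
  }
  prof <- data.frame(
    column = seq_len(ncol(m)),
    target_consensus = cons,
    target_has_gap = has_gap,
    is_discriminative = !is.na(cons) & !has_gap & margin >= 1L,
    discrimination_margin = margin)
  alphabet <- sort(unique(as.vector(m)))
  counts <- lapply(split(seq_len(nrow(m)), grp), function(rows) {
    vapply(seq_len(ncol(m)),
           function(j) table(factor(m[rows, j], levels = alphabet)),
           integer(length(alphabet)))
  })
  attr(prof, "counts") <- counts
  prof
}

#' Discover discriminative regions (variable domains)
#'
#' Slides a window of `window_length` columns across the alignment; a window
#' qualifies when it contains at least `min_discriminative` discriminative
#' columns and no column where the target group is gapped (a probe cannot
#' span a target gap). Overlapping qualifying windows are merged into maximal
#' regions, reported by ascending start column.
#'
#' @inheritParams column_profiles
#' @param window_length Window size in alignment columns (>= 1).
#' @param min_discriminative Minimum discriminative columns per window (>= 1).
#' @return A data frame with columns `start`, `end`, `n_discriminative`,
#'   `columns` (comma-separated discriminative columns inside the region).
#'   Zero rows when no window qualifies.
#' @export
find_discriminative_regions <- function(panel, window_length = 18L,
                                        min_discriminative = 1L,
                                        target_tolerance = 0) {
  stopifnot(window_length >= 1, min_discriminative >= 1)
  if (window_length > panel$length)
    stop("window_length (", window_length, ") exceeds alignment length (",
         panel$length, ")")
  prof <- column_profiles(panel, target_tolerance = target_tolerance)
  d <- prof$is_discriminative
  g <- prof$target_has_gap
  w <- as.integer(window_length)
  n <- length(d)
  cd <- cumsum(d); cg <- cumsum(g)
  starts <- seq_len(n - w + 1L)
  nd <- cd[starts + w - 1L] - c(0L, cd)[starts]
  ng <- cg[starts + w - 1L] - c(0L, cg)[starts]
  ok <- starts[nd >= min_discriminative & ng == 0L]
  merge_windows(ok, w, d)
}

# Merge overlapping windows [s, s+w-1] into maximal regions and annotate
# discriminative columns. Shared by the fast path and usable on oracle output.
merge_windows <- function(ok_starts, w, disc_flags) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_discriminative = integer(0), columns = character(0))
  if (length(ok_starts) == 0) return(empty)
  ok_starts <- sort(ok_starts)
  breaks <- which(diff(ok_starts) >= w)  # diff == w: windows touch, don't overlap
  run_start <- ok_starts[c(1L, breaks + 1L)]
  run_end <- ok_starts[c(breaks, length(ok_starts))] + w - 1L
  cols <- mapply(function(s, e) which(disc_flags[s:e]) + s - 1L,
                 run_start, run_end, SIMPLIFY = FALSE)
  data.frame(
    start = run_start, end = run_end,
    n_discriminative = vapply(cols, length, 0L),
    columns = vapply(cols, paste, "", collapse = ","))
}
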