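# Probe ranking: combine specificity, accessibility and physical properties
# into a deterministic, totally ordered report.

#' Rank candidate probes
#'
#' Orders probes lexicographically by (1) descending minimum off-target
#' mismatch distance, (2) ascending worst accessibility class rank (probes
#' without accessibility information rank after those with), (3) absolute
#' deviation of Tm from `target_tm` (ignored when `target_tm` is `NULL`),
#' (4) probe name — a fully deterministic total order. Alternatively a
#' weighted scalar score can be requested via `weights`.
#'
#' A probe gets the `specific` badge when its minimum off-target distance is
#' at least one mismatch against every off-target sequence.
#'
#' @param matrix A [specificity_matrix()].
#' @param access Optional [site_accessibility()] data frame.
#' @param probes Optional `probe_set` supplying `tm` per probe.
#' @param target_tm Optional target melting temperature (degrees C).
#' @param positive_max,weak_max Spectrum thresholds passed to
#'   [predict_spectrum()] for the summary column.
#' @param weights Optional numeric vector
#'   `c(specificity =, accessibility =, tm =)`; when supplied, probes are
#'   ranked by descending
#'   `specificity*min_offtarget - accessibility*worst_rank - tm*|tm - target_tm|`.
#' @return A `ProbeReport` data frame ordered by rank: `rank`, `probe_name`,
#'   `min_offtarget`, `n_zero_mm_offtargets`, `spectrum_summary`,
#'   `worst_class`, `tm`, `specific`.
#' @export
rank_probes <- function(matrix, access = NULL, probes = NULL, target_tm = NULL,
                        positive_max = 0L, weak_max = 1L, weights = NULL) {
  mo <- min_offtarget(matrix)
  nm <- names(mo)
  off <- as.data.frame(matrix)[matrix$group %in% offtarget_groups, ]
  nz <- tapply(off$n_mismatches == 0, off$probe_name, sum)[nm]
  spec <- predict_spectrum(matrix, positive_max, weak_max)
  spec_off <- spec[spec$group %in% offtarget_groups, ]
  summ <- vapply(nm, function(p) {
    s <- spec_off[spec_off$probe == p, ]
    sprintf("pos:%d|weak:%d|neg:%d", sum(s$call == "positive"),
            sum(s$call == "weak"), sum(s$call == "negative"))
  }, "")
  worst <- rep(NA_character_, length(nm))
  if (!is.null(access))
    worst <- access$worst_class[match(nm, access$probe_name)]
  worst_rank <- match(worst, ACCESS_CLASSES)
  tm <- rep(NA_real_, length(nm))
  if (!is.null(probes)) tm <- probes$tm[match(nm, probes$name)]
  tm_dev <- if (is.null(target_tm)) rep(0, length(nm)) else abs(tm - target_tm)
  tm_dev[is.na(tm_dev)] <- 0

  rep_df <- data.frame(
    probe_name = nm, min_offtarget = as.integer(mo),
    n_zero_mm_offtargets = as.integer(nz), spectrum_summary = summ,
    worst_class = worst, tm = tm,
    specific = mo >= 1L, stringsAsFactors = FALSE)

  if (is.null(weights)) {
    ord <- order(-rep_df$min_offtarget,
                 ifelse(is.na(worst_rank), length(ACCESS_CLASSES) + 1L, worst_rank),
                 tm_dev, rep_df$probe_name)
  } else {
    w <- c(specificity = 1, accessibility = 0, tm = 0)
    w[names(weights)] <- weights
    score <- w[["specificity"]] * rep_df$min_offtarget -
      w[["accessibility"]] * ifelse(is.na(worst_rank), length(ACCESS_CLASSES) + 1L,
                                    worst_rank) -
      w[["tm"]] * tm_dev
    ord <- order(-score, rep_df$probe_name)
  }
  rep_df <- rep_df[ord, , drop = FALSE]
  rep_df <- cbind(rank = seq_len(nrow(rep_df)), rep_df)
  rownames(rep_df) <- NULL
  rep_df
}

#' Human-readable summary block per probe
#' @param report A [rank_probes()] report.
#' @return Character vector of formatted lines, invisibly; also printed.
#' @export
report_summary <- function(report) {
  lines <- unlist(lapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    c(sprintf("#%d %s%s", r$rank, r$probe_name,
              if (isTRUE(r$specific)) "  [specific]" else ""),
      sprintf("   min off-target mismatches: %d (0-mm off-targets: %d)",
              r$min_offtarget, r$n_zero_mm_offtargets),
      sprintf("   off-target spectrum: %s", r$spectrum_summary),
      sprintf("   worst accessibility class: %s   Tm: %s",
              ifelse(is.na(r$worst_class), "unknown", r$worst_class),
              ifelse(is.na(r$tm), "NA", sprintf("%.1f C", r$tm))))
  }))
  cat(lines, sep = "\n")
  invisible(lines)
}
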