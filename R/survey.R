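# Detection-survey tabulation: per-site, per-species counts of analyzed and
# PCR-positive plant samples, summarized with integer round-half-up
# percentages (16.7 -> 17, 42.9 -> 43). Undefined percentages (0 analyzed)
# are NA, never 0.

#' Read a detection table
#'
#' TSV with columns `site`, `species`, `n_analyzed`, `n_positive`; one row per
#' (site, species). `n_positive` must not exceed `n_analyzed`.
#'
#' @param path TSV path or an equivalent data frame.
#' @return A validated `detection_table` data frame.
#' @export
read_detection_table <- function(path) {
  tab <- if (is.character(path)) read_tsv_meta(path) else as.data.frame(path)
  need <- c("site", "species", "n_analyzed", "n_positive")
  if (!all(need %in% names(tab)))
    stop("detection table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (any(tab$n_analyzed < 0) || any(tab$n_positive < 0))
    stop("counts must be non-negative")
  bad <- which(tab$n_positive > tab$n_analyzed)
  if (length(bad))
    stop("n_positive exceeds n_analyzed for row(s): ",
         paste(sprintf("%s/%s", tab$site[bad], tab$species[bad]), collapse = ", "))
  key <- paste(tab$site, tab$species, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (site, species) rows: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  structure(tab, class = c("detection_table", "data.frame"))
}

#' Tabulate a detection table
#'
#' Computes per-site, per-species and overall totals with positivity
#' percentages (`round_digits` decimal places, round-half-up). Groups with
#' zero analyzed samples get `NA` percentages.
#'
#' @param table A [read_detection_table()] table (or path/data frame).
#' @param round_digits Decimal places for percentages (default 0, matching
#'   integer reporting conventions).
#' @return A `detection_summary` list with elements `per_site`,
#'   `per_species`, `overall` (data frames with `n_analyzed`, `n_positive`,
#'   `pct_positive`).
#' @export
tabulate_detections <- function(table, round_digits = 0) {
  if (!inherits(table, "detection_table")) table <- read_detection_table(table)
  pct <- function(p, n) ifelse(n > 0, round_half_up(100 * p / n, round_digits), NA_real_)
  agg <- function(by) {
    if (nrow(table) == 0)
      return(data.frame(group = character(0), n_analyzed = integer(0),
                        n_positive = integer(0), pct_positive = numeric(0),
                        stringsAsFactors = FALSE))
    a <- stats::aggregate(cbind(n_analyzed, n_positive) ~ g,
                          data = data.frame(g = table[[by]],
                                            n_analyzed = table$n_analyzed,
                                            n_positive = table$n_positive),
                          FUN = sum)
    names(a)[1] <- by
    a$pct_positive <- pct(a$n_positive, a$n_analyzed)
    a[order(a[[by]]), , drop = FALSE]
  }
  overall <- data.frame(n_analyzed = sum(table$n_analyzed),
                        n_positive = sum(table$n_positive))
  overall$pct_positive <- pct(overall$n_positive, overall$n_analyzed)
  structure(list(per_site = agg("site"), per_species = agg("species"),
                 overall = overall, round_digits = round_digits),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Overall:", x$overall$n_positive, "positive of", x$overall$n_analyzed,
      "analyzed",
      if (is.na(x$overall$pct_positive)) "(NA%)" else
        sprintf("(%s%%)", format(x$overall$pct_positive)), "\n\nPer site:\n")
  print(x$per_site, row.names = FALSE)
  cat("\nPer species:\n")
  print(x$per_species, row.names = FALSE)
  invisible(x)
}

#' Write a detection summary to TSV
#'
#' Emits the site, species and overall blocks into a single TSV with a
#' `level` column.
#'
#' @param summary A [tabulate_detections()] summary.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_summary <- function(summary, path) {
  blk <- function(df, level, keycol) {
    data.frame(level = rep(level, nrow(df)),
               group = if (is.null(keycol)) "all" else df[[keycol]],
               n_analyzed = df$n_analyzed, n_positive = df$n_positive,
               pct_positive = ifelse(is.na(df$pct_positive), "NA",
                                     format(df$pct_positive, trim = TRUE)))
  }
  out <- rbind(blk(summary$per_site, "site", "site"),
               blk(summary$per_species, "species", "species"),
               blk(summary$overall, "overall", NULL))
  write_tsv_meta(out, path, command = "tabulate")
}
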