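# Target-site accessibility against an empirical 18S brightness-class map.
#
# Accessibility classes I..VI grade how brightly probes at an rRNA region
# hybridize in fixed cells (I = brightest). The map is user-supplied data on
# its own reference coordinates; this package ships only the file format and
# a toy synthetic example, not transcribed published values.

ACCESS_CLASSES <- c("I", "II", "III", "IV", "V", "VI")

#' Load an accessibility-class map
#'
#' Reads a TSV with columns `start`, `end`, `class` (1-based closed intervals
#' on the map's reference; classes `I`..`VI`). Intervals must not overlap.
#'
#' @param path TSV path or an equivalent data frame.
#' @param reference_name Name of the map's reference sequence (metadata).
#' @return An `accessibility_map` data frame sorted by `start`.
#' @export
load_accessibility_map <- function(path, reference_name = "18S") {
  map <- if (is.character(path)) read_tsv_meta(path) else as.data.frame(path)
  if (nrow(map) == 0) {
    map <- data.frame(start = integer(0), end = integer(0), class = character(0))
  } else {
    need <- c("start", "end", "class")
    if (!all(need %in% names(map)))
      stop("accessibility map must have columns: ", paste(need, collapse = ", "))
    bad <- setdiff(unique(map$class), ACCESS_CLASSES)
    if (length(bad)) stop("unknown accessibility class label(s): ",
                          paste(bad, collapse = ", "))
    if (any(map$end < map$start)) stop("interval with end < start")
    map <- map[order(map$start), c("start", "end", "class")]
    if (nrow(map) > 1 && any(map$start[-1] <= map$end[-nrow(map)]))
      stop("overlapping intervals in accessibility map")
  }
  structure(map, class = c("accessibility_map", "data.frame"),
            reference_name = reference_name)
}

#' Accessibility score of probe target sites
#'
#' Looks up the accessibility class of every map position overlapped by each
#' probe's target site (site positions are translated to map coordinates by
#' the integer `offset`, map_position = target_position + offset). The
#' headline score is the worst (numerically highest) class over the site;
#' the mean class rank is reported for ranking granularity. Positions outside
#' every interval are `unknown` and excluded from the mean; a site with no
#' known position scores `worst_class = NA`.
#'
#' @param probes A `probe_set` (one or more rows).
#' @param map An [load_accessibility_map()] object.
#' @param offset Integer offset from probe reference to map reference
#'   coordinates (default 0: identical numbering).
#' @return Data frame: `probe_name`, `classes_covered` (e.g. `"I:10,II:8"`),
#'   `worst_class`, `mean_class_rank`, `n_unknown`.
#' @export
site_accessibility <- function(probes, map, offset = 0L) {
  stopifnot(inherits(map, "accessibility_map"))
  rows <- lapply(seq_len(nrow(probes)), function(i) {
    pos <- (probes$target_start[i]:probes$target_end[i]) + as.integer(offset)
    cls <- position_classes(pos, map)
    known <- !is.na(cls)
    covered <- if (any(known)) {
      tab <- table(factor(cls[known], levels = ACCESS_CLASSES))
      tab <- tab[tab > 0]
      paste(names(tab), tab, sep = ":", collapse = ",")
    } else ""
    data.frame(
      probe_name = probes$name[i], classes_covered = covered,
      worst_class = if (any(known))
        ACCESS_CLASSES[max(match(cls[known], ACCESS_CLASSES))] else NA_character_,
      mean_class_rank = if (any(known))
        mean(match(cls[known], ACCESS_CLASSES)) else NA_real_,
      n_unknown = sum(!known), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-position class lookup (NA where uncovered).
position_classes <- function(positions, map) {
  cls <- rep(NA_character_, length(positions))
  for (k in seq_len(nrow(map))) {
    inside <- positions >= map$start[k] & positions <= map$end[k]
    cls[inside] <- map$class[k]
  }
  cls
}
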