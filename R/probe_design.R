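# Probe enumeration, physical properties and anti-sense controls.
#
# A probe is a short DNA oligonucleotide complementary to the rRNA: its
# sequence (5'->3') is the reverse complement of the target-site sense window
# on the ungapped reference. Probes are represented as rows of a `probe_set`
# data frame (name, sequence, target_start, target_end, length, gc, tm, role,
# label, region).

#' Hybridization buffer conditions
#'
#' Monovalent salt and formamide conditions under which melting temperatures
#' are computed. Defaults correspond to a standard FISH buffer (5x SSC is
#' about 0.9 M Na+; 30% formamide).
#'
#' @param na_molar Na+ concentration in mol/L.
#' @param formamide_pct Formamide, percent v/v.
#' @return A list with elements `na_molar`, `formamide_pct`.
#' @export
hybridization_conditions <- function(na_molar = 0.9, formamide_pct = 30) {
  stopifnot(na_molar > 0, formamide_pct >= 0)
  list(na_molar = na_molar, formamide_pct = formamide_pct)
}

#' Probe design constraints
#'
#' @param length_min,length_max Probe length range (nt).
#' @param gc_min,gc_max GC fraction range.
#' @param tm_min,tm_max Melting temperature range (degrees C) under
#'   `conditions`.
#' @param max_homopolymer Longest allowed single-base run.
#' @param conditions A [hybridization_conditions()] list.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(length_min = 18L, length_max = 18L,
                               gc_min = 0.40, gc_max = 0.65,
                               tm_min = -Inf, tm_max = Inf,
                               max_homopolymer = 4L,
                               conditions = hybridization_conditions()) {
  stopifnot(length_min >= 1, length_max >= length_min,
            gc_min <= gc_max, tm_min <= tm_max, max_homopolymer >= 1)
  structure(list(length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 conditions = conditions),
            class = "design_constraints")
}

#' GC fraction of a DNA sequence
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector in [0, 1].
#' @export
gc_fraction <- function(sequence) {
  vapply(strsplit(toupper(sequence), "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")) / length(ch), 0)
}

#' Salt- and formamide-corrected melting temperature
#'
#' Empirical duplex Tm for hybridization probes:
#' `Tm = 81.5 + 16.6 log10[Na+] + 0.41 (%GC) - 675/length - 0.62 (%formamide)`.
#'
#' @param sequence Character vector of DNA sequences.
#' @param conditions A [hybridization_conditions()] list.
#' @return Tm in degrees Celsius (numeric vector).
#' @export
#' @examples
#' melting_temperature(strrep("AC", 10),
#'                     hybridization_conditions(0.9, 0)) # 67.49
melting_temperature <- function(sequence, conditions = hybridization_conditions()) {
  len <- nchar(sequence)
  if (any(len == 0)) stop("zero-length sequence")
  gc_pct <- 100 * gc_fraction(sequence)
  81.5 + 16.6 * log10(conditions$na_molar) + 0.41 * gc_pct -
    675 / len - 0.62 * conditions$formamide_pct
}

max_homopolymer_run <- function(sequence) {
  vapply(strsplit(sequence, "", fixed = TRUE),
         function(ch) max(rle(ch)$lengths), 0L)
}

new_probe_row <- function(name, sequence, target_start, target_end,
                          role = "sense", label = NA_character_,
                          region = NA_integer_,
                          conditions = hybridization_conditions()) {
  structure(data.frame(
    name = name, sequence = sequence,
    target_start = as.integer(target_start), target_end = as.integer(target_end),
    length = nchar(sequence), gc = gc_fraction(sequence),
    tm = melting_temperature(sequence, conditions),
    role = role, label = label, region = region,
    stringsAsFactors = FALSE),
    class = c("probe_set", "data.frame"))
}

# Target-site sense consensus over ungapped reference positions start..end.
# Errors (design error) if the target group is polymorphic or gapped there.
target_site_sense <- function(panel, start, length) {
  cmap <- build_coordinate_map(panel)
  end <- start + length - 1L
  if (start < 1 || end > nrow(cmap))
    stop("site [", start, ", ", end, "] outside ungapped reference (length ",
         nrow(cmap), ")")
  cols <- ref_to_column(cmap, start:end)
  prof <- column_profiles(panel)
  bad <- cols[is.na(prof$target_consensus[cols]) | prof$target_has_gap[cols]]
  if (length(bad))
    stop("target group is polymorphic or gapped at alignment column(s): ",
         paste(bad, collapse = ", "))
  list(sense = paste(prof$target_consensus[cols], collapse = ""), columns = cols)
}

#' Design a probe at a reference site
#'
#' Builds the probe complementary to the target-group consensus over the
#' ungapped-reference interval `[start, start + length - 1]`. The probe name
#' is `<prefix><start>`, following the convention of naming probes by their
#' target-site start position.
#'
#' @param panel An `aligned_panel` with group metadata.
#' @param start 1-based start position on the ungapped reference.
#' @param length Probe length in nt.
#' @param prefix Name prefix (e.g. `"T.mag"`).
#' @param label Optional fluorophore label (metadata only).
#' @param conditions A [hybridization_conditions()] list for Tm.
#' @return A one-row `probe_set` data frame.
#' @export
probe_from_site <- function(panel, start, length, prefix = "probe",
                            label = NA_character_,
                            conditions = hybridization_conditions()) {
  site <- target_site_sense(panel, start, length)
  new_probe_row(name = paste0(prefix, start), sequence = revcomp(site$sense),
                target_start = start, target_end = start + length - 1L,
                label = label, conditions = conditions)
}

#' Enumerate candidate probes over discriminative regions
#'
#' Slides every allowed probe length across each candidate region, keeping
#' sites where the target group is monomorphic and ungapped, that satisfy the
#' physical constraints, and that cover at least `min_discriminative`
#' discriminative columns (so every candidate interrogates a diagnostic
#' polymorphism). Output is ordered by `target_start`, then length.
#'
#' @param panel An `aligned_panel` with group metadata.
#' @param regions Regions from [find_discriminative_regions()] on this panel.
#' @param constraints A [design_constraints()] list.
#' @param prefix Name prefix for [probe_from_site()]-style names; duplicate
#'   start positions (different lengths) get a `.L<len>` suffix.
#' @param min_discriminative Minimum discriminative columns a probe site must
#'   cover (default 1).
#' @return A `probe_set` data frame (possibly zero rows).
#' @export
enumerate_probes <- function(panel, regions, constraints = design_constraints(),
                             prefix = "probe", min_discriminative = 1L) {
  stopifnot(inherits(panel, "aligned_panel"))
  cmap <- build_coordinate_map(panel)
  prof <- column_profiles(panel)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    cols <- regions$start[r]:regions$end[r]
    ref_pos <- column_to_ref(cmap, cols)
    ref_pos <- ref_pos[!is.na(ref_pos)]
    if (length(ref_pos) == 0) next
    for (len in constraints$length_min:constraints$length_max) {
      if (len > length(ref_pos)) next
      for (s in ref_pos[1]:(ref_pos[length(ref_pos)] - len + 1L)) {
        site_cols <- ref_to_column(cmap, s:(s + len - 1L))
        if (site_cols[len] > regions$end[r]) next
        pc <- prof[site_cols, ]
        if (any(is.na(pc$target_consensus)) || any(pc$target_has_gap)) next
        if (sum(pc$is_discriminative) < min_discriminative) next
        sense <- paste(pc$target_consensus, collapse = "")
        seq <- revcomp(sense)
        gc <- gc_fraction(seq)
        if (gc < constraints$gc_min || gc > constraints$gc_max) next
        if (max_homopolymer_run(seq) > constraints$max_homopolymer) next
        tm <- melting_temperature(seq, constraints$conditions)
        if (tm < constraints$tm_min || tm > constraints$tm_max) next
        out[[length(out) + 1L]] <- new_probe_row(
          name = paste0(prefix, s), sequence = seq,
          target_start = s, target_end = s + len - 1L,
          region = r, conditions = constraints$conditions)
      }
    }
  }
  if (length(out) == 0)
    return(new_probe_row("x", "A", 1, 1)[0, ])
  probes <- do.call(rbind, out)
  probes <- probes[order(probes$target_start, probes$length), , drop = FALSE]
  dup <- duplicated(probes$name) | duplicated(probes$name, fromLast = TRUE)
  probes$name[dup] <- paste0(probes$name[dup], ".L", probes$length[dup])
  rownames(probes) <- NULL
  class(probes) <- c("probe_set", "data.frame")
  probes
}

#' Anti-sense (non-binding) control probe
#'
#' Returns the inverted-and-complemented version of a sense probe: its
#' sequence equals the rRNA sense strand at the target site and therefore
#' cannot hybridize the rRNA, making it a negative control for nonspecific
#' binding. Names are prefixed `AS-`; controls cannot be chained.
#'
#' @param probe A one-row `probe_set` with `role == "sense"`.
#' @return A one-row `probe_set` with `role == "antisense_control"`.
#' @export
antisense_control <- function(probe) {
  stopifnot(is.data.frame(probe), nrow(probe) == 1)
  if (probe$role != "sense")
    stop("anti-sense controls are built from sense probes only, got role '",
         probe$role, "'")
  probe$sequence <- revcomp(probe$sequence)
  probe$name <- paste0("AS-", probe$name)
  probe$role <- "antisense_control"
  probe$gc <- gc_fraction(probe$sequence)
  probe
}

#' Physical properties of a probe sequence
#'
#' @param probe A one-row `probe_set` (or any data frame with a `sequence`).
#' @param conditions A [hybridization_conditions()] list.
#' @return List with `gc_fraction` and `tm_celsius`.
#' @export
physical_properties <- function(probe, conditions = hybridization_conditions()) {
  list(gc_fraction = gc_fraction(probe$sequence),
       tm_celsius = melting_temperature(probe$sequence, conditions))
}

#' Write a probe set as TSV (with metadata header) or FASTA
#' @param probes A `probe_set` data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv_meta(probes, path, command = "design")
  } else {
    ss <- Biostrings::BStringSet(stats::setNames(probes$sequence, probes$name))
    Biostrings::writeXStringSet(ss, filepath = path)
  }
  invisible(path)
}

#' Read a probe set from TSV
#' @param path A TSV written by [write_probes()] (columns `name`, `sequence`,
#'   `target_start`, `target_end`, `role` at minimum).
#' @return A `probe_set` data frame.
#' @export
read_probes <- function(path) {
  df <- read_tsv_meta(path)
  need <- c("name", "sequence", "target_start", "target_end")
  if (!all(need %in% names(df)))
    stop("probe TSV must have columns: ", paste(need, collapse = ", "))
  if (!"role" %in% names(df)) df$role <- "sense"
  class(df) <- c("probe_set", "data.frame")
  df
}
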