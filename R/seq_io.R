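# Alignment and panel-metadata I/O, plus gapped<->ungapped coordinate maps.
#
# An `aligned_panel` holds a multiple sequence alignment of SSU rDNA sequences
# together with per-sequence taxon/group metadata and a designated ungapped
# coordinate reference (normally the target species' sequence). All probe
# coordinates in this package are 1-based closed intervals on that ungapped
# reference.

PANEL_GROUPS <- c("target", "non_target", "outgroup", "unassigned")

new_aligned_panel <- function(seqs, records, reference_id) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  obj <- structure(
    list(seqs = seqs, records = records,
         reference_id = reference_id,
         length = if (length(seqs)) nchar(seqs[[1]]) else 0L),
    class = "aligned_panel")
  validate_aligned_panel(obj)
}

validate_aligned_panel <- function(panel) {
  ids <- panel$records$id
  if (any(!nzchar(ids))) stop("panel contains an empty sequence id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in panel: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(panel$seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(panel$seqs)[lens != lens[1]][1]
    stop("ragged alignment: sequence '", bad, "' has length ", nchar(panel$seqs[[bad]]),
         ", expected ", lens[1])
  }
  if (!panel$reference_id %in% ids)
    stop("reference_id '", panel$reference_id, "' not present in panel")
  panel
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' Reads an aligned FASTA file into an `aligned_panel`. Residues are
#' upper-cased and RNA `U` is normalized to `T` (a per-record `rna_input` flag
#' preserves the original alphabet). All sequences must have equal gapped
#' length. Taxon/group metadata are initially unassigned; attach them with
#' [attach_panel_metadata()]. The coordinate reference defaults to the first
#' record and can be changed with [set_reference()].
#'
#' @param path Path to an aligned FASTA file.
#' @return An `aligned_panel` object.
#' @seealso [attach_panel_metadata()], [build_coordinate_map()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("alignment file is empty: ", path)
  seqs <- toupper(as.character(ss))
  # FASTA headers may carry descriptions; the id is the first token
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  rna <- grepl("U", seqs, fixed = TRUE)
  seqs <- chartr("U", "T", seqs)
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    paste(setdiff(ch, .allowed_residues), collapse = "")
  }, "")
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("sequence '", names(seqs)[i], "' contains invalid residues: ", bad[i])
  }
  records <- data.frame(
    id = names(seqs), taxon = NA_character_, group = "unassigned",
    accession = NA_character_, rna_input = rna,
    stringsAsFactors = FALSE, row.names = NULL)
  new_aligned_panel(seqs, records, reference_id = names(seqs)[1])
}

#' Write an alignment to FASTA
#'
#' @param panel An `aligned_panel`.
#' @param path Output path.
#' @param width Line-wrap width (fixed so round trips are byte-stable).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(panel, path, width = 60L) {
  ss <- Biostrings::BStringSet(panel$seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Attach taxon/group metadata to a panel
#'
#' Assigns each sequence a taxon name, a group label (`target`, `non_target`,
#' `outgroup`) and an optional accession from a 4-column TSV
#' (`id  taxon  group  accession`) or an equivalent data frame. Panel ids
#' absent from the table keep `group = "unassigned"` (with a warning); table
#' ids absent from the panel are an error. The coordinate reference is moved
#' to the first target-group record unless it was set explicitly with
#' [set_reference()].
#'
#' @param panel An `aligned_panel`.
#' @param table Path to a TSV file, or a data frame with columns
#'   `id`, `taxon`, `group` and optionally `accession`.
#' @return The panel with metadata attached.
#' @export
attach_panel_metadata <- function(panel, table) {
  stopifnot(inherits(panel, "aligned_panel"))
  tab <- if (is.character(table)) read_tsv_meta(table) else as.data.frame(table)
  need <- c("id", "taxon", "group")
  if (!all(need %in% names(tab)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  if (!"accession" %in% names(tab)) tab$accession <- NA_character_
  if (anyDuplicated(tab$id))
    stop("duplicate id rows in metadata table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  unknown <- setdiff(tab$id, panel$records$id)
  if (length(unknown))
    stop("metadata ids not present in panel: ", paste(unknown, collapse = ", "))
  badg <- setdiff(unique(tab$group), PANEL_GROUPS)
  if (length(badg))
    stop("unknown group labels: ", paste(badg, collapse = ", "),
         " (allowed: ", paste(PANEL_GROUPS, collapse = ", "), ")")
  missing <- setdiff(panel$records$id, tab$id)
  if (length(missing))
    warning("panel ids without metadata remain unassigned: ",
            paste(missing, collapse = ", "))
  i <- match(tab$id, panel$records$id)
  panel$records$taxon[i] <- tab$taxon
  panel$records$group[i] <- tab$group
  panel$records$accession[i] <- as.character(tab$accession)
  if (!isTRUE(attr(panel, "reference_explicit"))) {
    tgt <- panel$records$id[panel$records$group == "target"]
    if (length(tgt)) panel$reference_id <- tgt[1]
  }
  validate_aligned_panel(panel)
}

#' Designate the ungapped coordinate reference of a panel
#'
#' @param panel An `aligned_panel`.
#' @param id Id of the record whose ungapped coordinates anchor probe sites.
#' @return The modified panel.
#' @export
set_reference <- function(panel, id) {
  stopifnot(inherits(panel, "aligned_panel"))
  if (!id %in% panel$records$id) stop("unknown sequence id: ", id)
  panel$reference_id <- id
  attr(panel, "reference_explicit") <- TRUE
  panel
}

#' Gapped/ungapped coordinate map for one panel record
#'
#' Returns the strictly increasing pairing of alignment columns with ungapped
#' positions (both 1-based) for a record, covering exactly its non-gap columns.
#'
#' @param panel An `aligned_panel`.
#' @param id Record id; defaults to the panel reference.
#' @return A `coordinate_map`: data frame with columns `column`, `position`.
#' @export
build_coordinate_map <- function(panel, id = panel$reference_id) {
  stopifnot(inherits(panel, "aligned_panel"))
  if (!id %in% panel$records$id) stop("unknown sequence id: ", id)
  ch <- strsplit(panel$seqs[[id]], "", fixed = TRUE)[[1]]
  cols <- which(ch != "-")
  if (length(cols) == 0) warning("record '", id, "' is all gaps; empty coordinate map")
  structure(data.frame(column = cols, position = seq_along(cols)),
            class = c("coordinate_map", "data.frame"), id = id)
}

#' Map ungapped reference positions to alignment columns
#' @param map A `coordinate_map`.
#' @param positions Integer vector of ungapped positions.
#' @return Integer vector of alignment columns.
#' @export
ref_to_column <- function(map, positions) {
  if (any(positions < 1 | positions > nrow(map)))
    stop("position outside ungapped reference (length ", nrow(map), ")")
  map$column[positions]
}

#' Map alignment columns to ungapped reference positions
#' @param map A `coordinate_map`.
#' @param columns Integer vector of alignment columns; columns where the
#'   record has a gap return `NA`.
#' @return Integer vector of ungapped positions (`NA` at gap columns).
#' @export
column_to_ref <- function(map, columns) {
  map$position[match(columns, map$column)]
}

#' Ungapped sequence of a panel record
#' @param panel An `aligned_panel`.
#' @param id Record id; defaults to the panel reference.
#' @return Ungapped sequence string.
#' @export
ungapped_sequence <- function(panel, id = panel$reference_id) {
  if (!id %in% panel$records$id) stop("unknown sequence id: ", id)
  gsub("-", "", panel$seqs[[id]], fixed = TRUE)
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat("aligned_panel:", nrow(x$records), "sequences x", x$length, "columns\n")
  cat("  reference:", x$reference_id,
      sprintf("(ungapped length %d)\n", nchar(ungapped_sequence(x))))
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$records$group)),
                                 table(x$records$group)), collapse = " "), "\n")
  invisible(x)
}
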