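# Internal helpers shared across modules: IUPAC matching, reverse complement,
# and TSV I/O with `#`-prefixed metadata headers.

# IUPAC nucleotide codes -> set of unambiguous bases each code stands for.
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.allowed_residues <- c(names(.iupac_sets), "-")

# Lookup matrix: does observed residue `obs` (rows, incl. '-') cover expected
# unambiguous base `exp` (cols)? A gap covers nothing; an ambiguity code covers
# the bases in its set.
.iupac_cover <- local({
  m <- matrix(FALSE, nrow = length(.allowed_residues), ncol = 4,
              dimnames = list(.allowed_residues, c("A", "C", "G", "T")))
  for (code in names(.iupac_sets)) m[code, .iupac_sets[[code]]] <- TRUE
  m
})

# Vectorized: TRUE where observed residue is compatible with the expected base
# (exact match, or ambiguity code whose set contains the expected base).
residue_matches <- function(expected, observed) {
  out <- logical(length(observed))
  known <- observed %in% rownames(.iupac_cover) & expected %in% colnames(.iupac_cover)
  out[known] <- .iupac_cover[cbind(observed[known], expected[known])]
  out
}

#' Reverse complement of DNA sequences
#'
#' Thin wrapper over [Biostrings::reverseComplement()] returning plain
#' character vectors. Sequences must be unambiguous DNA (A/C/G/T).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GATTACA")
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into a character matrix (rows = sequences).
seq_char_matrix <- function(seqs) {
  m <- matrix("", nrow = length(seqs), ncol = if (length(seqs)) nchar(seqs[[1]]) else 0L)
  for (i in seq_along(seqs)) m[i, ] <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
  rownames(m) <- names(seqs)
  m
}

# TSV output with '#'-prefixed metadata lines (tool version + parameters);
# deterministic, no timestamps, so identical runs are byte-identical.
write_tsv_meta <- function(df, path, command = NULL, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("probespectrum"))
  writeLines(sprintf("# probespectrum %s", ver), con)
  if (!is.null(command)) {
    kv <- if (length(params))
      paste(names(params), vapply(params, function(p) paste(p, collapse = ","), ""),
            sep = "=", collapse = " ") else ""
    writeLines(trimws(sprintf("# command: %s %s", command, kv)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# round-half-up at `digits` decimal places (0.5 always rounds away from zero
# for the non-negative quantities used here), unlike banker's round().
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}
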