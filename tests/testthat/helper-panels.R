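# Test helpers: building panels through the public I/O surface, plus naive
# brute-force oracles kept deliberately independent of the implementation.

# Build an aligned_panel from named sequences via FASTA + metadata TSV files.
panel_from_seqs <- function(seqs, groups, taxa = names(seqs), reference = NULL) {
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fa)
  panel <- read_alignment(fa)
  meta <- data.frame(id = names(seqs), taxon = taxa, group = groups,
                     accession = NA_character_)
  panel <- attach_panel_metadata(panel, meta)
  if (!is.null(reference)) panel <- set_reference(panel, reference)
  panel
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Random panel: a target clade plus diverged off-target sequences, optional gaps.
random_panel <- function(n_seq, n_col, n_target = 2, p_sub = 0.05, p_gap = 0) {
  ref <- strsplit(random_dna(n_col), "")[[1]]
  seqs <- character(n_seq)
  for (i in seq_len(n_seq)) {
    s <- ref
    if (i > n_target) {
      mut <- runif(n_col) < p_sub
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
      if (p_gap > 0) s[runif(n_col) < p_gap] <- "-"
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- paste0("s", seq_len(n_seq))
  groups <- c(rep("target", n_target), rep("non_target", n_seq - n_target))
  panel_from_seqs(seqs, groups)
}

# Naive Hamming screen: double loop over subjects and windows, comparing the
# probe's sense target pattern (revcomp of the probe string, computed here by
# lookup, not via the package) to each window character by character.
naive_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

naive_screen <- function(probe_seq, subjects, max_mm) {
  pattern <- strsplit(naive_revcomp(probe_seq), "")[[1]]
  L <- length(pattern)
  out <- list()
  for (id in names(subjects)) {
    ch <- strsplit(subjects[[id]], "")[[1]]
    if (length(ch) < L) next
    for (s in seq_len(length(ch) - L + 1)) {
      mm <- 0L
      for (i in seq_len(L)) if (ch[s + i - 1] != pattern[i]) mm <- mm + 1L
      if (mm <= max_mm)
        out[[length(out) + 1]] <- data.frame(subject_id = id, subject_start = s,
                                             n_mismatches = mm)
    }
  }
  if (length(out) == 0)
    return(data.frame(subject_id = character(0), subject_start = integer(0),
                      n_mismatches = integer(0)))
  do.call(rbind, out)
}

# Naive region discovery: recompute discriminative columns from scratch,
# test every window by explicit loops, merge overlapping windows by interval
# sweeping. Returns data.frame(start, end).
naive_regions <- function(panel, w, min_disc) {
  m <- do.call(rbind, strsplit(unname(panel$seqs), ""))
  grp <- panel$records$group
  tm <- m[grp == "target", , drop = FALSE]
  om <- m[grp %in% c("non_target", "outgroup"), , drop = FALSE]
  n_col <- ncol(m)
  disc <- logical(n_col); tgap <- logical(n_col)
  for (j in seq_len(n_col)) {
    tgap[j] <- any(tm[, j] == "-")
    if (!tgap[j] && length(unique(tm[, j])) == 1) {
      cons <- tm[1, j]
      disc[j] <- sum(om[, j] != cons) >= 1
    }
  }
  ok <- integer(0)
  for (s in seq_len(n_col - w + 1)) {
    win <- s:(s + w - 1)
    if (!any(tgap[win]) && sum(disc[win]) >= min_disc) ok <- c(ok, s)
  }
  if (length(ok) == 0) return(data.frame(start = integer(0), end = integer(0)))
  iv <- cbind(ok, ok + w - 1)
  merged <- list(iv[1, ])
  for (r in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[r, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
    } else merged[[length(merged) + 1]] <- iv[r, ]
  }
  data.frame(start = vapply(merged, `[`, 0, 1), end = vapply(merged, `[`, 0, 2))
}

# A small clean panel used across tests: 20-column alignment, two target and
# two off-target sequences differing at columns 5 and 12.
clean_panel <- function() {
  t1 <- "ACGTACGTACGTACGTACGT"
  nt <- t1
  substr(nt, 5, 5) <- "G"   # target A -> G
  substr(nt, 12, 12) <- "A" # target T -> A
  panel_from_seqs(
    c(tgt1 = t1, tgt2 = t1, off1 = nt, off2 = nt),
    groups = c("target", "target", "non_target", "non_target"),
    taxa = c("T_target", "T_target", "T_off", "T_off"))
}
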