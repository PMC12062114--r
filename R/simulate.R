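# Synthetic SSU-like panel generator with planted diagnostic SNPs.
#
# The generator emits a gapless (optionally gapped) alignment of a target
# clade plus several non-target clades derived from one random reference
# sequence. Divergence has two components: planted diagnostic sites (exact,
# per-clade base assignments, the ground truth for discrimination tests) and
# i.i.d. per-site background substitutions applied clade-wise outside the
# planted sites. All randomness flows through a single integer seed.

BASES <- c("A", "C", "G", "T")

#' Simulate a synthetic SSU-like aligned panel
#'
#' @param seed Integer seed; panels are byte-identical for a fixed seed.
#' @param n_target Number of (identical) target-group sequences.
#' @param n_nontarget_per_clade Sequences per non-target clade (clade members
#'   are identical; divergence acts between clades).
#' @param n_clades Number of non-target clades.
#' @param length Ungapped reference length (nt).
#' @param background_divergence Per-site substitution probability applied to
#'   each clade outside planted sites (default 0: all divergence planted).
#' @param planted_sites Optional data frame with columns `position`,
#'   `alt_clades` (comma-separated clade names, or `"*"` for every clade),
#'   and optionally `target_base` / `alt_base` (`NA` = drawn from the
#'   reference / chosen as a transition).
#' @param clade_names Clade names (default `clade1`..`cladeN`).
#' @param clade_groups Group label per clade, `non_target` (default) or
#'   `outgroup`.
#' @param indel_rate Per-site probability of a gap in a clade sequence
#'   outside planted sites (default 0: gapless).
#' @return List with `panel` (an `aligned_panel`, reference = first target
#'   sequence) and `truth` (seed, reference string, resolved planted sites,
#'   group memberships).
#' @export
simulate_panel <- function(seed, n_target = 3L, n_nontarget_per_clade = 2L,
                           n_clades = 4L, length = 1800L,
                           background_divergence = 0,
                           planted_sites = NULL,
                           clade_names = NULL, clade_groups = NULL,
                           indel_rate = 0) {
  stopifnot(n_target >= 1, n_nontarget_per_clade >= 1, n_clades >= 1,
            length >= 1, background_divergence >= 0, background_divergence < 1,
            indel_rate >= 0, indel_rate < 1)
  if (is.null(clade_names)) clade_names <- paste0("clade", seq_len(n_clades))
  stopifnot(length(clade_names) == n_clades)
  if (is.null(clade_groups)) clade_groups <- rep("non_target", n_clades)
  stopifnot(all(clade_groups %in% c("non_target", "outgroup")))

  transition <- c(A = "G", G = "A", C = "T", T = "C")
  set.seed(as.integer(seed))
  ref <- sample(BASES, length, replace = TRUE)

  # resolve planted sites against the drawn reference
  if (!is.null(planted_sites)) {
    ps <- as.data.frame(planted_sites)
    stopifnot(all(c("position", "alt_clades") %in% names(ps)))
    if (anyDuplicated(ps$position)) stop("planted sites must be distinct")
    if (any(ps$position < 1 | ps$position > length))
      stop("planted site position outside reference length ", length)
    if (!"target_base" %in% names(ps)) ps$target_base <- NA_character_
    if (!"alt_base" %in% names(ps)) ps$alt_base <- NA_character_
    keep <- is.na(ps$target_base)
    ps$target_base[keep] <- ref[ps$position[keep]]
    ref[ps$position] <- ps$target_base
    ps$alt_base[is.na(ps$alt_base)] <- transition[ps$target_base[is.na(ps$alt_base)]]
    if (any(ps$alt_base == ps$target_base))
      stop("alt_base equal to target_base at a planted site")
    ps$alt_clades <- as.character(ps$alt_clades)
    bad <- setdiff(setdiff(unlist(strsplit(ps$alt_clades, ",")), "*"), clade_names)
    if (length(bad)) stop("unknown clade(s) in planted_sites: ",
                          paste(bad, collapse = ", "))
  } else {
    ps <- data.frame(position = integer(0), alt_clades = character(0),
                     target_base = character(0), alt_base = character(0))
  }
  planted_pos <- ps$position

  clade_seq <- function(clade) {
    s <- ref
    free <- setdiff(seq_len(length), planted_pos)
    if (background_divergence > 0) {
      mut <- free[stats::runif(length(free)) < background_divergence]
      for (p in mut) s[p] <- sample(setdiff(BASES, s[p]), 1L)
    }
    if (indel_rate > 0) {
      del <- free[stats::runif(length(free)) < indel_rate]
      s[del] <- "-"
    }
    for (k in seq_len(nrow(ps))) {
      clades <- strsplit(ps$alt_clades[k], ",")[[1]]
      if (identical(clades, "*") || clade %in% clades)
        s[ps$position[k]] <- ps$alt_base[k]
    }
    paste(s, collapse = "")
  }

  target_ids <- paste0("target_", seq_len(n_target))
  seqs <- stats::setNames(rep(paste(ref, collapse = ""), n_target), target_ids)
  taxa <- rep("target_taxon", n_target)
  groups <- rep("target", n_target)
  for (ci in seq_len(n_clades)) {
    cs <- clade_seq(clade_names[ci])
    ids <- paste0(clade_names[ci], "_", seq_len(n_nontarget_per_clade))
    seqs[ids] <- cs
    taxa <- c(taxa, rep(clade_names[ci], n_nontarget_per_clade))
    groups <- c(groups, rep(clade_groups[ci], n_nontarget_per_clade))
  }
  records <- data.frame(id = names(seqs), taxon = taxa, group = groups,
                        accession = NA_character_, rna_input = FALSE,
                        stringsAsFactors = FALSE)
  panel <- new_aligned_panel(seqs, records, reference_id = target_ids[1])

  # generation-time self-check: emitted panel agrees with the planted truth
  mat <- seq_char_matrix(panel$seqs)
  for (k in seq_len(nrow(ps))) {
    p <- ps$position[k]
    if (any(mat[groups == "target", p] != ps$target_base[k]))
      stop("internal error: target not monomorphic at planted site ", p)
    clades <- strsplit(ps$alt_clades[k], ",")[[1]]
    if (identical(clades, "*")) clades <- clade_names
    for (cl in clades) {
      if (any(mat[taxa == cl, p] != ps$alt_base[k]))
        stop("internal error: clade ", cl, " lacks alt base at planted site ", p)
    }
  }

  truth <- list(seed = as.integer(seed), ref_length = as.integer(length),
                reference = paste(ref, collapse = ""),
                planted_sites = ps,
                groups = stats::setNames(groups, names(seqs)),
                clade_names = clade_names, clade_groups = clade_groups)
  list(panel = panel, truth = truth)
}

#' Build the truffle-style synthetic validation bundle
#'
#' A fully synthetic end-to-end fixture emulating the structure of a truffle
#' SSU probe-design panel: one target taxon (a *T. magnatum* analog, three
#' identical sequences), four relative clades (analogs of *T. borchii*,
#' *T. aestivum*, *T. brumale* and *Choiromyces*) and two outgroup clades
#' (*Morchella*- and *Dissingia*-like), with all divergence planted in four
#' 18-nt variable regions starting at reference positions 185, 645, 1313 and
#' 1647. Each region carries a designed probe (`syn185`, `syn645`, `syn1313`,
#' `syn1647`) whose planted mismatch structure mirrors the published probe
#' behavior: `syn185` has at least one SNP to every non-target; `syn645` is
#' pan-clade (matches all four relatives, three SNPs to outgroups);
#' `syn1313` matches the borchii-analog exactly and has a single SNP to the
#' aestivum-analog; `syn1647` has three SNPs to every non-target.
#'
#' @param seed Integer seed (the planted structure is seed-independent; the
#'   background reference sequence is not).
#' @param dir Optional directory; when given, the bundle files (`msa.fa`,
#'   `panel.tsv`, `truth.json`, `expected_spectrum.tsv`) are written there.
#' @return List: `panel`, `truth` (including `floors` and per-clade expected
#'   mismatch matrix `expected_mm`), `probes` (4-row `probe_set`),
#'   `expected_spectrum` (data frame derived from the planted truth, not from
#'   the specificity engine), `regions_expected` (the four planted regions).
#' @export
make_validation_bundle <- function(seed = 1L, dir = NULL) {
  clades <- c("borchii_like", "aestivum_like", "brumale_like",
              "choiromyces_like", "morchella_like", "dissingia_like")
  groups <- c(rep("non_target", 4), rep("outgroup", 2))
  relatives <- clades[1:4]; outgroups <- clades[5:6]
  planted <- rbind(
    data.frame(position = 188L, alt_clades = "*"),
    data.frame(position = 192L,
               alt_clades = paste(c("borchii_like", "aestivum_like",
                                    "choiromyces_like", outgroups), collapse = ",")),
    data.frame(position = 197L, alt_clades = paste(outgroups, collapse = ",")),
    data.frame(position = 648L, alt_clades = paste(outgroups, collapse = ",")),
    data.frame(position = 652L, alt_clades = paste(outgroups, collapse = ",")),
    data.frame(position = 658L, alt_clades = paste(outgroups, collapse = ",")),
    data.frame(position = 1316L,
               alt_clades = paste(c("aestivum_like", "brumale_like",
                                    "choiromyces_like", outgroups), collapse = ",")),
    data.frame(position = 1321L,
               alt_clades = paste(c("brumale_like", "choiromyces_like", outgroups),
                                  collapse = ",")),
    data.frame(position = 1326L, alt_clades = paste(outgroups, collapse = ",")),
    data.frame(position = 1650L, alt_clades = "*"),
    data.frame(position = 1655L, alt_clades = "*"),
    data.frame(position = 1660L, alt_clades = "*"))

  sim <- simulate_panel(seed = seed, n_target = 3L, n_nontarget_per_clade = 2L,
                        n_clades = 6L, length = 1800L,
                        background_divergence = 0,
                        planted_sites = planted,
                        clade_names = clades, clade_groups = groups)
  panel <- sim$panel
  starts <- c(185L, 645L, 1313L, 1647L)
  probes <- do.call(rbind, lapply(starts, function(s)
    probe_from_site(panel, s, 18L, prefix = "syn")))

  # expected per-clade mismatch counts, straight from the planted design
  ps <- sim$truth$planted_sites
  expected_mm <- t(vapply(starts, function(s) {
    inside <- ps$position >= s & ps$position <= s + 17L
    vapply(clades, function(cl) {
      sum(vapply(which(inside), function(k) {
        ac <- strsplit(ps$alt_clades[k], ",")[[1]]
        identical(ac, "*") || cl %in% ac
      }, TRUE))
    }, 0L)
  }, stats::setNames(integer(length(clades)), clades)))
  rownames(expected_mm) <- probes$name
  floors <- apply(expected_mm, 1, min)

  call_of <- function(mm) ifelse(mm == 0, "positive", ifelse(mm == 1, "weak", "negative"))
  taxa <- c("target_taxon", clades)
  expected_spectrum <- do.call(rbind, lapply(probes$name, function(pn) {
    mm <- c(0L, expected_mm[pn, ])
    data.frame(probe = pn, taxon = taxa,
               group = c("target", groups),
               min_mismatches = as.integer(mm), call = call_of(mm),
               stringsAsFactors = FALSE)
  }))
  expected_spectrum <- expected_spectrum[order(expected_spectrum$probe,
                                               expected_spectrum$taxon), ]
  rownames(expected_spectrum) <- NULL

  # self-check: the specificity engine reproduces the planted floors
  for (i in seq_len(nrow(probes))) {
    got <- min_offtarget_distance(probes[i, ], panel)
    if (got != floors[[probes$name[i]]])
      stop("internal error: planted floor mismatch for ", probes$name[i])
  }

  truth <- sim$truth
  truth$floors <- floors
  truth$expected_mm <- expected_mm
  truth$regions_expected <- data.frame(start = starts, end = starts + 17L)
  bundle <- list(panel = panel, truth = truth, probes = probes,
                 expected_spectrum = expected_spectrum,
                 regions_expected = truth$regions_expected)
  if (!is.null(dir)) write_fixture_bundle(bundle, dir)
  bundle
}

#' Write a fixture bundle to disk
#'
#' Emits `msa.fa` (aligned FASTA), `panel.tsv` (id/taxon/group/accession),
#' `truth.json` and `expected_spectrum.tsv` into `dir`.
#'
#' @param bundle A [make_validation_bundle()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(bundle$panel, file.path(dir, "msa.fa"))
  utils::write.table(bundle$panel$records[, c("id", "taxon", "group", "accession")],
                     file.path(dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$expected_mm <- as.data.frame(truth$expected_mm)
  truth$floors <- as.list(truth$floors)        # keep probe names in JSON
  truth$groups <- as.list(truth$groups)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  # header matches what `probespectrum spectrum` writes, so the pipeline
  # output can be compared byte-for-byte against this expectation
  write_tsv_meta(bundle$expected_spectrum, file.path(dir, "expected_spectrum.tsv"),
                 command = "spectrum",
                 params = list(positive_max = 0L, weak_max = 1L))
  invisible(dir)
}
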