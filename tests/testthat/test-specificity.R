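test_that("mismatch profiles count substitutions, gaps and ambiguity correctly", {
  #            123456789012345
  t1  <- "CCCCGATTACACCCC"
  sub <- "CCCCGATAACACCCC"  # sense position 8 (site pos 4) differs
  gap <- "CCCCGA-TACACCCC"  # gap inside the site
  amb <- "CCCCRATTACACCCC"  # R = A/G covers the expected G at site pos 1
  bad <- "CCCCYATTACACCCC"  # Y = C/T does not cover G
  panel <- panel_from_seqs(
    c(t1 = t1, sub = sub, gap = gap, amb = amb, bad = bad),
    groups = c("target", rep("non_target", 4)))
  probe <- probe_from_site(panel, 5, 7)  # site = GATTACA at 5..11
  prof <- mismatch_profile(probe, panel)
  rownames(prof) <- prof$sequence_id

  expect_equal(prof["t1", "n_mismatches"], 0)  # identity
  expect_equal(prof["sub", "n_mismatches"], 1)
  # sense site position 4 -> probe-local position 7 - 4 + 1 = 4
  expect_equal(prof["sub", "mismatch_positions"], "4")
  expect_equal(prof["gap", "n_mismatches"], 1)
  expect_true(prof["gap", "has_gap"])
  expect_equal(prof["gap", "n_gap"], 1)
  expect_equal(prof["gap", "mismatch_positions"], "")
  expect_equal(prof["amb", "n_mismatches"], 0)  # ambiguity covers expected base
  expect_equal(prof["bad", "n_mismatches"], 1)  # ambiguity not covering
})

test_that("probe-local mismatch positions run antiparallel to the sense site", {
  t1 <- "GATTACAGGG"
  o1 <- "CATTACAGGG"  # first sense base of the site differs
  panel <- panel_from_seqs(c(t = t1, o = o1), groups = c("target", "non_target"))
  probe <- probe_from_site(panel, 1, 7)
  prof <- mismatch_profile(probe, panel, ids = "o")
  expect_equal(prof$mismatch_positions, "7")  # 3' end of the probe
})

test_that("specificity matrices are complete with consistent min_offtarget", {
  bundle <- make_validation_bundle(seed = 6)
  mat <- specificity_matrix(bundle$probes, bundle$panel)
  expect_equal(nrow(mat), nrow(bundle$probes) * nrow(bundle$panel$records))
  mo <- min_offtarget(mat)
  off <- mat[mat$group %in% c("non_target", "outgroup"), ]
  for (p in names(mo))
    expect_equal(unname(mo[p]), min(off$n_mismatches[off$probe_name == p]))
  expect_equal(unname(mo), unname(bundle$truth$floors))
  for (i in seq_len(nrow(bundle$probes)))
    expect_equal(min_offtarget_distance(bundle$probes[i, ], bundle$panel),
                 unname(bundle$truth$floors[i]))
})

test_that("min_offtarget_distance needs off-target records and hits zero on equality", {
  t1 <- "GATTACAGGG"
  panel <- panel_from_seqs(c(a = t1, b = t1), groups = c("target", "target"))
  probe_panel <- panel_from_seqs(c(a = t1, b = t1),
                                 groups = c("target", "non_target"))
  probe <- probe_from_site(probe_panel, 1, 7)
  expect_error(min_offtarget_distance(probe, panel), "off-target")
  expect_equal(min_offtarget_distance(probe, probe_panel), 0)
})

test_that("spectrum calls follow thresholds and aggregate taxa by minimum", {
  # two sequences of one off-target taxon: 0 and 2 mismatches -> min 0 -> positive
  t1 <- "CCCCGATTACACCCC"
  s0 <- t1
  s2 <- "CCCCGAAAACACCCC"
  panel <- panel_from_seqs(c(t = t1, x1 = s0, x2 = s2),
                           groups = c("target", "non_target", "non_target"),
                           taxa = c("T_target", "T_x", "T_x"))
  probe <- probe_from_site(panel, 5, 7)
  mat <- specificity_matrix(probe, panel)
  sp <- predict_spectrum(mat)
  expect_equal(sp$min_mismatches[sp$taxon == "T_x"], 0)
  expect_equal(sp$call[sp$taxon == "T_x"], "positive")

  bundle <- make_validation_bundle(seed = 6)
  mat2 <- specificity_matrix(bundle$probes, bundle$panel)
  sp2 <- predict_spectrum(mat2)
  # >= 2 mismatches everywhere off-target -> negative for all non-targets
  s1647 <- sp2[sp2$probe == "syn1647" & sp2$group != "target", ]
  expect_true(all(s1647$call == "negative"))
  expect_error(predict_spectrum(mat2, positive_max = 2, weak_max = 1))
})

test_that("relaxing the positive threshold never shrinks the positive set", {
  bundle <- make_validation_bundle(seed = 9)
  mat <- specificity_matrix(bundle$probes, bundle$panel)
  prev <- character(0)
  for (k in 0:3) {
    sp <- predict_spectrum(mat, positive_max = k, weak_max = k + 1)
    pos <- paste(sp$probe, sp$taxon)[sp$call == "positive"]
    expect_true(all(prev %in% pos))
    prev <- pos
  }
})

test_that("screening finds planted sites and honors the orientation contract", {
  set.seed(31)
  subject <- random_dna(1000)
  probe_seq <- "TGACCTGAAGTCATCGAT"
  site <- naive_revcomp(probe_seq)  # sense window the probe hybridizes
  substr(subject, 101, 118) <- site
  probe <- data.frame(name = "p1", sequence = probe_seq, target_start = 1L,
                      target_end = 18L, role = "sense")
  hits <- screen_collection(probe, c(subj = subject), max_mismatches = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$subject_start, 101)
  expect_equal(hits$n_mismatches, 0)
  expect_equal(hits$strand, "+")

  # max_mismatches = 0 equals exact substring search for the sense site
  found <- gregexpr(site, subject, fixed = TRUE)[[1]]
  expect_equal(hits$subject_start, as.integer(found))

  # an anti-sense control screened against rRNA-sense subjects matches nowhere
  as_probe <- probe
  as_probe$sequence <- naive_revcomp(probe_seq)
  as_probe$name <- "AS-p1"
  as_hits <- screen_collection(as_probe, c(subj = subject), max_mismatches = 0)
  expect_equal(nrow(as_hits), 0)
})

test_that("both-strand screening reports minus-strand coordinates correctly", {
  set.seed(8)
  subject <- random_dna(300)
  probe_seq <- "ACGGATTCAACGGATGCA"
  # a minus-strand site at plus coords 51..68 means the plus strand carries
  # the probe sequence itself there
  substr(subject, 51, 68) <- probe_seq
  probe <- data.frame(name = "p1", sequence = probe_seq, target_start = 1L,
                      target_end = 18L, role = "sense")
  hits <- screen_collection(probe, c(s = subject), max_mismatches = 0,
                            both_strands = TRUE)
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$subject_start, 51)
})

test_that("short subjects are skipped with a warning; stringency bound enforced", {
  probe <- data.frame(name = "p", sequence = "ACGTACGTAC", target_start = 1L,
                      target_end = 10L, role = "sense")
  expect_warning(h <- screen_collection(probe, c(tiny = "ACGT"), 0), "skipped")
  expect_equal(nrow(h), 0)
  expect_error(screen_collection(probe, c(s = strrep("A", 50)), 10), "smaller")
})

test_that("screening equals the naive double-loop Hamming oracle", {
  set.seed(17)
  for (trial in 1:20) {
    L <- sample(8:22, 1)
    probe <- data.frame(name = "p", sequence = random_dna(L),
                        target_start = 1L, target_end = L, role = "sense")
    subjects <- setNames(lapply(1:2, function(i) random_dna(sample(80:400, 1))),
                         c("u", "v"))
    mm <- sample(0:4, 1)
    got <- screen_collection(probe, unlist(subjects), max_mismatches = mm)
    want <- naive_screen(probe$sequence, subjects, mm)
    want <- want[order(want$subject_id, want$subject_start), ]
    expect_equal(got$subject_id, want$subject_id)
    expect_equal(got$subject_start, want$subject_start)
    expect_equal(got$n_mismatches, want$n_mismatches)
  }
})
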