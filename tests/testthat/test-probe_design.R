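test_that("probe_from_site builds the reverse complement and position-based name", {
  # reference sense window GATTACA at ungapped positions 10-16
  ref <- paste0(strrep("C", 9), "GATTACA", strrep("C", 9))
  off <- chartr("G", "A", ref)
  panel <- panel_from_seqs(c(ref = ref, off = off),
                           groups = c("target", "non_target"))
  p <- probe_from_site(panel, 10, 7, prefix = "T.mag")
  expect_equal(p$sequence, "TGTAATC")
  expect_equal(p$name, "T.mag10")
  expect_equal(p$target_start, 10)
  expect_equal(p$target_end, 16)
  expect_equal(p$length, 7)
  expect_equal(p$role, "sense")
})

test_that("sites spanning target gaps or polymorphisms are design errors", {
  # the reference is ungapped but a second target record has a gap at column 5
  seqs <- c(t1 = "ACGTAACGTA", t2 = "ACGT-ACGTA", o = "ACGTTACGTA")
  panel <- panel_from_seqs(seqs, groups = c("target", "target", "non_target"))
  expect_error(probe_from_site(panel, 3, 5), "gapped")
  poly <- c(t1 = "ACGTAACGTA", t2 = "ACGTCACGTA", o = "ACGTTACGTA")
  panel2 <- panel_from_seqs(poly, groups = c("target", "target", "non_target"))
  expect_error(probe_from_site(panel2, 3, 5), "polymorphic")
  expect_error(probe_from_site(panel, 8, 5), "outside")
})

test_that("melting temperature follows the salt/formamide-corrected formula", {
  cond0 <- hybridization_conditions(na_molar = 0.9, formamide_pct = 0)
  tm <- melting_temperature(strrep("AC", 10), cond0)  # 20-mer, 50% GC
  expect_equal(tm, 81.5 + 16.6 * log10(0.9) + 0.41 * 50 - 675 / 20,
               tolerance = 1e-10)
  expect_equal(round(tm, 2), 67.49)

  # 30% formamide depresses Tm by exactly 0.62 * 30 = 18.6 C
  cond30 <- hybridization_conditions(na_molar = 0.9, formamide_pct = 30)
  expect_equal(tm - melting_temperature(strrep("AC", 10), cond30), 18.6)

  # monotone in GC and in log[Na+]
  expect_gt(melting_temperature(strrep("GC", 10), cond0),
            melting_temperature(strrep("AT", 10), cond0))
  expect_gt(melting_temperature(strrep("AC", 10),
                                hybridization_conditions(1.2, 0)), tm)
  expect_error(melting_temperature(""), "zero-length")
})

test_that("gc_fraction and physical_properties agree", {
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(gc_fraction("GATC"), 0.5)
  p <- data.frame(sequence = "GATCGATCGA")
  pp <- physical_properties(p, hybridization_conditions(0.9, 0))
  expect_equal(pp$gc_fraction, 0.5)
  expect_equal(pp$tm_celsius, melting_temperature("GATCGATCGA",
                                                  hybridization_conditions(0.9, 0)))
})

test_that("anti-sense controls are reverse complements and cannot be chained", {
  probe <- data.frame(name = "p10", sequence = "TGTAATC", target_start = 10L,
                      target_end = 16L, length = 7L, gc = gc_fraction("TGTAATC"),
                      tm = 0, role = "sense", label = NA, region = NA)
  as_probe <- antisense_control(probe)
  expect_equal(as_probe$sequence, "GATTACA")
  expect_equal(as_probe$name, "AS-p10")
  expect_equal(as_probe$role, "antisense_control")
  expect_error(antisense_control(as_probe), "sense probes only")
  # involution check via role reset
  as_probe$role <- "sense"
  expect_equal(antisense_control(as_probe)$sequence, probe$sequence)
})

test_that("reverse complement is an involution", {
  set.seed(3)
  for (i in 1:50) {
    s <- random_dna(sample(5:40, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("enumerate_probes counts, constraints and ordering behave as specified", {
  # one clean 18-column region, length fixed at 18 -> exactly one probe
  set.seed(21)
  sense <- "GACTGACTGACTGACTGA"  # 50% GC
  ref <- paste0(strrep("A", 10), sense, strrep("A", 10))
  off <- ref
  substr(off, 15, 15) <- chartr("GACT", "AGTC", substr(ref, 15, 15))
  panel <- panel_from_seqs(c(t = ref, o = off), groups = c("target", "non_target"))
  regions <- data.frame(start = 11, end = 28)
  probes <- enumerate_probes(panel, regions, design_constraints(18, 18))
  expect_equal(nrow(probes), 1)
  expect_equal(probes$sequence, revcomp(sense))
  expect_equal(probes$target_start, 11)

  # GC window excludes an all-A region
  allA <- paste0(strrep("A", 40))
  offA <- allA; substr(offA, 20, 20) <- "G"
  panel2 <- panel_from_seqs(c(t = allA, o = offA), groups = c("target", "non_target"))
  probes2 <- enumerate_probes(panel2, data.frame(start = 10, end = 30),
                              design_constraints(18, 18, gc_min = 0.4, gc_max = 0.6))
  expect_equal(nrow(probes2), 0)

  # ... but passes with no GC constraint (homopolymer cap lifted too)
  probes3 <- enumerate_probes(panel2, data.frame(start = 10, end = 30),
                              design_constraints(18, 18, gc_min = 0, gc_max = 1,
                                                 max_homopolymer = 18))
  expect_gt(nrow(probes3), 0)
  expect_true(all(diff(probes3$target_start) >= 0))  # deterministic order
})

test_that("fixture-enumerated probes always cover a planted diagnostic SNP", {
  bundle <- make_validation_bundle(seed = 13)
  regions <- find_discriminative_regions(bundle$panel, 18, 1)
  probes <- enumerate_probes(bundle$panel, regions,
                             design_constraints(18, 18, gc_min = 0, gc_max = 1,
                                                max_homopolymer = 18),
                             prefix = "cand")
  expect_gt(nrow(probes), 0)
  planted <- bundle$truth$planted_sites$position
  for (i in seq_len(nrow(probes)))
    expect_true(any(planted >= probes$target_start[i] &
                    planted <= probes$target_end[i]))
})

test_that("designed sense probes have zero mismatches to every target sequence", {
  bundle <- make_validation_bundle(seed = 2)
  mat <- specificity_matrix(bundle$probes, bundle$panel)
  tgt <- mat[mat$group == "target", ]
  expect_true(all(tgt$n_mismatches == 0))
})

test_that("probe sets round-trip through TSV and FASTA", {
  bundle <- make_validation_bundle(seed = 4)
  tsv <- tempfile(fileext = ".tsv")
  write_probes(bundle$probes, tsv, "tsv")
  back <- read_probes(tsv)
  expect_equal(back$name, bundle$probes$name)
  expect_equal(back$sequence, bundle$probes$sequence)
  expect_equal(back$target_start, bundle$probes$target_start)
  fa <- tempfile(fileext = ".fa")
  write_probes(bundle$probes, fa, "fasta")
  ss <- Biostrings::readBStringSet(fa)
  expect_equal(as.character(ss[["syn185"]]), bundle$probes$sequence[1])
})
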