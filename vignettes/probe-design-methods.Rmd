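---
title: "Methods: mismatch-based design and validation of taxon-specific rRNA FISH probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mismatch-based design and validation of taxon-specific rRNA FISH probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probespectrum)
```

## Scope and model

`probespectrum` works entirely at the sequence level. Its model of
hybridization is deliberately minimal: a probe binds a sequence according to
the number of base mismatches between the probe's target-site sense pattern
and that sequence over the aligned site. Everything downstream — specificity
grades, spectrum calls, screening hits, rankings — derives deterministically
from those mismatch counts. The package does *not* model duplex
thermodynamics of individual mismatches, mismatch position effects, rRNA
secondary structure, or fluorophore photophysics; those belong to the wet-lab
validation step that this toolkit is designed to precede and to summarize.

The assumptions, stated explicitly:

1. **The alignment is trusted.** The panel is a pre-computed multiple
   alignment of SSU rDNA sequences; the package never re-aligns. Columns are
   treated as homologous positions.
2. **Hamming geometry.** Gaps at a site count as mismatches (tracked
   separately, with a strict mode available downstream since a gap may also
   reflect alignment uncertainty). Insertions in a non-reference sequence
   relative to the reference are invisible to a probe placed on the
   reference and are ignored.
3. **Minimum aggregation.** A taxon represented by several sequences is
   called by the *minimum* mismatch count across them — any matching strain
   can light up, so the most permissive call is the safe prediction.
4. **Conservative ambiguity handling.** An IUPAC ambiguity code in a panel
   sequence counts as a match only when its base set contains the expected
   base (so `R` matches an expected `A` or `G`, and `N` matches anything —
   i.e. an ambiguous position is assumed capable of binding).

## Coordinates and orientation

Probe coordinates are 1-based closed intervals on the **ungapped designated
reference** (by default the first target-group sequence). This matches the
field convention of naming probes by target-site start position. The
alternative — numbering against the *E. coli*/yeast small subunit as done
for canonical probes like Euk516 — is equally defensible; we chose the
target reference because the panel always contains it, whereas an external
numbering requires one more alignment. The accessibility module accepts an
integer offset precisely so that externally numbered brightness maps can
still be used.

Probes are stored 5'→3' in the orientation that hybridizes the rRNA, i.e.
as the reverse complement of the target-site sense sequence. All
comparisons (mismatch profiling and collection screening) are made between
the probe's sense pattern and subject residues read in rRNA sense
orientation: a screening hit at a window means the probe would hybridize
that window's transcript. Under this contract an anti-sense control probe —
the inverted-and-complemented oligo, identical in sequence to the rRNA
itself — screens against a sense-strand collection with no hits, which is
exactly the negative-control behavior it has at the bench.

## Discriminative columns and variable domains

A column is *discriminative* when (a) the target group is monomorphic there
(single base, no gap; a `target_tolerance` fraction of deviating target
records, default 0, can be allowed for noisy panels) and (b) at least one
off-target sequence (groups `non_target` and `outgroup` both count) differs.
The *discrimination margin* is the number of off-target sequences that
differ.

Variable domains are found by sliding a window (`window_length`, default
18 columns — the length of a typical rRNA probe) and keeping windows with at
least `min_discriminative` discriminative columns (default 1) and no
target-group gap; overlapping qualifying windows merge into maximal regions.
The published workflow this emulates reports only that polymorphic regions
were "retained", not how they were delimited, so the window/threshold
mechanism is this package's own declared operationalization — the defaults
are not inferred from the source study. The merge rule treats windows that
merely touch (distance exactly one window) as separate regions; only
genuinely overlapping windows merge.

Candidate enumeration additionally requires every emitted probe to cover at
least one discriminative column. A merged region can be wider than one
window, so without this requirement a sub-window of a long region could
contain no diagnostic site at all; requiring coverage keeps the guarantee
"every candidate probe interrogates a polymorphism" true by construction.

## Probe physical properties

* **GC fraction**: (G+C)/length.
* **Melting temperature** (°C): the empirical salt- and formamide-corrected
  formula `Tm = 81.5 + 16.6·log10[Na+] + 0.41·(%GC) − 675/L − 0.62·(%FA)`,
  with `[Na+]` in mol/L and formamide in percent v/v. Defaults are 0.9 M
  Na+ (≈ 5× SSC) and 30% formamide, the hybridization buffer of the
  motivating protocol. This formula is an ensemble approximation — it is
  used for *relative* ranking and sanity bounds, not as a quantitative
  prediction for 18-mers, which is one reason Tm is only the third ranking
  key.
* **Default design constraints**: length 18 nt (Euk516-like), GC between
  0.40 and 0.65, homopolymer runs ≤ 4. The source workflow states none of
  these; they are ordinary probe-design practice and fully overridable.

## Spectrum thresholds

Per-taxon calls use two thresholds: `positive_max` (default 0) and
`weak_max` (default 1), i.e. 0 mismatches → positive, 1 → weak,
≥ 2 → negative. The defaults encode the observed bench behavior that a
single SNP can still permit a faint signal (the weak off-target signal of a
probe one mismatch away from a non-target species), while two or more
mismatches reliably abolish binding at moderate stringency. The same
evidence also contains a 1-SNP case with *no* observable off-target signal,
so a single threshold set cannot reproduce both outcomes — mismatch
position and identity effects, which likely explain the difference, are
not modeled. Reports therefore treat `weak` as "at risk of cross-reaction",
not as a guaranteed signal, and the thresholds are configurable.

Raising `positive_max` can only grow the predicted-positive set
(monotonicity), which is enforced by property tests.

## Screening

`screen_collection()` is exhaustive: every length-L window of every subject
is compared to the probe's sense pattern and reported when the Hamming
distance is at most `max_mismatches`. At SSU scale (a few kb per subject,
dozens of subjects) exhaustive scanning is fast, fully deterministic, and
trivially checkable against a brute-force oracle — properties that seeded
heuristic search (the BLAST-style approach it replaces) does not have. The
stringency bound must be strictly below the probe length; at the bound
`max_mismatches = L` every window of every subject would qualify, which is
a degenerate query rejected as an input error.

## Accessibility

Empirical brightness-class maps (classes I–VI, I brightest) assign each
rRNA region a category describing how well probes there hybridize in fixed
cells. The package consumes such maps as plain interval TSVs on the map's
own reference; the shipped example map is synthetic (filename and header
say so) because the published class boundaries are data of their source
publication, not of this package. Scoring follows a worst-class-governs
rule — the darkest class overlapped by the site is the headline score,
since a probe partially in a closed region is compromised — with the mean
class rank as a tiebreaker. How accessibility should be weighed against
mismatch counts is not specified by the emulated workflow; the default
ranking therefore uses accessibility only lexicographically after
specificity, and a weighted scalar mode exists for exploration.

## Ranking

The default ranking is lexicographic: descending minimum off-target
distance, then ascending worst accessibility class (unknown after known),
then |Tm − target|, then name. A lexicographic order was chosen over a
weighted score because no weighting is given by the emulated selection
procedure; the final tiebreak by name makes the order total and
permutation-invariant. The `specific` badge marks probes with at least one
mismatch to every off-target sequence.

## Survey tabulation

Detection tables (site × species, samples analyzed vs PCR-positive) are
summarized with percentages rounded **half-up** to integers — the
convention that reproduces every published value in the motivating survey
(e.g. 5/30 → 16.7 → 17, 3/7 → 42.9 → 43), where banker's rounding would
not. Zero-analyzed groups report `NA`, never 0%. The packaged fixture
transcribes the published survey counts; two per-species analyzed counts
that the source text reports inconsistently were reconciled from its
family-level sample counts (noted in the fixture header), and per-site
"other_species" filler rows (all negative) complete the printed site
totals.

## The synthetic panel generator

`simulate_panel()` emits a gapless (optionally gapped) alignment built from
one random reference: a monomorphic target clade plus non-target clades
that differ at *planted* diagnostic sites (exact per-clade base
assignments) and, optionally, at i.i.d. background substitutions outside
the planted sites. Background substitutions are drawn per clade — clade
members are identical — with no phylogenetic correlation; this is
sufficient to test discrimination logic, which only sees columns, but it
does **not** emulate rate heterogeneity along the molecule, covariation
imposed by secondary structure, within-clade polymorphism, or alignment
error. Passing tests on synthetic panels therefore demonstrates algorithmic
correctness (the code finds exactly what was planted), not robustness to
misalignment or to intragenomic rRNA variation in real data.

The generator self-checks at generation time: the emitted panel is
re-examined to confirm the target is monomorphic at every planted site and
each assigned clade carries its alternative base.

`make_validation_bundle()` instantiates the study-like conditions used for
end-to-end validation: 3 target sequences, four relative clades and two
outgroup clades of 2 sequences each (15 sequences, 1800 nt — the scale of
an SSU design panel), background divergence 0, and four planted 18-nt
regions at positions 185/645/1313/1647 whose probes have planted per-clade
mismatch structure mirroring the motivating probe set: floors of 1 (at
least one SNP to everything), 0 (pan-genus, matching all relatives), 0 with
a single-SNP neighbor (exact match to one relative, one SNP to another) and
3 (species-specific). Background divergence is 0 in this preset because SSU
sequences within the emulated genus are exceptionally conserved — the
divergence that exists is concentrated in the variable domains — and
because it makes "exactly the four planted regions are recovered" a sharp,
assertable truth.

## Numerical and degenerate-input choices

* Coordinates: 1-based, closed, everywhere; gapped↔ungapped maps are
  strictly increasing and round-trip exactly.
* RNA input (`U`) is normalized to DNA (`T`) at ingestion; probes are
  synthesized as DNA.
* All-gap records yield an empty coordinate map plus a warning, not an
  error.
* Ragged alignments, unknown metadata ids, duplicate metadata rows,
  overlapping accessibility intervals and positive>analyzed count rows are
  hard errors naming the offending record.
* Empty results (no qualifying windows, no probes passing constraints, no
  screening hits, empty detection tables) are empty tables, not errors.
* CLI outputs carry `#` metadata headers without timestamps, so identical
  configurations give byte-identical files; exit codes are 2 for usage
  errors and 1 for validation failures.

## Problem sizes used by the test suite

The properties are exercised at sizes chosen to finish comfortably on one
CPU while covering the regime the tool targets: region discovery is checked
against a brute-force enumeration oracle on 100 random panels (mostly
4–20 sequences × 60–300 columns, periodically up to 50 × 2000); screening
against a naive double-loop Hamming oracle on 50 random probe/subject pairs
(subjects up to 600 nt); coordinate-map round trips on 200 random gapped
records; and the full pipeline end to end on the 15 × 1800 synthetic
bundle, including a byte-identical comparison of the predicted spectrum
table against the truth-derived expectation.

## Known limitations

* No mismatch-position or nearest-neighbor thermodynamic modeling — two
  probes with identical mismatch counts can behave differently at the
  bench, as the motivating probe set itself shows.
* No secondary-structure-aware accessibility prediction; the accessibility
  module only transfers a user-supplied empirical map.
* The alignment is an input; errors in it propagate directly into
  discriminative-column calls.
* Signal intensity is out of scope: a predicted `positive` says a perfect
  duplex can form, not how bright it will be.
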