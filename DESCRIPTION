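Package: probespectrum
Title: Design and In-Silico Specificity Screening of Taxon-Specific rRNA FISH Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs taxon-specific oligonucleotide probes for fluorescence in
    situ hybridization (FISH) against small-subunit (SSU/18S) rRNA alignments
    and predicts their hybridization specificity spectra by exhaustive mismatch
    analysis. Profiles alignment columns by taxon group to locate variable
    domains carrying diagnostic polymorphisms, enumerates candidate probes with
    salt- and formamide-corrected melting temperatures, computes per-sequence
    mismatch profiles and minimum off-target distances, predicts per-taxon
    hybridization calls (positive/weak/negative), scores probe target-site
    accessibility against a brightness-class map, ranks candidates, tabulates
    detection survey tables, and generates synthetic SSU-like panels with
    planted diagnostic SNPs for validation. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
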