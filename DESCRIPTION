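Package: colligator
Title: Triple Colligation of Small RNA Abundance, Hairpin Structure and
    3'UTR Complementarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering candidate regulatory small RNAs
    processed from noncoding RNAs. Small-RNA sequencing reads are adapter-
    and poly-A-trimmed, collapsed to exact copies and clustered into shared
    "core sequences"; a permutation null quantifies how unexpected the
    absence of shuffled variants of a core is; noncoding RNAs are scanned
    for stable stem-loop hairpins scored with a nearest-neighbour free
    energy model, the stability ratio -dG/L and the minimal folding free
    energy index (MFEI); 3'UTRs are scanned for maximal exact
    reverse-complement target sites of each core; and the three evidence
    streams are joined through ribonucleoprotein complex annotations into
    "triple colligation" records. Includes a synthetic-data generator with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
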