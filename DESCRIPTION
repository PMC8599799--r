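Package: footprintr
Title: Predict RNA-Protein Footprints and PolyA Sites from Orthogonal In-Cell RNA Structure Probing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns paired treatment/control reverse-transcription stop counts from
    in-cell RNA chemical probing (a flexibility probe and a solvent-accessibility
    probe) into normalized per-nucleotide reactivity profiles, and uses windows of
    those profiles to predict RNA-binding-protein occupancy at motif sites and
    polyadenylation-signal usage with a support-vector-machine harness evaluated by
    ROC/AUC. Includes in-vivo-minus-in-vitro difference (VTD) summaries, hexamer
    and anchor-aligned metaprofiles, a polyA-site caller for 3'-end sequencing
    read pileups, and a fully seeded synthetic-experiment generator that emulates
    probing reads, protein footprints, peak annotations and polyA-site reads for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    e1071,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
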