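Package: hacseq
Title: Single-Nucleotide m3C Site Calling from Hydrazine-Aniline Cleavage Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 3-methylcytidine (m3C) RNA modification sites at
    single-nucleotide resolution from three-arm hydrazine-aniline cleavage
    sequencing (HAC-seq) libraries. Converts transcriptome alignments into
    per-position read-start and read-depth profiles, computes cleavage
    ratios, and applies a three-criterion calling procedure contrasting
    untreated (Ctrl), cleaved (HAC) and demethylated-then-cleaved (DM-HAC)
    arms with replicate statistics. Includes a generative simulator of the
    cleavage chemistry (fragmentation, 5'-fragment loss, demethylase arms)
    so the pipeline can be validated against planted ground truth, plus
    motif-window extraction and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
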