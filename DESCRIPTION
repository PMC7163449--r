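Package: crisprAllele
Title: Allele-Specific CRISPR Target Discovery and Editing-Outcome Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether single-nucleotide variants can be
    targeted allele-specifically by CRISPR nucleases (SpCas9, SaCas9, LbCpf1
    or user-defined enzymes), based on PAM and seed-window membership on
    either strand of the mutant allele. Includes a mutation-catalog scanner
    that reports per-gene editability statistics, an amplicon deep-sequencing
    profiler that classifies per-read editing outcomes (insertion, deletion,
    substitution, combination) into type/length/position spectra, a
    mismatch-based off-target site enumerator with treated/control variant
    background subtraction and frameshift annotation, and seeded synthetic
    data generators with independently computed ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
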