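Package: crisprad
Title: Design Toolkit for Bacterial CRISPRa Promoters, Target Sites and Scaffold RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing bacterial CRISPR activation (CRISPRa)
    experiments. Generates PAM-periodic synthetic promoter tiling arrays
    from a repeating base unit under GC-content, homopolymer,
    transcription-factor-binding-site and genome-homology constraints;
    scans promoters for SpCas9 NGG target sites and scores them against
    empirically determined TSS distance windows for activation; assembles
    guide RNA and scaffold RNA (MS2/PP7 aptamer) constructs; and provides
    the standard reporter-assay quantification formulas (Miller units,
    delta-delta-Ct fold change, OD-normalized fluorescence, ethanol yield)
    together with the linker/B-DNA geometry arithmetic used to reason
    about activator reach.
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
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
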