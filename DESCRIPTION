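Package: hmcall
Title: Joint 5mC and 5hmC Methylome Analysis from Paired BS/oxBS RRBS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint profiling of 5-methylcytosine (5mC) and
    5-hydroxymethylcytosine (5hmC) from paired bisulfite (BS) and oxidative
    bisulfite (oxBS) reduced representation bisulfite sequencing (RRBS)
    libraries. Reads and writes Bismark coverage files, infers per-CpG 5hmC
    by count subtraction with integer-count reconstruction, calls
    differentially methylated cytosines between sample groups with a pooled
    exact test or a replicate-aware binomial likelihood-ratio test under a
    percent-change plus FDR filter, and quantifies annotation-class
    enrichment of differentially methylated sites with an odds ratio and a
    one-sided hypergeometric test. Includes a calibrated simulator of paired
    BS/oxBS coverage with known per-site ground truth for validation, and an
    end-to-end pipeline driver with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
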