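Package: kprobe
Title: Reference-Free Quantification and Calling of RNA Events from
    k-mer Count Indexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds multi-sample k-mer count indexes from RNA-seq reads,
    compressing runs of adjacent k-mers that share a per-sample count
    vector into monotigs, and queries them with engineered probe
    sequences to quantify and call arbitrary RNA events without a
    reference alignment: point mutations and indels (paired
    mutant/wildtype probes centered on the variant), fusion and
    neo-splicing junctions (short probes centered on the breakpoint),
    and full transcripts.  Includes probe design from variant and
    junction tables, unicity and low-complexity masking of
    non-specific k-mers, weighted count aggregation (mean, median,
    sum, max) with presence-threshold star marking, k-mer-based
    variant allele frequency estimation, min-hits event calling with
    precision/recall evaluation against a truth set, and a
    deterministic synthetic-cohort simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
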