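Package: hmcquant
Title: Quantification and Comparative Analysis of 5-Hydroxymethylcytosine
    from Paired Bisulfite and Oxidative-Bisulfite Methylation Arrays
Version: 0.9.0
Authors@R:
    person("Exeter", "Epigenomics Tools", email = "tools@example.org",
           role = c("aut", "cre"))
Description: Estimates 5-hydroxymethylcytosine (5hmC) from paired
    bisulfite (BS) and oxidative-bisulfite (oxBS) Illumina-450K-style
    beta-value matrices.  Implements detection-p and SNP/cross-reactive
    probe filtering, the BS-minus-oxBS delta-beta statistic with an
    empirical negative-tail detection threshold, tissue-specific and
    variable-site ranking, Fisher's-exact genomic-feature enrichment with
    Woolf confidence intervals, logistic-regression gene-set testing with
    probe-count confounder control and redundancy grouping, canonical
    metagene sliding-window profiles, BED track export, and a fully
    parameterised synthetic-data generator with known per-probe truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
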