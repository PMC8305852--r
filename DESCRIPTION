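Package: dhblocks
Title: Parental-Origin Block Calling and Co-Segregation Analysis for
    Doubled-Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers parental-origin recombinant blocks in biparental
    doubled-haploid (DH) populations from multi-sample variant calls, using
    parent-informative marker extraction, a three-state hidden Markov model
    with Viterbi decoding, and small-block merging.  Projects blocks onto
    gene annotations to discover genomic regions and genes whose parental
    origin perfectly co-segregates with a binary phenotype grouping, and
    computes the metabolite-table statistics (totals, component fractions,
    fold enrichments, one-way ANOVA with compact letter displays) used to
    define high- and low-glucosinolate phenotype groups in Brassica rapa.
    Includes a synthetic-data generator for biparental DH populations with
    known ground truth, so the whole inference chain is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
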