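Package: spongenet
Title: Integrated lncRNA-miRNA-mRNA Differential Expression and ceRNA
    Sponge Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for inferring competing endogenous RNA
    (ceRNA, "sponge") regulation from two-group transcriptomic experiments.
    Provides quantile normalization and Student's t differential expression
    for microarray intensities, a common-dispersion negative-binomial exact
    test for small-RNA read counts, genomic-context classification of long
    non-coding RNAs (intergenic, natural antisense, intronic antisense) with
    proximity- and antisense-based lncRNA-mRNA candidate pairing,
    co-expression concordance and disease-annotation filters, construction
    of bidirectional DE-gated lncRNA-miRNA-mRNA sponge triads and their
    tripartite network, hypergeometric over-representation analysis, and
    Kruskal-Wallis/Dunn validation statistics. A synthetic-data generator
    with planted truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    rtracklayer,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
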