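Package: phylosel
Title: Selective-Pressure Estimation and Pathway-Topology Association for
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of selective pressure (omega = dN/dS)
    on protein-coding genes under Goldman-Yang-style codon substitution models,
    including the one-ratio model M0, the site-class models M1a/M2a and M7/M8,
    and branch-site model A with foreground-branch tagging.  Provides likelihood
    ratio tests of positive selection with multiple-testing correction, Bayes
    Empirical Bayes identification of selected codon sites, centrality analysis
    of curated pathway interaction networks, and nonparametric association of
    evolutionary rates with network topology and functional gene classifications.
    Ships a forward codon-sequence simulator and a synthetic study generator for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
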