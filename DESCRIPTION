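Package: dtlroot
Title: Species-Tree Rooting by Duplication-Transfer-Loss Reconciliation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Roots species trees by gene-tree/species-tree reconciliation
    under an undated duplication-transfer-loss (DTL) model. Implements the
    reconciliation likelihood with free or ratio-constrained transfer and
    duplication rates, exhaustive scanning of all candidate root branches,
    approximately unbiased (AU) root tests via multiscale bootstrap of
    per-family log-likelihoods, loss:gain genome-flux diagnostics, and a
    block-ranked power analysis relating duplication rates to rooting
    precision. Includes a birth-death-transfer simulator of gene families
    along a dated species tree with ground-truth event counts, covering
    transfer-dominated (bacteria-like) and duplication-rich (eukaryote-like)
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phytools,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
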