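Package: pseudogeneKit
Title: Detection, Dating and Selection Analysis of Gene Loss on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying the decay of protein-coding genes on a
    phylogeny. Detects and classifies inactivating mutations (frameshift
    indels, premature stop codons, start/stop codon mutations, splice-site
    mutations, exon losses) from codon-aware alignments, maps shared lesions
    to branches by delayed-transformation parsimony, computes percent-intact
    reading frames and screens for convergent gene losses with a
    phylogenetically corrected association test, estimates branch-category
    dN/dS under a GY94 codon substitution model by maximum likelihood, and
    dates gene inactivation on transitional branches from mixture dN/dS
    equations. Includes a GY94 codon-alignment simulator with within-branch
    selection switches and lesion injection so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
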