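Package: mycocub
Title: Codon Usage Bias Analysis of Mycoviral Coding Sequences and Their Hosts
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying codon usage bias (CUB) in viral coding
    sequences and comparing it with host gene repertoires. Implements CDS
    validation against standard inclusion criteria, nucleotide and positional
    GC composition (GC1/GC2/GC3/GC12, GC3s), relative synonymous codon usage
    (RSCU), Wright's effective number of codons (ENc) with the expected
    ENc-GC3s curve, Parity Rule 2 and neutrality-plot diagnostics of mutation
    versus selection, relative dinucleotide abundance (rho), joint virus-host
    RSCU principal component analysis with circle-based selection of host
    genes sharing viral codon usage, hypergeometric GO-term enrichment of the
    selected genes, and a synthetic CDS generator with controllable GC3,
    within-family bias strength, and CpG depletion for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
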