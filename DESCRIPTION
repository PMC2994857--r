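Package: unigenicEoS
Title: Evidence of Selection from Unigenic Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Site-wise Bayesian analysis of unigenic evolution (saturating
    mutagenesis plus functional selection) experiments. Tabulates nucleotide
    misincorporation and codon mutation counts from wild-type and clone
    sequences, estimates mutagenic-PCR mutation frequencies under either a
    Dirichlet-multinomial null or a mechanistic error-prone polymerase model
    (Jeffreys prior from the Fisher information, maximum a posteriori fit,
    Metropolis posterior sampling), lifts nucleotide frequencies to codon
    synonymous/nonsynonymous mutation probabilities through a Kronecker
    operator under any NCBI genetic code, and scores each codon site with an
    Evidence-of-Selection expected log-odds-ratio together with
    Kullback-Leibler reliability (power) estimates. Includes a synthetic
    clone-population generator with known mutation and selection structure
    and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
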