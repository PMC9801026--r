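Package: kaksr
Title: Selective Pressure on Coding and Non-Coding Sequences (Ka/Ks and Kn/Ks)
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pairwise estimation of selective pressure on molecular sequences.
    For protein-coding alignments it implements seven approximate
    nonsynonymous/synonymous rate-ratio (Ka/Ks) estimators (NG, LWL, LPB,
    MLWL, MLPB, YN, MYN) and a maximum-likelihood family based on the
    Goldman-Yang codon model, including information-criterion model selection
    (MS) and Akaike-weight model averaging (MA) over fourteen nucleotide
    exchangeability structures. For non-coding alignments it computes the
    substitution rate Kn under JC69, K2P, or HKY85 multiple-hit corrections
    and the selection statistic xi = Kn/Ks, taking the neutral rate Ks from
    an adjacent coding alignment or from a user-supplied value. Includes an
    exact matrix-exponential sequence-pair simulator for parameter-recovery
    testing, readers for AXT paired-block and aligned-FASTA input, and a
    command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
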