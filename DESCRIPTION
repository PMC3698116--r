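Package: biocode
Title: Biologically Compatible Embedding of Binary Data in DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codecs for embedding binary messages in DNA sequences under
    biological constraints.  The non-coding codec writes bits into a base
    sequence while guaranteeing that no start codon appears in any of the six
    reading frames; the protein-coding codecs rewrite synonymous codons so that
    the translated protein (and, in the codon-count-preserving variant, the
    exact codon histogram) of the host gene is unchanged.  Both are driven by
    graduated prefix-free bit-to-symbol codebooks that are rebuilt dynamically
    as symbols are exhausted.  The package also provides a cascaded Kimura
    substitution-mutation channel, marker- and watermark-code bitframe
    resynchronisation, closed-form and Markov-chain embedding-rate analyses,
    and a Monte-Carlo harness measuring bit-error probability and empirical
    mutual information across generations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
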