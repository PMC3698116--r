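# Synthetic sequence generators.  All tests and simulations run on generated
# hosts, so no downloads are needed; codon bias and amino-acid composition
# are controllable to emulate genes of differing redundancy.

#' Random DNA sequence
#'
#' @param n Length in bases.
#' @param seed Optional integer seed.
#' @param weights Optional base probabilities, in A/C/T/G order.
#' @return DNA string.
#' @export
random_dna <- function(n, seed = NULL, weights = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  paste(sample(DNA_BASES, n, replace = TRUE, prob = weights), collapse = "")
}

#' Random codon sequence with direct codon weights
#'
#' Draws codons i.i.d. from a distribution over all 64 codons (uniform by
#' default, the regime in which the static codec attains its 1.75 bits/codon
#' table rate).
#'
#' @param n Number of codons.
#' @param weights Optional named weights over the 64 codons.
#' @param seed Optional integer seed.
#' @return Character vector of codons.
#' @export
random_codons <- function(n, weights = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  codons <- names(GENETIC_CODE_3L)
  if (!is.null(weights)) {
    weights <- weights[codons]
    if (anyNA(weights)) stop("weights must be named by the 64 codons")
  }
  sample(codons, n, replace = TRUE, prob = weights)
}

#' Generate a synthetic coding sequence
#'
#' Draws an amino acid per position from a composition distribution, then a
#' codon within the amino acid's synonymous set from a bias distribution.
#' This emulates genes with arbitrary codon usage bias; internal stops are
#' excluded unless requested.
#'
#' @param n_codons Gene length in codons.
#' @param aa_weights `"uniform"` (default, over the 20 amino acids) or a
#'   named non-negative vector over amino-acid labels.
#' @param codon_bias `"uniform"` (default) or a named non-negative vector of
#'   per-codon weights applied within each synonymous set.
#' @param include_stops If `TRUE`, `"Stp"` joins the amino-acid alphabet.
#' @param seed Optional integer seed.
#' @return Character vector of codons.
#' @examples
#' generate_synthetic_cds(5, seed = 1)
#' @export
generate_synthetic_cds <- function(n_codons, aa_weights = "uniform",
                                   codon_bias = "uniform",
                                   include_stops = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  alphabet <- if (include_stops) AMINO_ACIDS else setdiff(AMINO_ACIDS, "Stp")
  if (identical(aa_weights, "uniform")) {
    aw <- stats::setNames(rep(1, length(alphabet)), alphabet)
  } else {
    aw <- aa_weights[alphabet]
    aw[is.na(aw)] <- 0
    names(aw) <- alphabet
  }
  if (any(aw < 0) || sum(aw) <= 0) stop("degenerate amino-acid weights")
  aas <- sample(alphabet, n_codons, replace = TRUE, prob = aw)
  vapply(aas, function(a) {
    s <- SYNONYMOUS_SETS[[a]]
    if (identical(codon_bias, "uniform")) {
      w <- rep(1, length(s))
    } else {
      w <- codon_bias[s]
      w[is.na(w)] <- 0
      if (sum(w) <= 0) stop("degenerate codon-bias weights for ", a)
    }
    sample(s, 1L, prob = w)
  }, character(1L), USE.NAMES = FALSE)
}
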