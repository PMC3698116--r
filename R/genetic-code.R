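# Static biological tables: the standard (near-universal) genetic code,
# synonymous codon sets, start-codon policies and strand complements.

DNA_BASES <- c("A", "C", "T", "G")

# Standard genetic code, codons in alphabetical order (A < C < G < T).
# "Stp" is carried as a 21st amino-acid label so that stop codons form an
# ordinary synonymous class of size 3.
GENETIC_CODE_3L <- c(
  AAA = "Lys", AAC = "Asn", AAG = "Lys", AAT = "Asn", ACA = "Thr", ACC = "Thr",
  ACG = "Thr", ACT = "Thr", AGA = "Arg", AGC = "Ser", AGG = "Arg", AGT = "Ser",
  ATA = "Ile", ATC = "Ile", ATG = "Met", ATT = "Ile", CAA = "Gln", CAC = "His",
  CAG = "Gln", CAT = "His", CCA = "Pro", CCC = "Pro", CCG = "Pro", CCT = "Pro",
  CGA = "Arg", CGC = "Arg", CGG = "Arg", CGT = "Arg", CTA = "Leu", CTC = "Leu",
  CTG = "Leu", CTT = "Leu", GAA = "Glu", GAC = "Asp", GAG = "Glu", GAT = "Asp",
  GCA = "Ala", GCC = "Ala", GCG = "Ala", GCT = "Ala", GGA = "Gly", GGC = "Gly",
  GGG = "Gly", GGT = "Gly", GTA = "Val", GTC = "Val", GTG = "Val", GTT = "Val",
  TAA = "Stp", TAC = "Tyr", TAG = "Stp", TAT = "Tyr", TCA = "Ser", TCC = "Ser",
  TCG = "Ser", TCT = "Ser", TGA = "Stp", TGC = "Cys", TGG = "Trp", TGT = "Cys",
  TTA = "Leu", TTC = "Phe", TTG = "Leu", TTT = "Phe"
)

AMINO_ACIDS <- sort(unique(unname(GENETIC_CODE_3L)))

# Synonymous codon sets in canonical (alphabetical) order; the canonical
# order doubles as the identity secret key.
SYNONYMOUS_SETS <- split(names(GENETIC_CODE_3L), GENETIC_CODE_3L)

#' Load a genetic code from a two-column text file
#'
#' Optional override of the built-in standard code.  The file must contain one
#' codon and one amino-acid label per line, whitespace-separated, for all 64
#' codons.
#'
#' @param path Path to a plain-text two-column file.
#' @return Named character vector mapping the 64 codons to amino-acid labels.
#' @export
read_genetic_code <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("codon", "aa"))
  codons <- toupper(tab$codon)
  if (length(codons) != 64L || anyDuplicated(codons) ||
      !all(sort(codons) == names(GENETIC_CODE_3L))) {
    stop("genetic code file must define all 64 codons exactly once")
  }
  stats::setNames(tab$aa, codons)[names(GENETIC_CODE_3L)]
}

split_codons <- function(x) {
  if (length(x) == 1L && nchar(x) > 3L) {
    n <- nchar(x)
    if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
    x <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  }
  x <- toupper(x)
  if (any(nchar(x) != 3L)) stop("codons must be base triplets")
  x
}

#' Translate codons to amino acids
#'
#' Applies the standard genetic code elementwise.  Stop codons translate to
#' the label `"Stp"`.
#'
#' @param codons Character vector of base triplets, or a single in-frame DNA
#'   string whose length is a multiple of 3.
#' @return Character vector of three-letter amino-acid labels.
#' @examples
#' translate_codons(c("ATG", "GGA", "TAA"))
#' @export
translate_codons <- function(codons) {
  codons <- split_codons(codons)
  aa <- unname(GENETIC_CODE_3L[codons])
  if (anyNA(aa)) {
    bad <- codons[is.na(aa)][1L]
    stop(sprintf("invalid codon '%s': alphabet must be A/C/G/T", bad))
  }
  aa
}

#' Synonymous codon set of an amino acid
#'
#' @param aa Three-letter amino-acid label (including `"Stp"`).
#' @return Character vector of codons in canonical (alphabetical) order.
#' @examples
#' synonymous_codons("Gly")
#' @export
synonymous_codons <- function(aa) {
  if (length(aa) != 1L || !aa %in% AMINO_ACIDS) {
    stop(sprintf("unknown amino-acid label '%s'", paste(aa, collapse = ",")))
  }
  SYNONYMOUS_SETS[[aa]]
}

#' Reverse complement of a DNA sequence
#'
#' @param s A DNA string over A/C/G/T (the empty string is allowed).
#' @return The Watson-Crick reverse complement.
#' @examples
#' reverse_complement("ATG") # "CAT"
#' @export
reverse_complement <- function(s) {
  if (length(s) != 1L) stop("'s' must be a single string")
  if (nchar(s) == 0L) return(s)
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[v]
  if (anyNA(comp)) stop("invalid symbol: alphabet must be A/C/G/T")
  paste(rev(unname(comp)), collapse = "")
}

#' Start-codon policy
#'
#' Defines which triplets count as translation starts on the sense strand,
#' derives the antisense triplets (their reverse complements read on the same
#' strand) and the set of special duplets that prefix either; those duplets
#' are the states in which the non-coding codec must restrict its next base.
#'
#' @param organism Either `"eukaryote"` (starts ATG, CTG, TTG; the default) or
#'   `"prokaryote-minimal"` (ATG only).
#' @return An object of class `start_codon_policy` with elements
#'   `sense_starts`, `antisense_triplets`, `duplets` and `restricted`, the
#'   per-duplet allowed base sets in the codec's table order (A, T, C, G).
#' @examples
#' start_codon_policy()$duplets
#' @export
start_codon_policy <- function(organism = c("eukaryote", "prokaryote-minimal")) {
  organism <- match.arg(organism)
  sense <- if (organism == "eukaryote") c("ATG", "CTG", "TTG") else "ATG"
  anti <- vapply(sense, reverse_complement, character(1L), USE.NAMES = FALSE)
  forbidden <- c(sense, anti)
  duplets <- unique(substr(forbidden, 1L, 2L))
  base_order <- c("A", "T", "C", "G") # ordering of the codec's lookup table
  restricted <- lapply(duplets, function(d) {
    base_order[!paste0(d, base_order) %in% forbidden]
  })
  names(restricted) <- duplets
  structure(
    list(organism = organism, sense_starts = sense,
         antisense_triplets = anti, duplets = duplets,
         restricted = restricted, base_order = base_order),
    class = "start_codon_policy"
  )
}

#' @export
print.start_codon_policy <- function(x, ...) {
  cat("Start-codon policy (", x$organism, ")\n", sep = "")
  cat("  sense starts:      ", paste(x$sense_starts, collapse = " "), "\n")
  cat("  antisense triplets:", paste(x$antisense_triplets, collapse = " "), "\n")
  cat("  restricted duplets:", paste(x$duplets, collapse = " "), "\n")
  invisible(x)
}

#' Locate start-codon triplets in a sequence
#'
#' Scans every consecutive base triplet of `s` for sense starts and antisense
#' start triplets under `policy`.  Because any reading frame's start codon on
#' either strand is some length-3 substring of `s`, an empty result certifies
#' all six frames clean.
#'
#' @param s DNA string.
#' @param policy A [start_codon_policy()].
#' @return Zero-based start positions of offending triplets (integer vector).
#' @examples
#' find_start_codons("GGATGG") # 2L
#' @export
find_start_codons <- function(s, policy = start_codon_policy()) {
  n <- nchar(s)
  if (n < 3L) return(integer(0L))
  triplets <- substring(s, 1:(n - 2L), 3:n)
  which(triplets %in% c(policy$sense_starts, policy$antisense_triplets)) - 1L
}
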