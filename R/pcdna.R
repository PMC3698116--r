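# Protein-coding codecs.  Both rewrite a host gene codon-by-codon so that the
# translated amino-acid sequence is untouched.  The static codec (BCE) draws
# replacement codons from the full synonymous set of each amino acid; the
# dynamic codec additionally preserves the exact codon histogram of the host
# by giving every codon a usage budget equal to its original count and
# rebuilding the per-amino-acid codebooks as budgets run out.

.bce_cache <- new.env(parent = emptyenv())

# Static per-amino-acid codebooks over canonical synonymous sets; the
# identity-key tables are cached.
bce_tables <- function(key = NULL) {
  if (is.null(key) && !is.null(.bce_cache$tables)) return(.bce_cache$tables)
  cbs <- lapply(AMINO_ACIDS, function(a) {
    build_codebook(keyed_symbols(SYNONYMOUS_SETS[[a]], key, a))
  })
  names(cbs) <- AMINO_ACIDS
  if (is.null(key)) .bce_cache$tables <- cbs
  cbs
}

#' Embed bits by static synonymous-codon substitution (BCE)
#'
#' Replaces each host codon with a message-selected synonymous codon from the
#' full static lookup table.  Amino acids with a single codon (Met, Trp) copy
#' the forced codon and carry no bits.  The output always translates to the
#' same protein as the input.
#'
#' @param bits Integer 0/1 message vector; zero-padded if the gene can hold
#'   more (the true length travels out-of-band).
#' @param codons Host coding sequence: a character vector of codons or one
#'   in-frame DNA string (length a multiple of 3).
#' @param key Optional integer secret key permuting each synonymous set.
#' @return List with `codons` (encoded sequence), `bits_embedded` (message
#'   bits consumed, excluding padding) and `n_codons`.
#' @examples
#' bce_encode(c(0L, 1L), "GGATGG")$codons # "GGC" "TGG"
#' @export
bce_encode <- function(bits, codons, key = NULL) {
  stopifnot(all(bits %in% c(0L, 1L)))
  bits <- as.integer(bits)
  codons <- split_codons(codons)
  aas <- translate_codons(codons)
  cbs <- bce_tables(key)
  nb <- length(bits)
  out <- character(length(codons))
  i <- 1L
  for (j in seq_along(codons)) {
    cb <- cbs[[aas[j]]]
    if (cb$mu == 1L) {
      out[j] <- cb$symbols[1L]
    } else {
      p <- bit_pattern(bits, i, cb$l + 1L)
      k <- cb$pat_sym[p + 1L]
      out[j] <- cb$symbols[k]
      i <- i + cb$pat_len[p + 1L]
    }
  }
  list(codons = out, bits_embedded = min(i - 1L, nb),
       n_codons = length(codons))
}

#' Decode bits from a BCE-encoded sequence
#'
#' Emits, for every codon, its codeword within the static synonymous table of
#' its own amino acid.  Every codon is decodable, so mutations surface as bit
#' errors rather than failures.
#'
#' @param codons Received coding sequence (codon vector or in-frame string).
#' @param nbits Optional true message length for truncating padding.
#' @inheritParams bce_encode
#' @return Integer 0/1 vector.
#' @export
bce_decode <- function(codons, nbits = NULL, key = NULL) {
  codons <- split_codons(codons)
  aas <- translate_codons(codons)
  cbs <- bce_tables(key)
  bits <- integer(3L * length(codons))
  nb <- 0L
  for (j in seq_along(codons)) {
    cb <- cbs[[aas[j]]]
    k <- match(codons[j], cb$symbols)
    w <- cb$codewords[k]
    wl <- nchar(w)
    if (wl > 0L) {
      bits[nb + seq_len(wl)] <- as.integer(strsplit(w, "", fixed = TRUE)[[1L]])
      nb <- nb + wl
    }
  }
  bits <- bits[seq_len(nb)]
  if (!is.null(nbits)) bits <- bits[seq_len(min(nbits, length(bits)))]
  bits
}

#' Initialise dynamic codec state from a reference gene
#'
#' Builds, for every amino acid, the synonymous set restricted to codon types
#' actually present in the reference, the matching graduated codebook, and
#' the codon budget vector (the exact histogram of the reference).
#'
#' @param reference Codon vector or in-frame DNA string.
#' @inheritParams bce_encode
#' @return An environment of class `pcdna_state` with fields `sets`, `books`
#'   and `counts`.
#' @export
pcdna_init_state <- function(reference, key = NULL) {
  codons <- split_codons(reference)
  aas <- translate_codons(codons)
  counts <- table(codons)
  st <- new.env(parent = emptyenv())
  st$counts <- stats::setNames(as.integer(counts), names(counts))
  st$sets <- lapply(AMINO_ACIDS, function(a) {
    intersect(SYNONYMOUS_SETS[[a]], names(counts)) # canonical order kept
  })
  names(st$sets) <- AMINO_ACIDS
  st$key <- key
  st$books <- lapply(AMINO_ACIDS, function(a) {
    s <- st$sets[[a]]
    if (length(s) == 0L) NULL else build_codebook(keyed_symbols(s, key, a))
  })
  names(st$books) <- AMINO_ACIDS
  class(st) <- "pcdna_state"
  st
}

# Consume one codon's budget; rebuild the amino acid's codebook when a codon
# type is exhausted.
pcdna_spend <- function(st, aa, codon) {
  st$counts[[codon]] <- st$counts[[codon]] - 1L
  if (st$counts[[codon]] == 0L) {
    st$sets[[aa]] <- setdiff(st$sets[[aa]], codon)
    s <- st$sets[[aa]]
    st$books[[aa]] <- if (length(s) == 0L) NULL else
      build_codebook(keyed_symbols(s, st$key, aa))
  }
  invisible(st)
}

#' Embed bits with primary-structure and codon-count preservation
#'
#' The dynamic protein-coding codec: like [bce_encode()] it only substitutes
#' codons synonymously, but every codon type may be used at most as often as
#' it appears in the host, so the output's codon histogram equals the host's
#' exactly.  Codebooks shrink and remap in a graduated fashion as budgets are
#' exhausted.  Once the message runs out, each remaining position takes the
#' first surviving codon of its amino acid in canonical order, which keeps
#' the histogram constraint and is replayable by the decoder.
#'
#' @inheritParams bce_encode
#' @param codons Host coding sequence (codon vector or in-frame string).
#' @return List with `codons`, `bits_embedded` and `n_codons`.
#' @export
biocode_pc_encode <- function(bits, codons, key = NULL) {
  stopifnot(all(bits %in% c(0L, 1L)))
  bits <- as.integer(bits)
  codons <- split_codons(codons)
  aas <- translate_codons(codons)
  st <- pcdna_init_state(codons, key)
  nb <- length(bits)
  out <- character(length(codons))
  i <- 1L
  for (j in seq_along(codons)) {
    a <- aas[j]
    cb <- st$books[[a]]
    if (i > nb) { # message exhausted: deterministic canonical fill
      y <- st$sets[[a]][1L]
    } else if (cb$mu == 1L) {
      y <- cb$symbols[1L]
    } else {
      p <- bit_pattern(bits, i, cb$l + 1L)
      k <- cb$pat_sym[p + 1L]
      y <- cb$symbols[k]
      i <- i + cb$pat_len[p + 1L]
    }
    out[j] <- y
    pcdna_spend(st, a, y)
  }
  list(codons = out, bits_embedded = min(i - 1L, nb),
       n_codons = length(codons))
}

#' Decode bits from the codon-count-preserving codec
#'
#' The decoder rebuilds the dynamic tables from the received sequence's own
#' codon histogram -- which equals the encoder's initial state whenever no
#' mutation occurred, because the codec preserves codon counts -- and replays
#' the encoder: emit each codon's current codeword, spend its budget, remap.
#' A codon absent from the current set of its amino acid (mutation evidence)
#' is flagged, contributes zero bits, and leaves the budgets untouched.
#'
#' @inheritParams bce_decode
#' @return List with `bits` and `flags` (1-based codon positions).
#' @export
biocode_pc_decode <- function(codons, nbits = NULL, key = NULL) {
  codons <- split_codons(codons)
  aas <- translate_codons(codons)
  st <- pcdna_init_state(codons, key)
  bits <- integer(3L * length(codons))
  nb <- 0L
  flags <- integer(0L)
  for (j in seq_along(codons)) {
    a <- aas[j]
    cb <- st$books[[a]]
    k <- if (is.null(cb)) NA_integer_ else match(codons[j], cb$symbols)
    if (is.na(k)) {
      flags <- c(flags, j)
      next
    }
    w <- cb$codewords[k]
    wl <- nchar(w)
    if (wl > 0L) {
      bits[nb + seq_len(wl)] <- as.integer(strsplit(w, "", fixed = TRUE)[[1L]])
      nb <- nb + wl
    }
    pcdna_spend(st, a, codons[j])
  }
  bits <- bits[seq_len(nb)]
  if (!is.null(nbits)) bits <- bits[seq_len(min(nbits, length(bits)))]
  list(bits = bits, flags = flags)
}
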