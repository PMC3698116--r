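# Non-coding DNA codec: bits are written base-by-base while the trailing
# dinucleotide [y_{i-2}, y_{i-1}] is monitored.  Whenever it could be
# completed into a start codon (sense or antisense, any frame on either
# strand), the choice of the next base is restricted and a smaller graduated
# codebook is used, so no start codon can ever be produced.

NCDNA_BASE_ORDER <- c("A", "T", "C", "G") # lookup-table ordering

#' Restricted base set for a trailing dinucleotide
#'
#' @param d Two-character dinucleotide state.
#' @param policy A [start_codon_policy()].
#' @return Allowed next bases in table order: `{A,T,C}` after AT/CT/TT, `{C}`
#'   after CA, all four bases otherwise (eukaryote policy).
#' @examples
#' ncdna_restricted_set("CA") # "C"
#' @export
ncdna_restricted_set <- function(d, policy = start_codon_policy()) {
  d <- toupper(d)
  if (d %in% policy$duplets) policy$restricted[[d]] else policy$base_order
}

.ncdna_cache <- new.env(parent = emptyenv())

# Per-state codebooks over base indices 1..4 (A,T,C,G in table order),
# plus a 16-entry class map from dinucleotide index to codebook.  Identity-key
# tables are cached per organism class.
ncdna_tables <- function(policy, key = NULL) {
  if (is.null(key)) {
    hit <- .ncdna_cache[[policy$organism]]
    if (!is.null(hit)) return(hit)
  }
  base_order <- policy$base_order
  # indexed as (first - 1) * 4 + second over table-order base indices
  states <- paste0(rep(base_order, each = 4L), rep(base_order, times = 4L))
  cbs <- vector("list", 16L)
  names(cbs) <- states
  for (s in states) {
    symbols <- keyed_symbols(ncdna_restricted_set(s, policy), key, s)
    cb <- build_codebook(match(symbols, base_order))
    cb$decode_bits <- lapply(seq_len(cb$mu), function(k) {
      w <- cb$codewords[k]
      if (nchar(w) == 0L) integer(0L) else
        as.integer(strsplit(w, "", fixed = TRUE)[[1L]])
    })
    # base index -> position in codebook (NA when the base is forbidden)
    cb$base_pos <- match(1:4, cb$symbols)
    cbs[[s]] <- cb
  }
  if (is.null(key)) .ncdna_cache[[policy$organism]] <- cbs
  cbs
}

ncdna_init_state <- function(flanks, policy) {
  left <- if (!is.null(flanks$left) && nchar(flanks$left) >= 2L) {
    toupper(substr(flanks$left, nchar(flanks$left) - 1L, nchar(flanks$left)))
  } else "GG" # virtual left context; never triggers a restriction
  match(strsplit(left, "", fixed = TRUE)[[1L]], policy$base_order)
}

# Filter the final-position symbol set against start triplets that would span
# the boundary into the right flank.
ncdna_boundary_filter <- function(symbols, prev_base, right, policy) {
  forb <- c(policy$sense_starts, policy$antisense_triplets)
  r1 <- substr(right, 1L, 1L)
  r2 <- substr(right, 2L, 2L)
  keep <- vapply(symbols, function(b) {
    !(paste0(prev_base, b, r1) %in% forb || paste0(b, r1, r2) %in% forb)
  }, logical(1L))
  symbols[keep]
}

#' Embed bits into a non-coding DNA sequence
#'
#' Encodes `bits` into a base sequence guaranteed to contain no start codon
#' (sense or antisense) in any of the six reading frames.  Encoding stops when
#' the message is exhausted (a final partial codeword is completed with zero
#' bits) or when `target_length` bases have been emitted, whichever comes
#' first; in the latter case `bits_embedded` reports how much of the message
#' fit.
#'
#' @param bits Integer 0/1 vector (see [random_bits()], [bits_from_bytes()]).
#' @param target_length Optional exact output length in bases; the message is
#'   zero-padded if it runs out early.
#' @param flanks Optional `list(left =, right =)` of genomic context strings.
#'   The last two left-flank bases seed the trailing-dinucleotide state and
#'   the first two right-flank bases additionally restrict the final base, so
#'   no start codon can span either junction.
#' @param key Optional integer secret key permuting each per-state base set.
#' @param policy A [start_codon_policy()].
#' @return List with `sequence` (DNA string), `bits_embedded` (message bits
#'   consumed, excluding padding) and `n_bases`.
#' @examples
#' enc <- ncdna_encode(random_bits(64, seed = 1))
#' find_start_codons(enc$sequence)
#' @export
ncdna_encode <- function(bits, target_length = NULL, flanks = NULL,
                         key = NULL, policy = start_codon_policy()) {
  stopifnot(all(bits %in% c(0L, 1L)))
  bits <- as.integer(bits)
  if (!is.null(target_length) && target_length < 1L) {
    stop("target_length must be at least 1")
  }
  cbs <- ncdna_tables(policy, key)
  nb <- length(bits)
  limit <- if (is.null(target_length)) 2L * nb + 4L else as.integer(target_length)
  out <- integer(limit)
  st <- ncdna_init_state(flanks, policy)
  has_right <- !is.null(flanks$right) && !is.null(target_length)
  i <- 1L; pos <- 0L
  while (pos < limit && (is.null(target_length) || pos < target_length)) {
    if (is.null(target_length) && i > nb) break
    cb <- cbs[[(st[1L] - 1L) * 4L + st[2L]]]
    if (has_right && pos == target_length - 1L) {
      syms <- policy$base_order[cb$symbols]
      prev <- policy$base_order[st[2L]]
      syms <- ncdna_boundary_filter(syms, prev, flanks$right, policy)
      if (length(syms) == 0L) {
        stop("right flank leaves no admissible final base; shorten by one")
      }
      cb <- build_codebook(match(syms, policy$base_order))
    }
    if (cb$mu == 1L) {
      k <- 1L; used <- 0L
    } else {
      p <- bit_pattern(bits, i, cb$l + 1L)
      k <- cb$pat_sym[p + 1L]
      used <- cb$pat_len[p + 1L]
    }
    pos <- pos + 1L
    out[pos] <- cb$symbols[k]
    i <- i + used
    st[1L] <- st[2L]; st[2L] <- cb$symbols[k]
  }
  list(sequence = paste(policy$base_order[out[seq_len(pos)]], collapse = ""),
       bits_embedded = min(i - 1L, nb),
       n_bases = pos)
}

#' Decode bits from a non-coding DNA sequence
#'
#' Replays the encoder's state machine on the received sequence itself.  A
#' base outside the admissible set of its state can only arise by mutation:
#' the position is flagged, contributes zero bits, and state tracking
#' continues with the observed base.  Note that a substitution can alter
#' downstream restricted sets and desynchronise the bitframe; marker or
#' watermark resynchronisation (see [watermark_decode()]) addresses this.
#'
#' @param sequence DNA string produced by [ncdna_encode()] (possibly mutated).
#' @param nbits Optional true message length for truncating codeword padding.
#' @inheritParams ncdna_encode
#' @return List with `bits` (integer vector) and `flags` (1-based positions
#'   of inadmissible bases).
#' @export
ncdna_decode <- function(sequence, flanks = NULL, nbits = NULL,
                         key = NULL, policy = start_codon_policy()) {
  cbs <- ncdna_tables(policy, key)
  z <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]],
             policy$base_order)
  if (anyNA(z)) stop("invalid symbol: alphabet must be A/C/G/T")
  L <- length(z)
  st <- ncdna_init_state(flanks, policy)
  has_right <- !is.null(flanks$right)
  bits <- integer(2L * L + 4L)
  nb <- 0L
  flags <- integer(0L)
  for (j in seq_len(L)) {
    cb <- cbs[[(st[1L] - 1L) * 4L + st[2L]]]
    if (has_right && j == L) {
      syms <- policy$base_order[cb$symbols]
      prev <- policy$base_order[st[2L]]
      syms <- ncdna_boundary_filter(syms, prev, flanks$right, policy)
      cb <- build_codebook(match(syms, policy$base_order))
      cb$decode_bits <- lapply(seq_len(cb$mu), function(k) {
        w <- cb$codewords[k]
        if (nchar(w) == 0L) integer(0L) else
          as.integer(strsplit(w, "", fixed = TRUE)[[1L]])
      })
      cb$base_pos <- match(1:4, cb$symbols)
    }
    k <- cb$base_pos[z[j]]
    if (is.na(k)) {
      flags <- c(flags, j)
    } else if (cb$mu > 1L) {
      cw <- cb$decode_bits[[k]]
      bits[nb + seq_along(cw)] <- cw
      nb <- nb + length(cw)
    }
    st[1L] <- st[2L]; st[2L] <- z[j]
  }
  bits <- bits[seq_len(nb)]
  if (!is.null(nbits)) bits <- bits[seq_len(min(nbits, length(bits)))]
  list(bits = bits, flags = flags)
}
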