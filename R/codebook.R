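# Graduated prefix-free codebooks: mu symbols mapped to bit strings of
# lengths l = floor(log2 mu) and l + 1.  The construction assigns the first
# 2^(l+1) - mu symbols the l-bit strings 0 .. 2^(l+1)-mu-1; each remaining
# l-bit string is extended with "0" and "1" to serve the last 2(mu - 2^l)
# symbols in order.  For mu = 1 the single symbol carries the empty codeword
# and encodes zero bits.

#' Build a graduated codebook
#'
#' @param symbols Character (or atomic) vector of distinct symbols; their
#'   order determines codeword assignment, so permuting it implements a
#'   secret-key mapping.
#' @return An object of class `codebook`: symbols, codewords (as `"0"`/`"1"`
#'   strings), codeword bit lengths, and fast bit-pattern lookup tables.
#' @examples
#' build_codebook(letters[1:5])$codewords # "00" "01" "10" "110" "111"
#' @export
build_codebook <- function(symbols) {
  mu <- length(symbols)
  if (mu < 1L) stop("codebook needs at least one symbol")
  if (anyDuplicated(symbols)) stop("symbols must be distinct")
  if (mu == 1L) {
    cb <- list(symbols = symbols, codewords = "", lengths = 0L,
               mu = 1L, l = 0L, pat_sym = 1L, pat_len = 0L)
    class(cb) <- "codebook"
    return(cb)
  }
  l <- floor(log2(mu))
  n_short <- 2L^(l + 1L) - mu          # codewords of length l
  n_long <- 2L * (mu - 2L^l)           # codewords of length l + 1
  bitstr <- function(v, width) {
    vapply(v, function(x) {
      paste(rev(as.integer(intToBits(x))[seq_len(width)]), collapse = "")
    }, character(1L))
  }
  short <- if (n_short > 0L) bitstr(0:(n_short - 1L), l) else character(0L)
  stems <- if (n_long > 0L) bitstr(n_short:(2L^l - 1L), l) else character(0L)
  long <- as.vector(t(outer(stems, c("0", "1"), paste0)))
  codewords <- c(short, long)
  lengths <- nchar(codewords)
  # lookup over all (l+1)-bit patterns: which symbol, how many bits consumed
  npat <- 2L^(l + 1L)
  pat_sym <- integer(npat)
  pat_len <- integer(npat)
  for (k in seq_len(mu)) {
    w <- codewords[k]
    v <- strtoi(w, base = 2L)
    if (lengths[k] == l) {
      pat_sym[2L * v + 1:2] <- k       # both extensions share the prefix
      pat_len[2L * v + 1:2] <- l
    } else {
      pat_sym[v + 1L] <- k
      pat_len[v + 1L] <- l + 1L
    }
  }
  cb <- list(symbols = symbols, codewords = codewords, lengths = lengths,
             mu = mu, l = l, pat_sym = pat_sym, pat_len = pat_len)
  class(cb) <- "codebook"
  cb
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("Graduated codebook (mu = %d, l = %d)\n", x$mu, x$l))
  print(data.frame(symbol = as.character(x$symbols), codeword = x$codewords),
        row.names = FALSE)
  invisible(x)
}

# Bit-pattern index of bits[i], bits[i+1], ... over `width` bits,
# zero-padding past the end of the stream.
bit_pattern <- function(bits, i, width) {
  p <- 0L
  n <- length(bits)
  for (k in seq_len(width)) {
    j <- i + k - 1L
    p <- 2L * p + if (j <= n) bits[j] else 0L
  }
  p
}

#' Encode the next symbol from a bit stream
#'
#' Consumes the unique codeword that prefixes the upcoming bits (prefix
#' freeness guarantees uniqueness) and returns the matching symbol.  A tail
#' shorter than every matching codeword is zero-padded; the true message
#' length is expected to travel out-of-band so the decoder can truncate.
#'
#' @param codebook A [build_codebook()] object.
#' @param bits Integer vector of 0/1 message bits.
#' @param at 1-based read position in `bits`.
#' @return List with `symbol`, its index `k`, and `nbits` consumed
#'   (0 for a single-symbol codebook).
#' @export
encode_next <- function(codebook, bits, at = 1L) {
  if (codebook$mu == 1L) {
    return(list(symbol = codebook$symbols[1L], k = 1L, nbits = 0L))
  }
  if (at > length(bits)) stop("bit stream exhausted")
  p <- bit_pattern(bits, at, codebook$l + 1L)
  k <- codebook$pat_sym[p + 1L]
  list(symbol = codebook$symbols[k], k = k, nbits = codebook$pat_len[p + 1L])
}

#' Decode a symbol to its codeword bits
#'
#' Inverse of [encode_next()]: looks the symbol up in the codebook and returns
#' its codeword as an integer 0/1 vector (length zero for a single-symbol
#' codebook).  An unknown symbol signals decoder-side mutation evidence.
#'
#' @inheritParams encode_next
#' @param symbol A symbol of the codebook.
#' @return Integer vector of bits.
#' @export
decode_symbol <- function(codebook, symbol) {
  k <- match(symbol, codebook$symbols)
  if (is.na(k)) stop(sprintf("symbol '%s' is not in the codebook", symbol))
  w <- codebook$codewords[k]
  if (nchar(w) == 0L) return(integer(0L))
  as.integer(strsplit(w, "", fixed = TRUE)[[1L]])
}

#' Remove a symbol and rebuild the codebook
#'
#' Dynamic remapping: the symbol is dropped, survivors keep their relative
#' order, and the codeword set is rebuilt in full for the new cardinality.
#' Removing the last symbol yields an empty (`mu = 0`) placeholder, legal only
#' as bookkeeping for exhausted synonymous classes.
#'
#' @inheritParams decode_symbol
#' @return A new `codebook` (or an empty placeholder list).
#' @export
remove_symbol <- function(codebook, symbol) {
  k <- match(symbol, codebook$symbols)
  if (is.na(k)) stop(sprintf("symbol '%s' is not in the codebook", symbol))
  rest <- codebook$symbols[-k]
  if (length(rest) == 0L) {
    return(structure(list(symbols = rest, codewords = character(0L),
                          lengths = integer(0L), mu = 0L, l = 0L),
                     class = "codebook"))
  }
  build_codebook(rest)
}
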