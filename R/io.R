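# FASTA input/output (via seqinr) and message-bit packing.

#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased; symbols outside A/C/G/T (including N) are
#' rejected by default because the codecs and the channel are defined over
#' the four-letter alphabet.
#'
#' @param path FASTA file path.
#' @param allow_n If `TRUE`, N symbols are tolerated and left in place.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, allow_n = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- toupper(vapply(recs, function(r) r[[1L]], character(1L)))
  names(seqs) <- names(recs)
  ok_alpha <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(ok_alpha, seqs))
  if (length(bad) > 0L) {
    stop(sprintf("record '%s' contains symbols outside the %s alphabet",
                 names(seqs)[bad[1L]], if (allow_n) "ACGTN" else "ACGT"))
  }
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA strings.
#' @param path Output file path.
#' @export
write_fasta <- function(sequences, path) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  seqinr::write.fasta(as.list(unname(sequences)), nm, path, as.string = TRUE)
  invisible(path)
}

#' Unpack bytes into bits
#'
#' Most-significant bit first within each byte, matching the order bit
#' strings are written in the codec tables.
#'
#' @param data A raw vector.
#' @return Integer 0/1 vector of length `8 * length(data)`.
#' @examples
#' bits_from_bytes(as.raw(0xA5)) # 1 0 1 0 0 1 0 1
#' @export
bits_from_bytes <- function(data) {
  stopifnot(is.raw(data))
  if (length(data) == 0L) return(integer(0L))
  m <- vapply(0:7, function(k) {
    as.integer(bitwAnd(as.integer(data), bitwShiftL(1L, 7L - k)) > 0L)
  }, integer(length(data)))
  as.integer(t(matrix(m, ncol = 8L)))
}

#' Pack bits into bytes
#'
#' Inverse of [bits_from_bytes()]; a trailing partial byte is zero-padded,
#' so callers should carry the true bit length out-of-band.
#'
#' @param bits Integer 0/1 vector.
#' @return Raw vector of `ceiling(length(bits) / 8)` bytes.
#' @export
bytes_from_bits <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% 0:1))
  if (length(bits) == 0L) return(raw(0L))
  pad <- (-length(bits)) %% 8L
  m <- matrix(c(bits, rep(0L, pad)), ncol = 8L, byrow = TRUE)
  as.raw(m %*% bitwShiftL(1L, 7:0))
}

#' Parse a message of 0/1 characters
#'
#' @param text String of `0` and `1` characters (whitespace ignored).
#' @return Integer 0/1 vector.
#' @export
bits_from_text <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  if (nchar(text) == 0L) return(integer(0L))
  if (!grepl("^[01]+$", text)) stop("message text must be 0/1 characters")
  as.integer(strsplit(text, "", fixed = TRUE)[[1L]])
}

#' Uniform random message bits
#'
#' @param n Number of bits.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector.
#' @export
random_bits <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sample(0:1, n, replace = TRUE)
}
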