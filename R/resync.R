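# Bitframe resynchronisation.  Variable-length decoding under substitutions
# can insert or delete message bits, after which every downstream bit index
# is wrong.  Marker codes insert a pilot pattern at regular intervals and
# repair one desynchronisation per block; watermark codes XOR a sparsified
# message with a shared pseudo-random vector and realign the received stream
# against that vector by banded edit distance.

#' Marker-code configuration
#'
#' @param pilot Pilot bit pattern (length >= 2); the published example "001"
#'   is the default.
#' @param block_length Message bits between consecutive pilots.
#' @return List of class `marker_config`.
#' @export
marker_config <- function(pilot = c(0L, 0L, 1L), block_length = 99L) {
  pilot <- as.integer(pilot)
  stopifnot(all(pilot %in% 0:1), length(pilot) >= 2L,
            block_length > length(pilot))
  structure(list(pilot = pilot, block_length = as.integer(block_length)),
            class = "marker_config")
}

#' Insert pilot markers into a message
#'
#' A pilot copy follows every `block_length` message bits (including a final
#' partial block), so the overhead is
#' `ceiling(length(bits) / block_length) * length(pilot)` bits.
#'
#' @param bits Integer 0/1 message vector.
#' @param cfg A [marker_config()].
#' @return Integer 0/1 vector with pilots interleaved.
#' @export
marker_encode <- function(bits, cfg = marker_config()) {
  bits <- as.integer(bits)
  n <- length(bits)
  if (n == 0L) return(integer(0L))
  nblk <- ceiling(n / cfg$block_length)
  out <- vector("list", 2L * nblk)
  for (b in seq_len(nblk)) {
    lo <- (b - 1L) * cfg$block_length + 1L
    hi <- min(b * cfg$block_length, n)
    out[[2L * b - 1L]] <- bits[lo:hi]
    out[[2L * b]] <- cfg$pilot
  }
  unlist(out)
}

#' Decode a marker-coded stream
#'
#' At each expected pilot offset the decoder compares the received bits with
#' the pilot.  A pilot consistent with a one-bit leftward shift implies a
#' deletion in the preceding block: a zero bit is inserted at the block's
#' midpoint and the cursor realigned; a rightward shift implies an insertion
#' and the midpoint bit is dropped.  At most one desynchronisation per block
#' is repaired, and bit flips inside the damaged block are not corrected.
#'
#' @param received Integer 0/1 vector (marker-encoded, possibly damaged).
#' @param nbits Optional true message length; decoding stops after `nbits`
#'   message bits.
#' @inheritParams marker_encode
#' @return Integer 0/1 vector with pilots stripped.
#' @export
marker_decode <- function(received, cfg = marker_config(), nbits = NULL) {
  received <- as.integer(received)
  pl <- length(cfg$pilot)
  bl <- cfg$block_length
  out <- integer(0L)
  cur <- 1L
  n <- length(received)
  repeat {
    if (cur > n || (!is.null(nbits) && length(out) >= nbits)) break
    want <- if (is.null(nbits)) bl else min(bl, nbits - length(out))
    blk_hi <- min(cur + want - 1L, n)
    block <- received[cur:blk_hi]
    at <- blk_hi + 1L
    window <- function(s) {
      if (s < 1L || s + pl - 1L > n) return(NULL)
      received[s:(s + pl - 1L)]
    }
    w0 <- window(at)
    if (!is.null(w0) && all(w0 == cfg$pilot)) {
      cur <- at + pl
    } else if (!is.null(window(at - 1L)) && all(window(at - 1L) == cfg$pilot)) {
      # stream shifted left: a deletion occurred inside this block
      mid <- max(1L, length(block) %/% 2L)
      block <- append(block[-length(block)], 0L, after = mid)
      cur <- at - 1L + pl
    } else if (!is.null(window(at + 1L)) && all(window(at + 1L) == cfg$pilot)) {
      # stream shifted right: an insertion occurred inside this block
      mid <- max(1L, (length(block) + 1L) %/% 2L)
      block <- c(block, received[at])[-mid]
      cur <- at + 1L + pl
    } else {
      cur <- at + pl # pilot merely flipped; accept block as-is
    }
    out <- c(out, block)
    if (blk_hi == n) break
  }
  if (!is.null(nbits)) out <- out[seq_len(min(nbits, length(out)))]
  out
}

#' Watermark-code configuration
#'
#' Builds the shared pseudo-random watermark vector and the sparsification
#' layout for a message of known length.  Message bits occupy every
#' `floor(k / sparsity)`-th slot; the remaining slots carry fixed zeros, and
#' the whole sparse vector is XORed with the watermark.
#'
#' @param n_message Message length in bits.
#' @param sparsity Fraction of slots carrying message bits, in `(0, 1]`.
#' @param seed Integer seed generating the shared watermark vector.
#' @return List of class `watermark_config` with `w` (watermark bits),
#'   `slots` (1-based message positions) and `n_message`.
#' @export
watermark_config <- function(n_message, sparsity = 0.5, seed = 7L) {
  stopifnot(sparsity > 0, sparsity <= 1, n_message >= 0)
  L <- ceiling(n_message / sparsity)
  slots <- floor((seq_len(n_message) - 1L) / sparsity) + 1L
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  w <- sample(0:1, L, replace = TRUE)
  structure(list(w = as.integer(w), slots = as.integer(slots),
                 n_message = as.integer(n_message),
                 sparsity = sparsity, seed = seed),
            class = "watermark_config")
}

#' Watermark-encode a message
#'
#' @param bits Integer 0/1 vector of length `cfg$n_message`.
#' @param cfg A [watermark_config()].
#' @return Integer 0/1 vector of length `length(cfg$w)`.
#' @export
watermark_encode <- function(bits, cfg) {
  bits <- as.integer(bits)
  if (length(bits) != cfg$n_message) {
    stop("message length does not match the watermark configuration")
  }
  sparse <- integer(length(cfg$w))
  sparse[cfg$slots] <- bits
  xor(sparse, cfg$w) * 1L
}

#' Watermark-decode a received stream
#'
#' Realigns the received vector against the shared watermark `w` by banded
#' edit distance in which insertions and deletions are only permitted on the
#' received side (desynchronisation cannot occur in `w` itself).  Mismatches
#' cost far less than indels because substitution flips are the expected
#' channel noise: with the default costs a spurious insertion-deletion pair
#' would have to save more than `2 / mismatch` matched positions to displace
#' the identity path, so a flip-only stream realigns to itself.  At mismatch
#' columns the received value is kept; slots lost to deletions fall back to
#' the watermark value (decoding to a zero message bit).  The realigned
#' vector is un-sparsified and XORed with `w`.
#'
#' @param received Integer 0/1 vector (possibly shorter or longer than `w`).
#' @param cfg A [watermark_config()].
#' @param band Half-width of the alignment band around the diagonal; must
#'   exceed the absolute drift `length(received) - length(w)`.
#' @param mismatch,indel Alignment costs (received-side indels only).
#' @return Integer 0/1 vector of exactly `cfg$n_message` bits.
#' @export
watermark_decode <- function(received, cfg, band = 32L,
                             mismatch = 0.15, indel = 1) {
  received <- as.integer(received)
  L <- length(cfg$w)
  drift <- abs(length(received) - L)
  band <- max(as.integer(band), drift + 4L)
  aligned <- align_to_watermark(cfg$w, received, band, mismatch, indel)
  xor(aligned[cfg$slots], cfg$w[cfg$slots]) * 1L
}
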