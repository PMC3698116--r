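# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# Brute-force start-codon scan: every length-3 substring of s and of its
# reverse complement, with antisense loci mapped back to s coordinates.
scan_starts_bruteforce <- function(s, starts = c("ATG", "CTG", "TTG")) {
  hit <- function(x) {
    n <- nchar(x)
    if (n < 3L) return(integer(0L))
    which(substring(x, 1:(n - 2L), 3:n) %in% starts) - 1L
  }
  fwd <- hit(s)
  rc <- hit(reverse_complement(s))
  n <- nchar(s)
  # position i (0-based) on the reverse strand covers s[(n-3-i) .. (n-1-i)]
  rev_mapped <- if (length(rc) > 0L) sort(n - 3L - rc) else integer(0L)
  list(fwd = fwd, rev = rev_mapped, any = length(fwd) + length(rc) > 0L)
}

# Naive repeated matrix multiplication.
naive_power <- function(P, p) {
  acc <- diag(nrow(P))
  dimnames(acc) <- dimnames(P)
  for (i in seq_len(p)) acc <- acc %*% P
  acc
}

# Expected codeword length of a graduated codebook under uniform random bits,
# by direct enumeration of codeword-usage probabilities (each codeword of
# length L is selected with probability 2^-L).
expected_codeword_length <- function(mu) {
  lens <- nchar(build_codebook(seq_len(mu))$codewords)
  sum(2^(-lens) * lens)
}

# Shannon binary entropy in bits.
binary_entropy <- function(p) {
  q <- c(p, 1 - p)
  -sum(ifelse(q > 0, q * log2(q), 0))
}

random_message <- function(n) sample(0:1, n, replace = TRUE)
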