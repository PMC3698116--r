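# Secret-key support.  A key is an integer from which a deterministic
# permutation of each symbol set's canonical order is derived before codeword
# assignment; NULL (the default) keeps the canonical order, reproducing the
# published lookup tables.

key_permutation <- function(n, key, label) {
  if (is.null(key) || n < 2L) return(seq_len(n))
  h <- sum(utf8ToInt(label) * 131L^(seq_len(nchar(label)) - 1L)) %% 1000003L
  s <- (as.integer(key) %% 1000000007) * 31 + h
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(s %% 2147483647))
  sample.int(n)
}

keyed_symbols <- function(symbols, key, label) {
  symbols[key_permutation(length(symbols), key, label)]
}
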