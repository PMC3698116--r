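test_that("graduated construction reproduces the worked codeword sets", {
  expect_equal(build_codebook(letters[1:5])$codewords,
               c("00", "01", "10", "110", "111"))
  expect_equal(build_codebook(letters[1:4])$codewords,
               c("00", "01", "10", "11"))
  expect_equal(build_codebook("a")$codewords, "")
  expect_equal(build_codebook(letters[1:3])$codewords, c("0", "10", "11"))
  expect_equal(build_codebook(letters[1:6])$codewords,
               c("00", "01", "100", "101", "110", "111"))
  expect_error(build_codebook(character(0)), "at least one symbol")
  expect_error(build_codebook(c("a", "a")), "distinct")
})

test_that("codebooks are prefix-free with the graduated length profile", {
  for (mu in 1:64) {
    cb <- build_codebook(seq_len(mu))
    l <- floor(log2(mu))
    expect_equal(sum(cb$lengths == l), 2^(l + 1) - mu)
    if (mu > 1) expect_equal(sum(cb$lengths == l + 1), 2 * (mu - 2^l))
    if (mu > 1) {
      for (k in seq_len(mu)) {
        others <- cb$codewords[-k]
        expect_false(any(startsWith(others, cb$codewords[k])))
      }
    }
  }
})

test_that("encode_next consumes the unique matching prefix", {
  cb3 <- build_codebook(c("A", "T", "C")) # 0, 10, 11
  r <- encode_next(cb3, c(1L, 0L, 1L))
  expect_equal(r$symbol, "T")
  expect_equal(r$nbits, 2L)

  cb1 <- build_codebook("X")
  r1 <- encode_next(cb1, integer(0))
  expect_equal(r1$symbol, "X")
  expect_equal(r1$nbits, 0L)

  cb5 <- build_codebook(letters[1:5])
  r5 <- encode_next(cb5, c(1L, 1L, 1L, 0L))
  expect_equal(r5$symbol, "e")
  expect_equal(r5$nbits, 3L)

  # tail underflow: the stream is zero-padded
  r_pad <- encode_next(cb5, c(1L, 1L)) # reads "110"
  expect_equal(r_pad$symbol, "d")
  expect_error(encode_next(cb5, integer(0)), "exhausted")
})

test_that("decode_symbol inverts encode_next over random streams", {
  cb <- build_codebook(c("A", "T", "C"))
  expect_equal(decode_symbol(cb, "C"), c(1L, 1L))
  expect_equal(decode_symbol(build_codebook("Z"), "Z"), integer(0))
  expect_error(decode_symbol(cb, "G"), "not in the codebook")

  set.seed(5)
  for (mu in c(2, 3, 5, 6, 17, 64)) {
    cb <- build_codebook(seq_len(mu))
    bits <- random_message(200)
    i <- 1L
    out <- integer(0)
    while (i + cb$l + 1L <= length(bits)) {
      r <- encode_next(cb, bits, i)
      out <- c(out, decode_symbol(cb, r$symbol))
      i <- i + r$nbits
    }
    expect_equal(out, bits[seq_along(out)])
  }
})

test_that("symbol removal rebuilds the mapping gracefully", {
  cb <- build_codebook(letters[1:5])
  cb2 <- remove_symbol(cb, "d")
  expect_equal(cb2$symbols, c("a", "b", "c", "e"))
  expect_equal(cb2$codewords, c("00", "01", "10", "11"))

  tiny <- remove_symbol(build_codebook(c("x", "y")), "x")
  expect_equal(tiny$codewords, "")
  expect_error(remove_symbol(cb, "q"), "not in the codebook")

  # removing all but one symbol, in any order, ends at the zero-bit book
  set.seed(8)
  for (i in 1:10) {
    cb <- build_codebook(letters[1:6])
    for (drop in sample(letters[1:5])) cb <- remove_symbol(cb, drop)
    expect_equal(cb$symbols, "f")
    expect_equal(cb$codewords, "")
  }
})

test_that("average codeword length under uniform bits matches the closed form", {
  for (mu in 1:64) {
    expect_equal(expected_codeword_length(mu), graduated_rate(mu))
  }
  # Monte-Carlo cross-check at a few sizes
  set.seed(13)
  for (mu in c(3, 5, 6, 12)) {
    cb <- build_codebook(seq_len(mu))
    bits <- random_message(6e4)
    i <- 1L; n_sym <- 0L
    while (i + cb$l + 1L <= length(bits)) {
      i <- i + encode_next(cb, bits, i)$nbits
      n_sym <- n_sym + 1L
    }
    expect_equal((i - 1) / n_sym, graduated_rate(mu), tolerance = 0.02)
  }
})
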