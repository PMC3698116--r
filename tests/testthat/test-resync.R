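test_that("marker pilots land at the expected offsets", {
  cfg <- marker_config(pilot = c(0L, 0L, 1L), block_length = 10L)
  m <- random_bits(20, seed = 101)
  tx <- marker_encode(m, cfg)
  expect_length(tx, 20 + 2 * 3)
  expect_equal(tx[11:13], c(0L, 0L, 1L))
  expect_equal(tx[24:26], c(0L, 0L, 1L))
  expect_equal(marker_encode(integer(0), cfg), integer(0))
  # overhead for a partial final block
  expect_length(marker_encode(random_bits(15, seed = 1), cfg), 15 + 2 * 3)
  expect_error(marker_config(pilot = 1L), "length")
})

test_that("marker decoding strips pilots and repairs one desync per block", {
  cfg <- marker_config()
  set.seed(103)
  m <- random_message(500)
  tx <- marker_encode(m, cfg)
  expect_equal(marker_decode(tx, cfg, nbits = 500), m)

  # deletion mid-block: the remainder of the message realigns
  dec <- marker_decode(tx[-50], cfg, nbits = 500)
  expect_length(dec, 500)
  expect_equal(dec[100:500], m[100:500])

  # insertion mid-block
  dec_i <- marker_decode(append(tx, 1L, after = 49), cfg, nbits = 500)
  expect_length(dec_i, 500)
  expect_equal(dec_i[100:500], m[100:500])
})

test_that("a left-shifted pilot implies a deletion in its block", {
  cfg <- marker_config(pilot = c(0L, 0L, 1L), block_length = 8L)
  m <- c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, # block 1
         0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L) # block 2 starts with 0
  tx <- marker_encode(m, cfg)
  rx <- tx[-3] # a deletion in block 1 shifts the stream left
  # at the expected offset the decoder now reads the pilot as "010"
  expect_equal(rx[9:11], c(0L, 1L, 0L))
  dec <- marker_decode(rx, cfg, nbits = 16)
  expect_length(dec, 16)
  expect_equal(dec[9:16], m[9:16]) # block 2 realigned exactly
})

test_that("watermark encoding sparsifies then masks", {
  m <- c(1L, 0L, 1L, 1L)
  cfg <- watermark_config(4, sparsity = 1, seed = 5)
  expect_equal(watermark_encode(m, cfg), xor(m, cfg$w) * 1L)

  cfg2 <- watermark_config(4, sparsity = 0.5, seed = 5)
  expect_length(watermark_encode(m, cfg2), 8)
  # an all-zero message transmits the watermark pattern itself
  expect_equal(watermark_encode(rep(0L, 4), cfg2), cfg2$w)
  expect_error(watermark_encode(c(1L, 0L), cfg2), "length")
})

test_that("watermark decoding is exact over an identity channel", {
  set.seed(107)
  for (i in 1:10) {
    n <- sample(100:2500, 1)
    m <- random_message(n)
    cfg <- watermark_config(n, sparsity = 0.5, seed = i)
    expect_equal(watermark_decode(watermark_encode(m, cfg), cfg), m)
  }
})

test_that("flip-only damage never changes the decoded length", {
  set.seed(109)
  for (i in 1:10) {
    n <- 800
    m <- random_message(n)
    cfg <- watermark_config(n, sparsity = 0.5, seed = 20 + i)
    tx <- watermark_encode(m, cfg)
    flips <- sample(length(tx), 25)
    tx[flips] <- 1L - tx[flips]
    dec <- watermark_decode(tx, cfg)
    expect_length(dec, n)
    # errors only at flipped message slots: the alignment stayed diagonal
    expect_lte(sum(dec != m), 25)
  }
})

test_that("watermark realignment absorbs deletions and insertions", {
  set.seed(113)
  for (i in 1:8) {
    n <- 1500
    m <- random_message(n)
    cfg <- watermark_config(n, sparsity = 0.5, seed = 40 + i)
    tx <- watermark_encode(m, cfg)
    tx <- tx[-sample(length(tx), 1)] # one deletion
    flips <- sample(length(tx), 8)
    tx[flips] <- 1L - tx[flips]
    dec <- watermark_decode(tx, cfg)
    expect_length(dec, n) # bitframe restored
    expect_lt(sum(dec != m), 60) # residual damage stays local
  }
  # an insertion, likewise
  m <- random_message(1000)
  cfg <- watermark_config(1000, sparsity = 0.5, seed = 60)
  tx <- append(watermark_encode(m, cfg), 1L, after = 777)
  dec <- watermark_decode(tx, cfg)
  expect_length(dec, 1000)
  expect_lt(sum(dec != m), 40)
})

test_that("the coded error rate improves on the uncoded rate under mutations", {
  base <- experiment_config(codec = "ncdna", resync = "none",
                            generations = c(1e6, 1e7),
                            message_length = 2000, trials = 6, seed = 11)
  wm <- experiment_config(codec = "ncdna", resync = "watermark",
                          generations = c(1e6, 1e7),
                          message_length = 2000, trials = 6, seed = 11)
  r0 <- run_experiment(base)
  r1 <- run_experiment(wm)
  tol <- 2 * (r0$pb_se + r1$pb_se)
  expect_true(all(r1$pb <= r0$pb + tol))
})
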