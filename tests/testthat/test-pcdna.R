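test_that("static codec follows the published translation table", {
  # forced singletons carry no bits
  expect_equal(bce_encode(c(1L, 0L), "ATG")$codons, "ATG")
  expect_equal(bce_encode(c(1L, 0L), "ATG")$bits_embedded, 0L)
  # Gly codebook {00,01,10,11} over {GGA,GGC,GGG,GGT}
  expect_equal(bce_encode(c(0L, 1L), "GGA")$codons, "GGC")
  expect_equal(bce_decode("GGC"), c(0L, 1L))
  expect_equal(bce_decode("TGG"), integer(0))
  # Ile (3 codons): graduated {0,10,11}
  expect_equal(bce_encode(c(1L, 1L), "ATA")$codons, "ATT")
  expect_equal(bce_decode("ATA"), 0L)
})

test_that("static codec round-trips and preserves the protein", {
  set.seed(53)
  for (i in 1:25) {
    x <- random_codons(sample(1:80, 1))
    m <- random_message(sample(0:120, 1))
    enc <- bce_encode(m, x)
    expect_equal(translate_codons(enc$codons), translate_codons(x))
    k <- enc$bits_embedded
    expect_equal(bce_decode(enc$codons, nbits = k), m[seq_len(k)])
  }
})

test_that("dynamic state restricts synonymous sets to codons present", {
  st <- pcdna_init_state(c("GGA", "GGC", "GGG", "GGA"))
  expect_equal(st$sets$Gly, c("GGA", "GGC", "GGG"))
  expect_equal(st$books$Gly$codewords, c("0", "10", "11"))
  expect_equal(st$counts[["GGA"]], 2L)

  # a reference holding all 64 codons reproduces the full static tables
  st64 <- pcdna_init_state(names(biocode:::GENETIC_CODE_3L))
  static <- biocode:::bce_tables()
  for (a in biocode:::AMINO_ACIDS) {
    expect_equal(st64$books[[a]]$symbols, static[[a]]$symbols)
    expect_equal(st64$books[[a]]$codewords, static[[a]]$codewords)
  }

  single <- pcdna_init_state("ATG")
  expect_equal(single$sets$Met, "ATG")
  expect_equal(single$counts, c(ATG = 1L))
})

test_that("codon budgets force remapping as they exhaust", {
  # Gly budget {GGA:1, GGC:1}: first Gly takes GGA on a 0 bit, the second is
  # forced to GGC and carries nothing
  enc <- biocode_pc_encode(0L, c("GGA", "GGC"))
  expect_equal(enc$codons, c("GGA", "GGC"))
  expect_equal(enc$bits_embedded, 1L)
  enc1 <- biocode_pc_encode(1L, c("GGA", "GGC"))
  expect_equal(enc1$codons, c("GGC", "GGA"))
  dec <- biocode_pc_decode(enc1$codons, nbits = 1)
  expect_equal(dec$bits, 1L)
})

test_that("dynamic codec preserves protein and exact codon histogram", {
  set.seed(59)
  for (i in 1:30) {
    x <- if (i %% 2 == 0) {
      random_codons(sample(2:100, 1))
    } else {
      generate_synthetic_cds(sample(2:100, 1),
                             include_stops = sample(c(TRUE, FALSE), 1))
    }
    m <- random_message(sample(0:150, 1))
    enc <- biocode_pc_encode(m, x)
    expect_equal(translate_codons(enc$codons), translate_codons(x))
    expect_equal(sort(enc$codons), sort(x)) # multiset equality
    k <- enc$bits_embedded
    dec <- biocode_pc_decode(enc$codons, nbits = k)
    expect_equal(dec$bits, m[seq_len(k)])
    expect_length(dec$flags, 0)
  }
})

test_that("invariant-codon genes carry no information", {
  gene <- rep(c("ATG", "TGG"), 10)
  enc <- biocode_pc_encode(random_message(40), gene)
  expect_equal(enc$bits_embedded, 0L)
  expect_equal(enc$codons, gene)
  expect_equal(biocode_pc_decode(enc$codons)$bits, integer(0))
})

test_that("a synonymous substitution perturbs decoding locally", {
  set.seed(61)
  x <- random_codons(60)
  m <- random_message(80)
  enc <- biocode_pc_encode(m, x)
  k <- enc$bits_embedded
  z <- enc$codons
  # replace the first multi-codon position with a different synonym
  j <- which(vapply(translate_codons(z),
                    function(a) length(synonymous_codons(a)) > 1,
                    logical(1)))[1]
  alt <- setdiff(synonymous_codons(translate_codons(z[j])), z[j])[1]
  z[j] <- alt
  dec <- biocode_pc_decode(z, nbits = k)
  expect_true(!identical(dec$bits, m[seq_len(k)]) || length(dec$flags) > 0)
  expect_equal(translate_codons(z), translate_codons(enc$codons))
})

test_that("per-amino-acid keys permute codewords reversibly", {
  set.seed(67)
  x <- random_codons(50)
  m <- random_message(60)
  enc <- biocode_pc_encode(m, x, key = 99L)
  expect_false(identical(enc$codons, biocode_pc_encode(m, x)$codons))
  k <- enc$bits_embedded
  expect_equal(biocode_pc_decode(enc$codons, nbits = k, key = 99L)$bits,
               m[seq_len(k)])
  expect_equal(sort(enc$codons), sort(x))
})

test_that("frames that are not codon-aligned are rejected", {
  expect_error(biocode_pc_encode(c(1L), "ATGA"), "multiple of 3")
  expect_error(bce_decode("GG"), "base triplets")
})

test_that("embedding rate grows with gene length at fixed codon bias", {
  set.seed(71)
  bias <- stats::setNames(rep(1, 64), names(biocode:::GENETIC_CODE_3L))
  rates <- lapply(c(30, 150, 900), function(n) {
    g <- generate_synthetic_cds(n, codon_bias = bias, seed = n)
    empirical_gene_rate(g, trials = 12, seed = n + 1)
  })
  r <- vapply(rates, `[[`, numeric(1), "rate")
  ci <- vapply(rates, `[[`, numeric(1), "ci")
  expect_gt(r[2], r[1] - ci[1] - ci[2])
  expect_gt(r[3], r[2] - ci[2] - ci[3])
  expect_gt(r[3], r[1]) # clear trend over a 30x length span
})
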