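# Monte-Carlo evaluation harness: encode a fresh random message, pass the
# carrier sequence through the cascaded substitution channel, decode, and
# accumulate the bit-error probability and the empirical mutual information
# between sent and decoded message bits across generations.

#' Bit-error probability between two bit vectors
#'
#' Mismatch fraction over aligned positions, with positions missing from the
#' shorter vector counted as errors (length mismatch is desynchronisation
#' damage); the denominator is the longer length.
#'
#' @param m,m_prime Integer 0/1 vectors.
#' @return Error probability in `[0, 1]`.
#' @examples
#' bit_error_rate(c(0L,0L,0L,0L), c(0L,1L,0L,0L)) # 0.25
#' @export
bit_error_rate <- function(m, m_prime) {
  n <- max(length(m), length(m_prime))
  if (n == 0L) return(0)
  k <- min(length(m), length(m_prime))
  errs <- if (k > 0L) sum(m[seq_len(k)] != m_prime[seq_len(k)]) else 0L
  (errs + (n - k)) / n
}

# Pool (sent, decoded) pairs into a 2x2 joint count matrix; missing decoded
# positions are treated as flipped bits (maximal damage), surplus decoded
# bits are ignored.
joint_counts <- function(m, m_prime) {
  k <- min(length(m), length(m_prime))
  cnt <- matrix(0, 2L, 2L, dimnames = list(sent = 0:1, decoded = 0:1))
  if (k > 0L) {
    a <- m[seq_len(k)]; b <- m_prime[seq_len(k)]
    cnt[1, 1] <- sum(a == 0L & b == 0L)
    cnt[1, 2] <- sum(a == 0L & b == 1L)
    cnt[2, 1] <- sum(a == 1L & b == 0L)
    cnt[2, 2] <- sum(a == 1L & b == 1L)
  }
  if (length(m) > k) {
    rest <- m[(k + 1L):length(m)]
    cnt[1, 2] <- cnt[1, 2] + sum(rest == 0L)
    cnt[2, 1] <- cnt[2, 1] + sum(rest == 1L)
  }
  cnt
}

mi_from_joint <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  p <- cnt / n
  pm <- rowSums(p); pp <- colSums(p)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pm[i] * pp[j]))
  }
  max(0, s)
}

#' Empirical mutual information between sent and decoded bits
#'
#' Plug-in estimate from the pooled 2x2 joint distribution over all positions
#' (and, when lists are given, all trials).  Bounded by 1 bit/bit; zero-count
#' cells contribute zero.
#'
#' @param m,m_prime Integer 0/1 vectors, or lists of such vectors (one per
#'   trial).
#' @return Mutual information in bits per message bit.
#' @examples
#' mutual_information(c(0L,1L,0L,1L), c(0L,1L,0L,1L)) # 1 for balanced input
#' @export
mutual_information <- function(m, m_prime) {
  if (!is.list(m)) m <- list(m)
  if (!is.list(m_prime)) m_prime <- list(m_prime)
  stopifnot(length(m) == length(m_prime))
  cnt <- matrix(0, 2L, 2L)
  for (t in seq_along(m)) cnt <- cnt + joint_counts(m[[t]], m_prime[[t]])
  mi_from_joint(cnt)
}

#' Experiment configuration
#'
#' @param codec One of `"ncdna"` (non-coding codec), `"bce"` (static
#'   protein-coding codec) or `"biocode_pc"` (codon-count-preserving codec).
#' @param resync `"none"`, `"marker"` or `"watermark"` outer code.
#' @param q,gamma Kimura channel parameters (defaults follow realistic
#'   per-generation estimates: `q = 1e-8`, `gamma = 0.1`).
#' @param generations Ascending vector of generation counts `p`.
#' @param message_length Message bits per trial (non-coding codec default
#'   10000).
#' @param trials Monte-Carlo trials per generation count.
#' @param host_codons Host gene for the protein-coding codecs; defaults to a
#'   synthetic uniform-codon gene sized to fit the coded message.
#' @param seed Integer master seed; trials consume sequential substreams.
#' @param marker,watermark Optional [marker_config()] / parameter list
#'   (`sparsity`, `seed`, `band`) for [watermark_config()].
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(codec = c("ncdna", "bce", "biocode_pc"),
                              resync = c("none", "marker", "watermark"),
                              q = 1e-8, gamma = 0.1,
                              generations = 10^(0:8),
                              message_length = 10000L,
                              trials = 20L,
                              host_codons = NULL,
                              seed = 1L,
                              marker = marker_config(),
                              watermark = list(sparsity = 0.5, seed = 7L,
                                               band = 48L)) {
  codec <- match.arg(codec)
  resync <- match.arg(resync)
  stopifnot(trials >= 1L, !is.unsorted(generations))
  structure(list(codec = codec, resync = resync, q = q, gamma = gamma,
                 generations = generations,
                 message_length = as.integer(message_length),
                 trials = as.integer(trials), host_codons = host_codons,
                 seed = as.integer(seed), marker = marker,
                 watermark = watermark),
            class = "experiment_config")
}

# One trial: returns list(m, m_prime).  For the protein-coding codecs with no
# outer code, the message fills the host gene (its length therefore varies
# with codon composition), so the achieved rate is the gene's embedding rate.
run_trial <- function(cfg, Pi_p, host, wm_cfg) {
  fill_host <- cfg$codec != "ncdna" && cfg$resync == "none"
  m <- if (fill_host) {
    sample(0:1, 3L * length(host), replace = TRUE)
  } else {
    sample(0:1, cfg$message_length, replace = TRUE)
  }
  coded <- switch(cfg$resync,
    none = m,
    marker = marker_encode(m, cfg$marker),
    watermark = watermark_encode(m, wm_cfg))
  # the coded length is shared knowledge: the decoder drops codeword padding
  if (cfg$codec == "ncdna") {
    enc <- ncdna_encode(coded)
    z <- mutate_sequence(enc$sequence, Pi_p)
    raw <- ncdna_decode(z, nbits = length(coded))$bits
    n_sym <- enc$n_bases
  } else {
    enc <- if (cfg$codec == "bce") bce_encode(coded, host)
           else biocode_pc_encode(coded, host)
    if (fill_host) {
      m <- m[seq_len(enc$bits_embedded)]
      coded <- m
    } else if (enc$bits_embedded < length(coded)) {
      stop("host gene too short for the coded message; supply a longer host")
    }
    z <- mutate_codons(enc$codons, Pi_p)
    raw <- if (cfg$codec == "bce") bce_decode(z, nbits = length(coded))
           else biocode_pc_decode(z, nbits = length(coded))$bits
    n_sym <- enc$n_codons
  }
  m_prime <- switch(cfg$resync,
    none = raw[seq_len(min(length(m), length(raw)))],
    marker = marker_decode(raw, cfg$marker, nbits = cfg$message_length),
    watermark = watermark_decode(raw, wm_cfg, band = cfg$watermark$band))
  list(m = m, m_prime = m_prime, n_sym = n_sym)
}

#' Run a Monte-Carlo channel experiment
#'
#' For every generation count `p`, encodes fresh random messages, cascades
#' the Kimura channel to `Pi^p`, mutates the carrier, decodes (applying the
#' configured resynchronisation code), and accumulates the bit-error
#' probability and pooled empirical mutual information.  The mutual
#' information is also reported scaled to carrier units (bits/base for the
#' non-coding codec, bits/codon for the protein-coding codecs).
#'
#' @param cfg An [experiment_config()].
#' @return Data frame of class `biocode_sim`: one row per generation count
#'   with columns `p`, `pb`, `pb_se`, `mi_bit`, `mi_scaled`, `trials`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  Pi <- kimura_matrix(cfg$q, cfg$gamma)
  host <- cfg$host_codons
  if (cfg$codec != "ncdna" && is.null(host)) {
    factor <- switch(cfg$resync,
      none = 1,
      marker = 1 + length(cfg$marker$pilot) / cfg$marker$block_length,
      watermark = 1 / cfg$watermark$sparsity)
    # 1.3 bits/codon is a conservative floor for the achieved rate, so the
    # coded stream always fits while leaving little slack
    n <- ceiling(cfg$message_length * factor / 1.3)
    host <- random_codons(n, seed = cfg$seed + 104729L)
  }
  wm_cfg <- if (cfg$resync == "watermark") {
    watermark_config(cfg$message_length, cfg$watermark$sparsity,
                     cfg$watermark$seed)
  } else NULL
  rows <- vector("list", length(cfg$generations))
  for (gi in seq_along(cfg$generations)) {
    p <- cfg$generations[gi]
    Pi_p <- channel_power(Pi, p)
    set.seed((cfg$seed + 7919L * gi) %% 2147483647L)
    pbs <- numeric(cfg$trials)
    cnt <- matrix(0, 2L, 2L)
    sym_rate <- numeric(cfg$trials)
    for (t in seq_len(cfg$trials)) {
      tr <- run_trial(cfg, Pi_p, host, wm_cfg)
      pbs[t] <- bit_error_rate(tr$m, tr$m_prime)
      cnt <- cnt + joint_counts(tr$m, tr$m_prime)
      sym_rate[t] <- length(tr$m) / tr$n_sym
    }
    mi <- mi_from_joint(cnt)
    rows[[gi]] <- data.frame(
      p = p, pb = mean(pbs),
      pb_se = stats::sd(pbs) / sqrt(cfg$trials),
      mi_bit = mi,
      mi_scaled = mi * mean(sym_rate),
      trials = cfg$trials)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  class(out) <- c("biocode_sim", "data.frame")
  out
}

#' @export
print.biocode_sim <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Channel simulation: codec = %s, resync = %s, q = %g, gamma = %g\n",
              cfg$codec, cfg$resync, cfg$q, cfg$gamma))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot bit-error probability and mutual information against generations
#'
#' @param x A `biocode_sim` result.
#' @param which `"pb"` or `"mi"`.
#' @param ... Passed to [plot()].
#' @export
plot.biocode_sim <- function(x, which = c("pb", "mi"), ...) {
  which <- match.arg(which)
  if (which == "pb") {
    plot(x$p, pmax(x$pb, 1e-6), log = "xy", type = "b",
         xlab = "generations", ylab = "bit-error probability", ...)
  } else {
    plot(x$p, x$mi_scaled, log = "x", type = "b",
         xlab = "generations", ylab = "mutual information (scaled)", ...)
  }
  invisible(x)
}
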