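# Kimura two-parameter substitution channel.  One generation is a 4x4
# row-stochastic matrix with per-base substitution rate q; transitions
# (A<->G, C<->T) occur with probability (1 - 2*gamma/3)*q and each
# transversion with gamma*q/3.  gamma = 1 recovers Jukes-Cantor; p
# generations cascade as the matrix power Pi^p.

KIMURA_BASE_ORDER <- c("A", "C", "T", "G") # row/column order as conventional

#' One-generation Kimura substitution matrix
#'
#' @param q Per-generation base substitution probability, in `[0, 1]`.
#' @param gamma Transition/transversion shape parameter in `(0, 1.5]`;
#'   `gamma = 1` gives the Jukes-Cantor model (all off-diagonals `q/3`).
#' @return 4x4 row-stochastic matrix over bases A, C, T, G.
#' @examples
#' kimura_matrix(0.3, 1)
#' @export
kimura_matrix <- function(q, gamma = 1) {
  if (!is.numeric(q) || q < 0 || q > 1) stop("q must lie in [0, 1]")
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1.5) {
    stop("gamma must lie in (0, 1.5]")
  }
  tv <- gamma * q / 3          # each transversion
  ts <- (1 - 2 * gamma / 3) * q # the transition
  m <- matrix(tv, 4L, 4L, dimnames = list(KIMURA_BASE_ORDER, KIMURA_BASE_ORDER))
  diag(m) <- 1 - q
  m["A", "G"] <- ts; m["G", "A"] <- ts
  m["C", "T"] <- ts; m["T", "C"] <- ts
  m
}

#' Convert a transition:transversion ratio to the shape parameter
#'
#' @param epsilon Transition:transversion ratio, strictly positive.
#' @return `gamma = 3 / (2 * (epsilon + 1))`.
#' @examples
#' gamma_from_epsilon(0.5) # 1: Jukes-Cantor
#' @export
gamma_from_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || any(epsilon <= 0)) stop("epsilon must be > 0")
  3 / (2 * (epsilon + 1))
}

#' Cascade a channel matrix over p generations
#'
#' Matrix power by binary exponentiation in double precision; `p` may be any
#' non-negative whole number (including values such as `1e10` stored as
#' doubles).
#'
#' @param P Square one-generation transition matrix.
#' @param p Number of generations (whole number `>= 0`).
#' @return `P^p`, row-stochastic to near machine precision.
#' @export
channel_power <- function(P, p) {
  if (p < 0 || p %% 1 != 0) stop("p must be a non-negative whole number")
  # row-stochastic inputs are projected back onto the simplex after every
  # product, so rounding drift cannot accumulate over ~log2(p) squarings
  stoch <- all(abs(rowSums(P) - 1) < 1e-9)
  renorm <- function(M) if (stoch) M / rowSums(M) else M
  acc <- diag(nrow(P))
  dimnames(acc) <- dimnames(P)
  base <- P
  while (p > 0) {
    if (p %% 2 == 1) acc <- renorm(acc %*% base)
    p <- p %/% 2
    if (p > 0) base <- renorm(base %*% base)
  }
  acc
}

#' Construct a cascaded Kimura channel
#'
#' @inheritParams kimura_matrix
#' @param epsilon Alternative parameterisation; overrides `gamma` via
#'   [gamma_from_epsilon()] when supplied.
#' @param generations Number of generations `p`.
#' @return Object of class `kimura_channel` with the one-generation matrix
#'   `Pi` and its cascade `Pi_p`.
#' @examples
#' ch <- kimura_channel(q = 1e-8, gamma = 0.1, generations = 1e6)
#' @export
kimura_channel <- function(q, gamma = 1, epsilon = NULL, generations = 1) {
  if (!is.null(epsilon)) gamma <- gamma_from_epsilon(epsilon)
  Pi <- kimura_matrix(q, gamma)
  structure(
    list(q = q, gamma = gamma, generations = generations,
         Pi = Pi, Pi_p = channel_power(Pi, generations)),
    class = "kimura_channel"
  )
}

#' @export
print.kimura_channel <- function(x, ...) {
  cat(sprintf("Kimura channel: q = %g, gamma = %g, p = %g generations\n",
              x$q, x$gamma, x$generations))
  cat(sprintf("  per-base substitution probability after p generations: %.4g\n",
              1 - mean(diag(x$Pi_p))))
  invisible(x)
}

#' Pass a DNA sequence through a substitution channel
#'
#' Each base is replaced independently according to its row of the (cascaded)
#' transition matrix.
#'
#' @param sequence DNA string.
#' @param channel A [kimura_channel()], or a bare 4x4 matrix with A/C/T/G
#'   dimnames interpreted as the full-cascade transition matrix.
#' @param seed Optional integer seed for reproducibility.
#' @return Mutated DNA string of equal length.
#' @export
mutate_sequence <- function(sequence, channel, seed = NULL) {
  P <- if (inherits(channel, "kimura_channel")) channel$Pi_p else channel
  stopifnot(is.matrix(P), nrow(P) == 4L)
  ord <- rownames(P)
  y <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], ord)
  if (anyNA(y)) stop("invalid symbol: alphabet must be A/C/G/T")
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- integer(length(y))
  for (b in 1:4) {
    idx <- which(y == b)
    if (length(idx) > 0L) {
      z[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  paste(ord[z], collapse = "")
}

#' Pass a codon sequence through a substitution channel
#'
#' Convenience wrapper of [mutate_sequence()] for in-frame coding sequences.
#'
#' @param codons Codon vector or in-frame DNA string.
#' @inheritParams mutate_sequence
#' @return Character vector of (possibly mutated) codons.
#' @export
mutate_codons <- function(codons, channel, seed = NULL) {
  codons <- split_codons(codons)
  split_codons(mutate_sequence(paste(codons, collapse = ""), channel, seed))
}
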