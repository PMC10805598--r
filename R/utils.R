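## Internal validators and small helpers shared across modules.

check_simplex <- function(pi, arg = "pi", tol = 1e-8) {
  if (!is.numeric(pi) || length(pi) != 4L) {
    abort(sprintf("`%s` must be a numeric vector of 4 probabilities (A, C, G, T).", arg))
  }
  if (any(pi < -tol) || any(pi > 1 + tol)) {
    abort(sprintf("`%s` has entries outside [0, 1].", arg))
  }
  if (abs(sum(pi) - 1) > 1e-6) {
    abort(sprintf("`%s` must sum to 1 (got %.8f).", arg, sum(pi)))
  }
  pi <- pmin(pmax(as.numeric(pi), 0), 1)
  names(pi) <- NUC
  pi
}

encode_nuc <- function(x) {
  idx <- match(x, NUC)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    abort(sprintf("Non-ACGT symbol(s): %s", paste(bad, collapse = ", ")))
  }
  idx
}

decode_nuc <- function(i) NUC[i]

## Split a nucleotide string into an integer vector (1..4).
seq_to_int <- function(s) encode_nuc(strsplit(s, "", fixed = TRUE)[[1]])

## Row-normalize a non-negative matrix.
normalize_rows <- function(m) {
  sweep(m, 1L, rowSums(m), "/")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

softmax4 <- function(z3) {
  z <- c(z3, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## Kullback-Leibler divergence in bits with 0*log(0) = 0.
kl_bits <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * (log2(p[nz]) - log2(q[nz])))
}

## Jensen-Shannon divergence (base 2) between two probability vectors.
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  0.5 * kl_bits(p, m) + 0.5 * kl_bits(q, m)
}

## Derive a per-stream 31-bit seed from a master seed and a counter, so that
## per-site draws are independent of evaluation order.
substream_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + counter * 16807) %% 2147483647
  as.integer(x)
}
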