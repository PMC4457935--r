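# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package implementations.

# Smith-Waterman-Gotoh score by straightforward full-matrix dynamic
# programming (row-vectorized E and diagonal; sequential scan for the
# reference-consuming gap state). Gap of length L costs open + L * ext.
naive_sw_score <- function(query, reference, match = 2, mismatch = -3,
                           open = -5, ext = -2) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  n <- length(q)
  m <- length(r)
  NEG <- -1e18
  H_prev <- numeric(m)
  E_prev <- rep(NEG, m)
  best <- 0
  for (i in seq_len(n)) {
    s <- ifelse(q[i] == r, match, mismatch)
    E <- pmax(H_prev + open + ext, E_prev + ext)
    diag <- c(0, H_prev[-m]) + s
    H <- numeric(m)
    F_ <- NEG
    for (j in seq_len(m)) {
      F_ <- if (j == 1) NEG else max(F_ + ext, H[j - 1] + open + ext)
      H[j] <- max(0, diag[j], E[j], F_)
    }
    best <- max(best, max(H))
    H_prev <- H
    E_prev <- E
  }
  best
}

# P(all m types seen in n draws) by exhaustive enumeration of all m^n
# draw sequences (tiny m, n only).
brute_force_completion_cdf <- function(m, n) {
  if (n < m) return(0)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  mean(apply(grid, 1, function(x) length(unique(x)) == m))
}

# Same probability by exact Markov-chain power: state = number of types
# collected, absorbing at m.
markov_completion_cdf <- function(m, n) {
  T <- matrix(0, m + 1, m + 1)
  for (k in 0:m) {
    T[k + 1, k + 1] <- k / m
    if (k < m) T[k + 1, k + 2] <- (m - k) / m
  }
  v <- c(1, rep(0, m))
  for (i in seq_len(n)) v <- v %*% T
  v[m + 1]
}

# Substitution-count pmf by convolving per-segment binomial pmfs
# (polynomial multiplication), a different route from the positionwise
# convolution in the package.
convolve_pmf_oracle <- function(segments, max_k) {
  pmfs <- lapply(seq_len(nrow(segments)), function(i) {
    stats::dbinom(0:segments$length_nt[i], segments$length_nt[i],
                  segments$sub_prob[i])
  })
  out <- Reduce(function(a, b) {
    res <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
    }
    res
  }, pmfs)
  out[seq_len(max_k + 1L)]
}

# A fixed scrambled-but-valid CDS for small-region tests.
make_test_region <- function(n_codons = 20L, codon_start = 2L,
                             codon_end = n_codons - 1L, seed = 42L) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  withr::with_seed(seed, {
    target_region(paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
                  codon_start, codon_end)
  })
}
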