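#' Coupon-collector completion draws, Monte Carlo
#'
#' How many uniformly drawn clones does it take to see every one of
#' `n_types` distinct variants at least once? Each trial records that
#' completion count. The simulation uses the exact stage decomposition of the
#' coupon-collector process: after k types are collected the wait for the
#' next new type is geometric with success probability (m - k)/m, and the
#' completion count is the sum of the m independent stage waits. This is
#' distributed identically to drawing coupons one at a time and vectorizes
#' across trials (one million trials over 531 types run in seconds).
#'
#' @param n_types Number of distinct types m (531 single substitutions in the
#'   motivating library).
#' @param n_trials Number of independent trials.
#' @param seed Integer seed (required; the result is reproducible).
#' @return Object of class `completion_distribution`: integer vector `draws`
#'   of length `n_trials`, plus `n_types`, `n_trials`, `seed`.
#' @examples
#' d <- simulate_completion_draws(10, 1000, seed = 1)
#' mean(d$draws)   # ~ 10 * sum(1/(1:10)) = 29.3
#' @export
simulate_completion_draws <- function(n_types, n_trials, seed) {
  n_types <- as.integer(n_types)
  n_trials <- as.integer(n_trials)
  if (is.na(n_types) || n_types < 1L) stop("n_types must be >= 1")
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  stopifnot(!missing(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draws <- rep(n_types, n_trials)  # one success draw per stage
  for (collected in seq_len(n_types) - 1L) {
    p <- (n_types - collected) / n_types
    if (p < 1) draws <- draws + stats::rgeom(n_trials, p)
  }
  structure(list(draws = draws, n_types = n_types, n_trials = n_trials,
                 seed = as.integer(seed)),
            class = "completion_distribution")
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Literal draw-until-complete simulation (small problems)
#'
#' Reference implementation that draws uniform integers one at a time until
#' every type is seen. Used to validate the stage-decomposition simulator;
#' impractical for large `n_types * n_trials`.
#'
#' @inheritParams simulate_completion_draws
#' @return Integer vector of completion counts, one per trial.
#' @export
simulate_completion_draws_naive <- function(n_types, n_trials, seed) {
  if (n_types < 1L || n_trials < 1L) stop("arguments must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vapply(seq_len(n_trials), function(i) {
    seen <- logical(n_types)
    n_seen <- 0L
    draws <- 0L
    while (n_seen < n_types) {
      x <- sample.int(n_types, 1L)
      draws <- draws + 1L
      if (!seen[x]) {
        seen[x] <- TRUE
        n_seen <- n_seen + 1L
      }
    }
    draws
  }, integer(1))
}

#' Exact completion probability by inclusion-exclusion
#'
#' P(all m types seen in n uniform draws) =
#' sum_{k=0..m} (-1)^k C(m,k) (1 - k/m)^n. Terms are computed in log space
#' (lchoose + n*log1p) and accumulated with Kahan compensated summation to
#' control the alternating-sum cancellation; the result is clamped to [0, 1].
#'
#' @param n_types Number of types m (>= 1).
#' @param n_draws Number of draws n (>= 0); vectorized over `n_draws`.
#' @return Probability (vector along `n_draws`).
#' @details When n is only slightly above m the true probability is smaller
#'   than the cancellation noise of the alternating sum (terms up to
#'   exp(max log-magnitude) against a result near 0). That regime is
#'   detected from the largest term magnitude and handled by an exact
#'   forward recursion over the number of collected types, which involves
#'   no cancellation.
#' @examples
#' exact_completion_cdf(2, 2:3)  # 0.50 0.75
#' @export
exact_completion_cdf <- function(n_types, n_draws) {
  m <- as.integer(n_types)
  if (is.na(m) || m < 1L) stop("n_types must be >= 1")
  n_draws <- as.numeric(n_draws)
  if (any(n_draws < 0)) stop("n_draws must be >= 0")
  vapply(n_draws, function(n) {
    if (n < m) return(0)
    k <- 0:(m - 1L)  # the k = m term is (1 - m/m)^n = 0 for n >= m > 0
    logmag <- lchoose(m, k) + n * log1p(-k / m)
    sign <- ifelse(k %% 2L == 0L, 1, -1)
    terms <- sign * exp(logmag)
    # Kahan compensated summation over terms sorted by |magnitude| descending
    ord <- order(logmag, decreasing = TRUE)
    s <- 0
    c_ <- 0
    for (t in terms[ord]) {
      y <- t - c_
      tt <- s + y
      c_ <- (tt - s) - y
      s <- tt
    }
    noise_floor <- exp(max(logmag)) * 1e-13
    if (s < noise_floor) s <- completion_cdf_recursion(m, n)
    min(max(s, 0), 1)
  }, numeric(1))
}

# P(all m types seen in n draws) by forward recursion over the collected-type
# count (no alternating signs, stable down to the double underflow limit)
completion_cdf_recursion <- function(m, n) {
  p <- c(1, numeric(m))  # p[k + 1] = P(k distinct types collected)
  for (i in seq_len(n)) {
    k <- 0:m
    stay <- p * k / m
    advance <- c(0, p[seq_len(m)] * (m - (0:(m - 1L))) / m)
    p <- stay + advance
  }
  p[m + 1L]
}

#' Minimum draws for a stated completion confidence
#'
#' Smallest n such that the probability of having collected all `n_types`
#' variants in n draws is at least `level`. The Monte Carlo method matches
#' the original procedure (run many trials, take the smallest n that at
#' least `level * n_trials` of them complete within); the exact method
#' inverts [exact_completion_cdf()] by bisection.
#'
#' @param n_types Number of types.
#' @param level Confidence level in (0, 1), e.g. 0.90.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_trials Trials for the Monte Carlo method (default 1e6).
#' @param seed Seed for the Monte Carlo method.
#' @return Integer threshold number of draws (clones/colonies).
#' @examples
#' confidence_threshold(10, 0.9, method = "exact")
#' @export
confidence_threshold <- function(n_types, level,
                                 method = c("exact", "monte_carlo"),
                                 n_trials = 1e6, seed = NULL) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1")
  }
  method <- match.arg(method)
  if (method == "monte_carlo") {
    if (is.null(seed)) stop("monte_carlo method requires a seed")
    d <- simulate_completion_draws(n_types, n_trials, seed)
    # smallest n with at least level * n_trials trials completing within n
    return(as.integer(stats::quantile(d$draws, probs = level, type = 1)))
  }
  lo <- n_types
  hi <- max(n_types, ceiling(n_types * (log(n_types) + 10)))
  while (exact_completion_cdf(n_types, hi) < level) hi <- hi * 2L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (exact_completion_cdf(n_types, mid) >= level) hi <- mid else lo <- mid + 1L
  }
  as.integer(lo)
}

#' Gumbel asymptotic for the completion threshold
#'
#' Large-m approximation m log m - m log(-log p) to the level-p completion
#' quantile; agrees with the exact threshold to a fraction of a percent at
#' m = 531.
#'
#' @inheritParams confidence_threshold
#' @return Approximate threshold (not rounded).
#' @export
gumbel_threshold <- function(n_types, level) {
  if (any(level <= 0 | level >= 1)) {
    stop("level must lie strictly between 0 and 1")
  }
  n_types * log(n_types) - n_types * log(-log(level))
}

#' Coverage verdict for a library of a given size
#'
#' @param n_types Number of distinct variants required (531 in the motivating
#'   library).
#' @param n_colonies Number of independently drawn clones available.
#' @param levels Confidence levels to test against.
#' @return List: `probability` (exact completion probability),
#'   `n_colonies`, and logical `meets` per requested level.
#' @examples
#' coverage_report(531, 4565)
#' @export
coverage_report <- function(n_types, n_colonies, levels = c(0.90, 0.95)) {
  if (n_colonies < 0) stop("n_colonies must be >= 0")
  p <- exact_completion_cdf(n_types, n_colonies)
  meets <- stats::setNames(p >= levels, sprintf("level_%g", levels))
  list(probability = p, n_colonies = as.integer(n_colonies), meets = meets)
}

#' Single-mutant colony bookkeeping
#'
#' Number of clones carrying exactly one substitution in a library of
#' `total_colonies` clones of which a fraction `single_fraction` are single
#' mutants (e.g. 27,500 x 16.6% = 4,565).
#'
#' @param total_colonies Total clones pooled.
#' @param single_fraction Fraction that are single mutants.
#' @return Expected single-mutant colony count (rounded to an integer).
#' @export
single_mutant_colonies <- function(total_colonies, single_fraction) {
  if (total_colonies < 0) stop("total_colonies must be >= 0")
  if (single_fraction < 0 || single_fraction > 1) {
    stop("single_fraction must lie in [0, 1]")
  }
  as.integer(round(total_colonies * single_fraction))
}
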