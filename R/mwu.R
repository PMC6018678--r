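#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration (via the Wilcoxon rank-sum distribution) when the
#' smaller sample has at most `exact_max` observations and the pooled data
#' are tie-free; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest min(|x|, |y|) for which the exact null
#'   distribution is used (default 8).
#' @return Two-sided P value.
#' @export
mwu_test <- function(x, y, exact_max = 8) {
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) abort("mwu_test needs non-empty samples")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && min(m, n) <= exact_max) {
    mwu_exact_p(U, m, n)
  } else {
    mwu_approx_p(U, m, n, tie_term = tie_correction(r))
  }
}

# sum(t^3 - t) over tied groups, from pooled ranks
tie_correction <- function(r) {
  tt <- table(r)
  sum(tt^3 - tt)
}

# exact two-sided P for integer U (no ties), mirroring wilcox.test
mwu_exact_p <- function(U, m, n) {
  p <- if (U > m * n / 2) {
    stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
  } else {
    stats::pwilcox(U, m, n)
  }
  min(1, 2 * p)
}

# cached exact two-sided P lookup for all U = 0..m*n at fixed (m, n)
.mwu_cache <- new.env(parent = emptyenv())
mwu_exact_table <- function(m, n) {
  key <- paste0(m, "_", n)
  tab <- .mwu_cache[[key]]
  if (is.null(tab)) {
    U <- 0:(m * n)
    lo <- stats::pwilcox(U, m, n)
    hi <- stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    tab <- pmin(1, 2 * pmin(lo, hi))
    .mwu_cache[[key]] <- tab
  }
  tab
}

# vectorized tie-corrected normal approximation with continuity correction
mwu_approx_p <- function(U, m, n, tie_term = 0) {
  mu <- m * n / 2
  N <- m + n
  sigma <- sqrt((m * n / 12) * ((N + 1) - tie_term / (N * (N - 1))))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma
  pmin(1, 2 * pnorm(-abs(z)))
}

# P values of first-M prefixes of x against reference y, M = 1..length(x).
# Exact path (cached table) where tie-free and M <= exact_max.
mwu_prefix_p <- function(x, y, exact_max = 8) {
  n <- length(y)
  N <- length(x)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties) {
    # U_M accumulates the per-observation counts #(y < x_i)
    u <- findInterval(x, sort(y))
    U <- cumsum(u)
    p <- numeric(N)
    for (M in seq_len(N)) {
      p[M] <- if (M <= exact_max) {
        mwu_exact_table(M, n)[U[M] + 1L]
      } else {
        mwu_approx_p(U[M], M, n)
      }
    }
    p
  } else {
    vapply(seq_len(N), function(M) mwu_test(x[seq_len(M)], y,
                                            exact_max = exact_max), 0)
  }
}
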