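#' Build the quasi-gene false-positive-rate null model
#'
#' Quasi genes are pseudo-genes assembled from randomly drawn
#' negative-control sgRNAs; because the controls have no target, quasi-gene
#' scores trace out the null distribution of the gene score at each subset
#' size. Size 1 enumerates every negative control; for sizes 2..`max_size`,
#' `n_quasi` quasi genes are drawn as nested prefixes of `max_size`
#' distinct controls, so the size-i column is a uniform without-replacement
#' size-i sample and, at the same time, every draw carries its own full
#' adaptive subset-selection trajectory. The model stores, per size, (a)
#' the sorted quasi-gene scores, from which `FPR(lambda)` = fraction of
#' scores above `lambda` is interpolated, and (b) the sorted minima over
#' prefix sizes of those FPR values, which calibrate the adaptive
#' (min-over-M) statistic used in [call_gene()].
#'
#' @param nc_fitness Fitness values of all negative-control sgRNAs
#'   (length >= `max_size`).
#' @param n_quasi Quasi genes per size (default 10000).
#' @param max_size Largest subset size modeled (default 15).
#' @param seed Integer seed.
#' @return A `crispri_null` object.
#' @export
build_fpr_curves <- function(nc_fitness, n_quasi = 10000, max_size = 15,
                             seed = 1L) {
  n_nc <- length(nc_fitness)
  if (max_size > n_nc) abort("max_size exceeds the number of controls")
  set.seed(seed)

  # size-1 curve: every NC singleton
  p1 <- vapply(nc_fitness, function(v) mwu_test(v, nc_fitness), 0)
  s1 <- abs(nc_fitness) * (-log10(p1))

  # nested prefix draws; quasi-gene members always duplicate NC values, so
  # the tie-corrected normal approximation applies throughout (as it would
  # in mwu_test), and both the U statistic and the tie-correction term are
  # computed incrementally so every prefix size is vectorized.
  draws <- t(replicate(n_quasi, sample.int(n_nc, max_size)))
  V <- matrix(nc_fitness[draws], nrow = n_quasi)
  sv <- sort(nc_fitness)
  uv <- unique(sv)
  grp_size <- tabulate(match(nc_fitness, uv))
  t0 <- sum(grp_size^3 - grp_size)
  n_le <- matrix(findInterval(V, sv), nrow = n_quasi)
  n_lt <- matrix(findInterval(V, sv, left.open = TRUE), nrow = n_quasi)
  u <- n_lt + 0.5 * (n_le - n_lt)          # per-member #(nc < x) + 0.5 ties
  U <- t(apply(u, 1, cumsum))
  CV <- matrix(grp_size[match(V, uv)], nrow = n_quasi)
  prev_same <- matrix(0L, n_quasi, max_size) # earlier members, equal value
  for (M in seq_len(max_size)[-1]) {
    for (j in seq_len(M - 1)) {
      prev_same[, M] <- prev_same[, M] + (V[, j] == V[, M])
    }
  }
  tg <- CV + prev_same                      # tie-group size before joining
  delta <- ((tg + 1)^3 - (tg + 1)) - (tg^3 - tg)
  TT <- t0 + t(apply(delta, 1, cumsum))
  S <- matrix(0, n_quasi, max_size)
  for (M in seq_len(max_size)) {
    med <- apply(V[, seq_len(M), drop = FALSE], 1, median)
    p <- mwu_approx_p(U[, M], M, n_nc, tie_term = TT[, M])
    S[, M] <- abs(med) * (-log10(p))
  }
  curves <- c(list(sort(s1)), lapply(2:max_size, function(M) sort(S[, M])))
  # each curve can only resolve tail probabilities down to half a member
  floors <- vapply(curves, function(s) 1 / (2 * length(s)), 0)

  # adaptive null: running minimum of raw FPR along each trajectory
  Fm <- matrix(0, n_quasi, max_size)
  for (M in seq_len(max_size)) {
    Fm[, M] <- fpr_step(S[, M], curves[[M]], floors[M])
  }
  minF <- t(apply(Fm, 1, cummin))
  adaptive <- lapply(seq_len(max_size), function(N) sort(minF[, N]))

  structure(
    list(curves = curves, adaptive = adaptive, n_quasi = n_quasi,
         max_size = max_size, n_nc = n_nc, seed = seed,
         floors = floors, floor_fpr = 1 / (2 * n_quasi)),
    class = "crispri_null"
  )
}

# FPR(lambda) = fraction of sorted (ascending) null scores above lambda,
# linearly interpolated between adjacent scores, clamped to [floor, 1]
fpr_step <- function(score, sorted_scores, floor_fpr) {
  N <- length(sorted_scores)
  ux <- unique(sorted_scores)
  cnt_le <- findInterval(ux, sorted_scores)
  fr <- 1 - cnt_le / N
  if (length(ux) == 1) {
    out <- ifelse(score >= ux, fr, 1)
  } else {
    out <- approx(ux, fr, xout = score, rule = 2)$y
  }
  pmin(1, pmax(out, floor_fpr))
}

#' Interpolated FPR of a gene score under the size-specific null
#'
#' @param null A `crispri_null` from [build_fpr_curves()].
#' @param score Gene score(s) (vectorized).
#' @param size Subset size (1..`max_size`).
#' @return FPR value(s), floored at half a member of the size's curve
#'   (`1/(2 * 400)` for size 1, `1/(2 * n_quasi)` otherwise).
#' @export
fpr_lookup <- function(null, score, size) {
  stopifnot(size >= 1, size <= null$max_size)
  fpr_step(score, null$curves[[size]], null$floors[size])
}

# calibrated tail probability of the adaptive min-over-M FPR statistic:
# fraction of same-size null trajectories with min-FPR <= value
adaptive_fpr <- function(null, min_fpr, size) {
  ss <- null$adaptive[[size]]
  N <- length(ss)
  ux <- unique(ss)
  fr <- findInterval(ux, ss) / N
  out <- if (length(ux) == 1) {
    ifelse(min_fpr >= ux, fr, 0)
  } else {
    approx(ux, fr, xout = min_fpr, rule = 2)$y
  }
  pmin(1, pmax(out, null$floor_fpr))
}

#' @export
print.crispri_null <- function(x, ...) {
  cat("Quasi-gene FPR null model\n")
  cat("  negative controls:", x$n_nc, "\n")
  cat("  quasi genes/size: ", x$n_quasi,
      " (size 1: ", length(x$curves[[1]]), ")\n", sep = "")
  cat("  sizes:             1..", x$max_size, "\n", sep = "")
  invisible(x)
}

#' Per-size summary of a quasi-gene null model
#'
#' @param x A `crispri_null`.
#' @param ... Unused.
#' @return Tibble with one row per subset size: number of quasi genes and
#'   upper quantiles of the null score distribution.
#' @export
tidy.crispri_null <- function(x, ...) {
  bind_rows(lapply(seq_len(x$max_size), function(i) {
    s <- x$curves[[i]]
    tibble(size = i, n_members = length(s),
           score_q50 = quantile(s, 0.5, names = FALSE),
           score_q95 = quantile(s, 0.95, names = FALSE),
           score_q99 = quantile(s, 0.99, names = FALSE))
  }))
}

#' @rdname tidy.crispri_null
#' @export
glance.crispri_null <- function(x, ...) {
  tibble(n_nc = x$n_nc, n_quasi = x$n_quasi, max_size = x$max_size,
         seed = x$seed, floor_fpr = x$floor_fpr)
}
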