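#' Call one gene from its position-sorted sgRNA fitness values
#'
#' Implements the adaptive 5'-proximal subset selection: sgRNAs are taken
#' in order of their position in the ORF, and for every prefix size
#' M = 1..N the gene's median fitness, Mann-Whitney P against the
#' negative controls, score and raw FPR (size-M quasi-gene curve) are
#' computed. The prefix with the smallest raw FPR (ties toward smaller M)
#' supplies the gene's metrics. Because the minimum over M of the raw FPR
#' is not itself uniform under the null, the reported `fpr` is calibrated
#' against the null distribution of the same min-over-M statistic stored
#' in the model; the uncalibrated minimum is kept as `fpr_raw`.
#'
#' @param gene_fitness sgRNA fitness values, sorted by ascending position
#'   within the ORF.
#' @param nc_fitness All negative-control fitness values.
#' @param null A `crispri_null` from [build_fpr_curves()].
#' @return One-row tibble: `n_sgrnas`, `m` (chosen subset size),
#'   `fitness`, `p`, `score`, `fpr_raw`, `fpr`, `direction`.
#' @export
call_gene <- function(gene_fitness, nc_fitness, null) {
  N_all <- length(gene_fitness)
  if (N_all == 0) abort("gene without usable sgRNA fitness")
  N <- N_all
  if (N > null$max_size) {
    warn(paste0("gene has ", N, " sgRNAs; capping subsets at null model",
                " max size ", null$max_size))
    N <- null$max_size
  }
  x <- gene_fitness[seq_len(N)]
  # tie-corrected normal approximation at every size: quasi genes always
  # tie with the control pool, so exact P here would not be comparable to
  # the null curves
  p <- mwu_prefix_p(x, nc_fitness, exact_max = 0)
  med <- vapply(seq_len(N), function(M) median(x[seq_len(M)]), 0)
  score <- abs(med) * (-log10(p))
  fpr_m <- vapply(seq_len(N),
                  function(M) fpr_lookup(null, score[M], M), 0)
  m_star <- which.min(fpr_m)
  tibble(
    n_sgrnas = N_all,
    m = m_star,
    fitness = med[m_star],
    p = p[m_star],
    score = score[m_star],
    fpr_raw = fpr_m[m_star],
    fpr = adaptive_fpr(null, fpr_m[m_star], N),
    direction = ifelse(med[m_star] < 0, "depleted", "enriched")
  )
}

#' Call every gene of a screen
#'
#' @param fitness Tibble from [sgrna_fitness()] (`sgrna`, `fitness`,
#'   `is_nc`).
#' @param library Library tibble ([tidy.crispri_library()] layout:
#'   `name`, `gene`, `p`).
#' @param null A `crispri_null`.
#' @return Tibble with one row per gene (`gene` + [call_gene()] columns),
#'   sorted by `fpr`.
#' @export
call_genes <- function(fitness, library, null) {
  nc_fitness <- fitness$fitness[fitness$is_nc]
  if (length(nc_fitness) == 0) abort("no negative controls in fitness table")
  tab <- fitness |>
    filter(!.data$is_nc) |>
    dplyr::inner_join(select(library, "name", "gene", "p"),
                      by = c(sgrna = "name")) |>
    filter(!is.na(.data$gene)) |>
    arrange(.data$gene, .data$p)
  res <- tab |>
    group_by(.data$gene) |>
    dplyr::group_modify(~ call_gene(.x$fitness, nc_fitness, null)) |>
    ungroup()
  arrange(res, .data$fpr, .data$gene)
}

#' Storey-Tibshirani q-values from FPR values
#'
#' Treats the calibrated FPR values as P values. The null proportion is
#' estimated at lambda = 0.5, `pi0 = min(1, #(fpr > 0.5) / (0.5 m))`, and
#' `q_i = min over fpr_j >= fpr_i of pi0 * m * fpr_j / rank_j`, which makes
#' q monotone in FPR.
#'
#' @param fpr Numeric vector of FPR values in (0, 1].
#' @return q-values in the input order.
#' @export
estimate_qvalues <- function(fpr) {
  m <- length(fpr)
  if (m == 0) return(numeric(0))
  stopifnot(all(fpr > 0), all(fpr <= 1))
  pi0 <- min(1, sum(fpr > 0.5) / (0.5 * m))
  o <- order(fpr)
  q <- pi0 * m * fpr[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Annotate gene results with q-values and hit calls
#'
#' @param results Tibble from [call_genes()].
#' @param fdr Hit threshold on the q-value (default 0.05, strict `<`).
#' @param exclude Optional character vector of gene ids to drop before
#'   q-value estimation (e.g. essential genes from a reference screen via
#'   [essentiality_exclusion()], for phenotype screens where growth genes
#'   would swamp the signal).
#' @return `results` with `q`, `hit` and `no_doubling` columns
#'   (`no_doubling`: fitness at or below -6, the depletion expected of a
#'   gene whose knockdown stops cell division entirely).
#' @export
call_hits <- function(results, fdr = 0.05, exclude = NULL) {
  n_excluded <- 0L
  if (!is.null(exclude)) {
    n_excluded <- sum(results$gene %in% exclude)
    results <- filter(results, !(.data$gene %in% exclude))
  }
  results$q <- estimate_qvalues(results$fpr)
  results$hit <- results$q < fdr
  results$no_doubling <- results$fitness <= -6
  attr(results, "n_excluded") <- n_excluded
  results
}

#' Genes to exclude from downstream screens, from an essentiality run
#'
#' @param results Hit-annotated essentiality results ([call_hits()]
#'   output).
#' @param fitness_max Fitness threshold (default -4).
#' @param fdr_max q-value threshold (default 0.01).
#' @return Character vector of gene ids with
#'   `fitness <= fitness_max & q <= fdr_max`.
#' @export
essentiality_exclusion <- function(results, fitness_max = -4,
                                   fdr_max = 0.01) {
  results$gene[results$fitness <= fitness_max & results$q <= fdr_max]
}
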