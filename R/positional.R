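#' sgRNA activity profile along the ORF
#'
#' Bins sgRNAs by relative position in the coding region (bin width 0.05
#' by default; the first bin is `[0, 0.05]`, later bins half-open) and
#' tests each bin's |Z| distribution against the pooled set with a
#' two-sided Mann-Whitney U test. In tiling screens of genes with real
#' phenotypes, only the bin closest to the start codon shows elevated
#' activity.
#'
#' @param sgrnas Tibble with `relative_position` and `z` columns.
#' @param bin_width Bin width on (0, 1] (default 0.05).
#' @return Tibble per bin: `bin`, `lower`, `upper`, `n`, `median_abs_z`,
#'   `p` (NA for empty bins).
#' @export
position_activity_profile <- function(sgrnas, bin_width = 0.05) {
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  absz <- abs(sgrnas$z)
  idx <- cut(sgrnas$relative_position, breaks, include.lowest = TRUE,
             labels = FALSE)
  out <- lapply(seq_len(length(breaks) - 1), function(b) {
    zb <- absz[!is.na(idx) & idx == b]
    if (length(zb) == 0) {
      tibble(bin = b, lower = breaks[b], upper = breaks[b + 1], n = 0L,
             median_abs_z = NA_real_, p = NA_real_)
    } else {
      tibble(bin = b, lower = breaks[b], upper = breaks[b + 1],
             n = length(zb), median_abs_z = median(zb),
             p = mwu_test(zb, absz))
    }
  })
  bind_rows(out)
}

#' Recompute gene P values on sgRNA subsets of fixed size
#'
#' Used to ask how many sgRNAs per gene a screen needs: for each gene and
#' each size, a subset is chosen either by position (the most 5'-proximal
#' guides) or at random, and the Mann-Whitney P value against the
#' negative controls is recomputed on the subset.
#'
#' @param fitness Tibble from [sgrna_fitness()].
#' @param library Library tibble (`name`, `gene`, `p`).
#' @param sizes Subset sizes (default `c(3, 5, 10, 15, 20, 30)`).
#' @param method `"position"` or `"random"`.
#' @param seed Seed for the random method.
#' @return Tibble `gene`, `size`, `method`, `n_used`, `p`,
#'   `neg_log10_p`, `truncated` (TRUE when the gene had fewer sgRNAs than
#'   the requested size and all were used).
#' @export
subsample_gene_pvalues <- function(fitness, library,
                                   sizes = c(3, 5, 10, 15, 20, 30),
                                   method = c("position", "random"),
                                   seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  nc_fitness <- fitness$fitness[fitness$is_nc]
  tab <- fitness |>
    filter(!.data$is_nc) |>
    dplyr::inner_join(select(library, "name", "gene", "p"),
                      by = c(sgrna = "name")) |>
    filter(!is.na(.data$gene)) |>
    arrange(.data$gene, .data$p)
  out <- list()
  for (g in unique(tab$gene)) {
    x <- tab$fitness[tab$gene == g]
    for (s in sizes) {
      if (s >= length(x)) {
        sub <- x
      } else if (method == "position") {
        sub <- x[seq_len(s)]
      } else {
        sub <- x[sample.int(length(x), s)]
      }
      pv <- mwu_test(sub, nc_fitness)
      out[[length(out) + 1L]] <- tibble(
        gene = g, size = s, method = method, n_used = length(sub),
        p = pv, neg_log10_p = -log10(pv),
        truncated = s > length(x)
      )
    }
  }
  bind_rows(out)
}

#' Resolution limit of a dropout screen
#'
#' The largest depletion (in log2 units) a screen can resolve is capped
#' both by sequencing depth (an sgRNA present at ~`depth` reads can be
#' seen to drop at most `log2(depth)`-fold) and by how many times the
#' bulk culture doubled (a fully arrested clone is diluted 2-fold per
#' doubling).
#'
#' @param median_depth Median reads per sgRNA (> 0).
#' @param doublings Cell doublings during selection (> 0).
#' @return `min(log2(median_depth), doublings)`.
#' @export
resolution_limit <- function(median_depth, doublings) {
  if (median_depth <= 0 || doublings <= 0) {
    abort("median_depth and doublings must be positive")
  }
  min(log2(median_depth), doublings)
}

#' Number of culture doublings between two population sizes
#'
#' @param n_initial,n_final Cell counts (> 0).
#' @return `log2(n_final / n_initial)`.
#' @export
culture_doublings <- function(n_initial, n_final) {
  if (n_initial <= 0 || n_final <= 0) {
    abort("population sizes must be positive")
  }
  log2(n_final / n_initial)
}
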