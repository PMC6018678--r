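#' Compute sgRNA fitness from selective and control counts
#'
#' sgRNA fitness is the log2 ratio of (pseudocounted, depth-normalized)
#' selective to control read counts, centered so the median fitness of the
#' negative-control sgRNAs is exactly zero:
#' `fitness' = log2((sel + 1) / (ctrl + 1))`,
#' `fitness  = fitness' - median(fitness'[NC])`.
#'
#' @param counts Wide count tibble (id column `sgrna` + library columns),
#'   already normalized ([normalize_counts()]) and low-count filtered on
#'   the control/initial library ([filter_low_count()]).
#' @param selective,control Library column names.
#' @param nc_names Character vector of negative-control sgRNA names (must
#'   intersect `counts$sgrna`).
#' @return Tibble `sgrna`, `fitness_raw`, `fitness`, `is_nc`.
#' @export
sgrna_fitness <- function(counts, selective, control, nc_names) {
  if (length(nc_names) == 0) abort("empty negative-control set")
  is_nc <- counts$sgrna %in% nc_names
  if (!any(is_nc)) abort("no negative controls present in count table")
  raw <- log2((counts[[selective]] + 1) / (counts[[control]] + 1))
  centered <- raw - median(raw[is_nc])
  tibble(sgrna = counts$sgrna, fitness_raw = raw, fitness = centered,
         is_nc = is_nc)
}

#' Add activity Z scores to a fitness table
#'
#' The negative-control fitness values are modeled as a normal null; its
#' (sample) standard deviation sigma scales every sgRNA's fitness into a Z
#' score, `Z = fitness / sigma`. An sgRNA with |Z| >= 2 is conventionally
#' called active.
#'
#' @param fitness Tibble from [sgrna_fitness()] (columns `fitness`,
#'   `is_nc`).
#' @return Input with a `z` column added and a `sigma` attribute.
#' @export
z_scores <- function(fitness) {
  nc <- fitness$fitness[fitness$is_nc]
  if (length(nc) < 2) abort("need at least 2 negative controls for sigma")
  sigma <- sd(nc)
  if (sigma == 0) abort("negative-control fitness has zero variance")
  fitness$z <- fitness$fitness / sigma
  attr(fitness, "sigma") <- sigma
  fitness
}

#' Gene score from an sgRNA fitness subset
#'
#' `score = |median(subset)| * (-log10 P)` with P the two-sided
#' Mann-Whitney U P value of the subset against all negative-control
#' fitness values: large effect sizes and strong rank separation both push
#' the score up.
#'
#' @param subset_fitness Fitness values of the sgRNA subset (non-empty).
#' @param nc_fitness Fitness values of all negative controls.
#' @return List with `median`, `p`, `score`.
#' @export
gene_score <- function(subset_fitness, nc_fitness) {
  if (length(subset_fitness) == 0) abort("empty sgRNA subset")
  p <- mwu_test(subset_fitness, nc_fitness)
  med <- median(subset_fitness)
  list(median = med, p = p, score = abs(med) * (-log10(p)))
}

#' @importFrom stats sd
NULL
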