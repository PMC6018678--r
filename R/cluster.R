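#' Cluster genes by sequence similarity
#'
#' Groups genes whose sequences are nearly identical (e.g. duplicated genes,
#' tRNA isoacceptor families, rRNA operon copies) so that a single set of
#' sgRNAs can target every member jointly. Two genes are linked when a
#' pairwise local alignment reaches the identity threshold over at least
#' `coverage` of *both* sequences; clusters are the connected components of
#' this link graph (single linkage). The representative is the longest
#' member, ties broken by lexicographic `gene_id`.
#'
#' @param genes Gene-model tibble (see [read_gene_models()]); requires
#'   `gene_id` and `cds_sequence`.
#' @param identity Minimum fraction of identical positions within the
#'   aligned region (default 0.95).
#' @param coverage Minimum fraction of each sequence covered by the aligned
#'   region (default 0.95).
#' @param cluster_table Optional precomputed tibble/data.frame with columns
#'   `gene_id` and `cluster_id` (e.g. from an external BLASTN run at genome
#'   scale); when supplied, alignment is skipped and representatives are
#'   recomputed from the gene table.
#' @return Tibble with one row per gene: `gene_id`, `cluster_id`,
#'   `representative_id`. Singleton genes form their own cluster, named
#'   after the gene.
#' @export
cluster_genes <- function(genes, identity = 0.95, coverage = 0.95,
                          cluster_table = NULL) {
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), cluster_id = character(),
                  representative_id = character()))
  }
  if (any(nchar(genes$cds_sequence) == 0)) {
    abort("zero-length gene sequence")
  }
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1)
  n <- nrow(genes)
  if (is.null(cluster_table)) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    lens <- nchar(genes$cds_sequence)
    if (n > 1) {
      seqs <- Biostrings::DNAStringSet(genes$cds_sequence)
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          # cheap guard: length ratio already breaks mutual coverage
          if (min(lens[i], lens[j]) < coverage * max(lens[i], lens[j])) next
          if (genes_linked(seqs[[i]], seqs[[j]], identity, coverage)) {
            parent[find(i)] <- find(j)
          }
        }
      }
    }
    comp <- vapply(seq_len(n), find, 0L)
  } else {
    cluster_table <- as_tibble(cluster_table)
    idx <- match(genes$gene_id, cluster_table$gene_id)
    if (anyNA(idx)) abort("cluster_table does not cover all genes")
    comp <- match(cluster_table$cluster_id[idx],
                  unique(cluster_table$cluster_id[idx]))
  }
  out <- genes["gene_id"]
  out$.comp <- comp
  out$.len <- nchar(genes$cds_sequence)
  out <- out |>
    group_by(.data$.comp) |>
    mutate(
      representative_id =
        .data$gene_id[order(-.data$.len, .data$gene_id)][1],
      cluster_id = .data$representative_id
    ) |>
    ungroup() |>
    select("gene_id", "cluster_id", "representative_id")
  out
}

# single pairwise link test: local alignment identity + mutual coverage
genes_linked <- function(si, sj, identity, coverage) {
  aln <- Biostrings::pairwiseAlignment(
    si, sj,
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE
    ),
    gapOpening = 5, gapExtension = 2
  )
  aw <- Biostrings::nchar(aln)
  if (aw == 0) return(FALSE)
  ident <- Biostrings::nmatch(aln) / aw
  cov_i <- Biostrings::width(Biostrings::pattern(aln)) / length(si)
  cov_j <- Biostrings::width(Biostrings::subject(aln)) / length(sj)
  ident >= identity && cov_i >= coverage && cov_j >= coverage
}
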