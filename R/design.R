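#' Design negative-control sgRNAs with no genomic target
#'
#' Rejection-samples random 20-mers until `n` spacers are found that pass
#' the GC filter and have *zero* candidate off-target sites (NGG or NAG
#' PAM, up to `params$max_mismatch` mismatches) anywhere in the genome on
#' either strand. These no-target controls define the null fitness
#' distribution of the screen.
#'
#' @param genome A [Biostrings::DNAStringSet] (or character vector).
#' @param params A [design_params()] list; uses `n_negative_controls`,
#'   `gc_min`, `gc_max`, `max_mismatch` and `seed`.
#' @param n Number of controls (default `params$n_negative_controls`).
#' @param max_attempts Sampling budget per control (default 1e6).
#' @return Tibble with `name` (`NC_1` ...), `spacer`, `gc_fraction`.
#' @export
design_negative_controls <- function(genome, params = design_params(),
                                     n = params$n_negative_controls,
                                     max_attempts = 1e6) {
  set.seed(params$seed)
  spacers <- character(0)
  attempts <- 0L
  while (length(spacers) < n) {
    if (attempts >= max_attempts) {
      abort(paste0("negative-control sampling exhausted its budget of ",
                   format(max_attempts, scientific = FALSE),
                   " attempts per control (",
                   length(spacers), "/", n, " found)"))
    }
    attempts <- attempts + 1L
    cand <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
    gc <- gc_fraction(cand)
    if (gc < params$gc_min || gc > params$gc_max) next
    if (cand %in% spacers) next
    sites <- find_offtarget_sites(cand, genome,
                                  max_mismatch = params$max_mismatch)
    if (nrow(sites) > 0) next
    spacers <- c(spacers, cand)
    attempts <- 0L
  }
  tibble(name = paste0("NC_", seq_len(n)), spacer = spacers,
         gc_fraction = gc_fraction(spacers))
}

#' Design an sgRNA library from a genome and annotation
#'
#' Runs the full design workflow: cluster near-identical genes so their
#' shared sgRNAs are treated as intended targets; enumerate candidates on
#' each cluster representative (dropping candidates whose target site is
#' not an exact substring of every member); filter on GC content and on the
#' region-weighted off-target penalty; select up to `max_per_gene` guides
#' per cluster (tiling or genome mode, see [select_sgrnas()]); and append
#' negative controls.
#'
#' @param genome A [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param genes Gene-model tibble from [read_gene_models()] /
#'   [attach_gene_sequences()], or a path to a GFF3 file.
#' @param params A [design_params()] list.
#' @param clusters Optional precomputed cluster tibble (`gene_id`,
#'   `cluster_id`), passed to [cluster_genes()].
#' @param sublibrary_map Optional tibble (`cluster_id`, `sublibrary`);
#'   unmapped clusters get `"sublib_1"`.
#' @return A `crispri_library` object: list with `sgrnas` (selected
#'   guides), `candidates` (every enumerated candidate with its `status`:
#'   kept / rejected_gc / rejected_offtarget / not_selected),
#'   `negative_controls`, `per_gene_counts`, `clusters` and `params`.
#'   `tidy()` flattens it to the analysis-ready library table.
#' @export
design_library <- function(genome, genes, params = design_params(),
                           clusters = NULL, sublibrary_map = NULL) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
  }
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    genes <- read_gene_models(genes, genome)
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicated gene_ids in annotation")
  missing_chr <- setdiff(unique(genes$chromosome), names(genome))
  if (length(missing_chr)) {
    abort(paste0("annotation references absent chromosome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  cl <- cluster_genes(genes, identity = params$cluster_identity,
                      coverage = params$cluster_coverage,
                      cluster_table = clusters)
  genes <- left_join(genes, cl, by = "gene_id")

  all_cand <- list()
  selected <- list()
  for (cid in unique(genes$cluster_id)) {
    members <- filter(genes, .data$cluster_id == cid)
    rep_gene <- filter(members,
                       .data$gene_id == members$representative_id[1])
    cand <- enumerate_candidates(rep_gene)
    if (nrow(cand) == 0) {
      next
    }
    cand$cluster_id <- cid
    # multi-member clusters: the targeted 23-mer region (coding strand,
    # CC + downstream 21 nt) must appear verbatim in every member
    if (nrow(members) > 1) {
      region <- substring(rep_gene$cds_sequence, cand$p - 1L, cand$p + 21L)
      ok <- rep(TRUE, nrow(cand))
      for (m in seq_len(nrow(members))) {
        if (members$gene_id[m] == rep_gene$gene_id) next
        ok <- ok & vapply(region, function(r) {
          grepl(r, members$cds_sequence[m], fixed = TRUE)
        }, TRUE, USE.NAMES = FALSE)
      }
      cand <- cand[ok, ]
      if (nrow(cand) == 0) next
    }
    cand$status <- vapply(seq_len(nrow(cand)), function(i) {
      gc <- cand$gc_fraction[i]
      if (gc < params$gc_min || gc > params$gc_max) return("rejected_gc")
      sites <- find_offtarget_sites(cand$spacer[i], genome,
                                    max_mismatch = params$max_mismatch)
      off <- !on_target_site(sites, members)
      candidate_status(gc, sites$penalty[off], params)
    }, "")
    keep <- filter(cand, .data$status == "kept")
    sel <- select_sgrnas(keep, params)
    cand$status[cand$status == "kept" & !(cand$name %in% sel$name)] <-
      "not_selected"
    all_cand[[cid]] <- cand
    if (nrow(sel) > 0) selected[[cid]] <- sel
  }
  candidates <- bind_rows(all_cand)
  sgrnas <- bind_rows(selected)
  if (nrow(sgrnas) > 0 && anyDuplicated(sgrnas$name)) {
    abort("duplicate sgRNA names in design")
  }
  if (nrow(sgrnas) > 0) {
    if (is.null(sublibrary_map)) {
      sgrnas$sublibrary <- "sublib_1"
    } else {
      sgrnas <- left_join(sgrnas,
                          as_tibble(sublibrary_map)[c("cluster_id",
                                                      "sublibrary")],
                          by = "cluster_id")
      sgrnas$sublibrary[is.na(sgrnas$sublibrary)] <- "sublib_1"
    }
  }
  ncontrols <- design_negative_controls(genome, params)
  counts <- cl |>
    dplyr::distinct(.data$cluster_id) |>
    left_join(
      if (nrow(sgrnas)) dplyr::count(sgrnas, .data$cluster_id)
      else tibble(cluster_id = character(), n = integer()),
      by = "cluster_id"
    ) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(
    list(sgrnas = sgrnas, candidates = candidates,
         negative_controls = ncontrols, per_gene_counts = counts,
         clusters = cl, params = params),
    class = "crispri_library"
  )
}

# TRUE for rows of `sites` that are intended targets: perfect matches whose
# 23-mer lies inside a cluster member's annotated span
on_target_site <- function(sites, members) {
  if (nrow(sites) == 0) return(logical(0))
  vapply(seq_len(nrow(sites)), function(i) {
    if (sites$n_mismatch[i] != 0L) return(FALSE)
    any(members$chromosome == sites$chromosome[i] &
          members$start <= sites$position[i] &
          members$end >= sites$position[i] + 22L)
  }, TRUE)
}

#' @export
print.crispri_library <- function(x, ...) {
  cat("CRISPRi sgRNA library (", x$params$mode, " mode)\n", sep = "")
  cat("  clusters:          ",
      length(unique(x$clusters$cluster_id)), "\n", sep = "")
  cat("  selected sgRNAs:   ", nrow(x$sgrnas), "\n", sep = "")
  cat("  negative controls: ", nrow(x$negative_controls), "\n", sep = "")
  invisible(x)
}

#' Flatten a library design to the analysis-ready guide table
#'
#' @param x A `crispri_library`.
#' @param ... Unused.
#' @return Tibble with `name`, `gene` (cluster id, `NA` for negative
#'   controls), `spacer`, `p`, `relative_position`, `gc_fraction`,
#'   `is_nc`.
#' @export
tidy.crispri_library <- function(x, ...) {
  g <- x$sgrnas
  if (nrow(g) == 0) {
    g <- tibble(name = character(), gene = character(), spacer = character(),
                p = integer(), relative_position = double(),
                gc_fraction = double())
  } else {
    g <- tibble(name = g$name, gene = g$cluster_id, spacer = g$spacer,
                p = g$p, relative_position = g$relative_position,
                gc_fraction = g$gc_fraction)
  }
  nc <- x$negative_controls
  bind_rows(
    mutate(g, is_nc = FALSE),
    tibble(name = nc$name, gene = NA_character_, spacer = nc$spacer,
           p = NA_integer_, relative_position = NA_real_,
           gc_fraction = nc$gc_fraction, is_nc = TRUE)
  )
}

#' Per-gene coverage summary of a library design
#'
#' @param x A `crispri_library`.
#' @param ... Unused.
#' @return One-row tibble: number of clusters, clusters with at least 1
#'   and at least 3 sgRNAs, selected guides, negative controls.
#' @export
glance.crispri_library <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$per_gene_counts),
    n_ge1 = sum(x$per_gene_counts$n >= 1),
    n_ge3 = sum(x$per_gene_counts$n >= 3),
    n_sgrnas = nrow(x$sgrnas),
    n_negative_controls = nrow(x$negative_controls)
  )
}

#' Write library design artifacts to a directory
#'
#' Emits `library.tsv` (the tidy guide table), `candidates.tsv` (all
#' enumerated candidates with status), `per_gene_counts.tsv`, and
#' `oligos.fasta` where each spacer is embedded in the fixed cloning
#' cassette `GCAC<spacer>GTTT`.
#'
#' @param x A `crispri_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tidy(x)
  utils::write.table(tab, file.path(dir, "library.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cand <- x$candidates
  if (nrow(cand)) {
    utils::write.table(select(cand, -dplyr::any_of("mismatch_positions")),
                       file.path(dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(x$per_gene_counts, file.path(dir, "per_gene_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  oligo <- Biostrings::DNAStringSet(paste0("GCAC", tab$spacer, "GTTT"))
  names(oligo) <- tab$name
  Biostrings::writeXStringSet(oligo, file.path(dir, "oligos.fasta"))
  invisible(dir)
}

#' Read an analysis-ready library table from TSV
#'
#' @param path TSV written by [write_library()] (`library.tsv`), or any
#'   table with at least `name`, `spacer` and `gene` columns.
#' @return Tibble in the [tidy.crispri_library()] layout.
#' @export
read_library <- function(path) {
  tab <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE,
                                     na.strings = "NA"))
  if (!"is_nc" %in% names(tab)) tab$is_nc <- is.na(tab$gene)
  tab
}
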