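#' Enumerate all sgRNA candidates targeting the non-template strand
#'
#' CRISPRi silences a gene efficiently only when the sgRNA base-pairs with
#' the non-template (coding-sense) strand, which requires the protospacer
#' and its NGG PAM to lie on the template strand. On the coding sequence
#' this shows up as a `CC` dinucleotide: for every `CC` at coding positions
#' (p-1, p) with 2 <= p <= L-21 the candidate spacer is the reverse
#' complement of `cds[p+2 .. p+21]`. Candidates are named `gene_p`, where p
#' is the coding coordinate of the 5'-most G of the template-strand PAM.
#'
#' @param gene One-row gene-model tibble (or a list) with `gene_id` and
#'   `cds_sequence`.
#' @return Tibble of candidates ordered by ascending `p`: `name`,
#'   `gene_id`, `p`, `spacer`, `relative_position` (p / L) and
#'   `gc_fraction`. Genes shorter than 23 nt yield an empty tibble with a
#'   `too_short` attribute.
#' @export
enumerate_candidates <- function(gene) {
  cds <- gene$cds_sequence[[1]]
  id <- gene$gene_id[[1]]
  L <- nchar(cds)
  empty <- tibble(name = character(), gene_id = character(), p = integer(),
                  spacer = character(), relative_position = double(),
                  gc_fraction = double())
  if (L < 23L) {
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  # CC at (p-1, p): find "CC" starts s, then p = s + 1
  starts <- unlist(gregexpr("(?=CC)", cds, perl = TRUE))
  starts <- starts[starts > 0]
  p <- starts + 1L
  p <- p[p >= 2L & p <= L - 21L]
  if (length(p) == 0) return(empty)
  spacer <- revcomp(substring(cds, p + 2L, p + 21L))
  tibble(
    name = paste0(id, "_", p),
    gene_id = id,
    p = as.integer(p),
    spacer = spacer,
    relative_position = p / L,
    gc_fraction = gc_fraction(spacer)
  )
}

#' Classify a candidate sgRNA as kept or rejected
#'
#' A candidate fails the GC filter when its spacer GC fraction falls outside
#' `[gc_min, gc_max]` (bounds inclusive). Otherwise it fails the off-target
#' filter when any site other than a designated on-target site has penalty
#' strictly below `offtarget_threshold` (low penalty = dangerous site).
#'
#' @param gc Spacer GC fraction.
#' @param site_penalties Penalties of all candidate off-target sites that
#'   are *not* intended targets (on-target exact matches inside the
#'   candidate's own gene cluster must be removed by the caller before the
#'   call; see [design_library()]).
#' @param params A [design_params()] list.
#' @return One of `"kept"`, `"rejected_gc"`, `"rejected_offtarget"`.
#' @export
candidate_status <- function(gc, site_penalties, params) {
  if (gc < params$gc_min || gc > params$gc_max) return("rejected_gc")
  if (length(site_penalties) &&
      any(site_penalties < params$offtarget_threshold)) {
    return("rejected_offtarget")
  }
  "kept"
}

#' Select sgRNAs for one gene from its kept candidates
#'
#' Tiling mode walks the ORF 5'->3' and takes the first `max_per_gene` kept
#' candidates. Genome mode first takes every kept candidate in the "active"
#' region (relative position <= `active_fraction`, most 5'-proximal first,
#' capped at `max_per_gene`); if x < `max_per_gene` were found there, the
#' remaining `max_per_gene - x` are drawn from the downstream candidates at
#' evenly spaced rank quantiles of their position order - a deterministic
#' stand-in for "uniform" coverage of the rest of the ORF.
#'
#' @param kept Tibble of kept candidates for a single gene, with `p` and
#'   `relative_position`.
#' @param params A [design_params()] list.
#' @return The selected rows, ordered by ascending `p`.
#' @export
select_sgrnas <- function(kept, params) {
  kept <- arrange(kept, .data$p)
  k <- params$max_per_gene
  if (nrow(kept) == 0) return(kept)
  if (params$mode == "tiling") {
    return(head(kept, k))
  }
  active <- filter(kept, .data$relative_position <= params$active_fraction)
  if (nrow(active) >= k) return(head(active, k))
  rest <- filter(kept, .data$relative_position > params$active_fraction)
  need <- k - nrow(active)
  if (nrow(rest) <= need) return(bind_rows(active, rest))
  idx <- round(seq(1, nrow(rest), length.out = need))
  bind_rows(active, rest[idx, ])
}

#' Design parameters for an sgRNA library
#'
#' Bundles the tunable rules of library design. Defaults follow the mode:
#' tiling libraries (dense coverage of a few genes) use up to 50 sgRNAs per
#' gene and a permissive off-target threshold of 11; genome-scale libraries
#' use at most 15 sgRNAs per gene and a stricter threshold of 21 (a larger
#' threshold rejects more candidates, because sites *below* threshold are
#' significant).
#'
#' @param mode `"genome"` or `"tiling"`.
#' @param max_per_gene Maximum sgRNAs per gene cluster (default 15 genome /
#'   50 tiling).
#' @param offtarget_threshold Off-target significance threshold (default 21
#'   genome / 11 tiling).
#' @param gc_min,gc_max Inclusive spacer GC bounds (defaults 0.30, 0.85).
#' @param active_fraction 5'-proximal fraction of the ORF treated as the
#'   high-activity region in genome mode (default 0.05).
#' @param cluster_identity,cluster_coverage Gene-clustering thresholds
#'   (defaults 0.95).
#' @param n_negative_controls Number of no-target control spacers
#'   (default 400).
#' @param max_mismatch Off-target search mismatch tolerance (default 5).
#' @param seed Integer seed for the negative-control sampler.
#' @return Named list of validated parameters.
#' @export
design_params <- function(mode = c("genome", "tiling"),
                          max_per_gene = NULL,
                          offtarget_threshold = NULL,
                          gc_min = 0.30, gc_max = 0.85,
                          active_fraction = 0.05,
                          cluster_identity = 0.95,
                          cluster_coverage = 0.95,
                          n_negative_controls = 400,
                          max_mismatch = 5,
                          seed = 1L) {
  mode <- match.arg(mode)
  max_per_gene <- max_per_gene %||% if (mode == "genome") 15L else 50L
  offtarget_threshold <-
    offtarget_threshold %||% if (mode == "genome") 21 else 11
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1)) {
    abort("need 0 <= gc_min < gc_max <= 1")
  }
  if (offtarget_threshold <= 0) abort("offtarget_threshold must be > 0")
  list(mode = mode, max_per_gene = as.integer(max_per_gene),
       offtarget_threshold = offtarget_threshold,
       gc_min = gc_min, gc_max = gc_max,
       active_fraction = active_fraction,
       cluster_identity = cluster_identity,
       cluster_coverage = cluster_coverage,
       n_negative_controls = as.integer(n_negative_controls),
       max_mismatch = as.integer(max_mismatch),
       seed = as.integer(seed))
}
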