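#' Region-weighted off-target penalty for a candidate site
#'
#' The 20-nt protospacer is split by distance to the PAM into Region III
#' (spacer positions 1-8, 5' end), Region II (positions 9-13) and Region I
#' (positions 14-20, PAM-proximal). Each mismatch contributes the penalty of
#' its region: 2.5 / 4.5 / 8 (Regions III/II/I) for an NGG PAM, 3 / 7 / 10
#' for NAG, and 100 per mismatch for any other PAM class. A site whose
#' summed penalty falls *below* the design threshold is considered a
#' significant off-target and the sgRNA is rejected: PAM-proximal
#' mismatches, which CRISPRi tolerates poorly, are the ones that weigh
#' enough to push a site above threshold ("safe").
#'
#' @param pam_class `"NGG"`, `"NAG"` or `"other"`.
#' @param mismatch_positions Integer vector of spacer coordinates (1 = 5'
#'   end, 20 = PAM-proximal) at which the site differs from the spacer; may
#'   be empty (a perfect match scores 0).
#' @return Single non-negative penalty.
#' @examples
#' offtarget_penalty("NGG", c(20, 19, 10)) # 8 + 8 + 4.5 = 20.5
#' offtarget_penalty("NGG", c(14, 1))      # 8 + 2.5 = 10.5
#' @export
offtarget_penalty <- function(pam_class, mismatch_positions = integer()) {
  pam_class <- match.arg(pam_class, c("NGG", "NAG", "other"))
  mm <- as.integer(mismatch_positions)
  if (length(mm) && (any(mm < 1L) || any(mm > 20L))) {
    abort("mismatch positions must lie in 1..20")
  }
  if (length(mm) == 0) return(0)
  if (pam_class == "other") return(100 * length(mm))
  w <- if (pam_class == "NGG") c(2.5, 4.5, 8) else c(3, 7, 10)
  region <- ifelse(mm <= 8L, 1L, ifelse(mm <= 13L, 2L, 3L))
  sum(w[region])
}

#' Find candidate off-target sites of a spacer in a genome
#'
#' Scans both strands of every chromosome for 23-mers of the form
#' N20-NGG or N20-NAG whose 20-mer prefix differs from `spacer` at no more
#' than `max_mismatch` positions, and scores each with
#' [offtarget_penalty()]. Ambiguity codes (N) in the genome mismatch every
#' spacer base and cannot form a PAM.
#'
#' @param spacer 20-nt spacer sequence (character, 5'->3').
#' @param genome A [Biostrings::DNAStringSet] (or a plain character vector
#'   of chromosome sequences, which will be converted).
#' @param max_mismatch Maximum protospacer mismatches (default 5).
#' @return Tibble with one row per site: `chromosome`, `position` (1-based,
#'   leftmost base of the 23-mer on the plus strand), `strand`, `pam_class`,
#'   `n_mismatch`, `mismatch_positions` (list column of spacer coordinates)
#'   and `penalty`.
#' @export
find_offtarget_sites <- function(spacer, genome, max_mismatch = 5) {
  stopifnot(nchar(spacer) == 20L)
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
  }
  spacer_chars <- strsplit(spacer, "")[[1]]
  rc_spacer <- revcomp(spacer)
  rc_chars <- strsplit(rc_spacer, "")[[1]]
  out <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    L <- length(subject)
    chr_str <- as.character(subject)
    # plus strand: spacer..PAM reads left to right
    hits <- Biostrings::matchPattern(spacer, subject,
                                     max.mismatch = max_mismatch)
    for (s in Biostrings::start(hits)) {
      if (s + 22L > L) next
      pam <- substr(chr_str, s + 20L, s + 22L)
      pc <- pam_class_of(pam)
      if (is.na(pc)) next
      site <- substr(chr_str, s, s + 19L)
      mm <- which(strsplit(site, "")[[1]] != spacer_chars)
      if (length(mm) > max_mismatch) next
      out[[length(out) + 1L]] <- list(chromosome = chrom, position = s,
                                      strand = "+", pam_class = pc, mm = mm)
    }
    # minus strand: plus-strand text holds revcomp(PAM) then revcomp(spacer)
    hits <- Biostrings::matchPattern(rc_spacer, subject,
                                     max.mismatch = max_mismatch)
    for (s in Biostrings::start(hits)) {
      if (s - 3L < 1L) next
      pam <- revcomp(substr(chr_str, s - 3L, s - 1L))
      pc <- pam_class_of(pam)
      if (is.na(pc)) next
      site <- substr(chr_str, s, s + 19L)
      mm_rc <- which(strsplit(site, "")[[1]] != rc_chars)
      if (length(mm_rc) > max_mismatch) next
      mm <- sort(21L - mm_rc)
      out[[length(out) + 1L]] <- list(chromosome = chrom, position = s - 3L,
                                      strand = "-", pam_class = pc, mm = mm)
    }
  }
  if (length(out) == 0) {
    return(tibble(chromosome = character(), position = integer(),
                  strand = character(), pam_class = character(),
                  n_mismatch = integer(),
                  mismatch_positions = list(), penalty = double()))
  }
  tibble(
    chromosome = vapply(out, `[[`, "", "chromosome"),
    position = vapply(out, `[[`, 0L, "position"),
    strand = vapply(out, `[[`, "", "strand"),
    pam_class = vapply(out, `[[`, "", "pam_class"),
    n_mismatch = vapply(out, function(x) length(x$mm), 0L),
    mismatch_positions = lapply(out, `[[`, "mm"),
    penalty = vapply(out, function(x) offtarget_penalty(x$pam_class, x$mm), 0)
  )
}

pam_class_of <- function(pam) {
  suffix <- substr(pam, 2L, 3L)
  if (suffix == "GG") "NGG" else if (suffix == "AG") "NAG" else NA_character_
}
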