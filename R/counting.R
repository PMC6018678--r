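#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (optionally gzipped). Phred+33 qualities.
#' @return Tibble with `id`, `bases`, `qualities` (quality string).
#' @export
read_fastq <- function(path) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(paste0("malformed FASTQ '", path, "': ", conditionMessage(e)))
    }
  )
  quals <- S4Vectors::mcols(reads)$qualities
  tibble(id = names(reads) %||% as.character(seq_along(reads)),
         bases = unname(as.character(reads)),
         qualities = unname(as.character(quals)))
}

#' Quality-filter and end-trim screen reads
#'
#' Applies, in order: (1) drop reads longer than `max_length` nucleotides;
#' (2) trim from both ends every base with quality below `trim_quality`;
#' (3) keep a read only if, after trimming, it has no base below Q10, more
#' than 85% of bases at or above Q20 and more than 60% at or above Q30.
#'
#' @param reads Tibble from [read_fastq()] (columns `bases`, `qualities`).
#' @param max_length Maximum read length before trimming (default 194).
#' @param trim_quality End-trimming threshold (default 25).
#' @param min_q20,min_q30 Strict lower bounds on the fraction of bases at
#'   Q>=20 / Q>=30 (defaults 0.85, 0.60).
#' @return The surviving reads (trimmed), with a `counts` attribute
#'   recording how many reads each step removed.
#' @export
quality_filter <- function(reads, max_length = 194, trim_quality = 25,
                           min_q20 = 0.85, min_q30 = 0.60) {
  n_in <- nrow(reads)
  stopifnot(all(nchar(reads$bases) == nchar(reads$qualities)))
  keep_len <- nchar(reads$bases) <= max_length
  reads <- reads[keep_len, ]
  q <- lapply(reads$qualities, function(s) utf8ToInt(s) - 33L)
  bases <- reads$bases
  out_bases <- character(nrow(reads))
  out_quals <- character(nrow(reads))
  ok <- logical(nrow(reads))
  for (i in seq_along(q)) {
    qi <- q[[i]]
    good <- which(qi >= trim_quality)
    if (length(good) == 0) next
    i1 <- good[1]; i2 <- good[length(good)]
    qt <- qi[i1:i2]
    if (sum(qt < 10L) >= 1L) next
    if (mean(qt >= 20L) <= min_q20) next
    if (mean(qt >= 30L) <= min_q30) next
    ok[i] <- TRUE
    out_bases[i] <- substr(bases[i], i1, i2)
    out_quals[i] <- substr(reads$qualities[i], i1, i2)
  }
  res <- reads[ok, ]
  res$bases <- out_bases[ok]
  res$qualities <- out_quals[ok]
  attr(res, "counts") <- c(
    input = n_in,
    removed_too_long = n_in - sum(keep_len),
    removed_quality = sum(keep_len) - sum(ok),
    output = sum(ok)
  )
  res
}

#' Extract 20-nt spacers from reads carrying the cloning cassette
#'
#' Searches each read for the 28-mer `GCAC` + N20 + `GTTT` with exact
#' flanks, first in forward orientation and then on the reverse complement;
#' the first occurrence wins. Reads with any substitution in a flank (and
#' no intact cassette elsewhere) yield no spacer.
#'
#' @param reads Tibble with a `bases` column, or a character vector.
#' @return Character vector of spacers, `NA` where no intact cassette was
#'   found.
#' @export
extract_spacers <- function(reads) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  pat <- "GCAC[ACGT]{20}GTTT"
  pos <- regexpr(pat, bases)
  spacer <- ifelse(pos > 0, substr(bases, pos + 4L, pos + 23L), NA_character_)
  miss <- is.na(spacer)
  if (any(miss)) {
    rc <- revcomp(bases[miss])
    pos2 <- regexpr(pat, rc)
    spacer[miss] <- ifelse(pos2 > 0, substr(rc, pos2 + 4L, pos2 + 23L),
                           NA_character_)
  }
  hit <- which(!is.na(spacer) & pos > 0)
  if (length(hit)) {
    second <- regexpr(pat, substr(bases[hit], pos[hit] + 28L,
                                  nchar(bases[hit])))
    n_multi <- sum(second > 0)
    if (n_multi > 0) {
      warn(paste0(n_multi, " read(s) contained multiple cassettes; ",
                  "the first occurrence was used"))
    }
  }
  spacer
}

#' Count extracted spacers against a designed library
#'
#' Exact-match counting: a spacer increments the count of the library
#' member with the identical 20-mer; anything else is tallied as unmapped.
#'
#' @param spacers Character vector (possibly with `NA`s) from
#'   [extract_spacers()].
#' @param library Library tibble with unique `name` and `spacer` columns.
#' @return Tibble `name`, `count` covering every library member (zeros
#'   included), with attributes `mapping_ratio` (mapped / non-NA spacers;
#'   `NA` when nothing was extracted) and `n_unmapped`.
#' @export
count_spacers <- function(spacers, library) {
  if (anyDuplicated(library$spacer)) abort("library spacers must be unique")
  spacers <- spacers[!is.na(spacers)]
  idx <- match(spacers, library$spacer)
  counts <- tabulate(idx, nbins = nrow(library))
  out <- tibble(name = library$name, count = as.integer(counts))
  attr(out, "mapping_ratio") <-
    if (length(spacers)) sum(!is.na(idx)) / length(spacers) else NA_real_
  attr(out, "n_unmapped") <- sum(is.na(idx))
  out
}

#' Count a set of FASTQ files into an sgRNA count table
#'
#' Convenience wrapper: quality-filter, extract and count each FASTQ into
#' one column of a wide count table.
#'
#' @param fastq_paths Named character vector of FASTQ paths; names become
#'   library labels.
#' @param library Library tibble (`name`, `spacer`).
#' @param ... Passed to [quality_filter()].
#' @return Wide count tibble (`sgrna` + one column per library) with a
#'   `qc` attribute (per-library tibble of filter and mapping statistics).
#' @export
count_screen <- function(fastq_paths, library, ...) {
  labels <- names(fastq_paths) %||% paste0("lib", seq_along(fastq_paths))
  out <- tibble(sgrna = library$name)
  qc <- list()
  for (i in seq_along(fastq_paths)) {
    reads <- read_fastq(fastq_paths[[i]])
    filt <- quality_filter(reads, ...)
    sp <- extract_spacers(filt)
    cc <- count_spacers(sp, library)
    out[[labels[i]]] <- cc$count
    qc[[i]] <- tibble(library = labels[i],
                      reads_in = nrow(reads),
                      reads_pass = nrow(filt),
                      spacers_extracted = sum(!is.na(sp)),
                      mapping_ratio = attr(cc, "mapping_ratio"))
  }
  attr(out, "qc") <- bind_rows(qc)
  out
}

#' Normalize library read counts to a common depth
#'
#' Each library's counts are divided by its normalization factor
#' `total_i / mean(total)`, so every normalized library sums to the mean of
#' the original totals. Idempotent.
#'
#' @param counts Wide count tibble: an id column (`sgrna` or first
#'   non-numeric column) plus one numeric column per library.
#' @return Tibble of the same shape with normalized counts and a
#'   `normalization_factors` attribute.
#' @export
normalize_counts <- function(counts) {
  libs <- names(counts)[vapply(counts, is.numeric, TRUE)]
  totals <- vapply(counts[libs], sum, 0)
  if (any(totals <= 0)) abort("library with zero total read count")
  factors <- totals / mean(totals)
  for (j in seq_along(libs)) {
    counts[[libs[j]]] <- counts[[libs[j]]] / unname(factors[j])
  }
  attr(counts, "normalization_factors") <- setNames(factors, libs)
  counts
}

#' Remove sgRNAs with too few reads in a reference library
#'
#' @param counts Wide count tibble.
#' @param reference Name of the reference (initial or control-condition)
#'   library column.
#' @param min_reads Strict threshold: rows with `reference < min_reads` are
#'   dropped (default 20; a row at exactly 20 is kept).
#' @return Filtered tibble.
#' @export
filter_low_count <- function(counts, reference, min_reads = 20) {
  if (!reference %in% names(counts)) {
    abort(paste0("reference library '", reference, "' not in count table"))
  }
  counts[counts[[reference]] >= min_reads, ]
}

#' Combine two replicate count tables by the geometric mean
#'
#' Entrywise `sqrt(a * b)`; a zero in either replicate gives zero.
#'
#' @param table_a,table_b Wide count tibbles with identical id columns and
#'   library columns in the same order.
#' @return Combined tibble.
#' @export
combine_replicates <- function(table_a, table_b) {
  libs <- names(table_a)[vapply(table_a, is.numeric, TRUE)]
  libs_b <- names(table_b)[vapply(table_b, is.numeric, TRUE)]
  id <- setdiff(names(table_a), libs)
  if (!identical(dim(table_a), dim(table_b)) ||
      !identical(table_a[id], table_b[id]) ||
      length(libs) != length(libs_b)) {
    abort("replicate tables have mismatched rows or columns")
  }
  out <- table_a
  for (j in seq_along(libs)) {
    out[[libs[j]]] <- sqrt(table_a[[libs[j]]] * table_b[[libs_b[j]]])
  }
  out
}
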