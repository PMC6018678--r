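qstr <- function(qs) intToUtf8(qs + 33L)
read_tbl <- function(bases, quals) {
  tibble::tibble(id = paste0("r", seq_along(bases)), bases = bases,
                 qualities = quals)
}

test_that("quality filtering drops, trims and thresholds as specified", {
  reads <- read_tbl(
    c(strrep("A", 150),                 # clean
      strrep("A", 200),                 # too long
      paste0("GG", strrep("A", 96), "GG"), # low-quality ends, clean core
      strrep("A", 100),                 # interior Q5 after trimming
      strrep("A", 100)),                # fails Q30 fraction
    c(qstr(rep(40, 150)),
      qstr(rep(40, 200)),
      qstr(c(10, 10, rep(40, 96), 10, 10)),
      qstr(c(rep(40, 50), 5, rep(40, 49))),
      qstr(c(rep(40, 60), rep(25, 40))))
  )
  out <- quality_filter(reads)
  expect_equal(out$id, c("r1", "r3"))
  expect_equal(out$bases[2], strrep("A", 96))   # ends trimmed
  expect_equal(nchar(out$qualities[2]), 96)
  cnt <- attr(out, "counts")
  expect_equal(unname(cnt["removed_too_long"]), 1L)
  expect_equal(unname(cnt["output"]), 2L)
  # Q30 boundary: exactly 60% at Q>=30 fails the strict > 0.60 rule
  expect_equal(mean(utf8ToInt(reads$qualities[5]) - 33 >= 30), 0.6)
})

test_that("a read of exactly 194 nt passes the length gate", {
  reads <- read_tbl(strrep("A", 194), qstr(rep(40, 194)))
  expect_equal(nrow(quality_filter(reads)), 1L)
})

test_that("spacer extraction honors exact flanks and orientation", {
  spacer <- "ACGTACGTACGTACGTACGT"
  fwd <- paste0("TTTTT", "GCAC", spacer, "GTTT", "AAAAA")
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  flank_mut <- sub("GCAC", "GCAA", fwd)
  expect_equal(extract_spacers(c(fwd, rev, flank_mut)),
               c(spacer, spacer, NA))
})

test_that("multiple cassettes take the first with a warning", {
  s1 <- strrep("A", 20)
  s2 <- strrep("C", 20)
  read <- paste0("GCAC", s1, "GTTT", "GG", "GCAC", s2, "GTTT")
  expect_warning(out <- extract_spacers(read), "multiple cassettes")
  expect_equal(out, s1)
})

test_that("counting is exact-match only, zeros included", {
  lib <- tibble::tibble(name = c("a", "b", "c"),
                        spacer = c(strrep("A", 20), strrep("C", 20),
                                   strrep("G", 20)))
  spacers <- c(rep(strrep("A", 20), 3), strrep("C", 20),
               paste0(strrep("A", 19), "T"), NA)
  out <- count_spacers(spacers, lib)
  expect_equal(out$count, c(3L, 1L, 0L))
  expect_equal(attr(out, "mapping_ratio"), 4 / 5)
  expect_equal(attr(out, "n_unmapped"), 1L)
  empty <- count_spacers(character(), lib)
  expect_equal(empty$count, c(0L, 0L, 0L))
  expect_true(is.na(attr(empty, "mapping_ratio")))
  expect_error(count_spacers("x", tibble::tibble(name = c("a", "b"),
                                                 spacer = rep(strrep("A", 20), 2))),
               "unique")
})

test_that("normalization equalizes library totals and is idempotent", {
  counts <- tibble::tibble(sgrna = c("a", "b"),
                           lib1 = c(40, 60), lib2 = c(100, 200))
  norm <- normalize_counts(counts)
  expect_equal(attr(norm, "normalization_factors"),
               c(lib1 = 0.5, lib2 = 1.5))
  expect_equal(sum(norm$lib1), 200)
  expect_equal(sum(norm$lib2), 200)
  norm2 <- normalize_counts(norm)
  expect_equal(norm2$lib1, norm$lib1, tolerance = 1e-12)
  one <- normalize_counts(tibble::tibble(sgrna = "a", lib1 = 7))
  expect_equal(one$lib1, 7)
  expect_error(normalize_counts(tibble::tibble(sgrna = "a", lib1 = 0)),
               "zero total")
})

test_that("equalized totals hold on random tables to 1e-9", {
  set.seed(61)
  counts <- tibble::tibble(sgrna = paste0("s", 1:50))
  for (j in 1:4) counts[[paste0("lib", j)]] <- rpois(50, 80 * j)
  norm <- normalize_counts(counts)
  totals <- colSums(norm[-1])
  expect_equal(unname(totals), rep(mean(colSums(counts[-1])), 4),
               tolerance = 1e-9)
})

test_that("low-count filtering is strict at the threshold", {
  counts <- tibble::tibble(sgrna = c("a", "b", "c"),
                           initial = c(19, 20, 500), sel = c(1, 2, 3))
  out <- filter_low_count(counts, "initial")
  expect_equal(out$sgrna, c("b", "c"))
  all_ok <- filter_low_count(counts[2:3, ], "initial")
  expect_equal(nrow(all_ok), 2L)
  # monotone: smaller min_reads never removes more
  expect_gte(nrow(filter_low_count(counts, "initial", 10)),
             nrow(filter_low_count(counts, "initial", 20)))
  expect_error(filter_low_count(counts, "nope"), "not in count table")
})

test_that("replicates combine by the geometric mean with a hard zero", {
  a <- tibble::tibble(sgrna = c("x", "y", "z"), lib = c(100, 0, 7))
  b <- tibble::tibble(sgrna = c("x", "y", "z"), lib = c(400, 50, 7))
  out <- combine_replicates(a, b)
  expect_equal(out$lib, c(200, 0, 7))
  expect_error(combine_replicates(a, b[c(2, 1, 3), ]), "mismatched")
})

test_that("simulated reads round-trip to the exact planted count matrix", {
  lib <- simulate_library(8, 5, n_nc = 10, seed = 71)
  counts <- tibble::tibble(sgrna = lib$name,
                           n = rpois(nrow(lib), 30))
  reads <- simulate_reads(counts, lib, seed = 72)
  filtered <- quality_filter(reads)
  expect_equal(nrow(filtered), sum(counts$n))
  got <- count_spacers(extract_spacers(filtered), lib)
  expect_identical(got$count, as.integer(counts$n))
  expect_equal(attr(got, "mapping_ratio"), 1)
})

test_that("fastq files survive a write/read cycle", {
  lib <- simulate_library(2, 3, n_nc = 2, seed = 73)
  counts <- tibble::tibble(sgrna = lib$name, n = rep(2L, nrow(lib)))
  reads <- simulate_reads(counts, lib, seed = 74)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$bases, reads$bases)
  expect_equal(back$qualities, reads$qualities)
  expect_error(read_fastq(tempfile()), "malformed|cannot|exist")
})

test_that("count_screen assembles a labeled table with QC", {
  lib <- simulate_library(4, 4, n_nc = 4, seed = 75)
  c1 <- tibble::tibble(sgrna = lib$name, n = rpois(nrow(lib), 20))
  c2 <- tibble::tibble(sgrna = lib$name, n = rpois(nrow(lib), 20))
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(c1, lib, seed = 76), f1)
  write_fastq(simulate_reads(c2, lib, seed = 77), f2)
  tab <- count_screen(c(ctrl = f1, sel = f2), lib)
  expect_equal(names(tab), c("sgrna", "ctrl", "sel"))
  expect_identical(tab$ctrl, as.integer(c1$n))
  expect_identical(tab$sel, as.integer(c2$n))
  qc <- attr(tab, "qc")
  expect_equal(qc$mapping_ratio, c(1, 1))
})
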