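test_that("simulated genomes carry extractable, non-overlapping ORFs", {
  sim <- simulate_genome_annotation(20, gene_length_range = c(300, 900),
                                    seed = 141)
  g <- sim$genes
  expect_equal(nrow(g), 20L)
  expect_true(all(g$end >= g$start))
  o <- order(g$start)
  expect_true(all(g$start[o][-1] > g$end[o][-20])) # no overlap
  # re-extracting from the chromosome must reproduce cds_sequence
  re <- attach_gene_sequences(g[setdiff(names(g), "cds_sequence")],
                              sim$genome)
  expect_equal(re$cds_sequence, g$cds_sequence)
  expect_true(all(substr(g$cds_sequence, 1, 3) == "ATG"))
  ends <- substring(g$cds_sequence, nchar(g$cds_sequence) - 2)
  expect_true(all(ends %in% c("TAA", "TAG", "TGA")))
})

test_that("duplicated gene pairs cluster as designed", {
  sim <- simulate_genome_annotation(12, n_duplicate_pairs = 2, seed = 142)
  cl <- cluster_genes(sim$genes)
  sizes <- table(table(cl$cluster_id))
  expect_equal(unname(sizes[["2"]]), 2L)   # exactly two 2-member clusters
  expect_equal(unname(sizes[["1"]]), 8L)
})

test_that("genome simulation is byte-deterministic and bounded", {
  a <- simulate_genome_annotation(5, seed = 143)
  b <- simulate_genome_annotation(5, seed = 143)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  expect_error(
    simulate_genome_annotation(10, gene_length_range = c(600, 900),
                               seed = 144, chromosome_length = 1000),
    "cannot be placed"
  )
})

test_that("fasta/gff output round-trips through the genome readers", {
  sim <- simulate_genome_annotation(6, seed = 145)
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  write_genome_annotation(sim, fa, gff)
  genome <- read_genome(fa)
  expect_equal(as.character(genome), as.character(sim$genome),
               ignore_attr = TRUE)
  genes <- read_gene_models(gff, genome)
  genes <- genes[match(sim$genes$gene_id, genes$gene_id), ]
  expect_equal(genes$cds_sequence, sim$genes$cds_sequence)
  expect_equal(genes$strand, sim$genes$strand)
})

test_that("null screens center sgRNA fitness at zero", {
  lib <- simulate_library(50, 10, n_nc = 100, seed = 146)
  truth <- simulation_truth(lib, seed = 147)
  fit <- simulate_screen_fitness(lib, truth, depth = 100, seed = 148)
  x <- fit$fitness[!fit$is_nc]
  # gene fitness is centered on the control median, so its offset is the
  # sampling error of that median (~1.25 sd / sqrt(n_nc))
  tol <- 3 * 1.2533 * sd(fit$fitness[fit$is_nc]) / sqrt(sum(fit$is_nc))
  expect_lt(abs(median(x)), tol + 0.01)
  expect_lt(abs(mean(x)), tol + 0.05)
})

test_that("planted effects at full activity are recovered in sgRNA fitness", {
  lib <- simulate_library(30, 10, n_nc = 200, seed = 149)
  truth <- simulation_truth(lib, c(g0001 = -6), activity = "uniform",
                            seed = 150)
  fit <- simulate_screen_fitness(lib, truth, depth = 400, seed = 151)
  hit <- fit$fitness[fit$sgrna %in% lib$name[!lib$is_nc &
                                               lib$gene == "g0001"]]
  expect_lt(abs(median(hit) + 6), 1)
  # bias bound for the round-trip contract
  expect_lt(abs(median(hit) - (-6)), 0.5)
})

test_that("doubling the sequencing depth roughly halves fitness variance", {
  lib <- simulate_library(40, 5, n_nc = 150, seed = 152)
  truth <- simulation_truth(lib, seed = 153)
  var_at <- function(depth) {
    v <- vapply(1:6, function(s) {
      fit <- simulate_screen_fitness(lib, truth, depth = depth,
                                     seed = 160 + s)
      var(fit$fitness)
    }, 0)
    mean(v)
  }
  v1 <- var_at(50)
  v2 <- var_at(200)   # 4x depth -> ~4x smaller variance
  expect_gt(v1 / v2, 2)
  expect_lt(v1 / v2, 8)
  expect_error(simulate_screen_counts(truth, depth = 0), "positive")
})

test_that("read simulation respects cassette geometry and error flags", {
  lib <- simulate_library(3, 4, n_nc = 3, seed = 154)
  counts <- tibble::tibble(sgrna = lib$name, n = rep(3L, nrow(lib)))
  expect_error(simulate_reads(counts, lib, read_length = 20), "too short")
  reads <- simulate_reads(counts, lib, read_length = 60, seed = 155)
  expect_true(all(nchar(reads$bases) == 60))
  sp <- extract_spacers(reads)
  expect_true(all(!is.na(sp)))
  # forcing errors into the upstream flank removes those reads
  broken <- reads
  broken$bases <- sub("GCAC", "GCAT", broken$bases)
  recovered <- extract_spacers(broken)
  # reverse-orientation reads are untouched by the forward substitution
  expect_lt(sum(!is.na(recovered)), nrow(broken))
  expect_error(simulate_reads(tibble::tibble(sgrna = lib$name[1], n = 1.5),
                              lib), "integral")
})

test_that("orientation mixing does not change counts", {
  lib <- simulate_library(5, 4, n_nc = 5, seed = 156)
  counts <- tibble::tibble(sgrna = lib$name, n = rpois(nrow(lib), 15))
  reads <- simulate_reads(counts, lib, seed = 157)
  got <- count_spacers(extract_spacers(reads), lib)
  expect_identical(got$count, as.integer(counts$n))
})

test_that("transposon tables avoid essential bodies and are deterministic", {
  sim <- simulate_genome_annotation(10, seed = 158)
  glen <- Biostrings::width(sim$genome)[1]
  ess <- sim$genes$gene_id[c(2, 5)]
  ins <- simulate_tn_insertions(sim$genes, glen, density = 1 / 40,
                                essential_ids = ess, seed = 159)
  expect_equal(anyDuplicated(ins$position), 0L)
  expect_true(!is.unsorted(ins$position))
  for (i in c(2, 5)) {
    expect_equal(sum(ins$position >= sim$genes$start[i] &
                       ins$position <= sim$genes$end[i]), 0L)
  }
  ins2 <- simulate_tn_insertions(sim$genes, glen, density = 1 / 40,
                                 essential_ids = ess, seed = 159)
  expect_identical(ins, ins2)
  expect_error(simulate_tn_insertions(sim$genes, glen, density = 0),
               "positive")
})

test_that("simulated libraries have the analysis-ready layout", {
  lib <- simulate_library(7, 9, n_nc = 13, gene_length = 600,
                          n_active = 3, seed = 161)
  expect_equal(sum(!lib$is_nc), 63L)
  expect_equal(sum(lib$is_nc), 13L)
  expect_equal(anyDuplicated(lib$spacer), 0L)
  per_gene <- table(lib$gene[!lib$is_nc])
  expect_true(all(per_gene == 9))
  active <- lib$relative_position[!lib$is_nc] <= 0.05
  expect_equal(sum(active) / 7, 3)
  expect_identical(lib, simulate_library(7, 9, n_nc = 13,
                                         gene_length = 600,
                                         n_active = 3, seed = 161))
})
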