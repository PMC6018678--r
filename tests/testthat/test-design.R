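# independent reference implementation of per-gene design used as oracle
bf_design_gene <- function(gene, members, chroms, params) {
  cds <- gene$cds_sequence
  L <- nchar(cds)
  if (L < 23) return(character(0))
  ch <- strsplit(cds, "")[[1]]
  sel <- list()
  for (p in 2:(L - 21)) {
    if (!(ch[p - 1] == "C" && ch[p] == "C")) next
    region <- substr(cds, p - 1, p + 21)
    if (!all(vapply(members$cds_sequence,
                    function(s) grepl(region, s, fixed = TRUE), TRUE))) next
    spacer <- chartr("ACGT", "TGCA",
                     paste(rev(strsplit(substr(cds, p + 2, p + 21),
                                        "")[[1]]), collapse = ""))
    gc <- mean(strsplit(spacer, "")[[1]] %in% c("G", "C"))
    if (gc < params$gc_min || gc > params$gc_max) next
    sites <- bf_offtarget_sites(spacer, chroms, params$max_mismatch)
    if (nrow(sites)) {
      on_target <- sites$n_mismatch == 0 &
        vapply(seq_len(nrow(sites)), function(i) {
          any(members$chromosome == sites$chromosome[i] &
                members$start <= sites$position[i] &
                members$end >= sites$position[i] + 22)
        }, TRUE)
      if (any(sites$penalty[!on_target] < params$offtarget_threshold)) next
    }
    sel[[length(sel) + 1L]] <- data.frame(p = p, rel = p / L)
  }
  if (!length(sel)) return(character(0))
  kept <- do.call(rbind, sel)
  kept <- kept[order(kept$p), ]
  k <- params$max_per_gene
  if (params$mode == "tiling") {
    chosen <- utils::head(kept$p, k)
  } else {
    act <- kept$p[kept$rel <= params$active_fraction]
    if (length(act) >= k) {
      chosen <- utils::head(act, k)
    } else {
      rest <- kept$p[kept$rel > params$active_fraction]
      need <- k - length(act)
      if (length(rest) <= need) {
        chosen <- c(act, rest)
      } else {
        chosen <- c(act, rest[round(seq(1, length(rest),
                                        length.out = need))])
      }
    }
  }
  paste0(gene$gene_id, "_", chosen)
}

test_that("library design reproduces a brute-force reference, gene by gene", {
  sim <- simulate_genome_annotation(6, gene_length_range = c(150, 300),
                                    seed = 41)
  params <- design_params("genome", n_negative_controls = 5, seed = 5)
  lib <- design_library(sim$genome, sim$genes, params)
  chroms <- stats::setNames(as.character(sim$genome), names(sim$genome))
  cl <- cluster_genes(sim$genes)
  genes <- dplyr::left_join(sim$genes, cl, by = "gene_id")
  for (cid in unique(genes$cluster_id)) {
    members <- genes[genes$cluster_id == cid, ]
    rep_gene <- members[members$gene_id == members$representative_id[1], ]
    want <- bf_design_gene(rep_gene, members, chroms, params)
    got <- lib$sgrnas$name[lib$sgrnas$cluster_id == cid]
    expect_equal(sort(got), sort(want), info = cid)
  }
  # tiling mode too
  params_t <- design_params("tiling", n_negative_controls = 5, seed = 5)
  lib_t <- design_library(sim$genome, sim$genes, params_t)
  for (cid in unique(genes$cluster_id)) {
    members <- genes[genes$cluster_id == cid, ]
    rep_gene <- members[members$gene_id == members$representative_id[1], ]
    want <- bf_design_gene(rep_gene, members, chroms, params_t)
    got <- lib_t$sgrnas$name[lib_t$sgrnas$cluster_id == cid]
    expect_equal(sort(got), sort(want), info = cid)
  }
})

test_that("library-wide invariants hold and degenerate genes are tolerated", {
  sim <- simulate_genome_annotation(5, gene_length_range = c(150, 250),
                                    seed = 42)
  # append a gene too short to host any guide
  tiny_start <- 3L
  sim$genes <- dplyr::bind_rows(sim$genes, tibble::tibble(
    gene_id = "tiny", chromosome = "chr1", start = tiny_start,
    end = tiny_start + 20L, strand = "+", biotype = "protein_coding",
    cds_sequence = substr(as.character(sim$genome[[1]]), tiny_start,
                          tiny_start + 20L)
  ))
  params <- design_params("genome", n_negative_controls = 8, seed = 2)
  lib <- design_library(sim$genome, sim$genes, params)
  expect_equal(anyDuplicated(lib$sgrnas$name), 0L)
  counts <- table(lib$sgrnas$cluster_id)
  expect_true(all(counts <= params$max_per_gene))
  expect_equal(lib$per_gene_counts$n[lib$per_gene_counts$cluster_id ==
                                       "tiny"], 0L)
  expect_true(all(lib$sgrnas$gc_fraction >= 0.30 &
                    lib$sgrnas$gc_fraction <= 0.85))
  tab <- tidy(lib)
  expect_true(all(c("name", "gene", "spacer", "p", "relative_position",
                    "is_nc") %in% names(tab)))
  expect_equal(sum(tab$is_nc), 8L)
  g <- glance(lib)
  expect_equal(g$n_clusters, 6L)
})

test_that("cluster members constrain candidates to shared target sites", {
  sim <- simulate_genome_annotation(4, gene_length_range = c(200, 300),
                                    n_duplicate_pairs = 1, seed = 43)
  params <- design_params("genome", n_negative_controls = 5, seed = 9)
  lib <- design_library(sim$genome, sim$genes, params)
  cl <- lib$clusters
  dup_cluster <- names(which(table(cl$cluster_id) == 2))
  expect_length(dup_cluster, 1)
  members <- sim$genes$cds_sequence[
    sim$genes$gene_id %in% cl$gene_id[cl$cluster_id == dup_cluster]]
  picked <- lib$sgrnas[lib$sgrnas$cluster_id == dup_cluster, ]
  for (i in seq_len(nrow(picked))) {
    protospacer_region <- vapply(members, function(m) {
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(picked$spacer[i]))), m, fixed = TRUE)
    }, TRUE)
    expect_true(all(protospacer_region))
  }
})

test_that("annotation errors are caught", {
  sim <- simulate_genome_annotation(3, gene_length_range = c(150, 200),
                                    seed = 44)
  bad <- sim$genes
  bad$chromosome[2] <- "chrX"
  expect_error(design_library(sim$genome, bad, design_params()),
               "absent chromosome")
  dup <- sim$genes
  dup$gene_id[2] <- dup$gene_id[1]
  expect_error(design_library(sim$genome, dup, design_params()),
               "duplicated gene_id")
})

test_that("negative controls are target-free, GC-bounded and deterministic", {
  set.seed(51)
  genome <- c(chr1 = random_genome_string(5000))
  params <- design_params("genome", n_negative_controls = 25, seed = 77)
  nc <- design_negative_controls(genome, params)
  expect_equal(nrow(nc), 25L)
  expect_equal(nc$name, paste0("NC_", 1:25))
  expect_equal(anyDuplicated(nc$spacer), 0L)
  expect_true(all(nc$gc_fraction >= 0.30 & nc$gc_fraction <= 0.85))
  for (sp in nc$spacer) {
    expect_equal(nrow(bf_offtarget_sites(sp, genome, 5)), 0L)
  }
  nc2 <- design_negative_controls(genome, params)
  expect_identical(nc, nc2)
})

test_that("an exhausted sampling budget is reported as such", {
  genome <- c(chr1 = random_genome_string(2000))
  # GC window so narrow that random 20-mers essentially never qualify
  params <- design_params("genome", gc_min = 0.96, gc_max = 1,
                          n_negative_controls = 5, seed = 1)
  expect_error(design_negative_controls(genome, params,
                                        max_attempts = 500),
               "budget")
})
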