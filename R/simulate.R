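#' Simulate a random genome with annotated ORFs
#'
#' Builds a single random chromosome containing `n_genes` non-overlapping
#' ORFs (ATG ... stop, no internal stop codons on the coding frame),
#' separated by random intergenic spacers and placed on both strands.
#' Optionally the last `2 * n_duplicate_pairs` genes are near-identical
#' pairs (>= 99% identity) to exercise gene clustering. Deterministic
#' under `seed`.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Two-element range of gene lengths in nt
#'   (rounded to codons; default `c(300, 900)`).
#' @param gc GC content of random sequence in (0, 1) (default 0.5).
#' @param n_duplicate_pairs Number of duplicated gene pairs (default 0).
#' @param seed Integer seed.
#' @param intergenic_range Range of intergenic spacer lengths (default
#'   `c(50, 150)`).
#' @param chromosome_length Optional fixed chromosome length; an error is
#'   raised when the genes cannot be placed within it.
#' @return List with `genome` (a one-chromosome
#'   [Biostrings::DNAStringSet] named `chr1`) and `genes` (gene-model
#'   tibble as from [read_gene_models()]).
#' @export
simulate_genome_annotation <- function(n_genes,
                                       gene_length_range = c(300, 900),
                                       gc = 0.5,
                                       n_duplicate_pairs = 0,
                                       seed = 1L,
                                       intergenic_range = c(50, 150),
                                       chromosome_length = NULL) {
  stopifnot(n_genes >= 1, gc > 0, gc < 1,
            2 * n_duplicate_pairs <= n_genes)
  set.seed(seed)
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rand_seq <- function(n) {
    paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs),
          collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  rand_orf <- function(len) {
    n_codon <- max(3L, round(len / 3))
    body <- character(n_codon - 2L)
    for (i in seq_along(body)) {
      repeat {
        cd <- rand_seq(3)
        if (!cd %in% stops) break
      }
      body[i] <- cd
    }
    paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
  }
  lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                 n_genes, replace = TRUE)
  seqs <- vapply(lens, rand_orf, "")
  if (n_duplicate_pairs > 0) {
    for (k in seq_len(n_duplicate_pairs)) {
      i <- n_genes - 2 * n_duplicate_pairs + 2 * k - 1L
      j <- i + 1L
      # copy with ~0.5% substitutions outside start/stop codons
      s <- strsplit(seqs[i], "")[[1]]
      n_sub <- max(1L, round(0.005 * length(s)))
      at <- sample(4:(length(s) - 3), n_sub)
      for (a in at) s[a] <- sample(setdiff(c("A", "C", "G", "T"), s[a]), 1)
      seqs[j] <- paste(s, collapse = "")
    }
  }
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  pieces <- character(2 * n_genes + 1)
  start <- integer(n_genes)
  end <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    gap <- sample(seq(intergenic_range[1], intergenic_range[2]), 1)
    pieces[2 * i - 1] <- rand_seq(gap)
    pos <- pos + gap
    genomic <- if (strands[i] == "+") seqs[i] else revcomp(seqs[i])
    pieces[2 * i] <- genomic
    start[i] <- pos + 1L
    end[i] <- pos + nchar(genomic)
    pos <- end[i]
  }
  tail_gap <- sample(seq(intergenic_range[1], intergenic_range[2]), 1)
  pieces[2 * n_genes + 1] <- rand_seq(tail_gap)
  pos <- pos + tail_gap
  if (!is.null(chromosome_length) && pos > chromosome_length) {
    abort(paste0("genes cannot be placed without overlap within ",
                 chromosome_length, " bp (need ", pos, ")"))
  }
  chrom <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chr1"
  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    chromosome = "chr1",
    start = start, end = end, strand = strands,
    biotype = "protein_coding",
    cds_sequence = seqs
  )
  list(genome = genome, genes = genes)
}

#' Write a simulated genome to FASTA and GFF3
#'
#' @param sim List from [simulate_genome_annotation()].
#' @param fasta,gff Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome_annotation <- function(sim, fasta, gff) {
  Biostrings::writeXStringSet(sim$genome, fasta)
  g <- sim$genes
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tcrisprikit\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
            g$chromosome, g$start, g$end, g$strand, g$gene_id, g$gene_id)
  )
  writeLines(lines, gff)
  invisible(list(fasta = fasta, gff = gff))
}

#' Ground-truth table for a simulated screen
#'
#' Assigns each library sgRNA a true gene effect (log2 depletion over the
#' screen; 0 for unperturbed genes and all negative controls) and an
#' activity in `[0, 1]`; the expected log2 change of an sgRNA is
#' `activity * effect`. Activities default to a broad Beta(2,2) draw, with
#' a strongly right-skewed Beta(6,1) draw inside the 5'-proximal 5% of the
#' ORF: guides near the start codon are not just somewhat better but
#' mostly near-fully active, mirroring the enhanced-activity window seen
#' in tiling screens.
#'
#' @param library Library tibble ([tidy.crispri_library()] layout).
#' @param gene_effects Named numeric vector of true effects per gene
#'   (genes not named get 0).
#' @param activity `"heterogeneous"` (Beta draws) or `"uniform"` (all 1).
#' @param shape Beta shape parameters for downstream sgRNAs (default
#'   `c(2, 2)`).
#' @param active_shape Beta shapes inside the active region (default
#'   `c(6, 1)`, median ~0.89: most guides near the start codon repress
#'   almost fully, which is what lets strong knockdowns of essential genes
#'   reach the screen's resolution limit).
#' @param seed Integer seed.
#' @return `library` with `effect` and `activity` columns added.
#' @export
simulation_truth <- function(library, gene_effects = NULL,
                             activity = c("heterogeneous", "uniform"),
                             shape = c(2, 2), active_shape = c(6, 1),
                             seed = 1L) {
  activity <- match.arg(activity)
  set.seed(seed)
  eff <- rep(0, nrow(library))
  if (!is.null(gene_effects)) {
    idx <- match(library$gene, names(gene_effects))
    eff <- ifelse(is.na(idx), 0, gene_effects[idx])
  }
  eff[library$is_nc] <- 0
  act <- if (activity == "uniform") {
    rep(1, nrow(library))
  } else {
    in_active <- !is.na(library$relative_position) &
      library$relative_position <= 0.05
    ifelse(in_active,
           rbeta(nrow(library), active_shape[1], active_shape[2]),
           rbeta(nrow(library), shape[1], shape[2]))
  }
  act[library$is_nc] <- 0
  library$effect <- unname(eff)
  library$activity <- act
  library
}

#' Simulate pooled-screen count tables
#'
#' Initial sgRNA abundances are drawn log-uniformly within a `skew`-fold
#' range; the selective-condition abundance of each sgRNA is its initial
#' abundance times `2^(activity * effect)` (negative effects deplete).
#' Read counts for the control and selective libraries of each replicate
#' are independent multinomial draws of `depth * n_sgrnas` total reads
#' from the respective abundance vectors. An optional Dirichlet
#' overdispersion adds extra-multinomial noise.
#'
#' @param truth Tibble from [simulation_truth()] (`name`, `effect`,
#'   `activity`).
#' @param depth Mean reads per sgRNA per library (> 0; default 100).
#' @param n_replicates Number of replicates (default 2).
#' @param skew Fold-range of initial abundances (default 10).
#' @param overdispersion Dirichlet noise level, 0 = pure multinomial.
#' @param seed Integer seed.
#' @return Wide count tibble: `sgrna` plus columns `control_r` /
#'   `selective_r` per replicate r; the initial abundances are attached as
#'   attribute `abundance`.
#' @export
simulate_screen_counts <- function(truth, depth = 100, n_replicates = 2,
                                   skew = 10, overdispersion = 0,
                                   seed = 1L) {
  if (depth <= 0) abort("depth must be positive")
  set.seed(seed)
  n <- nrow(truth)
  total <- round(depth * n)
  init <- skew^runif(n) # log-uniform in [1, skew]
  sel <- init * 2^(truth$activity * truth$effect)
  draw <- function(ab) {
    pr <- ab / sum(ab)
    if (overdispersion > 0) {
      g <- stats::rgamma(n, shape = pr / overdispersion)
      pr <- g / sum(g)
    }
    as.integer(rmultinom(1, total, pr))
  }
  out <- tibble(sgrna = truth$name)
  for (r in seq_len(n_replicates)) {
    out[[paste0("control_", r)]] <- draw(init)
    out[[paste0("selective_", r)]] <- draw(sel)
  }
  attr(out, "abundance") <- init
  out
}

#' Simulate error-free (or noisy) screen reads from counts
#'
#' Every read embeds the cassette `GCAC<spacer>GTTT` at a random offset in
#' random orientation, padded with random bases; substitution errors are
#' added at `error_rate` per base.
#'
#' @param counts Tibble with `sgrna` and exactly one integer count column
#'   (or a named integer vector).
#' @param library Library tibble (`name`, `spacer`).
#' @param error_rate Per-base substitution probability (default 0).
#' @param read_length Read length (must fit the 28-nt cassette).
#' @param quality_char Phred+33 quality character for all bases (default
#'   `"I"`, Q40).
#' @param seed Integer seed.
#' @return Read tibble (`id`, `bases`, `qualities`) for
#'   [quality_filter()], or writable with [write_fastq()].
#' @export
simulate_reads <- function(counts, library, error_rate = 0,
                           read_length = 150, quality_char = "I",
                           seed = 1L) {
  if (read_length < 28) abort("read_length too short for the cassette")
  set.seed(seed)
  if (is.data.frame(counts)) {
    num <- names(counts)[vapply(counts, is.numeric, TRUE)]
    if (length(num) != 1) abort("counts must have exactly one count column")
    k <- counts[[num]]
    nm <- counts$sgrna
  } else {
    k <- as.vector(counts)
    nm <- names(counts)
  }
  if (any(k != round(k))) abort("counts must be integral")
  spacer <- library$spacer[match(nm, library$name)]
  spacers <- rep(spacer, k)
  n_reads <- length(spacers)
  if (n_reads == 0) {
    return(tibble(id = character(), bases = character(),
                  qualities = character()))
  }
  cassette <- paste0("GCAC", spacers, "GTTT")
  pad <- read_length - 28L
  flip <- runif(n_reads) < 0.5
  assemble <- function(idx) {
    m <- length(idx)
    offset <- sample.int(pad + 1L, m, replace = TRUE) - 1L
    # slice prefixes/suffixes out of one long random string
    pool <- paste(sample(c("A", "C", "G", "T"), 2 * read_length + m,
                         replace = TRUE), collapse = "")
    at <- sample.int(m, m)
    prefix <- substring(pool, at, at + offset - 1L)
    suffix <- substring(pool, at + offset, at + pad - 1L)
    out <- paste0(prefix, cassette[idx], suffix)
    out[flip[idx]] <- revcomp(out[flip[idx]])
    out
  }
  bases <- assemble(seq_len(n_reads))
  # random padding can spell out an accidental cassette; redraw any read
  # whose first intact cassette would not yield its own spacer, so an
  # error-free library round-trips exactly
  mismatched <- function(b, idx) {
    ext <- suppressWarnings(extract_spacers(b))
    idx[is.na(ext) | ext != spacers[idx]]
  }
  bad <- mismatched(bases, seq_len(n_reads))
  for (tries in 1:25) {
    if (length(bad) == 0) break
    bases[bad] <- assemble(bad)
    bad <- mismatched(bases[bad], bad)
  }
  if (length(bad)) {
    abort("could not assemble unambiguous reads; is a spacer repeated?")
  }
  if (error_rate > 0) {
    mat <- strsplit(bases, "")
    for (i in seq_len(n_reads)) {
      hit <- which(runif(read_length) < error_rate)
      for (h in hit) {
        mat[[i]][h] <- sample(setdiff(c("A", "C", "G", "T"), mat[[i]][h]), 1)
      }
    }
    bases <- vapply(mat, paste, "", collapse = "")
  }
  ord <- sample.int(n_reads, n_reads)
  tibble(
    id = paste0("read_", seq_len(n_reads)),
    bases = bases[ord],
    qualities = strrep(quality_char, read_length)
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with `id`, `bases`, `qualities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- reads$id
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities)
  )
  invisible(path)
}

#' Simulate a transposon-insertion site table
#'
#' Unique insertion positions are drawn uniformly at a Poisson
#' genome-wide density and removed from the bodies of designated
#' essential genes.
#'
#' @param genes Gene-model tibble (`gene_id`, `start`, `end`).
#' @param genome_length Chromosome length in bp.
#' @param density Expected insertions per bp (> 0; default 1/50).
#' @param essential_ids Gene ids whose bodies exclude insertions.
#' @param seed Integer seed.
#' @return Tibble with a sorted unique `position` column.
#' @export
simulate_tn_insertions <- function(genes, genome_length, density = 1 / 50,
                                   essential_ids = character(), seed = 1L) {
  if (density <= 0) abort("density must be positive")
  set.seed(seed)
  n <- rpois(1, genome_length * density)
  pos <- sort(unique(sample.int(genome_length, min(n, genome_length),
                                replace = TRUE)))
  ess <- genes[genes$gene_id %in% essential_ids, ]
  if (nrow(ess) > 0) {
    inside <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(ess))) {
      inside <- inside | (pos >= ess$start[i] & pos <= ess$end[i])
    }
    pos <- pos[!inside]
  }
  tibble(position = pos)
}

#' Simulate an analysis-ready sgRNA library table
#'
#' Produces a guide table shaped like the output of a genome-mode design
#' ([tidy.crispri_library()] layout) without requiring a genome: each gene
#' gets `n_active` sgRNAs placed in the 5'-proximal active region (first
#' 5% of the ORF) and the remainder spread evenly across the rest of the
#' coding region, plus `n_nc` negative controls. Spacer sequences are
#' random distinct 20-mers. Useful for exercising the screen statistics at
#' scales where full sequence-level design would be wasteful.
#'
#' @param n_genes Number of genes.
#' @param sgrnas_per_gene Guides per gene (default 10).
#' @param n_nc Negative controls (default 400).
#' @param gene_length ORF length in nt used for relative positions
#'   (default 900).
#' @param n_active Guides inside the active region (default 3).
#' @param seed Integer seed.
#' @return Library tibble (`name`, `gene`, `spacer`, `p`,
#'   `relative_position`, `gc_fraction`, `is_nc`).
#' @export
simulate_library <- function(n_genes, sgrnas_per_gene = 10, n_nc = 400,
                             gene_length = 900, n_active = 3, seed = 1L) {
  set.seed(seed)
  n_active <- min(n_active, sgrnas_per_gene)
  L <- gene_length
  active_max <- max(2L, floor(0.05 * L))
  p_active <- sort(sample(seq(2L, active_max),
                          n_active, replace = FALSE))
  n_rest <- sgrnas_per_gene - n_active
  p_rest <- if (n_rest > 0) {
    as.integer(round(seq(active_max + 20L, L - 21L,
                         length.out = n_rest)))
  } else {
    integer(0)
  }
  p <- c(p_active, p_rest)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_total <- n_genes * sgrnas_per_gene + n_nc
  spacers <- character(0)
  while (length(spacers) < n_total) { # distinct random 20-mers
    more <- vapply(seq_len(n_total - length(spacers)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    }, "")
    spacers <- unique(c(spacers, more))
  }
  p_all <- rep(p, n_genes)
  g <- tibble(
    name = paste0(rep(genes, each = sgrnas_per_gene), "_", p_all),
    gene = rep(genes, each = sgrnas_per_gene),
    spacer = spacers[seq_len(n_genes * sgrnas_per_gene)],
    p = p_all,
    relative_position = p_all / L,
    gc_fraction = NA_real_,
    is_nc = FALSE
  )
  nc <- tibble(
    name = paste0("NC_", seq_len(n_nc)),
    gene = NA_character_,
    spacer = spacers[n_genes * sgrnas_per_gene + seq_len(n_nc)],
    p = NA_integer_,
    relative_position = NA_real_,
    gc_fraction = NA_real_,
    is_nc = TRUE
  )
  out <- bind_rows(g, nc)
  out$gc_fraction <- gc_fraction(out$spacer)
  out
}
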