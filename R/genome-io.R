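#' Read a genome FASTA into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates FASTA
#' headers to the first whitespace-delimited token, so sequence names match
#' the `seqid` column of a GFF3 file.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read gene models from a GFF3 annotation
#'
#' Extracts protein-coding (CDS) and non-coding RNA features from a GFF3
#' file and attaches the coding-strand sequence of each gene, pulled from
#' the genome. Multi-segment CDS are not supported (prokaryotic
#' single-exon genes only); duplicated `gene_id`s are an error.
#'
#' @param path Path to a GFF3 file. Feature types `CDS`, `ncRNA`, `rRNA`
#'   and `tRNA` are used; the gene identifier is taken from the
#'   `locus_tag`, `gene_id`, `Name` or `ID` attribute (first present).
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @return A gene-model tibble with columns `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `biotype` and `cds_sequence` (coding strand,
#'   5'->3').
#' @export
read_gene_models <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gene_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  keep <- as.character(gr$type) %in% c("CDS", "ncRNA", "rRNA", "tRNA")
  gr <- gr[keep]
  meta <- as.data.frame(gr)
  id <- rep(NA_character_, length(gr))
  for (attr in c("locus_tag", "gene_id", "Name", "ID")) {
    if (attr %in% names(meta)) {
      val <- as.character(meta[[attr]])
      id <- ifelse(is.na(id) & !is.na(val), val, id)
    }
  }
  if (anyNA(id)) abort("GFF3 features without a usable gene identifier")
  genes <- tibble(
    gene_id = id,
    chromosome = as.character(meta$seqnames),
    start = meta$start,
    end = meta$end,
    strand = as.character(meta$strand),
    biotype = ifelse(as.character(meta$type) == "CDS", "protein_coding", "rna")
  )
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicated gene_id in annotation")
  }
  attach_gene_sequences(genes, genome)
}

#' Attach coding-strand sequences to a gene table
#'
#' @param genes Tibble with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (and optionally `biotype`).
#' @param genome A [Biostrings::DNAStringSet].
#' @return `genes` with a `cds_sequence` column added (reverse-complemented
#'   for minus-strand genes so the sequence reads 5'->3' on the coding
#'   strand).
#' @export
attach_gene_sequences <- function(genes, genome) {
  missing_chr <- setdiff(unique(genes$chromosome), names(genome))
  if (length(missing_chr)) {
    abort(paste0("annotation references absent chromosome: ",
                 paste(missing_chr, collapse = ", ")))
  }
  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chr <- genome[[genes$chromosome[i]]]
    if (genes$end[i] > length(chr) || genes$start[i] < 1L) {
      abort(paste0("gene ", genes$gene_id[i], " out of chromosome bounds"))
    }
    s <- Biostrings::subseq(chr, genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  genes$cds_sequence <- seqs
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  as_tibble(genes)
}

# reverse complement of a plain character vector
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  vapply(strsplit(x, ""), function(ch) mean(ch %in% c("G", "C")), 0)
}
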