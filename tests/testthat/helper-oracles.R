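# Independent brute-force oracles. These deliberately avoid the package's
# own search/scan code paths (Biostrings matchPattern, rank shortcuts,
# trapezoid sweeps) so agreement is informative.

# all off-target sites of `spacer` in a genome given as a named character
# vector of chromosome strings, by exhaustive scan of every 23-mer window
# on both strands
bf_offtarget_sites <- function(spacer, chroms, max_mismatch = 5) {
  sp <- strsplit(spacer, "")[[1]]
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  out <- list()
  for (chrom in names(chroms)) {
    chars <- strsplit(chroms[[chrom]], "")[[1]]
    L <- length(chars)
    if (L < 23) next
    W <- vapply(0:22, function(k) chars[seq_len(L - 22) + k], character(L - 22))
    if (is.null(dim(W))) W <- matrix(W, nrow = 1)
    for (strand in c("+", "-")) {
      if (strand == "+") {
        proto <- W[, 1:20, drop = FALSE]
        pam <- W[, 21:23, drop = FALSE]
        pat <- sp
      } else {
        # read the window right-to-left complemented: PAM at left end
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        proto <- W[, 23:4, drop = FALSE]
        proto[] <- comp[proto]
        proto[is.na(proto)] <- "N"
        pam <- W[, 3:1, drop = FALSE]
        pam[] <- comp[pam]
        pam[is.na(pam)] <- "N"
        pat <- sp
      }
      pam_class <- ifelse(pam[, 2] == "G" & pam[, 3] == "G", "NGG",
                          ifelse(pam[, 2] == "A" & pam[, 3] == "G", "NAG",
                                 NA))
      mm_mat <- proto != matrix(pat, nrow(proto), 20, byrow = TRUE)
      nmm <- rowSums(mm_mat)
      keep <- which(!is.na(pam_class) & nmm <= max_mismatch)
      for (i in keep) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = chrom, position = i, strand = strand,
          pam_class = pam_class[i], n_mismatch = nmm[i],
          penalty = crisprikit::offtarget_penalty(pam_class[i],
                                                  which(mm_mat[i, ])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chromosome = character(), position = integer(),
                      strand = character(), pam_class = character(),
                      n_mismatch = integer(), penalty = double()))
  }
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$position, res$strand), ]
}

# exact two-sided Mann-Whitney P by exhaustive enumeration of all
# assignments of the pooled values to the two groups (no ties assumed)
bf_mwu_perm_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n_tot <- length(pooled)
  idx <- utils::combn(n_tot, m)
  u_of <- function(sel) {
    xs <- pooled[sel]
    ys <- pooled[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(m))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# AUC as the probability of concordance over all positive/negative pairs
bf_auc_concordance <- function(pred, labels) {
  pos <- pred[labels]
  neg <- pred[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

random_spacer <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }, "")
}

random_genome_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# run one simulated screen end to end up to the sgRNA fitness table
simulate_screen_fitness <- function(lib, truth, depth = 100, seed = 1) {
  counts <- simulate_screen_counts(truth, depth = depth, seed = seed)
  norm <- normalize_counts(counts)
  a <- norm[c("sgrna", "control_1", "selective_1")]
  b <- stats::setNames(norm[c("sgrna", "control_2", "selective_2")],
                       names(a))
  comb <- stats::setNames(combine_replicates(a, b),
                          c("sgrna", "control", "selective"))
  comb <- filter_low_count(comb, "control")
  sgrna_fitness(comb, "selective", "control", lib$name[lib$is_nc])
}
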