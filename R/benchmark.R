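#' Essentiality prediction score from CRISPRi screen results
#'
#' `prediction = 1 - FPR` for depleted genes (fitness < 0), 0 otherwise.
#'
#' @param results Gene-result tibble with `gene`, `fitness`, `fpr`.
#' @return Tibble `gene_id`, `prediction`, `source = "crispri"`.
#' @export
crispri_prediction <- function(results) {
  tibble(
    gene_id = results$gene,
    prediction = ifelse(results$fitness < 0, 1 - results$fpr, 0),
    source = "crispri"
  )
}

#' Essentiality prediction from transposon-insertion data
#'
#' A gene whose insertion index (unique insertions in the gene body
#' divided by gene length) reaches `cutoff` is non-required (prediction
#' 0). For required genes the prediction is `1 - exp(-local_index *
#' length)`, where the local insertion index is the count of unique
#' insertions in a 10-kb window centered on the gene midpoint divided by
#' `window`; a long gene with zero insertions in a densely inserted
#' region is strong evidence of essentiality.
#'
#' @param genes Tibble with `gene_id`, `start`, `end` (1-based inclusive).
#' @param insertions Integer/numeric vector of unique insertion positions,
#'   or a tibble with a `position` column.
#' @param cutoff Insertion-index cutoff for the required call (default
#'   0.00125, strict `<`).
#' @param window Flanking window width in bp (default 10000); the divisor
#'   stays at `window` even when the window is truncated at a contig end.
#' @param chromosome_length Optional contig length used to truncate the
#'   window.
#' @return Tibble `gene_id`, `insertion_index`, `local_index`,
#'   `prediction`, `source = "tnseq"`.
#' @export
tnseq_prediction <- function(genes, insertions, cutoff = 0.00125,
                             window = 10000, chromosome_length = NULL) {
  pos <- if (is.data.frame(insertions)) insertions$position else insertions
  pos <- unique(as.numeric(pos))
  len <- genes$end - genes$start + 1
  idx <- vapply(seq_len(nrow(genes)), function(i) {
    sum(pos >= genes$start[i] & pos <= genes$end[i]) / len[i]
  }, 0)
  mid <- (genes$start + genes$end) / 2
  lo <- mid - window / 2
  hi <- mid + window / 2
  lo <- pmax(lo, 1)
  if (!is.null(chromosome_length)) hi <- pmin(hi, chromosome_length)
  local_idx <- vapply(seq_len(nrow(genes)), function(i) {
    sum(pos >= lo[i] & pos <= hi[i]) / window
  }, 0)
  tibble(
    gene_id = genes$gene_id,
    insertion_index = idx,
    local_index = local_idx,
    prediction = ifelse(idx < cutoff, 1 - exp(-local_idx * len), 0),
    source = "tnseq"
  )
}

#' Essentiality prediction from genetic-footprinting annotations
#'
#' `prediction = 1 - P` for genes flagged essential, 0 otherwise.
#'
#' @param genes Tibble with `gene_id`, `essential` (logical or
#'   `"yes"`/`"no"`), `p_value`.
#' @return Tibble `gene_id`, `prediction`, `source = "footprinting"`.
#' @export
footprinting_prediction <- function(genes) {
  ess <- genes$essential
  if (is.character(ess)) ess <- tolower(ess) == "yes"
  tibble(
    gene_id = genes$gene_id,
    prediction = ifelse(ess, 1 - genes$p_value, 0),
    source = "footprinting"
  )
}

#' ROC curve and AUC of a classifier against a gold standard
#'
#' Threshold sweep over the unique prediction scores; AUC by the
#' trapezoidal rule, which with tied scores handled on shared thresholds
#' equals the rank-based (concordance) estimate. Genes absent from the
#' gold standard are dropped with a message.
#'
#' @param scores Tibble with `gene_id` and `prediction`.
#' @param gold Tibble with `gene_id` and `essential` (logical or
#'   `"essential"`/`"nonessential"`).
#' @param max_gene_length Optional length cutoff; when given, `gold` (or
#'   `scores`) must carry a `length` column and only shorter genes are
#'   evaluated.
#' @return A `roc_result`: list with `roc` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `n_pos`, `n_neg`, `n_dropped`.
#' @export
roc_auc <- function(scores, gold, max_gene_length = NULL) {
  g <- as_tibble(gold)
  if (is.character(g$essential)) {
    g$essential <- tolower(g$essential) %in% c("essential", "yes", "true")
  }
  tab <- dplyr::inner_join(as_tibble(scores), g, by = "gene_id")
  n_dropped <- nrow(scores) - nrow(tab)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " gene(s) absent from the gold standard ",
                  "dropped from ROC"))
  }
  if (!is.null(max_gene_length)) {
    if (!"length" %in% names(tab)) {
      abort("max_gene_length requires a `length` column")
    }
    tab <- filter(tab, .data$length < max_gene_length)
  }
  labels <- tab$essential
  pred <- tab$prediction
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("gold standard must contain both classes")
  }
  thr <- c(Inf, sort(unique(pred), decreasing = TRUE))
  roc <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(labels & pred >= t) / n_pos, 0),
    fpr = vapply(thr, function(t) sum(!labels & pred >= t) / n_neg, 0)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  structure(
    list(roc = roc, auc = auc, n_pos = n_pos, n_neg = n_neg,
         n_dropped = n_dropped),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$roc

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         n_dropped = x$n_dropped)
}

#' @param object A `roc_result`.
#' @param ... Unused.
#' @rdname roc_auc
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}
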