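# Tumour-versus-normal differential-expression screen.
#
# Works on log2(x+1)-scale matrices; the fold-change rule is a band of
# +/- log2(fc_threshold) around zero on the difference of group means.
# No multiple-testing correction is applied in this screen: hits are
# called at raw thresholds (fold change AND p), which is deliberate and
# documented — FDR control in this package appears only in the survival
# screen.

#' Tissues eligible for tumour-normal comparison
#'
#' @param samples Sample metadata (`sample`, `tissue`,
#'   `tumour_or_normal`).
#' @param min_per_group Minimum samples required in each of the tumour
#'   and normal groups (default 10).
#' @return Sorted character vector of eligible tissues.
#' @export
eligible_tissues <- function(samples, min_per_group = 10) {
  tab <- table(samples$tissue, samples$tumour_or_normal)
  need <- c("normal", "tumour")
  if (!all(need %in% colnames(tab))) return(character(0))
  ok <- tab[, "tumour"] >= min_per_group & tab[, "normal"] >= min_per_group
  sort(rownames(tab)[ok])
}

#' Differential-expression screen with up/down tally
#'
#' Per gene and per eligible tissue: two-sided t-test (Student's, pooled
#' variance) of tumour versus normal log2 expression; `log2_fc` is the
#' tumour minus normal difference of means. A gene-tissue pair is called
#' `up`/`down` only when both `|log2_fc| >= log2(fc_threshold)` and
#' `p < p_threshold`; otherwise `ns`. Degenerate pairs (zero variance in
#' both groups, or groups of size < 2) are not evaluable (`p = NA`,
#' direction `ns`).
#'
#' @param expression Genes x samples log2 matrix.
#' @param samples Sample metadata.
#' @param genes Optional subset of genes to screen (default: all rows).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 1.5; the rule is `|log2_fc| >= log2(1.5)`).
#' @param p_threshold Raw p-value threshold (default 0.01; 0.05 matches
#'   the looser convention some reports use — both are supported, and
#'   the default follows the stricter one).
#' @param min_per_group Eligibility threshold passed to
#'   [eligible_tissues()].
#' @return List with `results` (per gene-tissue: `gene`, `tissue`,
#'   `mean_log2_tumour`, `mean_log2_normal`, `log2_fc`, `p`,
#'   `direction`), `tally` (per gene: `up`, `down`, `ns`,
#'   `n_tissues`), and `tissues` (the eligible set).
#' @export
de_screen <- function(expression, samples, genes = NULL,
                      fc_threshold = 1.5, p_threshold = 0.01,
                      min_per_group = 10) {
  if (is.null(genes)) genes <- rownames(expression)
  tissues <- eligible_tissues(samples, min_per_group)
  lfc_min <- log2(fc_threshold)
  res <- list()
  for (tt in tissues) {
    tum <- samples$sample[samples$tissue == tt &
                            samples$tumour_or_normal == "tumour"]
    nrm <- samples$sample[samples$tissue == tt &
                            samples$tumour_or_normal == "normal"]
    tum <- intersect(tum, colnames(expression))
    nrm <- intersect(nrm, colnames(expression))
    X <- expression[genes, , drop = FALSE]
    tst <- row_t_test(X, match(tum, colnames(expression)),
                      match(nrm, colnames(expression)), var_equal = TRUE)
    lfc <- tst$mean1 - tst$mean2
    dir <- ifelse(!is.na(tst$p) & tst$p < p_threshold & abs(lfc) >= lfc_min,
                  ifelse(lfc > 0, "up", "down"), "ns")
    res[[tt]] <- data.frame(gene = genes, tissue = tt,
                            mean_log2_tumour = tst$mean1,
                            mean_log2_normal = tst$mean2,
                            log2_fc = lfc, p = tst$p, direction = dir,
                            stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res)
  else data.frame(gene = character(), tissue = character(),
                  mean_log2_tumour = numeric(), mean_log2_normal = numeric(),
                  log2_fc = numeric(), p = numeric(),
                  direction = character(), stringsAsFactors = FALSE)
  rownames(results) <- NULL
  tally <- data.frame(
    gene = genes,
    up = vapply(genes, function(g)
      sum(results$gene == g & results$direction == "up"), integer(1)),
    down = vapply(genes, function(g)
      sum(results$gene == g & results$direction == "down"), integer(1)),
    stringsAsFactors = FALSE)
  tally$n_tissues <- length(tissues)
  tally$ns <- tally$n_tissues - tally$up - tally$down
  rownames(tally) <- NULL
  list(results = results, tally = tally, tissues = tissues)
}
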