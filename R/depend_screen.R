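# CRISPR dependency analysis over a gene-effect matrix (genes x cell
# lines; more negative = greater sensitivity to knockout).

#' Per-gene essentiality summary
#'
#' Median gene effect over cell lines, the fraction of lines called
#' dependent (gene effect at or below `dependency_threshold`; public
#' dependency probabilities are not modelled — the -0.5 gene-effect
#' proxy is a documented stand-in with the threshold exposed), and the
#' essentiality percentile: 100 times the fraction of all genes whose
#' median effect is strictly greater (less essential), so the single
#' most essential gene among N scores 100*(N-1)/N.
#'
#' @param gene_effect Genes x cell-lines numeric matrix (NAs allowed).
#' @param dependency_threshold Gene-effect cut-off for a dependent line
#'   (default -0.5).
#' @return Data frame `gene`, `median_gene_effect`, `dependent_fraction`,
#'   `essentiality_percentile`, sorted by gene.
#' @export
essentiality_summary <- function(gene_effect, dependency_threshold = -0.5) {
  all_na <- apply(gene_effect, 1, function(x) all(is.na(x)))
  if (any(all_na)) {
    warning("excluding gene(s) with all-missing effects: ",
            paste(rownames(gene_effect)[all_na], collapse = ", "))
    gene_effect <- gene_effect[!all_na, , drop = FALSE]
  }
  med <- apply(gene_effect, 1, stats::median, na.rm = TRUE)
  dep <- apply(gene_effect, 1, function(x)
    mean(x <= dependency_threshold, na.rm = TRUE))
  n <- length(med)
  pct <- vapply(med, function(m) 100 * sum(med > m) / n, numeric(1))
  out <- data.frame(gene = rownames(gene_effect), median_gene_effect = med,
                    dependent_fraction = dep,
                    essentiality_percentile = pct,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' Cumulative rank curve of median gene effects
#'
#' Sorts genes by ascending median gene effect (most essential first;
#' ties broken by gene name) and attaches the cumulative fraction of
#' genes, reproducing the classical cumulative-frequency essentiality
#' plot.
#'
#' @inheritParams essentiality_summary
#' @return Data frame `gene`, `median_gene_effect`, `cumulative_fraction`
#'   (strictly increasing, ending at 1).
#' @export
cumulative_rank_curve <- function(gene_effect) {
  if (nrow(gene_effect) < 2)
    stop("need at least 2 genes for a cumulative curve", call. = FALSE)
  med <- apply(gene_effect, 1, stats::median, na.rm = TRUE)
  ord <- order(med, rownames(gene_effect))
  data.frame(gene = rownames(gene_effect)[ord],
             median_gene_effect = med[ord],
             cumulative_fraction = seq_along(med) / length(med),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise co-dependency correlations
#'
#' Pearson correlation of gene-effect profiles for every pair in a gene
#' set, over cell lines observed for both genes (pairwise-complete).
#' Significance is flagged at raw `p < alpha` by default (matching the
#' classical no-correction usage); Benjamini-Hochberg adjustment is
#' available by flag.
#'
#' @inheritParams essentiality_summary
#' @param gene_set Character vector of genes (rows of `gene_effect`).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust Apply BH adjustment across pairs before flagging.
#' @param min_shared Minimum shared cell lines per pair (default 3);
#'   pairs below it are not evaluable.
#' @return List with `table` (rows `gene_a`, `gene_b`, `n`, `r`, `p`,
#'   `p_adj` when `adjust`, `significant`) and symmetric matrices `r`
#'   and `p` with unit / zero diagonal.
#' @export
codependency_matrix <- function(gene_effect, gene_set, alpha = 0.05,
                                adjust = FALSE, min_shared = 3) {
  missing <- setdiff(gene_set, rownames(gene_effect))
  if (length(missing))
    stop("genes absent from gene_effect: ",
         paste(missing, collapse = ", "), call. = FALSE)
  k <- length(gene_set)
  rmat <- matrix(NA_real_, k, k, dimnames = list(gene_set, gene_set))
  pmat <- matrix(NA_real_, k, k, dimnames = list(gene_set, gene_set))
  diag(rmat) <- 1; diag(pmat) <- 0
  rows <- list()
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      x <- gene_effect[gene_set[i], ]
      y <- gene_effect[gene_set[j], ]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      r <- NA_real_; p <- NA_real_
      if (n >= min_shared && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rmat[i, j] <- rmat[j, i] <- r
      pmat[i, j] <- pmat[j, i] <- p
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = gene_set[i], gene_b = gene_set[j], n = n, r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_a = character(), gene_b = character(), n = integer(),
                  r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (adjust) {
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  } else {
    tab$significant <- !is.na(tab$p) & tab$p < alpha
  }
  rownames(tab) <- NULL
  list(table = tab, r = rmat, p = pmat)
}

#' Paralog-compensation screen
#'
#' For a dependent gene, ranks every candidate gene by the Pearson
#' correlation between the candidate's cell-line expression and the
#' dependent gene's gene-effect score across shared cell lines. A
#' positive correlation means buffering: lines expressing more of the
#' candidate tolerate knockout of the dependent gene better (effect
#' closer to zero). Candidates with constant expression are excluded.
#'
#' @inheritParams essentiality_summary
#' @param cell_line_expression Genes x cell-lines log2 expression matrix.
#' @param dependent_gene Gene whose knockout effect is being buffered.
#' @param candidates Candidate buffer genes (default: all expression rows
#'   except the dependent gene itself).
#' @return Data frame `candidate_buffer_gene`, `n`, `r`, `p`, `rank`
#'   (1 = largest positive r; ties broken by gene name), sorted by rank.
#' @export
compensation_screen <- function(gene_effect, cell_line_expression,
                                dependent_gene, candidates = NULL) {
  if (!dependent_gene %in% rownames(gene_effect))
    stop("dependent gene absent from gene_effect: ", dependent_gene,
         call. = FALSE)
  if (is.null(candidates))
    candidates <- setdiff(rownames(cell_line_expression), dependent_gene)
  shared <- intersect(colnames(gene_effect), colnames(cell_line_expression))
  eff <- gene_effect[dependent_gene, shared]
  rows <- lapply(candidates, function(g) {
    x <- cell_line_expression[g, shared]
    ok <- !is.na(x) & !is.na(eff)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(eff[ok]) == 0)
      return(NULL)
    ct <- stats::cor.test(x[ok], eff[ok], method = "pearson")
    data.frame(candidate_buffer_gene = g, n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(candidate_buffer_gene = character(), n = integer(),
                      r = numeric(), p = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(-out$r, out$candidate_buffer_gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
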