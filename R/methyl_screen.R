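# DNA-methylation / expression anti-correlation discovery.
#
# The screen is a conjunction of four order-free criteria evaluated per
# probe per tissue, gated on tissues where the probe's gene shows an
# expression change:
#   (beta floor)   max(mean beta normal, mean beta tumour) > beta_floor
#   (delta beta)   |mean beta tumour - mean beta normal| >= delta_beta_min
#                  with two-sided t-test p < p_beta
#   (anti-corr)    Pearson r(beta, log2 expression) over tumour samples
#                  <= r_max (a negative bound)
#   (gate)         the gene's |log2_fc| >= log2(gate_fc) in that tissue
# Relaxing any single threshold can only grow the pass set.

#' Filter probes to the regulatory window of the genes under study
#'
#' Keeps probes annotated to the promoter (up to 2 kb upstream of the
#' TSS), the gene body, or the first intron of a studied gene.
#' Unannotated probes (missing gene or region) are dropped with a
#' warning.
#'
#' @param probes Probe annotation (`probe_id`, `gene`, `region`).
#' @param genes Optional character vector restricting to genes under
#'   study.
#' @return The retained subset of `probes`.
#' @export
probe_region_filter <- function(probes, genes = NULL) {
  unann <- is.na(probes$gene) | is.na(probes$region) | probes$gene == "" |
    !probes$region %in% REGION_CLASSES
  if (any(unann))
    warning(sum(unann), " unannotated or out-of-window probe(s) excluded")
  out <- probes[!unann, , drop = FALSE]
  if (!is.null(genes)) out <- out[out$gene %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation-expression anti-correlation screen
#'
#' Evaluates every annotated probe, in every tissue where its gene passes
#' the expression-change gate, against the beta floor, differential-
#' methylation and anti-correlation criteria (see the module header for
#' the exact conjunction). The correlation is computed over tumour
#' samples of the tissue; probes with fewer than 3 paired tumour samples
#' are not evaluable.
#'
#' @param methylation Probes x samples beta matrix.
#' @param probes Probe annotation (`probe_id`, `gene`, `region`),
#'   normally pre-filtered by [probe_region_filter()].
#' @param expression Genes x samples log2 matrix.
#' @param samples Sample metadata.
#' @param de_results The `results` data frame from [de_screen()],
#'   supplying the gate's `log2_fc` per (gene, tissue).
#' @param beta_floor Minimum of the larger group mean beta (default 0.2).
#' @param delta_beta_min Minimum |difference of group mean betas|
#'   (default 0.1).
#' @param p_beta P-value threshold for the beta t-test (default 0.05).
#' @param r_max Upper bound on the Pearson correlation (default -0.2; a
#'   probe passes when `r <= r_max`).
#' @param gate_fc Expression-gate fold change (default 1.5). Setting
#'   `gate_fc = 1` disables the gate (every gene-tissue pair with DE
#'   results is evaluated), which is how null calibration is measured.
#' @param include_normals Also include normal samples in the correlation
#'   population (default `FALSE`: tumours only).
#' @return Data frame, one row per evaluated probe-tissue: `probe_id`,
#'   `gene`, `region`, `tissue`, `mean_beta_normal`, `mean_beta_tumour`,
#'   `delta_beta`, `p_beta`, `r`, `p_r`, per-criterion logicals
#'   (`pass_floor`, `pass_delta`, `pass_r`, `pass_gate`) and the
#'   conjunction `passes`.
#' @export
methylation_expression_screen <- function(methylation, probes, expression,
                                          samples, de_results,
                                          beta_floor = 0.2,
                                          delta_beta_min = 0.1,
                                          p_beta = 0.05, r_max = -0.2,
                                          gate_fc = 1.5,
                                          include_normals = FALSE) {
  probes <- probes[probes$probe_id %in% rownames(methylation) &
                     probes$gene %in% rownames(expression), , drop = FALSE]
  out <- list()
  tissues <- unique(de_results$tissue)
  for (tt in tissues) {
    de_tt <- de_results[de_results$tissue == tt, , drop = FALSE]
    gated <- de_tt$gene[!is.na(de_tt$log2_fc) &
                          abs(de_tt$log2_fc) >= log2(gate_fc)]
    pr <- probes[probes$gene %in% gated, , drop = FALSE]
    if (!nrow(pr)) next
    tum <- samples$sample[samples$tissue == tt &
                            samples$tumour_or_normal == "tumour"]
    nrm <- samples$sample[samples$tissue == tt &
                            samples$tumour_or_normal == "normal"]
    tum <- intersect(tum, intersect(colnames(methylation),
                                    colnames(expression)))
    nrm <- intersect(nrm, colnames(methylation))
    M <- methylation[pr$probe_id, , drop = FALSE]
    tst <- row_t_test(M, match(tum, colnames(methylation)),
                      match(nrm, colnames(methylation)), var_equal = TRUE)
    corr_samples <- if (include_normals)
      c(tum, intersect(nrm, colnames(expression))) else tum
    if (length(corr_samples) >= 3) {
      pc <- row_pearson(M[, corr_samples, drop = FALSE],
                        expression[pr$gene, corr_samples, drop = FALSE])
    } else {
      pc <- list(r = rep(NA_real_, nrow(pr)), p = rep(NA_real_, nrow(pr)))
    }
    db <- tst$mean1 - tst$mean2
    lfc <- de_tt$log2_fc[match(pr$gene, de_tt$gene)]
    res <- data.frame(probe_id = pr$probe_id, gene = pr$gene,
                      region = pr$region, tissue = tt,
                      mean_beta_normal = tst$mean2,
                      mean_beta_tumour = tst$mean1,
                      delta_beta = db, p_beta = tst$p,
                      r = pc$r, p_r = pc$p, stringsAsFactors = FALSE)
    res$pass_floor <- pmax(res$mean_beta_normal, res$mean_beta_tumour) >
      beta_floor
    res$pass_delta <- !is.na(res$p_beta) &
      abs(res$delta_beta) >= delta_beta_min & res$p_beta < p_beta
    res$pass_r <- !is.na(res$r) & res$r <= r_max
    res$pass_gate <- !is.na(lfc) & abs(lfc) >= log2(gate_fc)
    res$passes <- res$pass_floor & res$pass_delta & res$pass_r &
      res$pass_gate
    out[[tt]] <- res
  }
  if (!length(out))
    return(data.frame(probe_id = character(), gene = character(),
                      region = character(), tissue = character(),
                      mean_beta_normal = numeric(),
                      mean_beta_tumour = numeric(), delta_beta = numeric(),
                      p_beta = numeric(), r = numeric(), p_r = numeric(),
                      pass_floor = logical(), pass_delta = logical(),
                      pass_r = logical(), pass_gate = logical(),
                      passes = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
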