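# Mutation and copy-number burden screens.
#
# Frequencies are always computed against the profiled-sample universe
# (samples.tsv), never against mutated samples, and a sample counts once
# per gene regardless of how many alterations it carries.

is_truncating <- function(consequence) consequence %in% TRUNCATING_CLASSES

check_sample_universe <- function(ids, samples, what) {
  missing <- setdiff(unique(ids), samples$sample)
  if (length(missing))
    stop(sprintf("%s contains sample ids absent from the sample table: %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Per-gene genomic alteration frequencies
#'
#' Counts, per gene and per tumour type, the fraction of profiled tumour
#' samples carrying at least one alteration: a non-silent mutation or a
#' high-level CNV call (|call| = 2). A sample carrying several
#' alterations of the same gene counts once.
#'
#' @param mutations MAF-like data frame (`sample`, `gene`, `consequence`,
#'   ...); may be `NULL`.
#' @param cnv CNV call data frame (`sample`, `gene`, `call`); may be
#'   `NULL`.
#' @param samples Sample metadata (`sample`, `tumour_or_normal`,
#'   `tumour_type`); the tumour rows define the denominators.
#' @param threshold Flagging threshold on the per-type frequency
#'   (default 0.05, i.e. the classical "greater than 5%" call-out).
#' @return A list with `by_type` (gene x tumour-type rows: `n_altered`,
#'   `n_profiled`, `frequency`, `flagged`) and `overall` (per gene across
#'   all tumour samples).
#' @export
alteration_frequencies <- function(mutations, cnv, samples,
                                   threshold = 0.05) {
  tum <- samples[samples$tumour_or_normal == "tumour", , drop = FALSE]
  alt <- list()
  if (!is.null(mutations) && nrow(mutations)) {
    check_sample_universe(mutations$sample, samples, "mutation table")
    keep <- mutations$consequence != "silent"
    alt$mut <- unique(mutations[keep, c("sample", "gene")])
  }
  if (!is.null(cnv) && nrow(cnv)) {
    check_sample_universe(cnv$sample, samples, "CNV table")
    keep <- abs(cnv$call) == 2
    alt$cnv <- unique(cnv[keep, c("sample", "gene")])
  }
  pairs <- unique(do.call(rbind, unname(alt)))
  type_of <- stats::setNames(tum$tumour_type, tum$sample)
  n_by_type <- table(tum$tumour_type)
  types <- sort(unique(tum$tumour_type))
  if (is.null(pairs) || !nrow(pairs)) {
    return(list(by_type = data.frame(gene = character(),
                                     tumour_type = character(),
                                     n_altered = integer(),
                                     n_profiled = integer(),
                                     frequency = numeric(),
                                     flagged = logical()),
                overall = data.frame(gene = character(),
                                     n_altered = integer(),
                                     n_profiled = integer(),
                                     frequency = numeric())))
  }
  pairs <- pairs[pairs$sample %in% tum$sample, , drop = FALSE]
  pairs$tumour_type <- unname(type_of[pairs$sample])
  genes <- sort(unique(pairs$gene))
  by_type <- expand.grid(gene = genes, tumour_type = types,
                         stringsAsFactors = FALSE)
  cnt <- stats::aggregate(sample ~ gene + tumour_type, data = pairs,
                          FUN = function(x) length(unique(x)))
  names(cnt)[3] <- "n_altered"
  by_type <- merge(by_type, cnt, all.x = TRUE)
  by_type$n_altered[is.na(by_type$n_altered)] <- 0L
  by_type$n_profiled <- as.integer(n_by_type[by_type$tumour_type])
  by_type$frequency <- by_type$n_altered / by_type$n_profiled
  by_type$flagged <- by_type$frequency >= threshold
  by_type <- by_type[order(by_type$gene, by_type$tumour_type), ]
  rownames(by_type) <- NULL
  ov <- stats::aggregate(sample ~ gene, data = pairs,
                         FUN = function(x) length(unique(x)))
  overall <- data.frame(gene = ov$gene, n_altered = ov$sample,
                        n_profiled = nrow(tum),
                        frequency = ov$sample / nrow(tum),
                        stringsAsFactors = FALSE)
  overall <- overall[order(overall$gene), ]
  rownames(overall) <- NULL
  list(by_type = by_type, overall = overall)
}

#' ORF-length-normalised mutation burden
#'
#' For each gene and each mutation class (missense, truncating), divides
#' the mutation count by the ORF length in amino acids and then by the
#' reference gene's count-per-residue, so the reference gene scores 1 in
#' each class. Missense and truncating classes are normalised
#' independently; a class in which the reference gene has no mutations is
#' reported as `NA` (undefined), never as zero.
#'
#' @param mutations MAF-like data frame with `gene` and `consequence`.
#' @param gene_models Data frame with `symbol` and `orf_length_aa` (> 0).
#' @param reference_gene Symbol of the normalising gene.
#' @param gene_group Optional named character vector mapping gene symbols
#'   to pooled group labels (e.g. collapsing histone multi-copy genes)
#'   applied before counting; grouped ORF length is the sum of member
#'   lengths.
#' @return Data frame: `gene`, `orf_length_aa`, `missense_count`,
#'   `truncating_count`, `normalised_missense`, `normalised_truncating`,
#'   sorted by gene.
#' @export
normalised_burden <- function(mutations, gene_models, reference_gene,
                              gene_group = NULL) {
  gm <- gene_models[, c("symbol", "orf_length_aa")]
  if (any(gm$orf_length_aa <= 0))
    stop("all ORF lengths must be positive", call. = FALSE)
  mut <- mutations
  if (!is.null(gene_group)) {
    hit <- mut$gene %in% names(gene_group)
    mut$gene[hit] <- unname(gene_group[mut$gene[hit]])
    gh <- gm$symbol %in% names(gene_group)
    gm$symbol[gh] <- unname(gene_group[gm$symbol[gh]])
    gm <- stats::aggregate(orf_length_aa ~ symbol, data = gm, FUN = sum)
    if (reference_gene %in% names(gene_group))
      reference_gene <- unname(gene_group[reference_gene])
  }
  if (!reference_gene %in% gm$symbol)
    stop("reference gene not in gene models: ", reference_gene,
         call. = FALSE)
  count_class <- function(keep) {
    tab <- table(factor(mut$gene[keep], levels = gm$symbol))
    as.integer(tab)
  }
  mis <- count_class(mut$consequence == "missense")
  trn <- count_class(is_truncating(mut$consequence))
  out <- data.frame(gene = gm$symbol, orf_length_aa = gm$orf_length_aa,
                    missense_count = mis, truncating_count = trn,
                    stringsAsFactors = FALSE)
  ri <- match(reference_gene, out$gene)
  norm_class <- function(count) {
    rate <- count / out$orf_length_aa
    ref_rate <- rate[ri]
    if (count[ri] == 0) rep(NA_real_, length(rate)) else rate / ref_rate
  }
  out$normalised_missense <- norm_class(out$missense_count)
  out$normalised_truncating <- norm_class(out$truncating_count)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' Recurrent protein-level mutation events
#'
#' A recurrent event is an identical (gene, protein position, alternate
#' residue, consequence) combination observed at least `min_count` times;
#' requiring the alternate residue to match distinguishes e.g. S1C from
#' S1F at the same site.
#'
#' @param mutations MAF-like data frame.
#' @param min_count Minimum occurrences (>= 2).
#' @param class_filter Optional consequence filter: `"truncating"`,
#'   `"missense"`, or a character vector of consequence classes.
#' @param gene_group Optional named vector pooling genes (multi-copy
#'   families) before counting.
#' @return Data frame `gene`, `protein_pos`, `ref_aa`, `alt_aa`,
#'   `consequence`, `count`, `tumour_types` (per-type breakdown as
#'   `"type:count"` comma string), sorted by count descending then gene,
#'   then position.
#' @export
recurrent_mutations <- function(mutations, min_count = 2,
                                class_filter = NULL, gene_group = NULL) {
  if (min_count < 2) stop("min_count must be >= 2", call. = FALSE)
  mut <- mutations
  if (!is.null(class_filter)) {
    classes <- switch(class_filter[1],
                      truncating = TRUNCATING_CLASSES,
                      missense = "missense",
                      class_filter)
    mut <- mut[mut$consequence %in% classes, , drop = FALSE]
  }
  if (!is.null(gene_group)) {
    hit <- mut$gene %in% names(gene_group)
    mut$gene[hit] <- unname(gene_group[mut$gene[hit]])
  }
  if (!nrow(mut))
    return(data.frame(gene = character(), protein_pos = integer(),
                      ref_aa = character(), alt_aa = character(),
                      consequence = character(), count = integer(),
                      tumour_types = character(), stringsAsFactors = FALSE))
  key <- paste(mut$gene, mut$protein_pos, mut$alt_aa, mut$consequence,
               sep = "\r")
  tab <- table(key)
  keep <- names(tab)[tab >= min_count]
  if (!length(keep))
    return(data.frame(gene = character(), protein_pos = integer(),
                      ref_aa = character(), alt_aa = character(),
                      consequence = character(), count = integer(),
                      tumour_types = character(), stringsAsFactors = FALSE))
  rows <- lapply(keep, function(k) {
    sel <- mut[key == k, , drop = FALSE]
    tt <- sort(table(sel$tumour_type), decreasing = TRUE)
    data.frame(gene = sel$gene[1], protein_pos = sel$protein_pos[1],
               ref_aa = sel$ref_aa[1], alt_aa = sel$alt_aa[1],
               consequence = sel$consequence[1], count = nrow(sel),
               tumour_types = paste(sprintf("%s:%d", names(tt),
                                            as.integer(tt)),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$gene, out$protein_pos), ]
  rownames(out) <- NULL
  out
}

#' Missense mutation profile over the first N-terminal positions
#'
#' Tallies missense counts per protein position (default P1-P5), the
#' per-gene distribution of P2 events, and annotates each P2 record with
#' its Nt-acetylation consequence through [classify_substitution()],
#' reporting the fraction of class-preserving exchanges.
#'
#' @param mutations MAF-like data frame.
#' @param gene_models Optional gene models supplying real N-terminal
#'   sequences for the P2 annotation.
#' @param positions Integer positions profiled (default `1:5`).
#' @inheritParams route_nterm
#' @return List: `position_counts` (data frame `position`, `count`),
#'   `p2_by_gene` (data frame `gene`, `count`), `p2_records` (annotated
#'   P2 missense records), `preserving_fraction` (share of evaluable P2
#'   records whose effect is `preserves_class`; `NaN` when none).
#' @export
positional_mutation_profile <- function(mutations, gene_models = NULL,
                                        positions = 1:5, motif = "SGRG") {
  mis <- mutations[mutations$consequence == "missense", , drop = FALSE]
  counts <- vapply(positions, function(p) sum(mis$protein_pos == p),
                   integer(1))
  p2 <- mis[mis$protein_pos == 2, , drop = FALSE]
  if (nrow(p2)) {
    p2 <- annotate_nterm_effects(p2, gene_models = gene_models,
                                 motif = motif)
    by_gene <- as.data.frame(table(p2$gene), stringsAsFactors = FALSE)
    names(by_gene) <- c("gene", "count")
    evaluable <- p2$nt_effect %in% NT_EFFECTS
    pres <- sum(p2$nt_effect[evaluable] == "preserves_class") /
      sum(evaluable)
  } else {
    p2$nt_effect <- character(0)
    by_gene <- data.frame(gene = character(), count = integer(),
                          stringsAsFactors = FALSE)
    pres <- NaN
  }
  list(position_counts = data.frame(position = positions, count = counts),
       p2_by_gene = by_gene, p2_records = p2,
       preserving_fraction = pres)
}

#' Amplification-expression association
#'
#' Two-sided t-test (Student by default, matching classical figure-legend
#' usage; Welch by flag) comparing log2 expression between tumour samples
#' of one type carrying a high-level amplification (+2 call) of a gene
#' and those not carrying one. The difference of group means is the log2
#' fold change.
#'
#' @param cnv CNV call data frame (`sample`, `gene`, `call`).
#' @param expression Genes x samples log2 matrix.
#' @param samples Sample metadata.
#' @param gene,tumour_type The gene-type pair tested.
#' @param min_group_size Minimum samples in each group (default 3); below
#'   this the association is reported as not evaluable (`evaluable =
#'   FALSE`, statistics `NA`), never as p = 1.
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @return List: `gene`, `tumour_type`, `n_amplified`, `n_other`,
#'   `mean_log2_amplified`, `mean_log2_other`, `log2_fc`, `p`,
#'   `evaluable`.
#' @export
amplification_expression_association <- function(cnv, expression, samples,
                                                 gene, tumour_type,
                                                 min_group_size = 3,
                                                 welch = FALSE) {
  tum <- samples$sample[samples$tumour_or_normal == "tumour" &
                          samples$tumour_type == tumour_type]
  tum <- intersect(tum, colnames(expression))
  amp_samples <- cnv$sample[cnv$gene == gene & cnv$call == 2]
  grp_amp <- intersect(tum, amp_samples)
  grp_oth <- setdiff(tum, amp_samples)
  out <- list(gene = gene, tumour_type = tumour_type,
              n_amplified = length(grp_amp), n_other = length(grp_oth),
              mean_log2_amplified = NA_real_, mean_log2_other = NA_real_,
              log2_fc = NA_real_, p = NA_real_, evaluable = FALSE)
  if (length(grp_amp) < min_group_size || length(grp_oth) < min_group_size)
    return(out)
  x <- expression[gene, grp_amp]
  y <- expression[gene, grp_oth]
  out$mean_log2_amplified <- mean(x)
  out$mean_log2_other <- mean(y)
  out$log2_fc <- mean(x) - mean(y)
  tt <- tryCatch(stats::t.test(x, y, var.equal = !welch),
                 error = function(e) NULL)
  if (is.null(tt)) return(out)
  out$p <- tt$p.value
  out$evaluable <- TRUE
  out
}
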