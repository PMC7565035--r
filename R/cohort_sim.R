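# Synthetic multi-omic cohort generator.
#
# Emulates the shape of a pan-cancer multi-omic compendium (Xena-style
# log2 expression, 450K-style methylation beta values, MAF-like somatic
# mutations, GISTIC-thresholded CNV calls, DepMap-style CRISPR gene
# effects and CCLE-style cell-line expression, plus a survival table) at
# desk scale, with every signal planted by configuration and recorded in
# a machine-readable truth object. One global seed drives an independent
# RNG sub-stream per data type, so adding or reordering a data type never
# perturbs another's draws.

#' Build a validated simulation configuration
#'
#' All arguments have documented defaults describing a small but
#' realistic cohort: 100 genes, 4 tumour types with 30 tumour and 30
#' normal samples each, 100 cell lines, background somatic mutation rate
#' 2.5e-5 per residue per sample (which reproduces per-gene mutation
#' frequencies around 1% of samples at typical ORF lengths), log2-scale
#' expression noise sd 0.5, and ~30% censoring.
#'
#' Planted signals are lists of lists:
#' \describe{
#'   \item{planted_de}{`list(gene=, tumour_type=, log2_effect=)` — tumour
#'     samples of that type shift by `log2_effect` on the log2 scale.}
#'   \item{planted_meth}{`list(gene=, tumour_type=, target_r=, delta_beta=)`
#'     — the gene's first-intron probe drops by `delta_beta` in tumours of
#'     that type and is coupled to the gene's expression to achieve
#'     Pearson correlation ~ `target_r` (in `[-1, 0]`).}
#'   \item{planted_amp}{`list(gene=, tumour_type=, frequency=, log2_boost=)`
#'     — a fraction `frequency` of tumour samples carry a +2 CNV call and
#'     their expression is boosted by `log2_boost`.}
#'   \item{planted_hotspot}{`list(gene=, position=, alt_residue=, count=)`
#'     — exactly `count` identical mutation records; `alt_residue "*"`
#'     produces nonsense (truncating) records, otherwise missense.}
#'   \item{planted_essential}{`list(gene=, mean_effect=)` — the gene's
#'     CRISPR gene-effect scores centre on `mean_effect`.}
#'   \item{planted_compensation}{`list(dependent_gene=, buffer_gene=,
#'     strength=)` — the dependent gene's effect score increases (toward
#'     0) by `strength` per SD of the buffer gene's cell-line expression.}
#'   \item{planted_codep}{`list(gene_a=, gene_b=, latent_sd=)` — the two
#'     genes share a latent per-line sensitivity factor of sd
#'     `latent_sd`, producing a positive co-dependency correlation.}
#'   \item{planted_survival}{`list(gene=, tumour_type=, log_hazard_per_sd=)`
#'     — hazard multiplied by `exp(coef * z(expression))` within the type.}
#' }
#'
#' @param seed Integer master seed; identical configurations are
#'   bit-identical in output.
#' @param n_genes,n_tumour_types,n_tumour_samples_per_type,n_normal_samples_per_type,n_cell_lines
#'   Cohort dimensions (all positive integers).
#' @param planted_de,planted_meth,planted_amp,planted_hotspot,planted_essential,planted_compensation,planted_codep,planted_survival
#'   Planted signals (see Details).
#' @param expr_mean_range Range of per-gene baseline means, log2 scale.
#' @param expr_sd Per-sample expression noise sd (log2 scale).
#' @param tissue_sd Sd of per-gene per-tissue baseline offsets.
#' @param beta_precision Beta-distribution precision (a+b) for background
#'   methylation probes.
#' @param mut_rate Background mutation rate per residue per tumour sample.
#' @param censoring_rate Target fraction of censored survival records.
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 100L,
                       n_tumour_types = 4L,
                       n_tumour_samples_per_type = 30L,
                       n_normal_samples_per_type = 30L,
                       n_cell_lines = 100L,
                       planted_de = list(),
                       planted_meth = list(),
                       planted_amp = list(),
                       planted_hotspot = list(),
                       planted_essential = list(),
                       planted_compensation = list(),
                       planted_codep = list(),
                       planted_survival = list(),
                       expr_mean_range = c(3, 8),
                       expr_sd = 0.5,
                       tissue_sd = 0.25,
                       beta_precision = 50,
                       mut_rate = 2.5e-5,
                       censoring_rate = 0.3,
                       baseline_hazard = 0.02) {
  cfg <- list(seed = seed, n_genes = n_genes,
              n_tumour_types = n_tumour_types,
              n_tumour_samples_per_type = n_tumour_samples_per_type,
              n_normal_samples_per_type = n_normal_samples_per_type,
              n_cell_lines = n_cell_lines,
              planted_de = planted_de, planted_meth = planted_meth,
              planted_amp = planted_amp, planted_hotspot = planted_hotspot,
              planted_essential = planted_essential,
              planted_compensation = planted_compensation,
              planted_codep = planted_codep,
              planted_survival = planted_survival,
              expr_mean_range = expr_mean_range, expr_sd = expr_sd,
              tissue_sd = tissue_sd, beta_precision = beta_precision,
              mut_rate = mut_rate, censoring_rate = censoring_rate,
              baseline_hazard = baseline_hazard)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("seed", "n_genes", "n_tumour_types",
              "n_tumour_samples_per_type", "n_normal_samples_per_type",
              "n_cell_lines")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v != round(v))
      stop_config(f, "must be a single integer")
    if (f != "seed" && v <= 0) stop_config(f, "must be positive")
  }
  for (f in c("expr_sd", "tissue_sd", "beta_precision", "mut_rate",
              "baseline_hazard")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop_config(f, "must be a positive number")
  }
  if (!is.numeric(cfg$censoring_rate) || cfg$censoring_rate < 0 ||
      cfg$censoring_rate >= 1)
    stop_config("censoring_rate", "must be in [0, 1)")
  if (length(cfg$expr_mean_range) != 2 || diff(cfg$expr_mean_range) < 0)
    stop_config("expr_mean_range", "must be an increasing pair")
  check_entries <- function(field, required) {
    for (e in cfg[[field]]) {
      miss <- setdiff(required, names(e))
      if (length(miss))
        stop_config(field, paste("entry missing:",
                                 paste(miss, collapse = ", ")))
    }
  }
  check_entries("planted_de", c("gene", "tumour_type", "log2_effect"))
  check_entries("planted_meth", c("gene", "tumour_type", "target_r",
                                  "delta_beta"))
  check_entries("planted_amp", c("gene", "tumour_type", "frequency",
                                 "log2_boost"))
  check_entries("planted_hotspot", c("gene", "position", "alt_residue",
                                     "count"))
  check_entries("planted_essential", c("gene", "mean_effect"))
  check_entries("planted_compensation", c("dependent_gene", "buffer_gene",
                                          "strength"))
  check_entries("planted_codep", c("gene_a", "gene_b", "latent_sd"))
  check_entries("planted_survival", c("gene", "tumour_type",
                                      "log_hazard_per_sd"))
  for (e in cfg$planted_meth)
    if (e$target_r < -1 || e$target_r > 0)
      stop_config("planted_meth", "target_r must be in [-1, 0]")
  for (e in cfg$planted_amp)
    if (e$frequency < 0 || e$frequency > 1)
      stop_config("planted_amp", "frequency must be in [0, 1]")
  for (e in cfg$planted_hotspot)
    if (e$count < 1 || e$position < 1)
      stop_config("planted_hotspot", "count and position must be >= 1")
  invisible(cfg)
}

rbeta_mv <- function(n, mean, precision) {
  stats::rbeta(n, shape1 = mean * precision, shape2 = (1 - mean) * precision)
}

#' Simulate a multi-omic cohort with planted signals
#'
#' Generates expression, methylation (with probe annotation), somatic
#' mutations, CNV calls, CRISPR gene effects, cell-line expression and
#' survival for the cohort described by `config`, plus a `truth` record
#' of every planted signal. The same configuration always yields a
#' bit-identical cohort.
#'
#' @param config A [sim_config()] object (a plain list with the same
#'   fields is validated and accepted).
#' @return A list of class `synthetic_cohort` with elements `genes`,
#'   `samples`, `expression`, `methylation`, `probes`, `mutations`,
#'   `cnv`, `gene_effect`, `cell_line_expression`, `survival`, `truth`
#'   and `config`.
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 20, n_tumour_types = 2,
#'                   n_tumour_samples_per_type = 12,
#'                   n_normal_samples_per_type = 12, n_cell_lines = 20)
#' coh <- simulate_cohort(cfg)
#' dim(coh$expression)
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  seed <- cfg$seed
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  types <- sprintf("TT%d", seq_len(cfg$n_tumour_types))
  for (fld in c("planted_de", "planted_meth", "planted_amp",
                "planted_survival")) {
    for (e in cfg[[fld]]) {
      if (!e$gene %in% genes) stop_config(fld, paste("unknown gene", e$gene))
      if (!e$tumour_type %in% types)
        stop_config(fld, paste("unknown tumour_type", e$tumour_type))
    }
  }

  ## gene models ------------------------------------------------------
  gene_df <- with_substream(seed, 1, {
    roles <- rep(c("catalytic", "auxiliary", "paralog"),
                 length.out = cfg$n_genes)
    orf <- sample(150:900, cfg$n_genes, replace = TRUE)
    nterm <- vapply(seq_len(cfg$n_genes), function(i)
      paste0("M", paste(sample(AA20, 9, replace = TRUE), collapse = "")),
      character(1))
    data.frame(symbol = genes, role = roles, orf_length_aa = orf,
               nterm_seq = nterm, stringsAsFactors = FALSE)
  })

  ## samples ----------------------------------------------------------
  tum_ids <- unlist(lapply(types, function(tt)
    sprintf("%s_T%03d", tt, seq_len(cfg$n_tumour_samples_per_type))))
  nrm_ids <- unlist(lapply(types, function(tt)
    sprintf("%s_N%03d", tt, seq_len(cfg$n_normal_samples_per_type))))
  samples <- data.frame(
    sample = c(tum_ids, nrm_ids),
    tissue = c(rep(types, each = cfg$n_tumour_samples_per_type),
               rep(types, each = cfg$n_normal_samples_per_type)),
    tumour_or_normal = c(rep("tumour", length(tum_ids)),
                         rep("normal", length(nrm_ids))),
    tumour_type = c(rep(types, each = cfg$n_tumour_samples_per_type),
                    rep(types, each = cfg$n_normal_samples_per_type)),
    stringsAsFactors = FALSE)
  all_ids <- samples$sample
  n_s <- length(all_ids)
  is_tum <- samples$tumour_or_normal == "tumour"

  ## expression -------------------------------------------------------
  expr <- with_substream(seed, 2, {
    base <- stats::runif(cfg$n_genes, cfg$expr_mean_range[1],
                         cfg$expr_mean_range[2])
    toff <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tumour_types,
                                0, cfg$tissue_sd),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, types))
    mu <- base + toff[, samples$tumour_type, drop = FALSE]
    m <- mu + matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$expr_sd),
                     nrow = cfg$n_genes)
    dimnames(m) <- list(genes, all_ids)
    m
  })
  for (e in cfg$planted_de) {
    cols <- samples$tumour_type == e$tumour_type & is_tum
    expr[e$gene, cols] <- expr[e$gene, cols] + e$log2_effect
  }

  ## CNV calls (GISTIC-style thresholded) -----------------------------
  cnv_parts <- with_substream(seed, 5, {
    calls <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), cfg$n_genes * sum(is_tum),
                           replace = TRUE,
                           prob = c(0.005, 0.03, 0.93, 0.03, 0.005)),
                    nrow = cfg$n_genes,
                    dimnames = list(genes, all_ids[is_tum]))
    carriers <- lapply(cfg$planted_amp, function(e) {
      pool <- all_ids[is_tum & samples$tumour_type == e$tumour_type]
      sample(pool, max(1L, round(e$frequency * length(pool))))
    })
    list(calls = calls, carriers = carriers)
  })
  calls <- cnv_parts$calls
  amp_carriers <- cnv_parts$carriers
  for (i in seq_along(cfg$planted_amp)) {
    e <- cfg$planted_amp[[i]]
    calls[e$gene, amp_carriers[[i]]] <- 2L
    expr[e$gene, amp_carriers[[i]]] <-
      expr[e$gene, amp_carriers[[i]]] + e$log2_boost
  }
  nz <- which(calls != 0, arr.ind = TRUE)
  cnv <- data.frame(sample = colnames(calls)[nz[, 2]],
                    gene = rownames(calls)[nz[, 1]],
                    call = calls[nz], stringsAsFactors = FALSE)
  cnv <- cnv[order(cnv$sample, cnv$gene), , drop = FALSE]
  rownames(cnv) <- NULL
  expr <- pmax(expr, 0)

  ## methylation ------------------------------------------------------
  regions <- c(prom = "promoter_2kb", body = "gene_body",
               int1 = "first_intron")
  probes <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(cfg$n_genes * 3)),
    gene = rep(genes, each = 3),
    region = rep(unname(regions), cfg$n_genes),
    stringsAsFactors = FALSE)
  meth <- with_substream(seed, 3, {
    pm <- stats::rbeta(nrow(probes), 2, 2)
    m <- matrix(rbeta_mv(nrow(probes) * n_s, rep(pm, n_s),
                         cfg$beta_precision),
                nrow = nrow(probes), dimnames = list(probes$probe_id, all_ids))
    for (e in cfg$planted_meth) {
      pid <- probes$probe_id[probes$gene == e$gene &
                               probes$region == "first_intron"]
      in_type <- samples$tumour_type == e$tumour_type
      nrm <- in_type & !is_tum
      tum <- in_type & is_tum
      m[pid, nrm] <- pmin(pmax(stats::rnorm(sum(nrm), 0.5, 0.1), 0.001),
                          0.999)
      x <- as.numeric(scale(expr[e$gene, tum]))
      u <- e$target_r * x +
        sqrt(max(0, 1 - e$target_r^2)) * stats::rnorm(sum(tum))
      m[pid, tum] <- pmin(pmax(0.5 - e$delta_beta + 0.1 * u, 0.001), 0.999)
    }
    m
  })

  ## somatic mutations ------------------------------------------------
  mut <- with_substream(seed, 4, {
    rows <- list()
    tum_samples <- all_ids[is_tum]
    tum_type <- stats::setNames(samples$tumour_type, samples$sample)
    cons_lev <- c("missense", "nonsense", "frameshift", "splice",
                  "silent", "other")
    cons_p <- c(0.70, 0.08, 0.08, 0.05, 0.06, 0.03)
    for (gi in seq_len(cfg$n_genes)) {
      orf <- gene_df$orf_length_aa[gi]
      nmut <- stats::rpois(1, orf * length(tum_samples) * cfg$mut_rate)
      if (nmut == 0) next
      pos <- sample.int(orf, nmut, replace = TRUE)
      nt <- strsplit(gene_df$nterm_seq[gi], "")[[1]]
      ref <- ifelse(pos <= length(nt), nt[pmin(pos, length(nt))],
                    sample(AA20, nmut, replace = TRUE))
      cons <- sample(cons_lev, nmut, replace = TRUE, prob = cons_p)
      alt <- vapply(seq_len(nmut), function(k) {
        switch(cons[k],
               missense = sample(setdiff(AA20, ref[k]), 1),
               nonsense = "*",
               silent = ref[k],
               "-")
      }, character(1))
      smp <- sample(tum_samples, nmut, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, gene = genes[gi], protein_pos = pos, ref_aa = ref,
        alt_aa = alt, consequence = cons,
        tumour_type = unname(tum_type[smp]), stringsAsFactors = FALSE)
    }
    for (e in cfg$planted_hotspot) {
      gi <- match(e$gene, genes)
      if (is.na(gi)) stop_config("planted_hotspot",
                                 paste("unknown gene", e$gene))
      nt <- strsplit(gene_df$nterm_seq[gi], "")[[1]]
      ref <- if (e$position <= length(nt)) nt[e$position] else "L"
      smp <- sample(tum_samples, e$count,
                    replace = e$count > length(tum_samples))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, gene = e$gene, protein_pos = e$position,
        ref_aa = ref, alt_aa = e$alt_residue,
        consequence = if (e$alt_residue == "*") "nonsense" else "missense",
        tumour_type = unname(tum_type[smp]), stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(sample = character(), gene = character(),
                    protein_pos = integer(), ref_aa = character(),
                    alt_aa = character(), consequence = character(),
                    tumour_type = character(), stringsAsFactors = FALSE)
  })
  rownames(mut) <- NULL

  ## cell-line expression --------------------------------------------
  lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  cl_expr <- with_substream(seed, 7, {
    base <- stats::runif(cfg$n_genes, cfg$expr_mean_range[1],
                         cfg$expr_mean_range[2])
    m <- base + matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines, 0, 1),
                       nrow = cfg$n_genes)
    dimnames(m) <- list(genes, lines)
    pmax(m, 0)
  })

  ## CRISPR gene effect ----------------------------------------------
  ge <- with_substream(seed, 6, {
    m <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines, 0, 0.15),
                nrow = cfg$n_genes, dimnames = list(genes, lines))
    for (e in cfg$planted_essential)
      m[e$gene, ] <- stats::rnorm(cfg$n_cell_lines, e$mean_effect, 0.15)
    for (e in cfg$planted_codep) {
      lat <- stats::rnorm(cfg$n_cell_lines, 0, e$latent_sd)
      m[e$gene_a, ] <- -0.5 + lat + stats::rnorm(cfg$n_cell_lines, 0, 0.15)
      m[e$gene_b, ] <- -0.5 + lat + stats::rnorm(cfg$n_cell_lines, 0, 0.15)
    }
    for (e in cfg$planted_compensation) {
      z <- as.numeric(scale(cl_expr[e$buffer_gene, ]))
      m[e$dependent_gene, ] <- -0.8 + e$strength * z +
        stats::rnorm(cfg$n_cell_lines, 0, 0.15)
    }
    m
  })

  ## survival ---------------------------------------------------------
  surv <- with_substream(seed, 8, {
    tum <- samples[is_tum, , drop = FALSE]
    lp <- rep(0, nrow(tum))
    for (e in cfg$planted_survival) {
      in_type <- tum$tumour_type == e$tumour_type
      z <- as.numeric(scale(expr[e$gene, tum$sample[in_type]]))
      lp[in_type] <- lp[in_type] + e$log_hazard_per_sd * z
    }
    tt <- stats::rexp(nrow(tum), rate = cfg$baseline_hazard * exp(lp))
    if (cfg$censoring_rate > 0) {
      lam <- cfg$baseline_hazard
      f <- function(C) (1 - exp(-lam * C)) / (lam * C) - cfg$censoring_rate
      cmax <- stats::uniroot(f, c(1e-6, 1e6 / lam))$root
      cc <- stats::runif(nrow(tum), 0, cmax)
    } else cc <- rep(Inf, nrow(tum))
    data.frame(sample = tum$sample, tumour_type = tum$tumour_type,
               time = pmin(tt, cc), event = as.integer(tt <= cc),
               stringsAsFactors = FALSE)
  })
  rownames(surv) <- NULL

  ## truth ------------------------------------------------------------
  truth <- list(
    planted_de = cfg$planted_de,
    planted_meth = lapply(seq_along(cfg$planted_meth), function(i) {
      e <- cfg$planted_meth[[i]]
      e$probe_id <- probes$probe_id[probes$gene == e$gene &
                                      probes$region == "first_intron"]
      e
    }),
    planted_amp = lapply(seq_along(cfg$planted_amp), function(i) {
      e <- cfg$planted_amp[[i]]
      e$carriers <- amp_carriers[[i]]
      e
    }),
    planted_hotspot = cfg$planted_hotspot,
    planted_essential = cfg$planted_essential,
    planted_compensation = cfg$planted_compensation,
    planted_codep = cfg$planted_codep,
    planted_survival = cfg$planted_survival,
    seed = cfg$seed)

  structure(list(genes = gene_df, samples = samples, expression = expr,
                 methylation = meth, probes = probes, mutations = mut,
                 cnv = cnv, gene_effect = ge, cell_line_expression = cl_expr,
                 survival = surv, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic multi-omic cohort: %d genes, %d samples ",
                     "(%d tumour / %d normal), %d tumour types, %d cell ",
                     "lines, %d mutation records\n"),
              nrow(x$expression), ncol(x$expression),
              sum(x$samples$tumour_or_normal == "tumour"),
              sum(x$samples$tumour_or_normal == "normal"),
              length(unique(x$samples$tumour_type)),
              ncol(x$gene_effect), nrow(x$mutations)))
  n_planted <- sum(lengths(x$truth[startsWith(names(x$truth), "planted_")]))
  cat(sprintf("Planted signals: %d (see $truth)\n", n_planted))
  invisible(x)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits the cohort's external interface: `expression.tsv`,
#' `cell_line_expression.tsv`, `methylation.tsv` (features x samples),
#' `probes.tsv`, `mutations.tsv`, `cnv.tsv`, `gene_effect.tsv`,
#' `survival.tsv`, `samples.tsv`, `genes.tsv` and `truth.json`.
#' Round-trips losslessly (to 15 significant digits) through
#' [read_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @return Named character vector of written file paths (the manifest),
#'   invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  p <- function(f) file.path(directory, f)
  write_matrix_tsv(cohort$expression, p("expression.tsv"), "gene")
  write_matrix_tsv(cohort$cell_line_expression,
                   p("cell_line_expression.tsv"), "gene")
  write_matrix_tsv(cohort$methylation, p("methylation.tsv"), "probe_id")
  write_matrix_tsv(cohort$gene_effect, p("gene_effect.tsv"), "gene")
  write_tsv_file(cohort$probes, p("probes.tsv"))
  write_tsv_file(cohort$mutations, p("mutations.tsv"))
  write_tsv_file(cohort$cnv, p("cnv.tsv"))
  write_tsv_file(cohort$survival, p("survival.tsv"))
  write_tsv_file(cohort$samples, p("samples.tsv"))
  write_tsv_file(cohort$genes, p("genes.tsv"))
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- c(expression = p("expression.tsv"),
                cell_line_expression = p("cell_line_expression.tsv"),
                methylation = p("methylation.tsv"),
                gene_effect = p("gene_effect.tsv"),
                probes = p("probes.tsv"), mutations = p("mutations.tsv"),
                cnv = p("cnv.tsv"), survival = p("survival.tsv"),
                samples = p("samples.tsv"), genes = p("genes.tsv"),
                truth = p("truth.json"))
  invisible(manifest)
}
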