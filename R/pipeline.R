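# Orchestration: cohort directory readers, the end-to-end runner and a
# truth-aware recovery report.

COHORT_FILES <- c("expression.tsv", "samples.tsv", "genes.tsv")

#' Read a cohort directory into memory
#'
#' Inverse of [write_cohort()]: reads the TSV/JSON files of a cohort
#' directory, validates cross-references (every sample in an omics table
#' must exist in `samples.tsv`; matrix row ids must be unique) and
#' returns the same structure [simulate_cohort()] produces. Optional
#' files (`survival.tsv`, `methylation.tsv`, `gene_effect.tsv`,
#' `cnv.tsv`, `mutations.tsv`, `truth.json`, ...) may be absent, in
#' which case the corresponding element is `NULL` and downstream screens
#' that need it are skipped by [run_all()].
#'
#' @param directory Cohort directory path.
#' @return A list of class `synthetic_cohort`.
#' @export
read_cohort <- function(directory) {
  if (!dir.exists(directory))
    stop("cohort directory not found: ", directory, call. = FALSE)
  p <- function(f) file.path(directory, f)
  for (f in COHORT_FILES)
    if (!file.exists(p(f)))
      stop("required cohort file missing: ", p(f), call. = FALSE)
  opt <- function(f, reader, ...)
    if (file.exists(p(f))) reader(p(f), ...) else NULL
  samples <- read_tsv_file(p("samples.tsv"))
  expr <- read_matrix_tsv(p("expression.tsv"), "gene")
  genes <- read_tsv_file(p("genes.tsv"))
  meth <- opt("methylation.tsv", read_matrix_tsv, "probe_id")
  probes <- opt("probes.tsv", read_tsv_file)
  mutations <- opt("mutations.tsv", read_tsv_file)
  cnv <- opt("cnv.tsv", read_tsv_file)
  ge <- opt("gene_effect.tsv", read_matrix_tsv, "gene")
  cl_expr <- opt("cell_line_expression.tsv", read_matrix_tsv, "gene")
  surv <- opt("survival.tsv", read_tsv_file)
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = FALSE) else NULL

  check_ids <- function(ids, what) {
    dangling <- setdiff(unique(ids), samples$sample)
    if (length(dangling))
      stop(sprintf("%s references sample ids absent from samples.tsv: %s",
                   what, paste(dangling, collapse = ", ")), call. = FALSE)
  }
  check_ids(colnames(expr), "expression.tsv")
  if (!is.null(meth)) check_ids(colnames(meth), "methylation.tsv")
  if (!is.null(mutations) && nrow(mutations))
    check_ids(mutations$sample, "mutations.tsv")
  if (!is.null(cnv) && nrow(cnv)) check_ids(cnv$sample, "cnv.tsv")
  if (!is.null(surv) && nrow(surv)) check_ids(surv$sample, "survival.tsv")

  structure(list(genes = genes, samples = samples, expression = expr,
                 methylation = meth, probes = probes, mutations = mutations,
                 cnv = cnv, gene_effect = ge,
                 cell_line_expression = cl_expr, survival = surv,
                 truth = truth, config = NULL),
            class = "synthetic_cohort")
}

#' Default run configuration
#'
#' Every screen threshold with its standard default (the value each
#' screen's documentation justifies). Unknown keys passed to
#' [run_all()] via `overrides` are rejected by name.
#'
#' @return Named list of thresholds.
#' @export
default_run_config <- function() {
  list(freq_threshold = 0.05, reference_gene = NULL, min_recurrence = 2,
       recurrence_class = NULL, fc_threshold = 1.5, p_threshold = 0.01,
       min_per_group = 10, beta_floor = 0.2, delta_beta_min = 0.1,
       p_beta = 0.05, r_max = -0.2, gate_fc = 1.5,
       dependency_threshold = -0.5, gene_set = NULL, dependent_gene = NULL,
       min_events = 10, fdr = 0.05, z_scale = TRUE, seed = 1L)
}

merge_run_config <- function(overrides = list()) {
  cfg <- default_run_config()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run every screen over a cohort directory
#'
#' Executes the genomic, expression, methylation, dependency and
#' survival screens in order over the cohort in `cohort_dir`, writes one
#' TSV per screen into `out_dir`, and writes `report.json` recording
#' every threshold actually used plus — when the cohort carries a
#' `truth.json` — a recovery summary (planted signals found / missed
#' per signal class). Screens whose inputs are absent are skipped and
#' listed in the report. Rerunning with the same cohort and
#' configuration produces byte-identical outputs.
#'
#' @param cohort_dir Cohort directory (as written by [write_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param overrides Named list of threshold overrides; unknown keys are
#'   rejected (see [default_run_config()]).
#' @param quiet Suppress progress messages on stderr.
#' @param screens Which screens to run (default: all); the methylation
#'   screen implies the expression screen it is gated on.
#' @return The report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_all <- function(cohort_dir, out_dir, overrides = list(),
                    quiet = FALSE,
                    screens = c("genomic", "expression", "methylation",
                                "dependency", "survival")) {
  screens <- match.arg(screens, several.ok = TRUE)
  if ("methylation" %in% screens) screens <- union(screens, "expression")
  cfg <- merge_run_config(overrides)
  coh <- read_cohort(cohort_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(thresholds = cfg[!vapply(cfg, is.null, logical(1))],
                 screens_run = character(0), skipped = character(0))
  outputs <- character(0)
  t0 <- proc.time()[["elapsed"]]

  ## genomic ----------------------------------------------------------
  if ("genomic" %in% screens && !is.null(coh$mutations)) {
    say("[genomic] alteration frequencies / burden / recurrence")
    af <- alteration_frequencies(coh$mutations, coh$cnv, coh$samples,
                                 threshold = cfg$freq_threshold)
    write_tsv_file(af$by_type, file.path(out_dir, "alteration_freq.tsv"))
    ref <- cfg$reference_gene
    if (is.null(ref)) {
      # default reference: most-mutated gene, so normalisation is defined
      cnts <- table(coh$mutations$gene)
      ref <- names(cnts)[which.max(cnts)]
    }
    burden <- normalised_burden(coh$mutations, coh$genes, ref)
    write_tsv_file(burden, file.path(out_dir, "burden.tsv"))
    rec <- recurrent_mutations(coh$mutations,
                               min_count = cfg$min_recurrence,
                               class_filter = cfg$recurrence_class)
    write_tsv_file(rec, file.path(out_dir, "recurrence.tsv"))
    prof <- positional_mutation_profile(coh$mutations, coh$genes)
    write_tsv_file(prof$position_counts,
                   file.path(out_dir, "p2_profile.tsv"))
    report$screens_run <- c(report$screens_run, "genomic")
    report$genomic <- list(reference_gene = ref,
                           n_flagged = sum(af$by_type$flagged),
                           n_recurrent = nrow(rec),
                           preserving_fraction = prof$preserving_fraction)
    outputs <- c(outputs, "alteration_freq.tsv", "burden.tsv",
                 "recurrence.tsv", "p2_profile.tsv")
  } else report$skipped <- c(report$skipped, "genomic")

  ## expression -------------------------------------------------------
  de <- NULL
  if ("expression" %in% screens) {
    say("[expression] tumour vs normal screen")
    de <- de_screen(coh$expression, coh$samples,
                    fc_threshold = cfg$fc_threshold,
                    p_threshold = cfg$p_threshold,
                    min_per_group = cfg$min_per_group)
    write_tsv_file(de$results, file.path(out_dir, "de_results.tsv"))
    write_tsv_file(de$tally, file.path(out_dir, "de_tally.tsv"))
    report$screens_run <- c(report$screens_run, "expression")
    report$expression <- list(n_tissues = length(de$tissues),
                              n_up = sum(de$results$direction == "up"),
                              n_down = sum(de$results$direction == "down"))
    outputs <- c(outputs, "de_results.tsv", "de_tally.tsv")
  } else report$skipped <- c(report$skipped, "expression")

  ## methylation ------------------------------------------------------
  meth_hits <- NULL
  if ("methylation" %in% screens && !is.null(coh$methylation) &&
      !is.null(coh$probes)) {
    say("[methylation] anti-correlation screen")
    pr <- probe_region_filter(coh$probes, genes = rownames(coh$expression))
    meth_hits <- methylation_expression_screen(
      coh$methylation, pr, coh$expression, coh$samples, de$results,
      beta_floor = cfg$beta_floor, delta_beta_min = cfg$delta_beta_min,
      p_beta = cfg$p_beta, r_max = cfg$r_max, gate_fc = cfg$gate_fc)
    write_tsv_file(meth_hits, file.path(out_dir, "methylation_hits.tsv"))
    report$screens_run <- c(report$screens_run, "methylation")
    report$methylation <- list(n_evaluated = nrow(meth_hits),
                               n_passing = sum(meth_hits$passes))
    outputs <- c(outputs, "methylation_hits.tsv")
  } else report$skipped <- c(report$skipped, "methylation")

  ## dependency -------------------------------------------------------
  comp <- NULL
  if ("dependency" %in% screens && !is.null(coh$gene_effect)) {
    say("[dependency] essentiality / co-dependency / compensation")
    ess <- essentiality_summary(coh$gene_effect,
                                dependency_threshold =
                                  cfg$dependency_threshold)
    write_tsv_file(ess, file.path(out_dir, "essentiality.tsv"))
    gene_set <- cfg$gene_set
    if (is.null(gene_set))
      gene_set <- utils::head(rownames(coh$gene_effect), 30)
    codep <- codependency_matrix(coh$gene_effect, gene_set)
    write_tsv_file(codep$table, file.path(out_dir, "codependency.tsv"))
    outputs <- c(outputs, "essentiality.tsv", "codependency.tsv")
    if (!is.null(cfg$dependent_gene) &&
        !is.null(coh$cell_line_expression)) {
      comp <- compensation_screen(coh$gene_effect,
                                  coh$cell_line_expression,
                                  cfg$dependent_gene)
      write_tsv_file(comp, file.path(out_dir, "compensation.tsv"))
      outputs <- c(outputs, "compensation.tsv")
    }
    report$screens_run <- c(report$screens_run, "dependency")
    report$dependency <- list(
      n_codep_significant = sum(codep$table$significant, na.rm = TRUE))
  } else report$skipped <- c(report$skipped, "dependency")

  ## survival ---------------------------------------------------------
  surv_res <- NULL
  if ("survival" %in% screens && !is.null(coh$survival)) {
    say("[survival] Cox / log-rank screen")
    surv_res <- survival_screen(coh$expression, coh$survival,
                                min_events = cfg$min_events,
                                z_scale = cfg$z_scale, fdr = cfg$fdr)
    write_tsv_file(surv_res,
                   file.path(out_dir, "survival_associations.tsv"))
    report$screens_run <- c(report$screens_run, "survival")
    report$survival <- list(n_evaluated = nrow(surv_res),
                            n_significant = sum(surv_res$significant))
    outputs <- c(outputs, "survival_associations.tsv")
  } else report$skipped <- c(report$skipped, "survival")

  ## truth recovery ---------------------------------------------------
  if (!is.null(coh$truth)) {
    report$recovery <- recovery_summary(coh, de, meth_hits, surv_res,
                                        out_dir, cfg)
  }
  report$outputs <- outputs
  say("[done] %.1f s elapsed", proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Compare screen outputs against a cohort's planted truth.
recovery_summary <- function(coh, de, meth_hits, surv_res, out_dir, cfg) {
  tr <- coh$truth
  rec <- list()
  g1 <- function(e, f) if (is.list(e)) e[[f]] else e[f]
  if (length(tr$planted_de) && !is.null(de)) {
    rec$de <- lapply(tr$planted_de, function(e) {
      hit <- de$results$gene == g1(e, "gene") &
        de$results$tissue == g1(e, "tumour_type")
      found <- any(hit & de$results$direction ==
                     if (g1(e, "log2_effect") >= 0) "up" else "down")
      list(gene = g1(e, "gene"), tissue = g1(e, "tumour_type"),
           found = found)
    })
  }
  if (length(tr$planted_meth) && !is.null(meth_hits)) {
    rec$methylation <- lapply(tr$planted_meth, function(e) {
      found <- any(meth_hits$probe_id == g1(e, "probe_id") &
                     meth_hits$tissue == g1(e, "tumour_type") &
                     meth_hits$passes)
      list(probe_id = g1(e, "probe_id"), gene = g1(e, "gene"),
           found = found)
    })
  }
  if (length(tr$planted_amp) && !is.null(coh$cnv) &&
      !is.null(coh$mutations)) {
    af <- alteration_frequencies(coh$mutations, coh$cnv, coh$samples,
                                 threshold = cfg$freq_threshold)
    rec$amplification <- lapply(tr$planted_amp, function(e) {
      hit <- af$by_type$gene == g1(e, "gene") &
        af$by_type$tumour_type == g1(e, "tumour_type")
      assoc <- amplification_expression_association(
        coh$cnv, coh$expression, coh$samples, g1(e, "gene"),
        g1(e, "tumour_type"))
      list(gene = g1(e, "gene"), tumour_type = g1(e, "tumour_type"),
           flagged = any(hit & af$by_type$flagged),
           expression_p = assoc$p,
           found = any(hit & af$by_type$flagged) && assoc$evaluable &&
             assoc$p < 0.001)
    })
  }
  if (length(tr$planted_hotspot) && !is.null(coh$mutations)) {
    rec$hotspot <- lapply(tr$planted_hotspot, function(e) {
      rec_tab <- recurrent_mutations(coh$mutations, min_count = 2)
      hit <- rec_tab$gene == g1(e, "gene") &
        rec_tab$protein_pos == g1(e, "position") &
        rec_tab$alt_aa == g1(e, "alt_residue")
      list(gene = g1(e, "gene"), position = g1(e, "position"),
           found = any(hit & rec_tab$count >= g1(e, "count")))
    })
  }
  if (length(tr$planted_survival) && !is.null(surv_res)) {
    rec$survival <- lapply(tr$planted_survival, function(e) {
      hit <- surv_res$gene == g1(e, "gene") &
        surv_res$tumour_type == g1(e, "tumour_type")
      found <- any(hit & surv_res$significant)
      list(gene = g1(e, "gene"), tumour_type = g1(e, "tumour_type"),
           found = found)
    })
  }
  if (length(tr$planted_essential) && !is.null(coh$gene_effect)) {
    ess <- essentiality_summary(coh$gene_effect,
                                cfg$dependency_threshold)
    rec$essential <- lapply(tr$planted_essential, function(e) {
      row <- ess[ess$gene == g1(e, "gene"), ]
      list(gene = g1(e, "gene"),
           percentile = row$essentiality_percentile,
           found = nrow(row) > 0 && row$essentiality_percentile > 95)
    })
  }
  if (length(tr$planted_compensation) && !is.null(coh$gene_effect) &&
      !is.null(coh$cell_line_expression)) {
    rec$compensation <- lapply(tr$planted_compensation, function(e) {
      comp <- compensation_screen(coh$gene_effect,
                                  coh$cell_line_expression,
                                  g1(e, "dependent_gene"))
      row <- comp[comp$candidate_buffer_gene == g1(e, "buffer_gene"), ]
      list(dependent_gene = g1(e, "dependent_gene"),
           buffer_gene = g1(e, "buffer_gene"),
           rank = if (nrow(row)) row$rank else NA,
           found = nrow(row) > 0 && row$rank == 1)
    })
  }
  rec
}
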