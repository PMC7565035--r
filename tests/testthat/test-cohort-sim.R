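small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_genes = 20, n_tumour_types = 2,
             n_tumour_samples_per_type = 12, n_normal_samples_per_type = 12,
             n_cell_lines = 15, ...)
}

test_that("identical configurations give bit-identical cohorts", {
  c1 <- simulate_cohort(small_cfg(seed = 7))
  c2 <- simulate_cohort(small_cfg(seed = 7))
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$methylation, c2$methylation)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$cnv, c2$cnv)
  expect_identical(c1$gene_effect, c2$gene_effect)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$truth, c2$truth)
  # different seed changes the draws
  c3 <- simulate_cohort(small_cfg(seed = 8))
  expect_false(identical(c1$expression, c3$expression))
})

test_that("cohort structural invariants hold", {
  coh <- simulate_cohort(small_cfg())
  expect_true(all(coh$methylation >= 0 & coh$methylation <= 1))
  expect_true(all(coh$survival$time > 0))
  expect_true(all(coh$survival$event %in% c(0L, 1L)))
  expect_true(all(coh$cnv$call %in% c(-2L, -1L, 1L, 2L)))
  # every sample id in omics tables appears in the metadata
  expect_true(all(colnames(coh$expression) %in% coh$samples$sample))
  expect_true(all(colnames(coh$methylation) %in% coh$samples$sample))
  expect_true(all(coh$mutations$sample %in% coh$samples$sample))
  expect_true(all(coh$cnv$sample %in% coh$samples$sample))
  expect_true(all(coh$survival$sample %in% coh$samples$sample))
  # two tumour types requested -> exactly two labels in the metadata
  expect_equal(sort(unique(coh$samples$tumour_type)), c("TT1", "TT2"))
})

test_that("planted hotspot contributes exactly `count` identical records", {
  coh <- simulate_cohort(small_cfg(
    planted_hotspot = list(list(gene = "G003", position = 1,
                                alt_residue = "C", count = 5))))
  hit <- coh$mutations[coh$mutations$gene == "G003" &
                         coh$mutations$protein_pos == 1 &
                         coh$mutations$alt_aa == "C", ]
  expect_equal(nrow(hit), 5)
  expect_true(all(hit$consequence == "missense"))
  expect_true(all(hit$ref_aa == "M"))   # every N-terminus starts with iMet
  # stop-gain spelling produces truncating records
  coh2 <- simulate_cohort(small_cfg(
    planted_hotspot = list(list(gene = "G003", position = 4,
                                alt_residue = "*", count = 3))))
  hit2 <- coh2$mutations[coh2$mutations$gene == "G003" &
                           coh2$mutations$protein_pos == 4 &
                           coh2$mutations$alt_aa == "*", ]
  expect_equal(nrow(hit2), 3)
  expect_true(all(hit2$consequence == "nonsense"))
})

test_that("every planted signal appears in the truth record", {
  cfg <- strong_config(seed = 5)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth
  expect_length(tr$planted_de, 2)
  expect_length(tr$planted_meth, 1)
  expect_equal(tr$planted_meth[[1]]$gene, "G010")
  expect_match(tr$planted_meth[[1]]$probe_id, "^cg")
  expect_length(tr$planted_amp, 1)
  expect_gt(length(tr$planted_amp[[1]]$carriers), 0)
  expect_length(tr$planted_hotspot, 1)
  expect_length(tr$planted_essential, 1)
  expect_length(tr$planted_compensation, 1)
  expect_length(tr$planted_codep, 1)
  expect_length(tr$planted_survival, 1)
})

test_that("planted effects have the configured magnitude in expectation", {
  # average over seeds so the check targets the generating parameters
  lfc <- boost <- db <- numeric(0)
  for (s in 1:8) {
    coh <- simulate_cohort(strong_config(seed = s))
    sm <- coh$samples
    tum1 <- sm$sample[sm$tumour_type == "TT1" & sm$tumour_or_normal == "tumour"]
    nrm1 <- sm$sample[sm$tumour_type == "TT1" & sm$tumour_or_normal == "normal"]
    lfc <- c(lfc, mean(coh$expression["G010", tum1]) -
               mean(coh$expression["G010", nrm1]))
    carriers <- unlist(coh$truth$planted_amp[[1]]$carriers)
    tum2 <- sm$sample[sm$tumour_type == "TT2" & sm$tumour_or_normal == "tumour"]
    boost <- c(boost, mean(coh$expression["G020", carriers]) -
                 mean(coh$expression["G020", setdiff(tum2, carriers)]))
    pid <- coh$truth$planted_meth[[1]]$probe_id
    nrm_b <- mean(coh$methylation[pid, nrm1])
    tum_b <- mean(coh$methylation[pid, tum1])
    db <- c(db, nrm_b - tum_b)
  }
  expect_equal(mean(lfc), 1.0, tolerance = 0.15)
  expect_equal(mean(boost), 1.0, tolerance = 0.2)
  expect_equal(mean(db), 0.2, tolerance = 0.25)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_genes = 2.5), "n_genes")
  expect_error(sim_config(censoring_rate = 1.2), "censoring_rate")
  expect_error(sim_config(mut_rate = -1), "mut_rate")
  expect_error(sim_config(planted_amp = list(list(
    gene = "G001", tumour_type = "TT1", frequency = 1.4,
    log2_boost = 1))), "frequency")
  expect_error(sim_config(planted_meth = list(list(
    gene = "G001", tumour_type = "TT1", target_r = 0.5,
    delta_beta = 0.1))), "target_r")
  expect_error(sim_config(planted_de = list(list(gene = "G001"))),
               "planted_de")
  expect_error(simulate_cohort(sim_config(planted_de = list(list(
    gene = "NOPE", tumour_type = "TT1", log2_effect = 1)))), "NOPE")
})

test_that("write_cohort/read_cohort round-trips the cohort", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(small_cfg(
    planted_de = list(list(gene = "G002", tumour_type = "TT1",
                           log2_effect = 1))))
  manifest <- write_cohort(coh, dir)
  expect_true(all(file.exists(manifest)))
  back <- read_cohort(dir)
  expect_equal(back$expression, coh$expression, tolerance = 1e-12)
  expect_equal(back$methylation, coh$methylation, tolerance = 1e-12)
  expect_equal(back$gene_effect, coh$gene_effect, tolerance = 1e-12)
  expect_equal(back$mutations, coh$mutations)
  expect_equal(back$samples, coh$samples)
  expect_equal(back$genes, coh$genes)
  expect_equal(back$survival$time, coh$survival$time, tolerance = 1e-12)
  expect_equal(back$truth$planted_de[[1]]$gene, "G002")
})

test_that("empty mutation table writes a valid header-only file", {
  coh <- simulate_cohort(small_cfg(mut_rate = 1e-12))
  expect_equal(nrow(coh$mutations), 0)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  lines <- readLines(file.path(dir, "mutations.tsv"))
  expect_length(lines, 1)
  expect_match(lines, "^sample\tgene\tprotein_pos")
  back <- read_cohort(dir)
  expect_equal(nrow(back$mutations), 0)
})
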