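test_that("probe region filter keeps the regulatory window", {
  probes <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    gene = c("GA", "GA", "GB", NA, "GC"),
    region = c("promoter_2kb", "first_intron", "gene_body",
               "promoter_2kb", "upstream_5kb"),
    stringsAsFactors = FALSE)
  expect_warning(keep <- probe_region_filter(probes), "excluded")
  expect_equal(keep$probe_id, c("p1", "p2", "p3"))
  expect_equal(probe_region_filter(keep, genes = "GA")$probe_id,
               c("p1", "p2"))
  expect_equal(nrow(probe_region_filter(probes[0, ])), 0)
})

# A hand-built single-tissue world where every quantity is checkable by
# cor()/t.test() directly.
toy_meth_world <- function(beta_tumour, beta_normal, expr_tumour,
                           gene = "GA", region = "first_intron") {
  nt <- length(beta_tumour); nn <- length(beta_normal)
  sm <- toy_samples(nt, nn)
  tum <- sm$sample[sm$tumour_or_normal == "tumour"]
  nrm <- sm$sample[sm$tumour_or_normal == "normal"]
  meth <- matrix(c(beta_tumour, beta_normal), nrow = 1,
                 dimnames = list("p1", c(tum, nrm)))
  expr <- matrix(c(expr_tumour, rep(mean(expr_tumour), nn)), nrow = 1,
                 dimnames = list(gene, c(tum, nrm)))
  probes <- data.frame(probe_id = "p1", gene = gene, region = region,
                       stringsAsFactors = FALSE)
  de <- data.frame(gene = gene, tissue = "TX", log2_fc = 1, p = 1e-6,
                   stringsAsFactors = FALSE)
  list(sm = sm, meth = meth, expr = expr, probes = probes, de = de)
}

test_that("perfect anti-correlation gives r = -1", {
  w <- toy_meth_world(beta_tumour = c(0.1, 0.2, 0.3),
                      beta_normal = c(0.5, 0.5, 0.5),
                      expr_tumour = c(3, 2, 1))
  res <- methylation_expression_screen(w$meth, w$probes, w$expr, w$sm,
                                       w$de)
  expect_equal(res$r, -1)
  expect_true(res$pass_r)
})

test_that("beta floor fails low-methylation probes regardless of r", {
  w <- toy_meth_world(beta_tumour = c(0.10, 0.12, 0.14, 0.16),
                      beta_normal = c(0.18, 0.18, 0.18, 0.18),
                      expr_tumour = c(4, 3, 2, 1))
  res <- methylation_expression_screen(w$meth, w$probes, w$expr, w$sm,
                                       w$de)
  expect_true(res$pass_r)       # strongly anti-correlated
  expect_false(res$pass_floor)  # both means below 0.2
  expect_false(res$passes)
})

test_that("statistics agree with stats:: oracles on the toy world", {
  set.seed(99)
  bt <- pmin(pmax(rnorm(15, 0.3, 0.08), 0.01), 0.99)
  bn <- pmin(pmax(rnorm(15, 0.5, 0.08), 0.01), 0.99)
  ex <- rnorm(15, 5, 1)
  w <- toy_meth_world(bt, bn, ex)
  res <- methylation_expression_screen(w$meth, w$probes, w$expr, w$sm,
                                       w$de)
  expect_equal(res$p_beta, t.test(bt, bn, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  expect_equal(res$r, cor(bt, ex), tolerance = 1e-10)
  expect_equal(res$p_r, cor.test(bt, ex)$p.value, tolerance = 1e-10)
  expect_equal(res$delta_beta, mean(bt) - mean(bn), tolerance = 1e-12)
})

test_that("criteria are conjunctive and order-free", {
  coh <- simulate_cohort(strong_config(seed = 13))
  de <- de_screen(coh$expression, coh$samples)
  pr <- probe_region_filter(coh$probes)
  res <- methylation_expression_screen(coh$methylation, pr,
                                       coh$expression, coh$samples,
                                       de$results, gate_fc = 1)
  expect_gt(nrow(res), 0)
  expect_equal(res$passes,
               res$pass_floor & res$pass_delta & res$pass_r & res$pass_gate)
})

test_that("relaxing any single threshold never removes a passing probe", {
  coh <- simulate_cohort(strong_config(seed = 13))
  de <- de_screen(coh$expression, coh$samples)
  pr <- probe_region_filter(coh$probes)
  base <- methylation_expression_screen(coh$methylation, pr,
                                        coh$expression, coh$samples,
                                        de$results, gate_fc = 1)
  key <- function(r) paste(r$probe_id, r$tissue)[r$passes]
  relaxed <- list(
    methylation_expression_screen(coh$methylation, pr, coh$expression,
                                  coh$samples, de$results, gate_fc = 1,
                                  beta_floor = 0.1),
    methylation_expression_screen(coh$methylation, pr, coh$expression,
                                  coh$samples, de$results, gate_fc = 1,
                                  delta_beta_min = 0.05),
    methylation_expression_screen(coh$methylation, pr, coh$expression,
                                  coh$samples, de$results, gate_fc = 1,
                                  p_beta = 0.2),
    methylation_expression_screen(coh$methylation, pr, coh$expression,
                                  coh$samples, de$results, gate_fc = 1,
                                  r_max = -0.05))
  for (r in relaxed) expect_true(all(key(base) %in% key(r)))
})

test_that("tumour-only correlation ignores normal samples", {
  coh <- simulate_cohort(strong_config(seed = 17))
  de <- de_screen(coh$expression, coh$samples)
  pr <- probe_region_filter(coh$probes)
  res1 <- methylation_expression_screen(coh$methylation, pr,
                                        coh$expression, coh$samples,
                                        de$results)
  # permute normal-sample methylation values: r must be unchanged
  perm <- coh$methylation
  nrm <- coh$samples$sample[coh$samples$tumour_or_normal == "normal"]
  set.seed(1)
  perm[, nrm] <- perm[, sample(nrm)]
  res2 <- methylation_expression_screen(perm, pr, coh$expression,
                                        coh$samples, de$results)
  expect_equal(res2$r, res1$r)
})

test_that("the strong planted probe passes the full screen", {
  coh <- simulate_cohort(strong_config(seed = 23))
  de <- de_screen(coh$expression, coh$samples)
  pr <- probe_region_filter(coh$probes)
  res <- methylation_expression_screen(coh$methylation, pr,
                                       coh$expression, coh$samples,
                                       de$results)
  pid <- coh$truth$planted_meth[[1]]$probe_id
  hit <- res[res$probe_id == pid & res$tissue == "TT1", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$passes)
  expect_lt(hit$r, -0.2)
})
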