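# Shared fixtures: configurations used across tests. All cohorts are
# generated in code at test time; nothing is stored on disk.

# Null cohort: no planted effects anywhere (calibration world).
null_config <- function(seed, ...) {
  sim_config(seed = seed, ...)
}

# The documented "strong" planted defaults: one signal per screen at the
# effect sizes every recovery contract quotes (DE log2 effect 1.0;
# methylation delta-beta 0.2 with target r -0.6; amplification at 12%
# frequency with log2 boost 1.0; truncating hotspot of count 5; essential
# gene mean effect -1.0; compensation at default strength 0.2; survival
# log-hazard 0.7 per SD). The methylation target gene also carries the DE
# effect because the methylation screen is gated on expression change.
strong_config <- function(seed, n_tumour_samples_per_type = 30,
                          n_normal_samples_per_type = 30, ...) {
  sim_config(
    seed = seed,
    n_tumour_samples_per_type = n_tumour_samples_per_type,
    n_normal_samples_per_type = n_normal_samples_per_type,
    planted_de = list(
      list(gene = "G010", tumour_type = "TT1", log2_effect = 1.0),
      list(gene = "G011", tumour_type = "TT2", log2_effect = 1.0)),
    planted_meth = list(
      list(gene = "G010", tumour_type = "TT1", target_r = -0.6,
           delta_beta = 0.2)),
    planted_amp = list(
      list(gene = "G020", tumour_type = "TT2", frequency = 0.12,
           log2_boost = 1.0)),
    planted_hotspot = list(
      list(gene = "G030", position = 2, alt_residue = "*", count = 5)),
    planted_essential = list(list(gene = "G040", mean_effect = -1.0)),
    planted_compensation = list(
      list(dependent_gene = "G050", buffer_gene = "G051",
           strength = 0.2)),
    planted_codep = list(
      list(gene_a = "G060", gene_b = "G061", latent_sd = 0.3)),
    planted_survival = list(
      list(gene = "G070", tumour_type = "TT3", log_hazard_per_sd = 0.7)),
    ...)
}

# A small hand-built sample table: one tissue, explicit group sizes.
toy_samples <- function(n_tumour, n_normal, tissue = "TX") {
  data.frame(
    sample = c(sprintf("%s_T%02d", tissue, seq_len(n_tumour)),
               sprintf("%s_N%02d", tissue, seq_len(n_normal))),
    tissue = tissue,
    tumour_or_normal = c(rep("tumour", n_tumour), rep("normal", n_normal)),
    tumour_type = tissue,
    stringsAsFactors = FALSE)
}

# Minimal MAF-like record builder.
mut_rec <- function(sample, gene, pos, ref, alt, consequence = "missense",
                    tumour_type = "TX") {
  data.frame(sample = sample, gene = gene, protein_pos = pos,
             ref_aa = ref, alt_aa = alt, consequence = consequence,
             tumour_type = tumour_type, stringsAsFactors = FALSE)
}
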