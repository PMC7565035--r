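# Independent brute-force oracle for the N-terminus routing rules.
# This is a second, deliberately separate encoding of the specificity
# table (a flat lookup, no shared code with route_nterm) used to verify
# the rule engine exhaustively.

oracle_p2_class <- c(
  A = "NatA", C = "NatA", G = "NatA", S = "NatA", T = "NatA", V = "NatA",
  P = "blocked",
  D = "NatB", E = "NatB", N = "NatB", Q = "NatB",
  L = "NatC_E_F", I = "NatC_E_F", F = "NatC_E_F", W = "NatC_E_F",
  M = "NatC_E_F", Y = "NatC_E_F", K = "NatC_E_F", H = "NatC_E_F",
  R = "unacetylated")

oracle_acetylated <- c(NatA = TRUE, NatB = TRUE, NatC_E_F = TRUE,
                       NatD_motif = TRUE, blocked = FALSE,
                       unacetylated = FALSE)

# Effect of a P2 exchange ref -> alt in a non-motif context.
oracle_p2_effect <- function(ref, alt) {
  b <- oracle_p2_class[[ref]]
  a <- oracle_p2_class[[alt]]
  b_ac <- oracle_acetylated[[b]]
  a_ac <- oracle_acetylated[[a]]
  if (b_ac && a_ac) {
    if (b == a) "preserves_class" else "changes_class"
  } else if (b_ac && !a_ac) "abolishes_ntac"
  else if (!b_ac && a_ac) "gains_ntac"
  else if (b == a) "preserves_class" else "changes_class"
}
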