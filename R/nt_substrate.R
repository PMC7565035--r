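# N-terminal substrate routing rule engine.
#
# After translation every protein starts with the initiator methionine
# (iMet, position P1). Methionine aminopeptidases (MAP) remove iMet when
# the second residue (P2) is small; the exposed residue, or the retained
# iMet, then determines which N-terminal acetyltransferase (NAT) complex
# can acetylate the protein:
#
#   * iMet cleaved (P2 in A,C,G,P,S,T,V):
#       - post-cleavage N-terminus matching the histone motif (default
#         SGRG) -> NatD (NAA40); motif check precedes generic routing
#       - P2 in S,A,C,T,V,G -> NatA
#       - P2 = P -> blocked (proline N-termini are not acetylated)
#   * iMet retained:
#       - P2 in D,E,N,Q -> NatB
#       - P2 in L,I,F,W,M,Y,K,H -> NatC/NatE/NatF (one bucket; these
#         complexes share Met-starting substrates and the screens never
#         need finer granularity)
#       - otherwise (P2 = R) -> unacetylated
#
# Only the partial specificities are published; the full residue
# partition above is this package's documented completion (see the
# methods vignette).

CLEAVED_SET <- c("A", "C", "G", "P", "S", "T", "V")
NATA_SET <- c("S", "A", "C", "T", "V", "G")
NATB_SET <- c("D", "E", "N", "Q")
NATCEF_SET <- c("L", "I", "F", "W", "M", "Y", "K", "H")
NAT_CLASSES <- c("NatA", "NatB", "NatC_E_F", "NatD_motif",
                 "unacetylated", "blocked")
ACETYLATING_CLASSES <- c("NatA", "NatB", "NatC_E_F", "NatD_motif")
NT_EFFECTS <- c("initiator_loss", "preserves_class", "changes_class",
                "abolishes_ntac", "gains_ntac", "motif_disrupting",
                "outside_nterm")

validate_nterm <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  if (length(res) < 2)
    stop("N-terminal sequence must have length >= 2", call. = FALSE)
  bad <- which(!res %in% AA20)
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d",
                 res[bad[1]], bad[1]), call. = FALSE)
  res
}

#' Route a protein N-terminus to a NAT complex
#'
#' Applies the iMet-cleavage and NAT-specificity rule table to the first
#' residues of a protein and reports the predicted acetylation route.
#' The histone motif check (NatD/NAA40) takes precedence over generic
#' NatA routing: serine-starting cleaved N-termini that continue with the
#' motif are histone substrates, not NatA substrates.
#'
#' @param seq Character scalar, one-letter amino-acid codes, P1 first
#'   (P1 is normally the initiator methionine). Length >= 2; only P1-P5
#'   influence the result.
#' @param motif Histone N-terminal motif matched against the
#'   post-cleavage sequence (default `"SGRG"`, the shared H2A/H4
#'   N-terminus recognised by NAA40).
#' @return A list of class `nat_routing` with elements `cleaved`
#'   (logical; iMet removed by MAP), `nat_class` (one of `"NatA"`,
#'   `"NatB"`, `"NatC_E_F"`, `"NatD_motif"`, `"unacetylated"`,
#'   `"blocked"`) and `acetylated_residue` (1-based position of the
#'   acetylated residue on the uncleaved sequence: 2 for cleaved
#'   substrates, 1 for retained-Met substrates, `NA` when nothing is
#'   acetylated).
#' @examples
#' route_nterm("MSGRGKQGGK") # histone-like: NatD motif
#' route_nterm("MDVFMKGLSK") # retained Met, NatB
#' route_nterm("MPKRRA")     # cleaved, blocked proline N-terminus
#' @export
route_nterm <- function(seq, motif = "SGRG") {
  res <- validate_nterm(seq)
  p2 <- res[2]
  cleaved <- p2 %in% CLEAVED_SET
  if (cleaved) {
    post <- res[-1]
    mres <- strsplit(motif, "")[[1]]
    is_motif <- length(post) >= length(mres) &&
      all(post[seq_along(mres)] == mres)
    if (is_motif) {
      cls <- "NatD_motif"; ac <- 2L
    } else if (p2 %in% NATA_SET) {
      cls <- "NatA"; ac <- 2L
    } else {
      cls <- "blocked"; ac <- NA_integer_   # P2 == "P"
    }
  } else if (p2 %in% NATB_SET) {
    cls <- "NatB"; ac <- 1L
  } else if (p2 %in% NATCEF_SET) {
    cls <- "NatC_E_F"; ac <- 1L
  } else {
    cls <- "unacetylated"; ac <- NA_integer_
  }
  structure(list(cleaved = cleaved, nat_class = cls,
                 acetylated_residue = ac),
            class = "nat_routing")
}

#' @export
print.nat_routing <- function(x, ...) {
  cat(sprintf("N-terminus routing: %s (iMet %s%s)\n", x$nat_class,
              if (x$cleaved) "cleaved" else "retained",
              if (is.na(x$acetylated_residue)) ", not acetylated"
              else sprintf(", acetylated at P%d", x$acetylated_residue)))
  invisible(x)
}

compare_routing <- function(before, after) {
  b_ac <- before$nat_class %in% ACETYLATING_CLASSES
  a_ac <- after$nat_class %in% ACETYLATING_CLASSES
  if (b_ac && a_ac) {
    if (before$nat_class == after$nat_class) "preserves_class"
    else "changes_class"
  } else if (b_ac && !a_ac) {
    "abolishes_ntac"
  } else if (!b_ac && a_ac) {
    "gains_ntac"
  } else {
    # neither route is acetylated (blocked <-> unacetylated)
    if (before$nat_class == after$nat_class) "preserves_class"
    else "changes_class"
  }
}

#' Classify the Nt-acetylation effect of an N-terminal missense change
#'
#' Routes the sequence before and after the substitution and compares the
#' NAT assignments. P1 substitutions of the initiator methionine are
#' always `initiator_loss` (iMet loss is a translation-level event whose
#' consequence cannot be read off the routing table); positions beyond P5
#' are `outside_nterm`.
#'
#' @inheritParams route_nterm
#' @param position 1-based position on the translated protein (P1 = iMet).
#' @param alt Replacement residue (one-letter code), different from the
#'   reference residue at `position`.
#' @return A list of class `nt_mutation_effect` with elements `effect`
#'   (one of `"initiator_loss"`, `"preserves_class"`, `"changes_class"`,
#'   `"abolishes_ntac"`, `"gains_ntac"`, `"outside_nterm"`), `before` and
#'   `after` (`nat_routing` objects, `NULL` for `initiator_loss` /
#'   `outside_nterm`), `ref` and `position`.
#' @examples
#' classify_substitution("MSLLEA", 2, "A")$effect # NatA -> NatA
#' classify_substitution("MDLLEA", 2, "E")$effect # NatB -> NatB
#' classify_substitution("MSLLEA", 2, "D")$effect # NatA -> NatB
#' @export
classify_substitution <- function(seq, position, alt, motif = "SGRG") {
  res <- validate_nterm(seq)
  if (position < 1 || position > length(res))
    stop(sprintf("position %d out of range 1..%d", position, length(res)),
         call. = FALSE)
  if (!alt %in% AA20)
    stop("alt residue must be a standard one-letter code", call. = FALSE)
  ref <- res[position]
  if (alt == ref)
    stop("alt residue equals the reference residue", call. = FALSE)
  mk <- function(effect, before = NULL, after = NULL) {
    structure(list(effect = effect, before = before, after = after,
                   ref = ref, position = position, alt = alt),
              class = "nt_mutation_effect")
  }
  if (position > 5) return(mk("outside_nterm"))
  if (position == 1 && ref == "M") return(mk("initiator_loss"))
  before <- route_nterm(seq, motif = motif)
  res2 <- res
  res2[position] <- alt
  after <- route_nterm(paste(res2, collapse = ""), motif = motif)
  mk(compare_routing(before, after), before, after)
}

#' Classify a substitution within the histone N-terminal motif
#'
#' For histone-like proteins whose post-cleavage N-terminus carries the
#' NAA40 recognition motif, any substitution inside the motif destroys
#' NatD targeting. Positions are counted on the cleaved protein (the
#' motif serine is position 1).
#'
#' @param histone_nterm Uncleaved N-terminal sequence (P1 = iMet) whose
#'   post-cleavage N-terminus must match `motif`.
#' @param position 1-based position on the cleaved protein.
#' @param alt Replacement residue.
#' @inheritParams route_nterm
#' @return An `nt_mutation_effect` list; `effect` is
#'   `"motif_disrupting"` for positions within the motif and
#'   `"outside_nterm"` otherwise.
#' @examples
#' classify_motif_mutation("MSGRGKQGGK", 1, "C")$effect # S1C
#' classify_motif_mutation("MSGRGKQGGK", 3, "Q")$effect # R3Q
#' @export
classify_motif_mutation <- function(histone_nterm, position, alt,
                                    motif = "SGRG") {
  res <- validate_nterm(histone_nterm)
  before <- route_nterm(histone_nterm, motif = motif)
  if (before$nat_class != "NatD_motif")
    stop("post-cleavage N-terminus does not match the histone motif '",
         motif, "'", call. = FALSE)
  nmotif <- nchar(motif)
  full_pos <- position + 1L   # cleaved position 1 is P2 of the full protein
  if (position < 1 || full_pos > length(res))
    stop(sprintf("position %d out of range on the cleaved protein", position),
         call. = FALSE)
  if (!alt %in% AA20)
    stop("alt residue must be a standard one-letter code", call. = FALSE)
  ref <- res[full_pos]
  if (alt == ref)
    stop("alt residue equals the reference residue", call. = FALSE)
  if (position > nmotif) {
    return(structure(list(effect = "outside_nterm", before = before,
                          after = NULL, ref = ref, position = position,
                          alt = alt),
                     class = "nt_mutation_effect"))
  }
  res2 <- res
  res2[full_pos] <- alt
  after <- route_nterm(paste(res2, collapse = ""), motif = motif)
  structure(list(effect = "motif_disrupting", before = before, after = after,
                 ref = ref, position = position, alt = alt),
            class = "nt_mutation_effect")
}

#' @export
print.nt_mutation_effect <- function(x, ...) {
  cat(sprintf("%s%d%s: %s\n", x$ref, x$position, x$alt, x$effect))
  invisible(x)
}

#' Exhaustive P2 substitution truth table
#'
#' Materialises [classify_substitution()] for all 20 x 19 possible P2
#' exchanges (reference residue x non-identical replacement) in a neutral
#' non-motif context, giving the complete map from P2 exchange to
#' Nt-acetylation consequence.
#'
#' @inheritParams route_nterm
#' @return A 380-row `data.frame` with columns `ref`, `alt`,
#'   `class_before`, `class_after`, `effect`.
#' @export
substitution_truth_table <- function(motif = "SGRG") {
  grid <- expand.grid(ref = AA20, alt = AA20, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  grid <- grid[order(grid$ref, grid$alt), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ref <- grid$ref[i]; alt <- grid$alt[i]
    seq <- paste0("M", ref, "LLLLL")   # L context: never completes a motif
    eff <- classify_substitution(seq, 2L, alt, motif = motif)
    data.frame(ref = ref, alt = alt,
               class_before = eff$before$nat_class,
               class_after = eff$after$nat_class,
               effect = eff$effect, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate a mutation table with N-terminal acetylation effects
#'
#' Adds an `nt_effect` column to a MAF-like mutation table: missense
#' records at protein positions 1-5 are classified through
#' [classify_substitution()] (using each gene's N-terminal sequence when
#' supplied, otherwise a neutral context built from the record's
#' reference residue); everything else is `outside_nterm` or `NA` for
#' non-missense records.
#'
#' @param mutations Data frame with columns `gene`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `consequence`.
#' @param gene_models Optional data frame with columns `symbol`,
#'   `nterm_seq` supplying real N-terminal sequences.
#' @inheritParams route_nterm
#' @return `mutations` with an added character column `nt_effect`.
#' @export
annotate_nterm_effects <- function(mutations, gene_models = NULL,
                                   motif = "SGRG") {
  nterm <- NULL
  if (!is.null(gene_models))
    nterm <- stats::setNames(gene_models$nterm_seq, gene_models$symbol)
  eff <- rep(NA_character_, nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    if (mutations$consequence[i] != "missense") next
    pos <- mutations$protein_pos[i]
    if (pos > 5) { eff[i] <- "outside_nterm"; next }
    if (!is.null(nterm) && mutations$gene[i] %in% names(nterm)) {
      seq <- nterm[[mutations$gene[i]]]
    } else {
      # neutral context: place the record's own ref residue at the position
      res <- c("M", "L", "L", "L", "L", "L")
      res[pos] <- mutations$ref_aa[i]
      seq <- paste(res, collapse = "")
    }
    res <- strsplit(seq, "")[[1]]
    if (pos > length(res) || res[pos] != mutations$ref_aa[i] ||
        mutations$ref_aa[i] == mutations$alt_aa[i]) {
      eff[i] <- "ref_mismatch"
      next
    }
    eff[i] <- classify_substitution(seq, pos, mutations$alt_aa[i],
                                    motif = motif)$effect
  }
  mutations$nt_effect <- eff
  mutations
}
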