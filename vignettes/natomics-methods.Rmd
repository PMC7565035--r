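---
title: "Methods: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natomics)
```

This vignette is the package's own account of its science: the model
behind each screen, the defaults and why they hold, the choices made
where the published record is incomplete, and what a green test does and
does not establish. It states no empirical result that the test suite
does not itself compute.

## 1. The N-terminus routing rule table

Nt-acetylation routing is determined almost entirely by the second
residue (P2) of the translated protein. Methionine aminopeptidases (MAP)
remove the initiator methionine when P2 is small; the published
specificity statements, however, only cover parts of the residue
alphabet: the NatA set after cleavage (S/A/C/T/V/G), the fact that
NatB/NatC/NatE/NatF act on Met-retaining N-termini with examples
(aspartate for NatB), and the histone SGRG motif for NatD. The engine
therefore completes the partition, and the completion is a documented
design choice rather than a citation:

| P2 residue | iMet | class |
|---|---|---|
| A C G S T V | cleaved | NatA (acetylated at the new N-terminus) |
| P | cleaved | blocked — proline N-termini are not acetylated |
| D E N Q | retained | NatB (acidic/amide side chains) |
| L I F W M Y K H | retained | NatC/NatE/NatF (one bucket: hydrophobic/basic) |
| R | retained | unacetylated |

Choices worth flagging:

* **NatC/E/F are one bucket.** The literature treats their Met-retaining
  substrates collectively, and every consumer in this package (the
  "class-preserving exchange" count) only needs that granularity.
* **The histone motif is SGRG** (S1-G2-R3-G4 on the cleaved protein),
  configurable via the `motif` argument. The published record spells it
  both "SGRG" and "SRGR" in different places; only SGRG is consistent
  with the reported S1/R3 mutation hotspots (R at position 3), so SGRG is
  the default and the string is exposed rather than hard-coded.
* **Motif precedence.** A serine-starting N-terminus that continues with
  the motif is a NatD substrate, never NatA, even though S is in the NatA
  set. This ordering is load-bearing and has its own property test.
* **P1 policy.** Any missense at P1 (the iMet) is `initiator_loss` and is
  never interpreted through the routing table: losing the initiator
  affects translation itself, so downstream routing would be fiction.
* **Effect vocabulary.** Exchanges between two *acetylated* classes are
  `preserves_class`/`changes_class`; acetylated → non-acetylated is
  `abolishes_ntac`, the reverse `gains_ntac`. Exchanges between the two
  non-acetylated states (blocked ↔ unacetylated) are reported as
  `changes_class` — neither gains nor loses acetylation, but the
  N-terminal chemistry does change.

The engine is verified two ways: an exhaustive 380-row truth table
(`substitution_truth_table()`) that must agree with
`classify_substitution()` row for row, and an independently written
brute-force oracle in the test suite (a flat residue→class lookup with
separate effect logic) that must agree on all 380 P2 exchanges.

## 2. Genomic burden screens

*Frequencies.* Denominators are always profiled samples per tumour type,
never mutated samples, and a sample counts once per gene no matter how
many alterations it carries. "Alteration" means a non-silent mutation or
a high-level CNV call (|call| = 2); single-copy gains/losses are
excluded, matching the convention of GISTIC-thresholded call sets. The
flagging threshold defaults to 5%.

*ORF-normalised burden.* Mutation counts per class (missense;
truncating = nonsense + frameshift + splice) are divided by ORF length
in amino acids and then by the reference gene's count-per-residue, so
the reference gene scores exactly 1 in each class and the two classes
are normalised independently. A class in which the reference gene has no
mutations is *undefined* (`NA`), never zero — silently reporting 0 would
invert the meaning of the statistic.

*Recurrence.* A recurrent event is an identical (gene, position, alt
residue, consequence) tuple: requiring the alternate residue
distinguishes S1C from S1F at the same site, which matters because
specific exchanges (not just positions) recur. Multi-copy families
(e.g. histone H2A/H4 genes) can be pooled with a user-supplied
`gene_group` mapping applied before counting; pooled ORF length is the
sum of member lengths.

*Amplification–expression.* Student's t-test (pooled variance) is the
default because that is the classical convention in this literature;
Welch is available by flag. Groups below 3 samples make the pair *not
evaluable* rather than p = 1.

## 3. Differential expression

Log2(x+1)-scale group means, Student's t-test, fold change as the
difference of means — so the 1.5-fold rule is the band |log2FC| ≥
log2(1.5) ≈ 0.585. Only tissues with at least 10 tumour and 10 normal
samples are eligible. The default p-threshold is 0.01, with 0.05
available by argument: the published sources disagree between text and
figure legend, so both are supported rather than silently resolved.
**No multiple-testing correction is applied in this screen** — hits are
raw-threshold calls, and FDR control appears only in the survival
screen. This mirrors how such tallies are reported in practice, and is
why the screen's output should be read as a descriptive tally, not an
inferential discovery set.

## 4. Methylation–expression anti-correlation

Four conjunctive, order-free criteria per probe per tissue:

1. *Region*: probe annotated to the promoter (≤ 2 kb upstream of the
   TSS), gene body, or first intron of a studied gene.
2. *Floor*: max(mean β tumour, mean β normal) > 0.2 — probes unmethylated
   in both groups carry no signal.
3. *Differential methylation*: |Δβ| ≥ 0.1 with two-sided t-test p < 0.05
   (the Methods-section version of the published thresholds; the
   Results-section text differs — median vs mean, p < 0.01 — and both
   knobs are exposed).
4. *Anti-correlation*: Pearson r ≤ −0.2 between β and log2 expression
   over tumour samples of the tissue (normals can be included by flag).

plus the *gate*: the probe's gene must show ≥ 1.5-fold expression change
in that tissue. Conjunctivity and single-threshold monotonicity
(relaxing any one threshold never removes a passing probe) are tested as
properties.

One calibration subtlety: the marginal r ≤ −0.2 criterion alone passes
~14.5% of null probes at n = 30 tumours — that is simply
P(r ≤ −0.2 | ρ = 0, n = 30) under the t-distribution of a Pearson
correlation, a property of using a fixed effect-size cut-off without a
p-value. The screen's discoveries are conjunctions, and every
combination involving the differential-methylation test is calibrated
below 5% under the null (verified over 50 seeds).

## 5. CRISPR dependency

*Essentiality percentile* is 100 × (fraction of genes with strictly
greater median effect): the most essential of N genes scores
100·(N−1)/N, and the percentile is a strictly monotone transform of the
median. *Dependent fraction* uses a gene-effect ≤ −0.5 proxy; public
portals publish dependency probabilities, which this package does not
model, so the proxy threshold is exposed. Correlations
(co-dependency and compensation) use pairwise-complete observations;
co-dependency is flagged at raw p < 0.05 by default (matching the
no-correction convention of the source analyses) with BH available.
In the *compensation screen*, positive r means buffering — cell lines
expressing more of the candidate tolerate knockout of the dependent gene
better — and candidates are ranked descending with ties broken by gene
name.

## 6. Survival

The Cox fit is a single-covariate Newton–Raphson maximiser of the
Breslow partial likelihood (gradient tolerance 1e-8, ≤ 25 iterations),
written in-package and cross-checked against `survival::coxph(ties =
"breslow")` to 1e-6 in the test suite; Kaplan–Meier estimation and the
log-rank test are delegated to the `survival` package. Expression is
z-scored within tumour type by default so coefficients are per SD —
the external service that produced the published survival table does not
document its scaling, so per-SD continuous Cox is this package's
documented choice (raw scale by flag). BH-FDR is applied across the
*entire* gene × tumour family in one batch — the conservative reading —
and pairs with fewer than 10 events or non-converged fits are excluded
from the family rather than entering it with meaningless p-values.

## 7. The synthetic cohort: what it emulates, what it does not

The generator stands in for the external multi-omic compendia the
original analyses consumed. Its stated world:

* **Expression**: per-gene baselines uniform on log2 [3, 8], per-tissue
  offsets N(0, 0.25), sample noise N(0, 0.5) — the typical spread of
  log2(x+1) RNA-seq gene summaries. Planted fold changes shift tumour
  samples of one type additively.
* **Methylation**: background probes are Beta-distributed with
  precision 50 around a per-probe mean drawn from Beta(2, 2). A planted
  probe (always the gene's first-intron probe, echoing the biology that
  motivated the screen) is generated by monotone coupling to the gene's
  standardised tumour expression: β = 0.5 − Δβ + 0.1·(ρ·z +
  √(1−ρ²)·ε), clipped to (0, 1), which hits the target correlation up to
  clipping loss.
* **Mutations**: per-gene Poisson with rate 2.5e-5 per residue per
  tumour sample — chosen so a ~400-aa gene is mutated in about 1% of
  samples, the order of magnitude reported for NAT genes — with uniform
  positions, uniform alternate residues, and a fixed consequence mix
  (70% missense, 21% truncating, 9% silent/other). Hotspots are planted
  as exact record counts; a `"*"` alternate residue makes them nonsense.
* **CNV**: thresholded calls only, background P(±2) = 0.5% and
  P(±1) = 3% per gene per tumour sample; planted amplifications pick
  carriers at the configured frequency and add the expression boost.
* **Gene effects**: background N(0, 0.15); essential genes re-centred at
  their planted mean; compensation adds `strength` × z(buffer
  expression) to the dependent gene's row (strength 0.2 over noise 0.15
  gives r ≈ 0.8, the regime of a strong buffering paralog); co-dependent
  pairs share a latent N(0, 0.3) per-line factor.
* **Survival**: exponential baseline (0.02/month — median ~35 months),
  hazard × exp(coef · z(expression)) within tumour type, uniform
  censoring with the window solved numerically to hit the configured
  censoring fraction (~30%).
* **Determinism**: one master seed feeds an independent RNG sub-stream
  per data type, so adding or re-parameterising one data type never
  perturbs another's draws, and identical configurations are
  bit-identical.

What it does **not** emulate: count-level noise and library-size
effects, probe cross-hybridisation and region-level smoothing,
mutational signatures and selection, copy-number segmentation,
cell-line lineage structure, or non-proportional hazards. A green
recovery test therefore establishes that each screen implements its
statistical contract and finds what its model class says it should — not
that the thresholds are optimal for any particular real compendium.

One coupling is deliberate and worth knowing: the methylation screen is
gated on expression change, so a planted methylation signal is only
discoverable when the same gene–tissue pair also carries an expression
effect; the bundled "strong" configuration plants both together.

## 8. Numerical and tie-break conventions

* Student (pooled) t-tests throughout where the classical convention
  applies; zero-variance or undersized groups yield `NA` ("not
  evaluable"), never p = 1 or p = 0.
* Recurrence ordering: count descending, then gene name, then position.
  Compensation and cumulative-rank ties break by gene name. These rules
  make every output byte-deterministic, which `run_all()` guarantees
  end-to-end and the tests check literally (file comparison).
* TSV writers format doubles at 15 significant digits; round-trips
  through `write_cohort()`/`read_cohort()` are lossless at 1e-12.
* Newton Cox: β starts at 0; non-convergence flags the pair and removes
  it from the FDR family.

## 9. Known limitations

* The rule table's retained-Met buckets complete a partially published
  specificity map; organisms or contexts with different MAP kinetics or
  NAT repertoires need a different table (the motif is configurable, the
  buckets currently are not).
* The survival screen is univariate by design — no stratification,
  time-varying covariates, or competing risks.
* The published numeric results of the source analyses (alteration
  percentages, specific correlation values, survival coefficients)
  derive from external downloads and are deliberately *not* acceptance
  surfaces for this package; acceptance is property-based on the
  synthetic world.
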