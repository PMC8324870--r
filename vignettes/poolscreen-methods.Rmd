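---
title: "Methods: scoring pooled in vivo shRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring pooled in vivo shRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The experimental design this package models

A pooled shRNA dropout screen infects a cell population with a lentiviral
library at low multiplicity of infection (MOI ≈ 0.3), so most infected
cells carry a single integration and hence a single barcode. A reference
aliquot is sequenced before transplantation; the rest is injected into
mice (here, several patient-derived xenograft models, three tumor
replicates each). Hairpins that knock down genes required for tumor growth
deplete relative to the reference pool. The analysis problem is to turn raw
barcode-amplicon reads into per-screen gene essentiality calls and a
cross-model intersection, while distinguishing true dropout from the
stochastic losses imposed by the engraftment bottleneck.

## Deconvolution

Reads are filtered on a 4-bp `CGAA` spacer at bases 18–21 (1-based,
inclusive; at most one mismatch, `N` counts as a mismatch), and the 18-nt
barcode is sliced from bases 23–40 for targeting libraries or 1–18 for a
nontargeting library. Base 22 is a linker and is ignored. Coordinates are
1-based in the user-facing API and converted once, centrally
(`R/deconvolve.R` constants).

Barcodes are matched to the library by exact lookup first, then by unique
Hamming-distance-1 neighbourhood: a sequence one mismatch away from exactly
one library barcode is assigned to it; a sequence one mismatch away from
two barcodes is left unassigned. For fixed-length ungapped tags this
deterministic rule is at least as strict as a short-read aligner and has no
tunable scoring. Every read lands in exactly one tally — assigned,
unassigned, spacer failure, extraction failure — and the suite asserts
conservation of the total.

Quality strings are ignored; there is no adapter trimming or paired-end
support.

## Scoring

* **Normalization.** Reads per million with denominator = assigned reads
  for the sample, not raw FASTQ reads: spacer and assignment failures are
  technical artifacts of the amplicon and flow cell, not biology.
* **Fold change.** `log2((x_t + ε)/(x_ref + ε))` with ε = 0.5 RPM on both
  sides. In vivo bottlenecks produce genuine zero counts; a symmetric
  pseudocount keeps them finite and keeps LFC(ref, ref) ≡ 0. At the default
  depth (5e6 reads over 2,400 hairpins ≈ 2,000 RPM per hairpin) ε is
  negligible except at true dropout.
* **Robust z.** `(LFC − median)/(c · MAD)` with the standard consistency
  constant c = 1.4826, computed per replicate across all N hairpins. The
  constant is a config switch (`mad_constant`), since "median absolute
  deviation" scoring is sometimes run unscaled; all reported defaults use
  1.4826. A zero MAD (constant fold changes) is an error, not a silent NaN.
* **Replicate averaging, then ranking.** Hairpin z-scores are averaged
  across the tumor replicates of a screen and the means converted to
  depletion ranks 1..N and percentiles rank/N. Averaging precedes ranking;
  whatever replicates are provided are averaged (no replicate-QC gating).
  Ties are broken by input order — with continuous scores they essentially
  never occur, and stability keeps reruns byte-identical.

## Gene-level RSA statistic

For a gene with n hairpins at depletion ranks r₁ < … < rₙ among N total,
each order statistic i gets the hypergeometric tail probability
P(X ≥ i), X ~ Hypergeom(N, n, rᵢ) — the chance that a random draw of rᵢ
hairpins contains at least i of the gene's n. The gene's statistic is
`logP = log10 minᵢ pᵢ`. Redundancy is the point: one outlier hairpin (a
possible off-target) cannot drive the minimum, while several moderately
depleted hairpins can. Only the depletion direction is scored, as befits a
dropout screen, and all n hairpins participate (no rank-window bounds).

Tails come from `phyper(log.p = TRUE)` so that quantities like
1/C(2370, 10) ≈ 10⁻²⁷ are exact in log space. An independent
exact-summation oracle (`rsa_logp_oracle`, log-binomial-coefficient sums,
restricted to N ≤ 500) backs the implementation in the test suite at 10⁻⁹
agreement over 1,000 random rank sets.

**The minimum over order statistics is not a calibrated p-value.** Under
the null (ranks uniform without replacement) it is anti-conservative: the
test suite's Monte-Carlo check (10⁴ seeded draws at N = 100, n = 4) finds
about 14% of null genes at p ≤ 0.05, and the effect grows with n. This is
inherited by anything downstream that treats rsa_p as uniform — see the
null-behaviour section below.

* **FDR.** Benjamini–Hochberg across the targeting genes of each screen
  (via `stats::p.adjust`), the default convention when a screen reports an
  FDR threshold without naming a procedure. A permutation alternative
  (gene labels shuffled across hairpins, seeded, `fdr_method =
  "permutation"`) is provided for sensitivity analysis; it calibrates
  against the anti-conservative null directly but costs one full RSA pass
  per permutation. Control genes are excluded from the FDR family and get
  `NA` q-values: they are engineered spike-ins, not tested hypotheses.
* **Hits.** `logP ≤ −1.5` and `q ≤ 0.3`, both inclusive, applied to
  targeting genes only; positive controls deplete by design and would
  otherwise join every intersection. Cross-screen common hits are the
  intersection of per-screen hit sets, with the full membership matrix and
  per-region counts exported for Venn-style reporting. Requiring both
  thresholds per screen for intersection membership is the stricter of the
  readings of "hit in at least one model" designs, and is what
  `common_hits()` implements.

## The synthetic screen generator

`sim_config()` defaults describe the screen the analysis targets, and are
deliberately not free dials:

| parameter | default | meaning |
|---|---|---|
| `n_genes` × `hairpins_per_gene` | 237 × 10 | targeting library |
| `control_hairpins` | 10 each | RPL30, PSMA1 (positive), LUC (negative) |
| `library_skew_alpha` | 50 | Dirichlet concentration of the pool (CV ≈ 14%) |
| `moi` | 0.3 | metadata; infected fraction 1 − e^−0.3 ≈ 0.26 |
| `cells_per_mouse` | 3e6 | 1,250 cells/barcode over 2,400 barcodes |
| `tumor_replicates` × `n_models` | 3 × 4 | suite layout |
| `doublings` | 10 | neutral in vivo expansion (~3 weeks of growth) |
| `depth` | 5e6 | ≈ 2,000 reads/barcode, so sampling noise ≪ planted effects |
| `seq_error_rate` | 0.001 | per-base substitution in written FASTQ |

Generation per model: pool proportions ~ Dirichlet(α); engraftment is a
single multinomial bottleneck of `cells_per_mouse` cells; each barcode then
grows deterministically for T doublings at fitness f = 1 − s·e, where s is
the gene's essentiality effect and e the hairpin's efficacy; sequencing is
a multinomial draw over the final cell mass. A hairpin with s·e = 0.5 at
T = 10 therefore sits an expected ~5 log2 units below neutral barcodes —
comfortably detectable at default depth, which is the design point: the
suite tests the pipeline's logic, not its detection limit.

Planted truth: 5 pan-model essential genes (effect 0.5 in every model),
3 model-specific essentials per model (also 0.5; disjoint across models),
positive controls at 0.8, LUC at 0. Hairpin efficacy is fixed per hairpin
across models — it is a property of the sequence — with 8 of 10 hairpins
potent (Beta(5, 1)) and 2 of 10 weak (Beta(1, 3)), so RSA's redundancy
logic is exercised rather than trivially satisfied. Effect sizes not fixed
by the design above (the model-specific effect) were set once to 0.5 and
not revisited.

Barcodes are random 18-mers kept at pairwise Hamming distance ≥ 3 by
rejection, so single-mismatch assignment is provably unambiguous. MOI is
carried as metadata only: under the single-integration assumption it does
not change count distributions. One master seed fans out deterministically
per (model, replicate, stage), so suites are reproducible and FASTQ output
is byte-identical across reruns.

What the simulator does **not** model: clonal interference, barcode
recombination, microenvironment effects, replicate-specific engraftment
efficiency differences, PCR jackpotting, or quality-score structure.
Passing recovery tests therefore demonstrates correctness of the analysis
logic under a clean generative model, not performance on messy real
screens.

## Null behaviour and known limitations

With every effect set to zero, per-screen hit calling at the default
thresholds is *not* clean: the RSA minimum-p inflation at N = 2,400,
n = 10 pushes roughly one in six null genes past logP ≤ −1.5, and at that
density BH at q ≤ 0.3 passes essentially the whole block, so a null screen
still calls tens of per-screen "hits". The cross-model intersection is the
robust output: the 20-seed null check in the test suite finds zero common
hits in the large majority of seeds, with an occasional single false
common gene (the suite asserts the stricter ≥ 18/20 bound and documents
the shortfall rather than relaxing it). Practical consequence, as in real
screens of this design: per-screen hit lists at FDR 0.3 are candidate
pools; cross-model recurrence (or orthogonal validation) does the real
filtering. The permutation FDR is the in-package remedy when calibrated
per-screen error control matters.

Other limitations: no between-screen normalization or batch correction; no
UMI support; no gene-level NB-GLM scoring (maximum-likelihood methods in
the MAGeCK family solve a different formulation); tumor-study helpers stop
at volume and %TGI (no growth-curve ANOVA).

## Problem sizes and determinism

The test suite simulates at the full default scale (2,400 hairpins,
4 models × 4 samples, 5e6 reads/sample) in count-matrix mode, where a
suite takes about a second; FASTQ round-trip checks run at reduced depth
(10³–10⁴ reads), which is ample to verify exact read accounting. All
randomized tests fix seeds; identical inputs and configuration produce
bit-identical score tables, and the run manifest in `run_pipeline()`
records the parameters that produced any artifact set.
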