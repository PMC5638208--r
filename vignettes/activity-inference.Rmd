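---
title: "Regulon-based protein activity inference from perturbational signatures"
author: "netact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulon-based protein activity inference from perturbational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netact)
```

# The problem

A compound's transcriptional footprint is noisy at the single-gene level,
but the *regulatory proteins* whose activity it changes each control tens
to hundreds of target genes. Reading activity off the coordinated behavior
of a protein's regulon — its set of direct and indirect transcriptional
targets — multiplexes the measurement over many genes and is far more
robust than differential expression of the protein's own transcript.
`netact` implements this inference for drug-perturbation screens: it turns
differential gene-expression signatures into regulator-by-perturbation
activity matrices using regulatory networks from four kinds of sources
(ARACNE-style reverse-engineered networks, scored protein-link tables,
TF-target gene sets, and gene knock-down response signatures), combines
the evidence across networks, and provides the downstream analytics a
drug-mechanism study needs: bioactivity scoring, known-modulator and
known-target enrichment, drug-drug similarity, and gold-standard
construction with reciprocal validation.

# The model

## Signatures

All differential signals are carried as per-gene signed z-scores (positive
= up in treatment). Two-group comparisons use a plain Welch t statistic
converted through its two-sided p-value to a signed z. A moderated-variance
t (as in limma) would be a reasonable alternative for very small designs;
we use the plain Welch test to keep the pipeline self-contained and the
null model transparent, and cap the z at 12 (`z_cap`) where p-values
underflow. Single-sample signatures are per-gene z-scores within a scaling
group (a cell line, or a plate for plate-based screens).

## Three-tail regulon enrichment

Each signature is rank-transformed twice:

* a **two-tail** score `t2 = qnorm(r/(n+1))`, the probit of the fractional
  rank of the signed statistic, and
* a **one-tail** score `t1 = qnorm(0.5 + r'/(2(n+1)))`, the probit of the
  folded rank of the magnitude.

A regulon target carries a mode of regulation `m` in `[-1, 1]` (sign:
activation vs repression; magnitude: confidence in that sign) and a
non-negative confidence weight `w`, max-normalized to 1 within the
regulon. The enrichment score of a regulon on a transformed signature is
the weighted mean

```
ES = sum_i w_i [ m_i * t2_i + (1 - |m_i|) * t1_i ],   sum_i w_i = 1,
```

over the targets present in the signature. Fully signed targets contribute
directionally; direction-unknown targets contribute through magnitude
only; partial modes blend the two tails. Weights are renormalized over
*present* targets so ES is a weighted mean and its analytic null is exact.

## Calibration

Two calibrations convert ES to a normalized enrichment score (NES, a
z-like scale) and a two-sided p-value:

* **analytic** — under the null that the transformed per-target scores are
  iid standard normal, `NES = ES / sqrt(sum w_i^2)`. Fast, exact for
  fully signed regulons on independent genes.
* **empirical** (recommended for real data and used whenever a null set is
  supplied) — the regulon's ES is computed on every signature of a null
  set built by the same procedure as the data (random two-group splits of
  a baseline cohort), and `NES = (ES - mean_null)/sd_null`. The p-value is
  the normal tail of this standardized score rather than the raw
  empirical rank: with 1000 nulls a rank-based p floors at 1e-3, too
  coarse for FDR across thousands of regulators. Standardization is
  per-regulon.

The two differ in what they absorb: genes co-regulated by one protein move
together under any resampling of real data, so the empirical null ES
spread contains an intra-regulon coherence component that the analytic
null ignores. The empirical NES is therefore properly calibrated (the
package's null-calibration tests show type-I error of about 0.05 at
|NES| > 1.96 through the whole pipeline), at the price of a compressed
dynamic range; the analytic NES preserves dynamic range but treats
coherent biological noise as signal. The degradation benchmarks below use
whichever scale the measured quantity needs, and say so.

## Pleiotropy (shadow regulons)

Regulons overlap, so a strongly responding regulator can drag a
target-sharing "shadow" regulon into apparent significance.
`pleiotropy_adjust()` examines, per signature, every ordered pair of
significant regulators sharing at least `overlap_min` (10) targets,
recomputes the first one's NES on its unique targets, and — when that
unique-target NES is no longer significant while the partner remains
significant — shrinks the original NES toward the unique-target NES with
weight `penalty/(penalty + n_shared)` (`penalty` = 20 shared-target
units). The adjustment never flips a sign, and a regulator whose unique
targets still carry the signal is left untouched. This is a deliberately
simplified shadow correction in the spirit of the VIPER pleiotropy index,
whose exact form involves a different probabilistic machinery; it is
conservative (shrinks, never removes) and symmetric for identical
regulons.

## Multi-network integration

Activity matrices inferred from different networks are combined cell-wise
by the signed magnitude-weighted average `s* = sum_k s_k |s_k| / sum_k
|s_k|` over the networks where the cell exists, so stronger calls dominate
and `|s*| <= max_k |s_k|`. Cells tested in a single network pass through
unchanged; integration over partial coverage uses the available networks
only.

## IRS

The Interactome Reliability Score summarizes how much significant activity
a network extracts from a signature set: restrict cells to BH FDR < 0.05,
then sum `min(-log10 p, 20)`. This is identical to the area under the
significant-count curve `N(t) = #{cells with -log10 p >= t}` integrated
over `t` in `[0, 20]`, which reconciles the two common phrasings of the
score. A poor network model (or an inactive compound) yields few
significant calls and a low IRS, so the same score serves as a
network-quality metric (across a screen) and a compound-bioactivity
metric (per column). `relative_irs()` rescales a set of IRS values by
their maximum for cross-network comparison.

# Network construction

* **ARACNE-style**: `.adj` or 3-column TSV edge lists (regulator, target,
  mutual information). The mode of regulation is the Spearman correlation
  of regulator and target expression across the supporting cohort —
  rank-based, hence robust to monotone nonlinearity — and the weight is MI
  max-normalized per regulon. The MoR estimator is our choice (the usual
  convention in this family of methods); nothing in the upstream format
  fixes it.
* **Protein-link tables (STRING-like)**: links with combined score
  strictly greater than 0.7 are kept (0-1000 scales are auto-detected and
  divided by 1000); each undirected link yields two directed memberships
  with mode 0 (sign unknown) and the score as weight.
* **TF-target sets (GMT)**: repeated records for a TF are merged by target
  union; weight 1; mode 0 unless an expression matrix is supplied for
  Spearman estimation.
* **Knock-down regulons**: genes responding with |z| >= 3 to the silencing
  of g form regulon(g), capped at 400 targets by |z|; mode = -sign(z) (a
  gene that falls when g is silenced is positively regulated by g); weight
  = |z| max-normalized. The inclusion threshold mirrors the 3-SD
  silencing-confirmation convention; repeated silencing experiments are
  first combined per gene by Stouffer's method after a knock-down
  efficiency check (silenced gene down with p < 0.1).

Regulons with fewer than `min_targets` (10) usable targets are dropped (or
their cells left absent rather than zero): enrichment p-values on a
handful of genes are not meaningful, and "untestable" must stay
distinguishable from "no change". We do not prune large regulons by
default; `max_targets` exists for the KD source where tail noise is
heavy.

`randomize_interactome()` degrades a network controllably for benchmarking:
double-edge swaps on the bipartite regulator-target multigraph preserve
every out- and in-degree exactly, modes and weights travel with the
regulator-side stub, and the loop is driven by the realized fraction of
rewired edges (a fixed swap budget would leave about `exp(-1)` of the
edges untouched at nominal fraction 1).

# The synthetic ground-truth generator

The generator is a linear-Gaussian structural model — the simplest
structure matching the regulon-enrichment assumption, not a biological
claim. Latent activities `a_{s,r} ~ N(0,1)` drive target expression
`x = m * w * a + noise` for signed targets; direction-unknown targets
respond through the centered magnitude `w(|a| - sqrt(2/pi))` so the
one-tail component of the enrichment has signal to find; each regulator's
own transcript reports its activity so correlation-based mode recovery is
testable. Compound treatment shifts chosen regulators' latent activities
by a signed strength in the treated arm, and signatures are Welch
two-group comparisons of treated vs control replicates.

What it emulates: sparse signed weighted regulons, biological
(latent-activity) plus observation noise, replicate structure, shadow
regulons via controlled target overlap, magnitude-coupled
direction-unknown edges. What it does not: transcriptional kinetics,
batch/plate artefacts, platform-specific noise, feedback, off-target
compound effects. Passing the synthetic benchmarks therefore demonstrates
the *statistical machinery* — calibration, power, monotone degradation,
recoverability — not performance on any real screen.

Reference problem sizes (chosen once as realistic-but-fast; each run is a
few seconds on one CPU):

* **Recovery benchmark** (`benchmark_recovery()`): 100 regulators x 50
  targets over a 2000-gene pool, 10 perturbed regulators at strength
  +/-2, observation noise sd 1, 10 replicates per arm. Under these
  conditions AUROC for perturbed-regulator detection is ~0.99 and the NES
  sign matches the perturbation sign for all detected regulators.
* **Null calibration**: 2000-gene universe (50 regulators x 39 targets),
  1000 calibration and 400 evaluation null signatures from random
  10-vs-10 splits of a 160-sample baseline cohort.
* **Network-randomization curve** (`irs_randomization_curve()`): the
  recovery network, 10 compounds at strength +/-4, empirical calibration
  with 300 nulls, fractions {0, 0.25, 0.5, 0.75, 1}. IRS falls strictly
  with the randomized fraction (Spearman rho = -1 in almost every seed).
* **Signature-shuffling curve** (`shuffle_significance_curve()`): one
  compound perturbing 20 of 100 regulators with graded strengths 0.75-6
  (30 targets each, 3000-gene pool), analytic calibration. Graded
  strengths make the FDR-significant count decline progressively over
  shuffle fractions {0, 0.2, ..., 1} instead of collapsing at one step.
  The analytic scale is used deliberately: the empirical null absorbs
  intra-regulon coherence, which caps attainable NES near the FDR
  threshold and flattens the curve's tail, whereas the quantity of
  interest here is how coherent regulon signal dissolves as gene labels
  are scrambled.
* **Reciprocal validation** (`reciprocal_benchmark()`): 60 regulators x 25
  targets over 3000 genes, 15 gold-standard genes with 8 matched
  inhibitor compounds each (strength -4) plus 20 decoys, observation
  noise sd 2, 20 replicates. Three conditions are load-bearing and worth
  stating: (i) several inhibitors per gene are required because the
  recovery rule (enrichment NES > 1.96) cannot be met by a very small
  set — even a perfectly ranked 3-compound set barely reaches NES 2 under
  the permutation null; (ii) the reciprocal enrichment uses the classical
  unweighted KS statistic because with magnitude weighting the
  permutation null is dominated by whether a random set catches one
  extreme compound; (iii) the gold standard is built at p_cut 1e-4 rather
  than the liberal 0.05 default, because the correlation test's
  independent-genes assumption is optimistic under regulon-block
  coherence and would admit many spurious compounds. The randomized
  control permutes gene labels by a derangement so no gene keeps its own
  compound set.

# Numerical choices and degenerate inputs

* Rank ties get average ranks; an all-equal signature is a rank-degenerate
  error, not a silent zero.
* Zero-variance genes: mode 0 in network construction (with a warning),
  z = 0 in single-sample scaling, 0 or +/- `z_cap` in two-group
  signatures depending on whether the means differ.
* Cells with fewer than `min_targets` shared genes are absent (NA), never
  zero.
* Serialization is plain TSV at 15 significant digits; round-trips are
  lossless at that precision.
* All stochastic steps take explicit integer seeds and are bit-reproducible
  given the seed; derived sub-seeds stay below 2^31.
* BH correction is `stats::p.adjust`; Spearman/Pearson correlations are
  `stats::cor`; the enrichment core, the transforms, the integration rule,
  IRS, and the KS running sum are implemented here and cross-checked in
  the test suite against brute-force oracles (and `fgsea` for the
  weighted KS ES).

# Known limitations

* The pleiotropy correction is a shadow heuristic, not a full pleiotropy
  index; it only ever shrinks calls.
* The analytic null ignores inter-gene correlation and the small positive
  offset of the one-tail component for mode-0 targets; use empirical
  calibration for inference on real data.
* The gold-standard correlation p-value inherits the independent-genes
  assumption of the textbook test; on block-correlated signatures its
  nominal scale is optimistic (see the reciprocal benchmark's p_cut
  choice).
* Identifier mapping, normalization (RMA/MAS5/VST), and network reverse
  engineering itself (MI estimation, DPI) are out of scope; the package
  consumes already-normalized matrices and already-built edge lists.

# A compact end-to-end example

```{r example}
net <- make_network(20, 30, 800, seed = 1)
ex <- simulate_perturbation_experiment(
  net, list(drugA = c(R001 = 2), drugB = c(R005 = -2)),
  n_reps = 10, seed = 2)
act <- infer_activity(ex$signatures, net)
act
summary(act)[1:4, ]
recovery_metrics(act, ex$truth)[c("auroc", "sign_agreement")]
irs_score(act)
```
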