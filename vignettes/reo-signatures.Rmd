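---
title: "Rank-based gene-pair signatures for MSI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures for MSI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The problem

Microsatellite instability (MSI) marks colorectal tumors with deficient DNA
mismatch repair. It matters clinically — MSI tumors have distinct prognosis
and respond differently to fluoropyrimidine chemotherapy — but the standard
PCR and immunohistochemistry assays compare tumor against matched normal
tissue and are sensitive to laboratory conditions. A classifier that reads
MSI status off a single tumor expression profile, with no normal sample, no
normalisation and no batch correction, is therefore attractive.

Quantitative expression signatures fail that robustness requirement: absolute
expression values shift with platform, batch and preprocessing. `reosig`
implements the *qualitative* alternative: within one sample, ask only whether
gene $i$ is expressed above gene $j$. This relative expression ordering (REO)
is unchanged by any strictly increasing transform of that sample's values —
log transforms, scaling, quantile shifts, monotone batch effects all preserve
it — so a rule built from REOs transfers across laboratories and platforms
and applies to individual samples.

## The classification rule

A signature is an ordered set of gene pairs $(i_1,j_1),\dots,(i_m,j_m)$, each
oriented so that observing $E_{i} > E_{j}$ within a sample is a vote for MSI,
plus a vote threshold $k$:

$$\text{call MSI} \iff \#\{\,r : E_{i_r} > E_{j_r}\,\} \ge k.$$

The package ships the published 10-pair signature for right-sided colon
cancer (`builtin_10gps()`, $k = 7$) and can fit new signatures from labeled
training data.

## Signature discovery

`fit_signature()` runs five deterministic stages:

1. **DE screen.** Per gene, a classic equal-variance two-sided Student's
   *t*-test between MSI and MSS samples, with Benjamini–Hochberg FDR control;
   genes with $q <$ `de_fdr` (default 0.01) proceed. Genes with zero variance
   in both classes get $p = 1$ rather than an error. The classic *t* rather
   than a moderated variant is used deliberately: with scores of samples per
   class the moderation matters little, and the simple statistic keeps the
   screen assumption-light.
2. **Pair screen.** For every unordered pair of DE genes, the pattern
   frequency $p_{ij}(c) = P(E_i > E_j \mid c)$ is estimated in each class
   $c \in \{\text{MSI}, \text{MSS}\}$. The orientation with non-negative
   frequency difference is kept and tested with the **one-sided** Fisher's
   exact test (greater frequency in MSI); the one-sided form matches the
   question actually asked — is this ordering *enriched* in MSI — and the
   orientation step makes a two-sided test redundant. BH adjustment is
   applied across all tested pairs as a single family (one screen, one FDR
   control step); pairs with $q <$ `pair_fdr` (default 0.01) survive.
3. **Frequency difference.** Each surviving pair carries
   $FD_{ij} = p_{ij}(\text{MSI}) - p_{ij}(\text{MSS}) \in [0, 1]$ after
   orientation; larger FD means the ordering separates the classes more
   cleanly and is less likely to flip under measurement degradation.
4. **Redundancy removal.** Shared genes make votes correlated, so each gene
   may appear in at most one pair. The rule "keep the pair with the largest
   FD among pairs sharing a gene" is implemented as an iterative greedy pass:
   pairs are sorted by FD descending (ties broken by Fisher *p* ascending,
   then lexicographically by gene names, making the output deterministic),
   and a pair is kept iff neither gene is already used by a kept pair. A
   stricter reading — each gene contributes only its single best pair, which
   dies if that pair conflicts — would discard pairs the greedy pass can
   still use; the greedy variant retains more information and reduces to the
   same answer whenever no conflicts occur.
5. **FD filter and vote threshold.** Pairs with $FD \ge$ `fd_min` (default
   0.8; 0.9 is the analogous published choice for left-sided tumors, where
   0.8 left too many pairs with no performance gain) form the signature. The
   threshold $k$ is chosen by evaluating every $k = 1..m$ on the training
   votes and maximising the F-score
   $$F = \frac{2 \cdot \text{sens} \cdot \text{spec}}
              {\text{sens} + \text{spec}},$$
   the harmonic mean of sensitivity and specificity (not the
   precision–recall F1) — a classifier must serve both classes to score
   well, which matters because MSS samples outnumber MSI roughly 3:1 in
   colon cohorts. F-score ties are broken toward the **larger** $k$: among
   equally good thresholds the more specific classifier is preferred, since
   a false MSI call can wrongly steer a patient away from standard
   chemotherapy.

### Numerical and degenerate-input choices

* **Ties** ($E_i = E_j$) count as non-pattern everywhere — in pair counting
  and in voting. A tie is no evidence for the MSI-associated ordering, and
  the conservative rule never manufactures a vote. Ties are rare on
  continuous data but routine after aggressive rounding or degradation.
* **Missing genes at prediction time.** Default policy is an error naming
  the genes. With `missing_policy = "drop"`, unusable pairs are excluded and
  the threshold rescaled to $\lceil k \cdot m_\text{used} / m \rceil$
  (minimum 1), preserving the required vote *fraction* (7/10 for the
  built-in signature). The rescaling rule is this package's own convention
  for a situation the original development never faced.
* **AUC** uses the Mann–Whitney formulation with midrank tie handling —
  vote counts are small integers, so ties are the norm, and midranks give
  the same number as trapezoidal integration of the ROC curve.
* **Empty stages** (no DE genes, no significant pairs, nothing above
  `fd_min`) raise an error naming the stage and threshold rather than
  returning an empty signature.
* Reported metrics are rounded **half-up** to 4 decimals (base R's
  round-half-even would print 0.96345 as 0.9634); internal computation is
  full precision.

## Assessing disconfirmed samples

When the signature contradicts a sample's recorded status,
`cluster_assessment()` lets the transcriptome arbitrate: genes differentially
expressed between the signature-*confirmed* MSI and MSS samples are ranked
(ascending $q$, then $p$, then gene id — an operational tie-break for "top
significant genes"), the top 100 are used to cluster all samples by
complete-linkage hierarchical clustering on Euclidean distance, the tree is
cut into two, each cluster is labeled by the majority class of its confirmed
members (ties or empty clusters yield `"unassigned"` rather than a guess),
and each query's cluster label is reported. Sample order cannot affect the
result (columns are sorted internally before clustering). If fewer than 100
genes are significant, all available are used with a warning.

## The synthetic-data generator

`simulate_dataset()` produces the ground-truth datasets used throughout the
package's tests: a two-class matrix with

* background genes drawn around per-gene baselines uniform on [4, 12]
  (log2-like scale, i.e. log-normal on the raw scale) with Gaussian noise
  (`noise_sd`, default 1) and no class difference;
* planted pairs whose ordering $E_{g_1} > E_{g_2}$ holds with probability
  `p_pattern_msi` in MSI and `p_pattern_mss` in MSS samples. Both values are
  drawn first and the larger is assigned to $g_1$ with exactly the target
  probability, so the empirical FD concentrates on
  `p_pattern_msi - p_pattern_mss` with plain binomial error;
* a between-class mean shift of `de_shift` SDs on planted genes so they pass
  the DE screen, as genuine signature genes must.

Defaults — 60 samples per class, 200 genes, 10 planted pairs at pattern
probabilities 0.95/0.05 (expected FD 0.9), 2-SD shift — are the validation
conditions used by the test suite and acceptance script; at these sizes the
full pipeline runs in about a second, and the suite's repeated-seed checks
(20 seeds for recovery, null calibration and clustering) complete within a
minute. Two perturbation operators probe robustness:
`apply_monotone_distortion()` applies an independent strictly increasing map
per sample (cubic with positive coefficients) and must leave every REO-based
result bit-identical; `apply_degradation()` multiplicatively attenuates a
random gene subset per sample — *not* rank-preserving — to measure how many
signature orderings survive degradation-like signal loss (at 10% of genes
attenuated to 70–95%, over 90% of planted-pair orderings survive, matching
the stability reported for preserved-vs-frozen tissue comparisons).

What the generator does **not** emulate: probe-level microarray noise, GC
bias, tumor-purity mixtures, correlated gene modules, or realistic library
size effects. Passing tests on this generator demonstrate that the pipeline
recovers exactly the structure it models — planted order reversals riding on
mean shifts — and that its statistics are calibrated under a clean null; they
do not by themselves certify performance on real cohorts, which is why the
published validation metrics are reproduced separately from their printed
confusion counts.

## Worked example

```{r example}
sim <- simulate_dataset(seed = 7)
sig <- fit_signature(sim$expression, sim$labels)
glance(sig)

pred <- predict(sig, sim$expression)
evaluate_predictions(pred, sim$labels)

# rank invariance: a monotone warp changes nothing
warped <- apply_monotone_distortion(sim$expression, seed = 99)
identical(predict(sig, warped), pred)
```

## Known limitations

* Discovery at full scale (thousands of DE genes, millions of pairs) is
  quadratic in the DE gene count; `max_de_genes` caps the screen for
  desk-scale work.
* The published 10-pair signature is shipped as printed; its discovery
  cohort is not redistributed, so refitting it is out of scope.
* The 6-pair left-sided signature is supported as configuration
  (`fd_min = 0.9`, $k = 4$ of 6) but its gene list was not printed in the
  main text and is not shipped.
* Survival analysis of reclassified patients requires external clinical
  data and is outside the package.
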