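---
title: "Methods: models, scores and the synthetic-cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, scores and the synthetic-cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunocycle)
```

This vignette documents the statistical models implemented in
`immunocycle`, the conventions pinned for reproducibility, the design of
the synthetic-cohort generator, and the package's limitations. It is
shipped as source and is not built during installation.

## 1. Input model and normalization

Expression enters as a dense genes × samples matrix wrapped in an
`expr_matrix` that tracks its normalization state (`raw` → `log` →
`zscore`). The canonical chain is

\[
y_{gs} = \log_2(x_{gs} + 1), \qquad
z_{gs} = \frac{y_{gs} - \bar y_g}{\sigma_g},
\]

where \(\sigma_g\) is the **population** standard deviation (divisor
\(n\), not \(n-1\)). The population convention is used everywhere a
z-score appears — per-gene normalization, subgroup score summaries, the
arm-CNA burden score, and the TIC/IRP normalization — so that any
z-scored vector has mean exactly 0 and RMS exactly 1 regardless of
cohort size, and so re-applying `zscore_genes()` is an identity (within
floating-point tolerance). Constant genes are mapped to all-zero rows
with a warning rather than NaN.

Parsing rules are deliberately strict but forgiving where bulk matrices
are routinely messy: duplicate gene rows are collapsed by mean (the
common behavior of array probes mapping to one symbol), blank cells are
imputed to 0 with a counted warning, any other non-numeric cell is an
error, and duplicated sample columns are rejected by inspecting the raw
header line (before the reader would silently rename them).

## 2. Subgroup discovery: diagonal Gaussian mixture

Samples are clustered over the registry's panel genes with a
\(k\)-component Gaussian mixture with **diagonal** covariance, fit by
EM. Diagonal covariance is the only tractable choice here: with
\(d \approx 120\) panel genes and \(n \approx 99\) samples a full
covariance per component is unidentifiable, while the diagonal model
needs \((k-1) + 2kd\) parameters and regularizes naturally.

Implementation notes, each pinned by a test:

* **Restarts and determinism.** `n_init` k-means-style random restarts;
  all randomness flows from a single integer seed through a
  deterministic per-stage derivation, so a fit is byte-reproducible.
* **Monotone EM.** The per-iteration log-likelihood trace is recorded
  and asserted non-decreasing; responsibilities are computed with the
  log-sum-exp trick.
* **Variance floor** of `1e-6` per gene per component, preventing the
  classical collapse of a component onto a single point.
* **Model selection.** `select_k()` minimizes
  \(\mathrm{BIC} = -2\ell + p\log n\) with
  \(p = (k-1) + 2kd\); ties resolve to the smallest \(k\).
* **Cross-check.** The test suite refits reference problems with
  `mclust` (model `VVI`, i.e. diagonal) and requires identical
  partitions (adjusted Rand index 1); `mclust` is never used in the
  implementation itself, only as an independent oracle, and it also
  supplies `adjustedRandIndex` for recovery measurement.

## 3. Phenotype labels

Each cluster receives a three-axis label such as `UB+ IFN1p- AP-`. For
axis scores we average the z-scored expression of the relevant panel's
genes over the cluster's samples: ubiquitination (panel A), type I IFN
(panel B, with separate means for its `production` and `signaling`
sub-tags), and antigen presentation (panel C). Per axis, the top-ranked
cluster is called `+`, the bottom-ranked `-`, and the middle cluster
takes the sign of its mean (ties break toward the lower cluster index,
deterministically).

A cluster whose IFN axis is `-` is refined to name the defective arm:
the call is `p-` when the production arm is the more defective
(lower cluster-mean z, and actually negative), `s-` when the signaling
arm is, and stays `-` only if neither arm is individually negative. The
refinement is driven by *which arm is more defective* rather than by
which arm ranks last among clusters, because a broadly suppressed
cluster can rank last on **both** arms while its biology is dominated by
one of them; the more-defective-arm rule recovers the intended label in
exactly that situation. A sub-arm with non-negative mean z is never
called the defect.

Subgroups are numbered by increasing combined (IFN + AP) competence, so
the fully functioning cluster is always subgroup 3, stabilizing
downstream reporting against arbitrary mixture-component permutations
(the labels themselves are invariant to relabeling, which is tested).

## 4. Scores

* **Average-expression signatures** (immune, stromal, cell-cycle) are
  arithmetic means over the signature's present genes, computed on the
  log scale; missing genes are reported via an attribute rather than
  silently dropped.
* **Cytolytic activity** is the classical two-gene geometric mean on the
  linear scale with pseudocount 1:
  \(\mathrm{CYT} = \sqrt{(\mathrm{GZMA}+1)(\mathrm{PRF1}+1)} - 1\).
* **TIC** (7 genes: IFI16, MYD88, JAK2, TAP1, TAP2, PSMB9, HLA-DQA1) and
  **IRP** (6 genes: IFNGR1, CD274, CXCL9, IFNG, PDCD1, CXCR3) are
  per-sample geometric means of linear expression with pseudocount 1.
  The pseudocount prevents one zero-expression gene from annihilating
  the score; the two sets share no genes and total 13.
* **Quadrants.** Normalized TIC (x) and IRP (y) partition samples into
  quadrants 1 = (+,+), 2 = (−,+), 3 = (−,−), 4 = (+,−); an exact 0
  counts as positive.

**Normalization of TIC/IRP.** Within-cohort scaling is configurable:
`"log_zscore"` (default), `"zscore"` (raw scale), or `"minmax"`
(centered). The default z-scores \(\log_2(\text{score}+1)\) rather than
the raw geometric mean: geometric means of expression are approximately
log-normal, so on the raw scale the cohort mean sits far above the
median and the quadrant boundary cuts through the bulk of typical
samples, making quadrant membership noise-dominated. Taking logs first
makes the score distribution roughly symmetric and puts the boundary
near the typical sample. Both alternatives remain available for
sensitivity analysis.

* **Percentile classes** use `stats::quantile` type 7 (linear
  interpolation) with strict inequalities: above the 70th percentile is
  `high`, below the 30th is `low`.
* **Subgroup summaries** z-score each score across the whole cohort
  (population convention) and then average within subgroups, so the
  size-weighted sum of subgroup means is exactly 0 per score.

## 5. Group comparisons

Two-group comparisons offer Welch's *t* (delegated to `stats::t.test`;
a pooled-variance flag exists) and the Mann–Whitney *U*. For small
samples (smaller group < 8 and \(\binom{n}{n_A} \le 2\times 10^5\)) the
Mann–Whitney p-value is computed by **full enumeration** of all group
assignments, which remains exact in the presence of ties — identical
groups give \(p = 1\) by construction — whereas the classical exact
distribution is invalid under ties. Larger samples use the
tie-corrected normal approximation (`stats::wilcox.test`,
`exact = FALSE, correct = TRUE`). On untied small samples the
enumeration reproduces `wilcox.test`'s exact p-values to machine
precision, and both tests hold their nominal type-I error within
5% ± 1.5% over 2000 null simulations (asserted in the suite).
Multiple-testing adjustment, when requested, is Benjamini–Hochberg via
`stats::p.adjust`.

## 6. Genomic summaries

* **TMB** counts small somatic variants of classes missense,
  truncating, inframe (a MAF-dialect reader maps e.g.
  `Missense_Mutation`, `Frame_Shift_Del` onto this vocabulary) divided
  by the capture size, default 30 Mb. Structural classes
  (amplification, deep deletion) never count toward TMB.
* **Arm-level CNA burden** is the mean of \(|\log_2\text{ratio}|\) over
  the 39 non-acrocentric chromosome arms, z-scored across the cohort.
* **Mutation landscape** counts each sample at most once per gene
  within each subgroup, with a per-class breakdown attached.

## 7. The synthetic-cohort generator

`generate_cohort()` produces expression, mutations, arm CNA, optional
response labels and a truth table, byte-identical for identical
configurations. The defaults are the package's study conditions and are
not tuned:

* **Cohort**: \(n = 99\), subgroup probabilities \(37/99, 15/99,
  47/99\).
* **Expression**: per-gene baseline \(\mu_g \sim U(2, 8)\) on the log2
  scale, within-gene noise sd 1; each (subgroup, panel) pair applies a
  shift in z units — High = +1, Low = −1, Very low = −2 — encoding
  subgroup 1 as `UB+ IFN1p- AP-` (production arm down), subgroup 2 as
  `UB- IFN1s- AP-` (broadly very low), and subgroup 3 as fully
  functioning. Marker-set shifts (immune/stromal/cell-cycle) are planted
  analogously where a gene is not already claimed by a panel. Linear
  values are \(2^{y} - 1\), floored at 0, so `log2(x + 1)` recovers the
  latent scale exactly.
* **Mutations**: per-sample counts \(\sim\) Poisson(TMB mean × 30 Mb)
  with per-subgroup means 1.919 / 2.644 / 1.700 per Mb; genes drawn with
  EGFR-dominant weights (EGFR 8, TP53 5, CDKN2A 3, thirty others 1);
  classes missense/truncating/inframe at 0.75/0.20/0.05; sporadic EGFR
  amplification (p = 0.15) and CDKN2A deep deletion (p = 0.10) appear as
  structural records that TMB must ignore.
* **Arm CNA**: \(\log_2\) ratios \(\sim N(0, \sigma_k)\) with
  \(\sigma_k\) set so the expected mean \(|\cdot|\) per arm equals
  0.6 / 0.3 / 0.4 per subgroup (using \(E|N(0,\sigma)| =
  \sigma\sqrt{2/\pi}\)).
* **Responder model** (ICB preset, \(n = 13\)): a latent immune
  competence \(c \sim N(0,1)\) shifts the sample's TIC and IRP genes by
  \(1.5\,c\) z units on top of its subgroup shifts, and
  \(P(\mathrm{PR}) = \mathrm{logit}^{-1}\!\big(-1 + 2 \cdot
  (\Delta_{\mathrm{TIC}} + \Delta_{\mathrm{IRP}})/2\big)\) where the
  \(\Delta\)s are the sample's *total* true signature shifts. Response
  is therefore caused by the same planted biology the classifier
  measures, which is the property the quadrant-enrichment analysis is
  designed to detect; the truth table records competence and both
  shifts. Non-responders split evenly between NR and PD.

Generator properties pinned by tests: a zero-effect cohort yields
chance-level recovery (|ARI| < 0.15 over 20 seeds); recovery ARI is
monotone in effect scale over {0.1, 0.3, 1.0}; subgroup counts follow
the configured probabilities (binomial oracle); per-subgroup TMB means
land within 3 standard errors of their Poisson targets; PR samples
carry larger true TIC shifts than non-PR; and on the ICB preset the
fraction of responders in quadrant 1 averages well above 2/3 over 100
seeds.

## 8. Reproducibility conventions

One top-level integer seed drives everything; stage seeds are derived
arithmetically (multiplier 7919 modulo \(2^{31}-1\)) and applied inside
a wrapper that restores the caller's RNG state afterward. The pipeline's
`report.json` records package version, parameters, seed and MD5 digests
of every input, so any reported number can be recomputed by re-invoking
the corresponding function with the recorded parameters.
`scripts/acceptance.R --seed <s> --out <path>` recomputes the headline
quantities from scratch against the installed package.

## 9. Limitations

* The built-in registry is a reduced, curated 124-gene stand-in for the
  full 546-gene panel registry; the loader validates and accepts a full
  registry when supplied, and `synthetic_full_registry()` fabricates an
  explicitly synthetic one for exercising that path. Results on the
  reduced registry are not claims about the full one.
* The generator plants block-structured mean shifts only; it does not
  simulate realistic gene–gene correlation, library-size effects, or
  read-level noise.
* TIC/IRP quadrant analysis is descriptive on small ICB cohorts; with
  \(n \approx 13\) the Welch tests and quadrant counts carry wide
  uncertainty, and no survival or ROC analysis is attempted.
* Phenotype labeling assumes exactly three clusters when interpreting
  rank-based `+`/`-` calls; `select_k()` can choose other \(k\), but the
  three-axis display strings are designed for \(k = 3\).
* Arm-level CNA uses 39 arms (acrocentric p-arms excluded) and assumes
  arm calls are given; no segmentation is performed.
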