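---
title: "Methods: multi-cohort CNV genotyping and lung-function association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort CNV genotyping and lung-function association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvgwas)
```

## The problem

SNP genotyping arrays report a normalized probe intensity — the Log R Ratio
(LRR) — whose expectation tracks the local DNA copy number. At a catalogued
copy-number-variable region (CNVR), the distribution of a per-sample intensity
summary is a mixture: one component per copy-number class. `cnvgwas`
measures these class assignments across several cohorts genotyped on
different array platforms, harmonizes the calls so they are comparable, and
tests the (unanchored) copy-number *dose* for association with quantitative
lung-function traits (FEV1, FVC, FEV1/FVC), combining cohorts by fixed-effect
meta-analysis and replicating signals through tag SNPs in external summary
statistics.

## Copy-number calling

For each CNVR, the in-region probes of a sample are averaged into a single
1-D summary (samples with any missing in-region probe are excluded).
Region membership uses the BED convention: a probe at position $p$ is inside
$[\mathrm{start}, \mathrm{end})$; 1-based inclusive catalogues are converted
on read.

The summaries $x_1,\dots,x_n$ are modelled as a $K$-component Gaussian
mixture

$$ p(x_i) = \sum_{k=1}^K \pi_k \, \mathcal N(x_i \mid \mu_k, \sigma_k^2), $$

fitted by maximum-likelihood EM with free per-component variances floored at
$10^{-6}$ (LRR$^2$), convergence at a relative log-likelihood change below
$10^{-8}$ or 500 iterations. Initialization uses $K$ evenly spaced sample
quantiles for the means plus nine randomly perturbed restarts; each restart
is run for up to 50 iterations and the best is polished to full convergence
(the usual short-EM/long-EM strategy). Components are relabelled by
ascending mean, so class $k \in \{0,\dots,K-1\}$ orders with intensity.

$K$ is chosen by minimum BIC over $K = 1..K_\mathrm{max}$ (default 6), ties
resolved toward smaller $K$. A CNVR counts as *polymorphic* when the
selected $K \ge 2$ and every class has expected count $\pi_k n \ge 3$; the
minimum expected count is a configuration knob, as no published numeric rule
exists for it.

Classes are deliberately **relative**: no attempt is made to anchor the top
class to an absolute copy number, because the association model is invariant
to affine relabelling of the class index (a shift changes nothing; a scale
rescales the effect size with an unchanged P-value). This invariance is
tested explicitly.

Calling uncertainty propagates into association through the posterior dose

$$ d_i = \sum_{k=0}^{K-1} k\,\gamma_{ik}, \qquad
   \gamma_{ik} = \Pr(\text{class } k \mid x_i), $$

together with the MAP class and its posterior probability as a confidence.

## Sample quality control

* **Replicates**: declared duplicate sample ids keep their first occurrence.
* **Intensity noise**: the per-sample metric is the (population) SD of the
  sample's autosomal LRR values; samples above 0.30 LRR units (default) are
  excluded. The original filter behind this step is not publicly specified;
  the SD metric is this package's declared substitute and the threshold is a
  configuration knob. Inside `run_pipeline()` the metric is computed over
  probes *outside* the CNVR catalogue so genuine copy-number signal is not
  mistaken for noise.
* **Ancestry outliers**: SNP dosages are centred and scaled by
  $\sqrt{2p(1-p)}$, monomorphic SNPs dropped, and samples lying strictly more
  than 6 SD from the mean on any of the first 4 principal components are
  removed. The mean and SD are computed in a single pass over all samples —
  the simplest reading of the published rule — with an iterative mode behind
  a flag. The boundary (exactly 6 SD) is retained.

## Cross-cohort harmonization

Cohorts are clustered independently; platforms differ in probe density and
noise, so class counts can disagree. The *best-performing* cohort — an
explicit input, typically the one resolving the most polymorphic CNVRs — is
taken as the reference: its freely selected $K$ is the best estimate of the
true class count, other cohorts are re-clustered at that fixed $K$, and each
is tested for class-frequency compatibility with the reference by a Pearson
$\chi^2$ on the $2 \times K$ table of MAP-class counts (classes with expected
count below 1 are pooled with the adjacent class first). A cohort is
admitted for a CNVR iff $P \ge \alpha$ (default 0.05, logged in the output);
a cohort whose class count cannot match is incompatible by construction.
Lowering $\alpha$ can only grow the admitted set, and the test's type-I
error tracks $\alpha$ — both are verified in the suite.

CNVR type is classified from the fitted mixture: the modal class is the
diploid anchor; classes below it are losses and above it gains; losses only
→ deletion, gains only → amplification, both or $K > 3$ → multiallelic.
This rule is this package's construction — published type percentages come
without a stated rule.

## Association testing

Traits are adjusted in two stages, mirroring the adjust-then-test design:
least-squares residuals of the trait on intercept, age, age$^2$, sex,
height, height$^2$ and the first 4 ancestry PCs (when available), then a
regression of the residual on dose. Collinear covariates (e.g. constant sex)
are dropped with a warning. Discovery traits are left on their natural scale
(litres / ratio); the inverse rank inverse-normal transform — rank $r$ of
$n$ mapped to $\Phi^{-1}((r - 3/8)/(n + 1/4))$, the Blom offset, ties
sharing average ranks — is available behind a flag and describes the scale
of the external replication statistics. The Blom offset itself is a
package choice; the source material does not state one.

Cohorts of unrelated samples use ordinary least squares with the
two-sided t-test on the slope. The family cohort uses a Gaussian GEE with
an exchangeable working correlation and robust (sandwich) standard errors,
written in-package: with $V_i = \phi[(1-\alpha)I + \alpha J]$ per cluster,
$\alpha$ is the moment estimator from within-cluster residual products and
the closed-form $V_i^{-1}$ makes each update a small GLS step. With only
singleton clusters the estimator reduces to OLS (asserted to $10^{-8}$), and
the independence working correlation is available by flag. Exchangeable is
the default because the target design is sibships/households sharing a
single correlation. Fewer than 30 complete pairs, or a constant dose,
yields a no-result row whose direction is ".".

## Meta-analysis and replication

Discovery results share trait units across cohorts, so they combine by
fixed-effect inverse-variance weighting:
$\hat\beta = \sum w_i b_i / \sum w_i$, $w_i = SE_i^{-2}$,
$SE = (\sum w_i)^{-1/2}$. Replication uses the trait-specific method map:
IVW for FEV1 and FEV1/FVC; for FVC — where one external study analysed the
untransformed trait, so effect scales differ — a sample-size-weighted
Z-score (Stouffer) combination $Z = \sum \sqrt{N_i} z_i / \sqrt{\sum N_i}$
with $z_i = \mathrm{sign}_i\,\Phi^{-1}(1 - P_i/2)$. The $\sqrt N$ weights
are the field-standard choice for Z-mode meta-analysis; they reproduce the
published worked example. Signed z-scores are recovered from two-sided
P-values with the upper-tail inverse, keeping the $z \to P \to z$ round trip
below $10^{-8}$ up to $|z| = 8$.

Suggestive signals ($P < 0.001$, strict) are carried to replication when a
tag SNP exists: the best SNP within 1 Mb of the CNVR boundaries by squared
Pearson correlation with the dose (ties to the lowest genomic position),
tagged iff $r^2 > 0.7$ strictly. External study effects are sign-aligned to
the copy-number-increasing allele — flipping when the study's effect allele
is the other allele, and again when the tag SNP is negatively correlated
with copy number — so the result is invariant to allele coding. The
replication threshold is $0.05/m$ for the $m$ tagged tests; missing studies
contribute a dot to the direction string.

## The synthetic study generator

`simulate_multi_cohort_study()` generates the structure the pipeline
assumes, so every stage is testable without any external data:

* **Classes** follow Hardy-Weinberg frequencies for a variant allele at
  frequency $q$: deletions map genotypes to 0/1/2 copies ($K=3$) or merge
  the non-deleted states ($K=2$); amplifications to 2/3/4 copies;
  multiallelic regions are the sum of two independent biallelic duplications
  truncated to four classes — the simplest generative model with more than
  three classes.
* **Intensities** are class mean + i.i.d. Gaussian noise per probe, with the
  class mean $\log_2(c/2)$ for copy $c$ (zero copies floored at 0.25 copies
  so the mean stays finite). Cohorts differ in probe density and noise SD.
  One cohort uses the summed X+Y dialect, simulated as an affine transform
  of the LRR scale — a declared stand-in, since the real X+Y normalization
  is not described publicly; readers median-centre it per probe.
* **Phenotypes** are linear in age, age$^2$, sex, height, height$^2$ plus an
  optional spiked per-class CNV effect and Gaussian noise, with covariate
  coefficients chosen to land the trait means in realistic adult (and child)
  spirometry ranges. One cohort carries family structure: a shared family
  random effect inducing a chosen intraclass correlation (default 0.5).
* **Tag SNPs** copy the CNVR's copy-increasing allele and replace each
  sample's genotype with a fresh Hardy-Weinberg draw with probability
  $1-\sqrt{r^2_\mathrm{target}}$, which makes the expected $r^2$ exactly the
  target.
* Default cohort sizes (3084, 2492, 1765, 5062) mirror the per-cohort
  phenotyped sample counts of the emulated four-cohort design; identical
  configurations (including the seed) reproduce byte-identical datasets.

The generator does **not** emulate raw two-channel fluorescence, genomic
waves, batch/plate effects, probe-specific biases, linkage disequilibrium
between CNVRs, or sex chromosomes. Passing tests therefore demonstrate the
statistical machinery — clustering, harmonization, dose regression,
meta-analysis — under clean mixture assumptions, not robustness to every
artefact of real array data.

## Problem sizes used by the test suite

The suite exercises full-scale formulas but desk-scale simulations: mixture
recovery at $n = 2000$ over 100 seeds; EM monotonicity over 1000 random
fixtures; compatibility type-I error over 1000 replicate pairs at
$n = 2000$; GEE size over 1000 replicates of 200 four-member families;
and 50 end-to-end two-cohort studies (300 + 250 samples, 6 CNVRs) checking
that a spiked effect of 0.3 L per class tops the meta-analysis table.
These sizes keep the whole suite to a few minutes on one CPU while leaving
the Monte-Carlo error of each check well inside its assertion margin.

## Known limitations

* The EM caller is a maximum-likelihood stand-in for Bayesian hierarchical
  mixture callers; it exposes the same contract (class count, frequencies,
  posteriors, dose) but no prior pooling of variances across CNVRs, so very
  sparse classes rely on the expected-count guard rather than shrinkage.
* Classes are relative, so cross-study comparison of *absolute* copy numbers
  is out of scope by design.
* The compatibility test assumes independent cohorts and MAP counts; heavy
  call uncertainty (low confidence posteriors) makes the MAP tallies
  conservative inputs.
* Replication needs a biallelic tag; multiallelic CNVRs — often the most
  interesting — typically have none, exactly the situation the harmonized
  multi-cohort discovery stage is meant to address.
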