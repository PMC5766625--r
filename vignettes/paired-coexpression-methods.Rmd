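---
title: "Weighted co-expression network analysis for paired designs: methods and design notes"
author: "paircoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted co-expression network analysis for paired designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircoex)
```

## The problem

Weighted gene co-expression network analysis builds a network over genes (or
miRNAs) from an expression matrix, detects modules of densely interconnected
genes, and relates modules to a phenotype. The standard pipeline assumes
independent samples. Many cancer array studies instead use a *paired* design:
each subject contributes a tumour sample and a matched adjacent-normal
sample. Pairing removes subject-level confounding but induces within-pair
correlation, which invalidates the usual independent-samples association
tests, and raises the question of whether pooled Pearson correlation is even
a meaningful co-expression measure across the two conditions.

`paircoex` implements the network side unchanged — absolute Pearson
similarity, soft-thresholded adjacency, topological overlap, hierarchical
module detection — and replaces the association side with a random-intercept
linear mixed-effects model suited to pairing.

## Why pooled Pearson correlation remains valid

Write the pooled expression of gene $i$ as a two-component mixture
$Z_i = (1-\theta)X_i + \theta Y_i$, where $\theta \sim \mathrm{Bernoulli}(p)$
indicates case status, $X_i, Y_i$ are the control and case expression
variables, and $\delta_i = E(Y_i) - E(X_i)$. Then

$$
corr(Z_1, Z_2) =
\frac{(1-p)\,Cov(X_1,X_2) + p\,Cov(Y_1,Y_2) + p(1-p)\delta_1\delta_2}
{\sqrt{\big[(1-p)\sigma^2_{X_1} + p\sigma^2_{Y_1} + p(1-p)\delta_1^2\big]
       \big[(1-p)\sigma^2_{X_2} + p\sigma^2_{Y_2} + p(1-p)\delta_2^2\big]}}.
$$

The derivation never uses independence between the two samples of a pair, so
the identity — and hence the pooled similarity $s_{ij} = |cor(x_i, x_j)|$ —
holds for paired data exactly as for independent data.
`mixture_correlation()` evaluates the closed form; the test suite and the
acceptance script verify it against the empirical correlation of $10^6$
simulated mixture draws. Note the $p(1-p)\delta_1\delta_2$ term: two genes
that both shift with condition are correlated in the pooled data even if
they are conditionally independent. This is a real feature of pooled
similarity, not an artifact, and it is why strongly shifted synthetic
modules are slightly "tighter" than their loadings alone would suggest.

## The mixed-effects association model

For a response $y_{ij}$ (a module eigengene or one gene's profile) on
subject $i$, sample $j$:

$$
y_{ij} = \beta_{0i} + \beta_1\,\mathrm{tumour}_j + \beta_2\,\mathrm{age}_i +
\beta_3\,\mathrm{stage}_i + e_{ij},\qquad
\beta_{0i} \sim N(\beta_0, \tau^2),\ e_{ij} \sim N(0, \sigma^2).
$$

Gene significance is $GS = |t|$ for $\beta_1$; module significance is the
mean GS over a module's genes; module membership is $MM_i = cor(x_i, ME)$.

`fit_paired_lmm()` computes the REML fit in closed form by orthogonal
decomposition of the balanced complete-pair layout:

* within-pair differences $d_i \sim N(\beta_1, 2\sigma^2)$ carry all the
  information about the condition effect;
* pair means $m_i \sim N(\mu + x_i^\top\beta_c,\ \tau^2 + \sigma^2/2)$ carry
  the subject-level covariate effects and the between-pair variance.

Consequences, all exercised by tests:

* **Paired-t equivalence.** With $\hat\tau^2$ interior, the Wald $t$ for
  $\beta_1$ *is* the classical paired t-statistic on $n-1$ df (containment
  rule). This is the correctness anchor of the package and is asserted to
  `1e-8` against `t.test(paired = TRUE)` and against `lme4::lmer`.
* **Boundary handling.** When the unconstrained between-pair variance
  estimate is negative, $\tau^2$ is truncated at 0, $\sigma^2$ re-profiled
  over both strata for the reported variance components, and the fit is
  flagged `boundary = TRUE` instead of being refit by OLS. The Wald SE for
  $\beta_1$ always comes from the difference stratum ($sd(d)/\sqrt n$): it
  coincides with the REML SE in the interior case and keeps the condition
  test exactly the paired t-test — with an exact $t_{n-1}$ null — even at
  the boundary, at a small efficiency cost there.
* **Degrees of freedom.** Subject-level covariates are constant within
  pairs, never enter the difference stratum, and therefore never change the
  df of the condition test.
* **Stage coding.** Tumour stage is a numeric score by default
  (`stage_coding = "categorical"` switches to dummy coding); either way it
  only affects the pair-mean stratum.

Benjamini–Hochberg FDR is reported alongside raw p-values. Because $|t|$
values exceed 1, a normalized companion `gs_scaled` $= |t|/\max|t|$ is
emitted for displays that expect a $[0,1]$ scale; no claim is made that this
reproduces any particular published table's scaling.

## Network construction choices

* **Similarity** is unsigned, $s_{ij} = |cor|$: anticorrelated genes are
  considered co-expressed. Signed networks are out of scope.
* **Adjacency** $a_{ij} = s_{ij}^\beta$ with integer $\beta \ge 1$; the
  diagonal is zeroed so row sums are connectivities.
* **TOM** is the standard unsigned topological overlap
  $(\sum_{u\neq i,j} a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
  verified against a triple-loop brute force to `1e-12`.
* **Soft-threshold scan.** Connectivities are binned into 10 equal-width
  bins, $\log_{10}$ mean frequency regressed on $\log_{10}$ mean
  connectivity over non-empty bins, and the signed fit index
  $R^2 \cdot (-\mathrm{sign(slope)})$ recorded per $\beta$. The chosen power
  is the *first* strict local maximum of the curve — with one guard: a grid
  point only qualifies if its $R^2 \ge 0.8$. Without the guard, sampling
  noise on the flat low-$\beta$ part of the curve regularly produces
  spurious "peaks" (we observed a $\beta = 1$ local maximum with
  $R^2 = 0.15$). If no adequate peak exists the smallest $\beta$ with
  $R^2 \ge 0.90$ is used, and failing that the grid argmax with a warning.
  The last grid point never counts as a peak: a curve still rising at the
  end of the grid has not peaked.
* **When the scan is uninformative.** The scale-free criterion presumes an
  approximately power-law connectivity distribution. Strongly modular data —
  including this package's synthetic generator, whose connectivity is
  bimodal (module genes vs noise genes) — do not satisfy it at any power;
  the scan then warns and the power should be set explicitly. For such data
  we use $\beta = 6$, the long-standing default for unsigned networks, and
  the simulation-based tests do the same. On the synthetic default scenario,
  module recovery is excellent for $\beta \in [6, 9]$ (ARI 0.97–1.0) and
  degrades sharply for $\beta \ge 12$, which is worth knowing when choosing
  a power manually.

## Module detection

Average-linkage hierarchical clustering on $dissTOM = 1 - TOM$, cut at a
height (default $0.99 \times$ max merge height), with clusters smaller than
`min_module_size` (default 30) sent to the grey (unassigned) module. The
default `hybrid` method adds one rescue pass: each grey gene joins the
module with the smallest average dissimilarity to it, provided that average
is below the cut height. This is a deliberately simple stand-in for the
dynamic hybrid tree cut's PAM stage, which is not reimplemented. Modules are
labelled by size rank using the conventional colour palette (largest =
turquoise, then blue, brown, ...) with deterministic tie-breaking, so
identical inputs give identical module sets.

Module eigengenes are unit-variance first principal components of the
per-gene-standardized module submatrix, oriented so the mean correlation
with the module's genes is non-negative. The grey eigengene is computed the
same way — the unassigned set can carry a real association signal and is
tested like any module — but grey is excluded from hub analysis, since its
genes are not co-expressed by construction. Optional eigengene-based module
merging (`merge_close_modules()`) exists but is off by default.

## Hubs and exports

The weighted network is dichotomized at an edge threshold (default 0.1 on
TOM) within one module; the hub is the maximum-degree gene with ties broken
by summed edge weight, then lexicographically. The dichotomization threshold
is a genuinely free parameter: published degree counts are generally not
recoverable without knowing it, so the package documents a threshold search
rather than promising replication. Edges export as Cytoscape-ready SIF and
weighted TSV.

## The synthetic generator: what it emulates and what it does not

`simulate_paired()` generates the statistical world the model assumes: for
gene $g$ in module $m$,

$$
x_{g,ij} = \lambda_g\, f_{m,ij} + b_{g,i} + \delta_m\,\mathrm{tumour}_j
+ e_{g,ij},
$$

with a latent per-sample module score $f$, per-gene pair intercepts
$b_{g,i} \sim N(0, \tau^2)$ *independent across genes* (so noise genes stay
mutually uncorrelated), and noise $e \sim N(0, \sigma^2)$. Condition shifts
are stated in within-pair-SD units: one unit is $\sqrt 2\,\sigma$, the SD of
a paired difference for a pure-noise gene, so a shift of 1 gives a per-gene
paired-t noncentrality of about $\sqrt{n_\mathrm{pairs}}$.

Defaults (fixed once, before the test suite was frozen): 38 pairs; modules
of 250/190/80 genes — the approximate scale of a paired miRNA-array study
after QC — with shifts 1.5/0.75/0.25; 300 noise genes; $\tau = \sigma =
0.5$ (intraclass correlation 0.5 for noise genes, typical of matched-tissue
arrays); loadings drawn per gene as `loading_mean` $\times\ U(0.8, 1.1)$
with `loading_mean` 0.9, giving within-module correlations around 0.6.

What the generator does **not** emulate: array technical artifacts,
probe-level noise, non-Gaussian heavy tails, correlated noise between
modules, or any miRNA biology. A green recovery test therefore establishes
that the pipeline recovers planted linear-Gaussian structure of realistic
size and strength — not that it would reproduce any particular published
analysis of real arrays.

Two further honest limitations surfaced by testing:

* Exact hub identification is statistically hard. The similarity between two
  module genes depends on loadings through $\lambda/\sqrt{\lambda^2 + v}$,
  which saturates as $\lambda$ grows, so near-tied top loadings are
  indistinguishable at any realistic sample size. Even with a planted leader
  (loading 1.0 vs $\le 0.66$) the leader is the exact hub only about 70% of
  the time at 38 pairs; the tests assert top-5 membership instead, and the
  optional `leader_loading` config field exists precisely to make this
  property testable.
* Single within-pair label permutations are noisy null references for module
  genes, because module genes share the latent score; permutation checks
  average over several permutations.
* Because the latent score is drawn i.i.d. per sample (the stated additive
  design: condition shifts enter the gene means, never the score), its
  finite-sample case/control imbalance adds a module-level random component
  of SD about $\lambda\sqrt{2/n_\mathrm{pairs}}$ to the realized condition
  contrast. Realized per-module effects therefore scatter around their
  planted values across datasets; ranking properties are only asserted where
  the planted separation dominates this scatter.

## Numerical and degenerate-input policy

Missing values: genes with any non-finite value are dropped before network
construction (no pairwise-complete correlations; every downstream matrix
stays dense and deterministic). Zero-variance genes are an error in
similarity and eigengene computation, with offending gene ids named.
Orientation of expression files is always stated by the caller, never
guessed. A response that is constant within every pair yields estimate 0,
statistic 0. Identifiers are case-sensitive and whitespace-trimmed. All
tie-breaks (module size ranks, hub selection) are specified and
deterministic; reruns on identical input are bit-identical, which the
pipeline test asserts on the summary file.

The run configuration is JSON (not TOML: no TOML parser is available in the
package's dependency budget, and JSON round-trips through `jsonlite` without
extra code). Every CLI flag overrides its config key.

## What the acceptance checks establish

`scripts/acceptance.R` recomputes, from scratch at a caller-supplied seed:
the mixture-identity Monte-Carlo agreement (max deviation in MC-SE units),
the paired-t equivalence (max |t difference| over 200 genes), the type-I
error rate of the GS test over 1000 null genes, the TOM brute-force error,
default-scenario module recovery (ARI, module count, MS/ME ranking of the
most-shifted module), and the scale-free scan behaviour on a
preferential-attachment fixture. Published-data replication targets (module
sizes, eigengene t-values, a hub degree from a specific GEO series) require
an external download and under-specified preprocessing parameters; they are
deliberately not asserted, and the corresponding code paths are exercised on
synthetic fixtures instead.
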