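---
title: "Methods: differential co-expression networks with dcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression networks with dcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

`dcnet` analyzes two-condition expression data on a scored
protein–protein interaction (PPI) scaffold.  The question it answers is
not only *which genes change level* between health and disease, but
*which interactions change coordination*: gene pairs that are tightly
rank-correlated under one condition and uncorrelated under the other
("gained" and "lost" edges).  This vignette states the model behind each
stage, the defaults and why they are what they are, what the synthetic
generator does and does not emulate, and the numerical conventions.

## Differential expression: the moderated t

For gene $g$ with $n_1$ healthy and $n_2$ disease samples (log2 scale),
the effect is the mean difference
$\mathrm{lfc}_g = \bar d_g - \bar h_g$ (sign convention: positive means
higher in disease; the input matrix is assumed already log2, so this is
a log2 fold change).  With so few samples, gene-wise variances are noisy;
we use the standard empirical-Bayes remedy: assume sample variances
follow $s_g^2 \sim s_0^2 F(df, d_0)$ and shrink,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + df\, s_g^2}{d_0 + df},\qquad
t_g = \frac{\mathrm{lfc}_g}{\tilde s_g\sqrt{1/n_1+1/n_2}},$$

with $t_g$ referred to a t distribution on $d_0 + df$ degrees of
freedom.  $d_0, s_0^2$ are fitted by moment matching on the log
variances (digamma/trigamma equations solved by Newton iteration).  Two
limits are exercised in the tests: $d_0 = 0$ recovers the ordinary
pooled t exactly, and $d_0 = \infty$ pools completely
($\tilde s_g^2 \equiv s_0^2$).  When the observed spread of log
variances does not exceed pure sampling noise the fit returns
$d_0 = \infty$; when all variances are *identical* the common value is
returned as $s_0^2$ directly (the bias-corrected limit would
overshoot it, and a degenerate input deserves the obvious answer).  A
Welch t (`method = "welch"`) is available as a transparent,
assumption-light fallback.

A gene is a DEG when raw $p < 0.05$ **and** $|\mathrm{lfc}| > 0.5$, both
strict inequalities, no multiple-testing adjustment — these mirror the
printed criteria this class of study uses.  A BH-adjusted mode exists
(`adjust = "BH"`) but is off by default.

## The wild-type disease-related network

PPI edges are kept when their combined score is **strictly greater**
than 900 ("above 900"; `strict = FALSE` gives the ≥ convention some
STRING tools use).  The WDRN is then the subgraph of filtered edges with
at least one DEG endpoint; its node set is the union of retained edge
endpoints, so a DEG with no retained incident edge does not appear.
Construction is monotone in the DEG set and idempotent in the filter.

Coverage percentages (DEG share of nodes) are **truncated** to two
decimals, not rounded: 859 DEGs among 5195 nodes is 16.5351…%, printed
as 16.53.  Truncation is the only rule that reproduces all six published
coverage figures this convention was checked against; rounding fails on
exactly that case.  The computation uses integer division
(`(10000 * k) %/% n / 100`) so no floating-point boundary case can flip
a digit.

## Differentially correlated pairs

For each WDRN edge and each condition we compute Spearman's coefficient
on average ranks, $r_s = S_{uv}/\sqrt{S_u^2 S_v^2}$, and a two-sided
p-value.  The significance machinery is the part small studies get
wrong, so it is explicit here:

* **Exact permutation null** (`method = "exact"`, chosen by `auto` when
  $n \le 8$ with untied ranks): enumerate all $n!$ orderings, count
  $|r_s^{perm}| \ge |r_s^{obs}|$ including the observed one, so
  $p > 0$ always.  With ties, enumeration conditions on the observed tie
  pattern.  At $n = 3$ the smallest achievable two-sided p is $1/3$ —
  an exact test can *never* reject at 0.05 with three samples per group,
  which is why `t_approx` exists as a compatibility mode for published
  three-sample designs (those analyses must have used an approximation).
* **t approximation** (`auto` for $n > 8$):
  $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ df, with the p-value set to
  the smallest representable positive number at $|r_s| = 1$.

An edge is **gained** when $p_{disease} < \alpha$ and
$p_{healthy} \ge \alpha$, **lost** symmetrically, **none** otherwise
(including "significant in both": coordination that persists is not
differential).  "Uncorrelated or weakly correlated" is operationalized
as non-significance — the only threshold such studies state; no
secondary $|\rho|$ cutoff is imposed.  Edges with a constant expression
vector get status `none` with the correlation recorded as undefined;
edges with genes missing from the matrix are skipped with a warning.
Under independence the null rate of the two-test rule is
$2q(1-q)$ where $q$ is the *attainable* per-test level — for the exact
test at $n=6$, $q = 1/30 \approx 0.033$, giving ≈ 0.064, noticeably
more than $\alpha$ and less than $2\alpha$; the tests verify this
against enumeration rather than the $2\alpha(1-\alpha)$ shorthand.

The differential network (DN) keeps exactly the gained/lost edges, each
weighted by the perturbation magnitude
$|\rho_{disease} - \rho_{healthy}|$ (the edge-width convention of
differential-network figures; gained is drawn red, lost green).  No
formula for the width is standard, so the signed difference of
coefficients was chosen as the simplest faithful one.

## MCODE-style modules and hubs

Vertex weight = $k \times$ density of the highest $k$-core of the
vertex's closed neighborhood (the core-clustering coefficient).  Seeds
are processed in decreasing weight (lexicographic tie-break); expansion
admits unused neighbors with weight $> w_{seed}(1 - \mathrm{vwp})$,
default $\mathrm{vwp} = 0.2$; haircut iteratively removes degree-1
members (the 2-core of the candidate); fluff is implemented but off by
default — these are the published tool's defaults, since the method is
named but unparameterized in the studies that use it.  Module score =
density × size, retained when strictly greater than 3.  Two
determinism choices are ours: every vertex touched by a candidate module
is consumed whether or not the candidate passes the score threshold, and
all orderings are broken lexicographically; together they make output
independent of hash order and run-to-run identical.

Hub genes: a gene's score is its **degree in the network restricted to
its module's members**; hubs are genes with score strictly above 10.
When no gene qualifies, the single maximum-degree gene is returned with
`rule = "fallback_max"` (this mirrors the convention of reporting the
best available candidate — e.g. a gene of score 5 — when a network is
too small for the threshold).  "Score" is never explicitly defined in
the source literature; degree is the only reading consistent with the
reported fallback values, and the threshold is configurable.

## Cross-tissue comparison

Venn partitions assign every element of the union of $k$ labeled sets to
one of $2^k - 1$ disjoint membership regions.  **Housekeeping** DEGs/DCGs
are those present in *all* tissues — note this follows the
multi-tissue-comparison usage of "housekeeping", not the conventional
constitutive-expression meaning.  DCG pair identity across tissues is
the unordered gene pair regardless of gained/lost direction; per-tissue
directions are reported alongside.  Identifier matching everywhere is
exact string equality after one normalization (trim + uppercase); no
alias or ortholog resolution is attempted, and users mixing platforms
must harmonize identifiers upstream.

## The synthetic generator

`sim_config()` defaults describe the regime these analyses target: two
conditions × 6 samples (a 3-per-group preset mirrors small public
series), per-gene baselines uniform on [4, 12] log2 units, Gaussian
noise with σ = 0.5, 25% of genes shifted by ±1 log2 unit in disease,
and 4% of PPI edges planted as condition-specific correlated pairs with
target correlation 0.95.  The PPI is grown by preferential attachment
(scale-free degree structure) with integer scores split around the
900-confidence boundary by `fraction_above_900` (default 0.5).  No
published noise model exists for the motivating datasets, so these are
realistic free choices, not estimates.

Correlation is planted through a latent factor: both genes of a pair add
$\beta f$, $f \sim N(0,1)$ shared, with
$\beta = \sigma\sqrt{\rho/(1-\rho)}$, which makes the model Pearson
correlation exactly $\rho$ in the active condition.  Consequences worth
knowing:

* Planted endpoints have variance $\sigma^2 + \beta^2$ in the active
  condition ($\beta \approx 2.18$ at $\rho = 0.95, \sigma = 0.5$) —
  deliberately simple, but it means planted-pair endpoints are *harder*
  to call as DEGs than clean shifted genes.  Recovery experiments
  therefore supply the generator's true DEG set when building the WDRN
  (which the ground-truth invariant guarantees contains every planted
  edge); recovery through *detected* DEGs additionally measures DEG-call
  power on variance-inflated genes and is not a clean test of the edge
  classifier.
* Pairs are sampled as a vertex-disjoint matching whenever possible
  (the 4% default keeps this achievable), because a gene serving two
  pairs with independent factors realizes roughly half the target
  correlation with each partner.  Whole correlated *groups* (e.g. a
  clique sharing one factor, or one designated pair repeated across
  tissues) can be planted with `forced_groups`.
* Planted pairs are drawn only from edges with score > 900 and a DEG
  endpoint, so the default WDRN filters cannot remove them.
* Not emulated: count-level (negative binomial) noise, batch effects,
  probe-level artifacts, and realistic correlation *backgrounds* (all
  non-planted pairs are independent).  Passing recovery tests therefore
  demonstrates correctness of the machinery under the stated model, not
  performance on real tissue data.

Determinism: a `sim_config` seed fixes every draw; identical configs
give byte-identical fixture files (no timestamps are embedded in any
comparable artifact — only the human-readable run log is stamped).

## Problem sizes and verification

The shipped tests run the generator at 100–400 genes / 250–3000 edges —
large enough that the binomial checks have power, small enough that the
whole suite finishes in well under a minute: exact-p oracle equivalence
against full $n!$ enumeration (100 random pairs, $n \le 7$, ties
included), MCODE vertex weights against a brute-force subset oracle
(200 random graphs, ≤ 8 vertices), type-I error of the DEG caller on
1000 null genes, the null DCG rate on ~4000 WDRN edges against the
enumerated $2q(1-q)$, planted-pair recall/precision pooled over 20
seeds, moderation recovery on 500 scaled-F variances (also cross-checked
against the established empirical-Bayes implementation), and a planted
correlated 5-clique returned as the top module with score 5.
`scripts/acceptance.R` recomputes all of these from a command-line seed.

## Known limitations

* With 3 samples per condition the exact test cannot reject; analyses
  of such designs require `t_approx` and inherit its anticonservatism.
* No multiple-testing correction across edges by default (matching the
  per-test α convention of the motivating studies); with thousands of
  WDRN edges the DN contains an expected $2q(1-q)$ fraction of false
  edges.  `adjust = "BH"` is available in both the DEG and the edge
  classifiers when error control matters.
* Identifier mapping between expression platforms and PPI namespaces is
  the user's responsibility.
* The merged-network module analysis merges WDRNs by default (a flagged
  alternative is merging DNs); which variant a given published analysis
  used is often ambiguous.
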