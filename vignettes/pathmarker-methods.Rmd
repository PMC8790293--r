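---
title: "Marker discovery from differential expression and pathway networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery from differential expression and pathway networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmarker)
```

# Overview

`pathmarker` screens candidate diagnostic marker genes for a tumor-vs-normal
bulk RNA-seq design by requiring two independent lines of evidence per gene:
a significant expression difference between the groups, and a central (hub)
position in the gene interaction network assembled from KGML pathway files.
The intersection of the two gene sets is the marker panel; a linear
maximum-margin classifier trained on the panel's expression quantifies its
diagnostic value. This vignette documents the statistical models, the
numerical choices, and what the synthetic-data module does and does not
emulate.

# Differential expression

## Model

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $\mu_{gj}$ and variance $\mu_{gj} + \phi_g \mu_{gj}^2$; the dispersion
$\phi_g \ge 0$ captures biological variability beyond Poisson noise
($\phi = 0$ is the Poisson limit).

## Normalization

Two size-factor methods are provided. `libsize` sets each factor
proportional to the column sum, rescaled to geometric mean 1. `tmm`
additionally corrects composition bias by the trimmed mean of M-values:
gene-wise log2 ratios against a reference sample (the one whose
upper-quartile expression is closest to the mean) are trimmed two-sided —
30% on M, 5% on A — and averaged. The trim fractions are the customary
defaults for this estimator and are exposed as arguments. The TMM mean is
unweighted; precision weighting was left out deliberately, as the estimator
is used here for moderate-depth simulated libraries where the weights change
factors by well under a percent.

## Exact test

Before testing, every sample is rescaled to the common (geometric-mean)
effective library size and rounded, so that under the null hypothesis the
two group sums are exchangeable NB variables. Conditioning the group-A sum
on the overall total $t$ gives a discrete conditional law that does not
depend on the unknown mean; the two-sided p-value sums the probabilities of
all splits of $t$ no more probable than the observed one (ties included via
a $10^{-12}$ relative tolerance, so symmetric outcomes are never dropped and
the p-value at the mode is exactly 1). The conditional pmf is computed by
normalizing products of NB log-pmfs, which is numerically stable for the
totals that arise at the package's problem sizes (up to a few hundred
thousand); the test suite verifies it against an independent
beta-binomial-form enumeration and against the conditional-binomial limit at
$\phi = 0$.

## Dispersion

The quantile-adjusted conditional-likelihood and empirical-Bayes machinery
of the established DE packages is intentionally not reproduced; this
package's contribution is the pipeline, and a transparent estimator keeps
the exact test self-contained. Per-gene method-of-moments estimates
$(s^2 - \bar x)/\bar x^2$ are pooled across groups (weighted by degrees of
freedom), the common dispersion is their 10%-trimmed mean clamped at zero,
and per-gene values shrink toward it with weight `prior_weight` (default
0.3). The default weight is a compromise: 0 leaves noisy per-gene estimates
untouched, 1 ignores genuine dispersion heterogeneity. Parameter-recovery
tests (Poisson data, and $\phi = 0.4$ truth at 2000 genes × 50 samples)
bound the estimator's bias.

## Calling DEGs

A gene is called differentially expressed when $p < 0.05$ and its fold
change — the ratio of group CPM means with a pseudocount of 0.5 CPM to keep
zero-expression genes finite — satisfies $\mathrm{FC} > 2$ or
$\mathrm{FC} < 0.5$. All three inequalities are strict, read literally from
the rule the pipeline reproduces; a gene at FC exactly 2 is not called. No
multiplicity correction enters the filter (the rule is a raw-p rule); a BH
FDR column is emitted for information.

# Enrichment

Over-representation uses the upper-tail hypergeometric test
$p = P(X \ge k)$ for an overlap of $k$ between query and set within a
finite universe. The universe defaults to all genes in the count matrix,
not any annotation-service-internal background, because the pipeline should
be self-contained and reproducible; it is configurable. The conservative
EASE variant (replace $k$ by $k-1$) is available as a flag, since
over-representation services differ in this choice and the correct variant
is not derivable from the rule being reproduced. Significance is again a raw
$p < 0.05$ rule, mirroring the DEG filter's convention.

# KGML parsing and edge semantics

The parser captures the three KGML element families that carry interaction
information: `entry` (nodes; multi-id `name` attributes split on
whitespace), `relation` (typed ECrel / PPrel / GErel / PCrel / maplink) and
`group` (complexes with `component` references). Malformed structure —
dangling relation endpoints, empty groups, unknown relation types — is a
parse error naming the offending element, rather than silent loss.

Edge conversion rules, with rationale for the genuinely open cases:

* ECrel, PPrel, GErel, PCrel relations whose endpoints resolve to gene sets
  $A$ and $B$ (groups expand to their components' union) emit all pairs
  $A \times B$ minus self-pairs.
* **maplink emits nothing**: its target is a pathway map node, not a gene
  product, so no gene–gene edge can be formed; skipped relations are
  counted and reported.
* **PCrel** emits only when both endpoints are gene entries; protein–compound
  pairs are dropped, because the result is a *gene* interaction network.
* **Group co-membership edges are off by default** (`include_group_internal`
  flag): whether complex co-membership itself constitutes an interaction is
  ambiguous, and the default keeps every edge traceable to an explicit
  relation.
* Edges are undirected and self-loops always dropped, since the downstream
  statistic is plain degree.

# Network, degree and hubs

Per-pathway edge lists merge into a simple undirected graph; duplicate pairs
collapse to one edge whose provenance is the set of contributing pathways.
Nodes enter only through edges, so isolated nodes cannot occur — a
documented contract, not a limitation, as degree-0 nodes could never be
hubs. Degree is the number of distinct neighbors and satisfies the handshake
identity exactly.

Hubs are nodes with degree **strictly greater than 30**, the operative rule
of the study design this package reproduces; a top-fraction mode (top 10%
by degree, ties at the cutoff included) is provided as the alternative
heuristic. The power-law diagnostic bins degrees logarithmically (20 bins
by default) before regressing log density on log degree — logarithmic
binning tames tail noise that would otherwise dominate the fit — and
reports the exponent as minus the slope with the fit's $R^2$. Distributions
with fewer than 10 distinct degrees return a not-applicable result instead
of a meaningless line. This is a diagnostic, not rigorous power-law
inference (no MLE, no KS test), which is out of scope.

# Markers

Markers are the genes present in both the DEG table and the hub set,
annotated with degree and DE p-value and sorted alphabetically. Symbol
matching is case-insensitive after whitespace stripping; KEGG-id vs symbol
namespace mismatches must be resolved by the id map upstream — if they are
not, the intersection is empty and the pipeline halts before classification
with an explicit message rather than producing a vacuous model. A supplied
literature list flags confirmed markers; live literature mining is out of
scope, and the packaged 12-gene list is a transcribed reference fixture.

# Classification

The diagnostic model is a linear soft-margin SVM on the marker genes'
log2(x+1) normalized expression. The primal
$\min \tfrac12\|w\|^2 + C\sum_i \xi_i$ subject to
$y_i(w^\top x_i + b) \ge 1 - \xi_i$ is solved through its dual by SMO with
maximal-violating-pair selection, ties broken by lowest index and a fixed
sweep order, so the solver is fully deterministic; convergence is declared
at KKT gap $10^{-6}$, and failure to converge within the iteration cap is an
explicit error. The soft margin (default $C = 1$) is the practical form: the
hard-margin program alone is infeasible on non-separable data, and it is
recovered as the large-$C$ limit, where the geometric margin equals
$2/\|w\|$. Only the linear kernel is provided, matching the linear decision
function the model is defined by.

Features are standardized with training-data statistics only — recomputed
inside every cross-validation fold, so no information leaks from held-out
samples. A decision score of exactly zero is assigned to the positive
(tumor) class; the tie rule is arbitrary and documented.

Evaluation: stratified 50/50 train/test split (per-class training count
$\lfloor f \cdot n \rfloor$, assignment random given the seed), tenfold
stratified cross-validation on the training half with predictions pooled
into a single confusion matrix and ROC — pooled-fold evaluation is the
default reading of a single cross-validated training confusion matrix, with
resubstitution available via a flag — and a final model trained on the full
training half scored on the untouched test half. AUC is the Mann–Whitney
rank statistic with half credit for ties; the ROC sweeps thresholds over the
unique scores.

# The synthetic-data module

The generator produces every input the pipeline consumes, with ground-truth
manifests, and is first-class tested code.

**Counts.** Per-gene baseline means are log-normal (median ≈ 50 counts,
sdlog 1 — a typical moderate-depth bulk profile); NB draws use a single
dispersion shared across genes. A fraction of genes carries a multiplicative
$2^{\pm\mathrm{lfc}}$ effect on the tumor mean, half up and half down,
mirroring the near-even up/down split such screens report. Tumor and normal
samples are independent groups; the data the design emulates does not state
patient matching, and none is simulated.

**KGML.** One preferential-attachment graph is grown over the gene universe
(each new node attaches, degree-proportionally, a mean of
`attachment_param` edges; 5.75 reproduces the edge density of the reference
network: 1277 nodes, ~7345 edges), then edges are partitioned into pathway
documents, with ~10% emitted in two pathways to exercise provenance
merging. Documents contain gene entries with KEGG ids and symbol labels,
relations typed uniformly over the four gene-edge types, maplink relations
to map entries (which must yield no edges), and occasionally a wedge encoded
through a group entry — so parser, filter and group expansion are all
exercised. Hub truth is every node with merged degree > 30.

**Scenario.** `synthetic_scenario()` wires the two generators into one
seeded study: 2000 genes × (150 tumor + 100 normal) samples, a 300-gene
pathway sub-universe across 12 KGML files, 10% DE at |lfc| = 2 and
$\phi = 0.3$, with DE planted on 12 hub genes (the intended markers) and the
remaining DE quota drawn from non-hub genes, so the planted marker set is
exactly the DE∩hub intersection. The choices are deliberate: lfc 2 equals
the pipeline's own fold-change threshold, $\phi = 0.3$ is a realistic
biological dispersion for bulk tumor/normal cohorts, and the sample and gene
counts are a desk-scale version of the thousand-sample cohort the design
emulates — large enough for stable estimates, small enough that the full
test suite runs in minutes. These sizes are also the problem sizes the
package's validation uses throughout.

**What passing tests do and do not show.** The generator draws clean NB
counts with independent genes and a single batch; real cohorts have
correlated genes, batch structure, outlier libraries, GC/length biases and
matched-pair designs, none of which are simulated. End-to-end recovery of
the planted markers therefore validates the *pipeline's logic* — filters,
graph semantics, intersections, leakage-free evaluation — not robustness to
real-data artifacts. Likewise the perfect AUC in the demo scenario reflects
how separable a 12-gene coordinated 4-fold shift is, not expected clinical
performance.

# Numerical and degenerate-input conventions

* Exact test: both groups all-zero returns $p = 1$; tie tolerance
  $10^{-12}$ relative.
* Dispersion: constant genes clamp the raw estimate at 0; single-sample
  groups fall back to the other group's information with a warning.
* Enrichment: inconsistent 2×2 margins are an error; $k = 0$ returns 1.
* Power-law fit: degenerate degree distributions return
  `applicable = FALSE`, never a crash.
* Splits and folds: deterministic given the seed; all package randomness
  flows from explicit integer seeds with the caller's RNG state restored.
* Pipeline: by default the network uses every KGML file in the configured
  directory; `restrict_to_significant = TRUE` reproduces the stricter flow
  of building the network only from pathways the enrichment stage called
  significant. The permissive default keeps the generated scenario's hub
  truth (defined over all generated pathways) recoverable and makes the
  network stage independent of the enrichment stage's gene sets.

# Known limitations

* The dispersion estimator is method-of-moments, not CML/empirical Bayes;
  per-gene estimates at small sample sizes are noisy and lean on shrinkage.
* Enrichment p-values depend on the chosen universe; they will not match
  annotation services with proprietary backgrounds.
* The power-law diagnostic is descriptive.
* The SMO solver is pure R and intended for panel-sized feature sets
  (tens of genes) and cohort-sized sample counts (hundreds), which it
  handles in seconds; it is not a general-purpose SVM.
* KGML `reaction` elements and graphics coordinates are not parsed.
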