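---
title: "Identifying hub lncRNAs through co-expression networks: models and design"
author: "lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying hub lncRNAs through co-expression networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

# The problem

Idiopathic pulmonary fibrosis (IPF) profiling studies look for long
non-coding RNAs (lncRNAs) that sit at the centre of transcriptional
dysregulation: genes that are differentially expressed between IPF and
normal lung *and* strongly co-expressed with many differentially expressed
mRNAs. The analysis chain is simple but has many small contracts — which
test, which thresholds, strict or non-strict inequalities, which samples the
correlations are computed over, in what order single-cell QC filters are
applied. `lncnet` implements that chain as a set of testable components with
a synthetic-data generator that plants known structure, so every stage can
be validated against ground truth instead of against a figure.

# Pipeline stages and their contracts

## Differential expression

Expression values are assumed to be on a log2-like scale and already
normalized; no normalization is performed. Probe-level arrays are collapsed
first: probes mapping to no gene or to several genes are deleted, and a gene
measured by several probes takes the arithmetic mean of those probes'
values (`collapseProbes()`).

`runComparison()` applies the classic pooled-variance two-sample Student's
t-test per gene,

$$t = \frac{\bar x - \bar y}{s_p\sqrt{1/n_x + 1/n_y}},\qquad
s_p^2 = \frac{(n_x-1)s_x^2 + (n_y-1)s_y^2}{n_x+n_y-2},$$

with a two-sided p on $n_x+n_y-2$ degrees of freedom. The equal-variance
form (not Welch) is the default because the named procedure is Student's
test; Welch is available via `varEqual = FALSE` in `tTestTwoGroup()`.
Significance is a **raw** threshold, `p < 0.01` strict, with no multiplicity
correction — this mirrors the two-group comparison convention of the
analysis being reproduced; a BH-adjusted mode exists (`adjust = TRUE`) but
is off by default. Degenerate genes follow a fixed contract: both groups
constant and equal gives $t = 0, p = 1$; constant and unequal gives
$p = 0$ with a signed infinite $t$ and a `degenerate` flag plus a warning
listing the gene ids. This makes the noiseless (`sigma = 0`) simulation
limit exact rather than NaN-ridden.

"IPF-related" genes are those significant in **every** configured
comparison (`intersectComparisons()`), split by biotype. Whether
intersected genes must agree in direction across comparisons is genuinely
ambiguous; the package includes discordant genes and reports them in a
separate `discordant` field rather than silently guessing either way.

## Co-expression network

`buildNetwork()` tests all lncRNA x mRNA candidate pairs with the Pearson
correlation and its t-transform p-value,
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, retaining pairs with
$|r| > 0.8$ **and** $p < 0.01$, both strict. Three design choices are worth
stating:

* **Sample pooling.** Correlations are computed over *all* samples of the
  dataset, cases and controls together. The source convention does not
  specify the subset; pooling matches the co-expression framing (a
  regulator should track its targets across the whole cohort) and is the
  documented default.
* **Constant genes** have undefined correlations and are skipped with a
  warning, never emitted as NaN edges.
* **No multiplicity adjustment** of edge p-values — the thresholds are raw,
  as in the convention being reproduced.

The retained graph is bipartite by construction; nodes are stored only
while incident to an edge. The hub is the maximum-degree node
(`hubGenes()`); ties are all returned rather than broken arbitrarily.
`degreeTable(net, minDegreeShown = k)` reproduces the "genes with degree
greater than *k*" presentation convention with a strict cutoff.
`hubSubnetwork()` is the induced subgraph on the focal gene and its direct
neighbors: all original edges with both endpoints inside that
neighborhood. Whether edges *among* the neighbors (absent for a bipartite
first neighborhood around a lncRNA, possible around an mRNA) belong in the
subnetwork is not specified anywhere authoritative; the induced-subgraph
rule is this package's documented choice.

## Gene sets, crosstalk and enrichment

`enrichGeneSets()` uses the upper-tail hypergeometric model: for a query of
$n$ genes in a universe of $N$ with $K$ annotated,
$p = P(X \ge k)$, computed through `phyper`'s log-space tail (stable for
large counts), then Benjamini–Hochberg adjusted with significance at
FDR < 0.05. The background universe is an explicit input; the recommended
default is all genes of the collapsed expression matrix, and query genes
outside it are dropped with a message. Disease-specific pathway exclusion
(and any KEGG top-category restriction) is expressed as an id deny-list at
`GeneSetCollection()` construction — no live database queries.
`crosstalkTable()` emits the (gene, set) membership pairs behind a Sankey
diagram; rendering is out of scope.

## Single-cell QC

`qcFilter()` applies the cascade in a fixed order with strict inequalities:

1. drop cells detecting fewer than 200 genes;
2. drop genes detected in fewer than 3 of the remaining cells;
3. drop cells detecting more than 5000 genes **or** above 30%
   mitochondrial UMI fraction, both recomputed on the filtered panel.

Detection means count > 0. The order and the recomputation between steps
are part of the contract — the test suite contains a fixture where running
the gene filter first gives a different result. Mitochondrial genes come
from an `is_mito` annotation when present, otherwise from a
case-insensitive `"MT-"` symbol prefix. Normalization and regression-out of
mitochondrial effects are deliberately not implemented; the package stops
at QC accounting (`QCReport`) and raw-count summaries
(`expressionByGroup()`).

# The synthetic-data generators

## Bulk: factor model and its algebra

`simulateBulk()` draws a log2-scale matrix
$x_{gs} = \mu_g + \delta_g\,[s \in \mathrm{case}] + a f_s + b \varepsilon_{gs}$
where $\mu_g \sim N(7, 1.5^2)$ is a gene baseline, $\delta_g \in \{0, \pm e\}$
is the planted shift (effect size $e$, default 2 log2 units — a strong,
microarray-plausible fold change), and the $a f_s$ term exists only for hub
modules: one standard-normal factor $f$ per hub, shared by the hub lncRNA
and its `hubDegree` partner mRNAs. The loadings are chosen analytically as

$$a = \sigma\sqrt{\rho},\qquad b = \sigma\sqrt{1-\rho},$$

so that every gene keeps within-group variance $\sigma^2$ and any two
module members have **within-group** correlation exactly $\rho$
(`rhoTarget`, default 0.9). This parameterization was picked over the
alternative — calibrating the *pooled* correlation to $\rho$ — because the
pooled alternative forces $a^2 = \sigma^2\rho/(1-\rho) - e^2/4$, inflating
the within-group variance roughly tenfold at the defaults and destroying
the module's t-test power: the planted hub would no longer survive its own
DEG filter, which contradicts the point of planting it. With the chosen
form, pooling balanced groups adds the shared shift to the covariance of
two concordantly shifted module genes, giving the closed-form pooled
correlation

$$\rho^\ast = \frac{\rho\sigma^2 + e^2/4}{\sigma^2 + e^2/4}$$

(exported as `hubPartnerCorrelation()`; 0.95 at the defaults). Hub modules
are planted concordantly up-regulated — a co-regulated module — and always
inside the DE budget, so `deFrac * nGenes` must cover
`nHubs * (1 + hubDegree)`; violations are explicit errors.

Two consequences are worth knowing when interpreting simulations. First,
*any* two concordantly shifted DE genes gain pooled correlation
$\frac{e^2/4}{\sigma^2+e^2/4}$ (0.5 at the defaults) through the shared
group structure — comfortably below the 0.8 edge threshold at the default
noise, but approaching 1 as $\sigma \to 0$. The generator's noise default
($\sigma = 1$) keeps the background there harmless while the module at
$\rho^\ast = 0.95$ clears the threshold. Second, the module factor's group
means are themselves random, so a module's realized effect sizes move
coherently; occasionally a replicate loses several partners from the DEG
set at once. The headline recovery property is therefore stated (and
tested) as a rate — the planted hub is the unique top-degree lncRNA in at
least 95 of 100 replicates at the default configuration of 12+12 samples,
500 genes, 50 lncRNAs, 20% DE, effect 2, $\rho = 0.9$, $\sigma = 1$ — not
as a certainty.

The default sample size (12 + 12) reflects the modest cohort sizes typical
of IPF expression studies; 500 genes and 50 lncRNAs keep the all-pairs
correlation stage at interactive speed while leaving a realistic ~10:1
mRNA:lncRNA ratio.

## Single cell: Poisson programs with hard guarantees

`simulateSC()` draws UMI counts from per-cell-type Poisson rate programs
(rates $\mathrm{Exp}(1) + 0.3$ over a per-type gene block), with `"MT-"`
named mitochondrial genes at low rates, and plants three kinds of
low-quality cells that violate *by construction* exactly one threshold
each: `few_genes` cells only touch half the min-genes cutoff's worth of
genes; `many_genes` cells are forced positive on more than `maxGenes`
genes; `high_mito` cells carry a mitochondrial UMI majority (fraction at
least 0.5, strictly above the 0.30 cutoff) while keeping their detected
gene count inside the legal band. Because construction-level guarantees
(not probabilistic tendencies) are what make per-step QC accounting exactly
checkable, the generator also enforces deterministic floors and ceilings on
normal cells: a core of `minGenes + 10` always-detected genes per type,
each program gene detected in at least `minCells` cells, a detection
ceiling at `maxGenes`, and a capped mitochondrial fraction. Rare genes
(detected in a single cell) are planted so the gene-level filter has a
known truth too.

The QC thresholds are *generator arguments* (desk-scale defaults 50 / 3 /
500 / 0.30 against 1000 genes) so the guarantees hold at any size; passing
the same thresholds to `qcFilter()` recovers exactly the planted removals.
`qcFilter()`'s own defaults remain the full-scale 200 / 3 / 5000 / 0.30.

## What the generators do not emulate

Bulk: no batch effects, no heteroscedastic genes, no count-derived
mean-variance relationship (values are Gaussian on the log scale by
design), no probe-level artifacts beyond what `collapseProbes()` tests
construct. Single cell: no ambient RNA, no doublets, no depth gradients,
no batch structure. Passing the recovery tests therefore demonstrates that
the *pipeline logic and statistics* are correct under their stated
assumptions — not that the thresholds are optimal for any particular real
dataset.

# Numerical choices

* Pearson $|r|$ is clamped to 1 before the t-transform; $|r| = 1$ returns
  $p = 0$ exactly.
* The vectorised row t-test guards the zero-variance denominator with the
  degenerate contract above instead of producing NaN.
* `hypergeomUpper()` validates count consistency and delegates the tail to
  log-space `phyper`; the test suite sweeps every configuration with
  $N \le 25$ against exact combinatorial enumeration.
* Degree-table ties are broken lexicographically by node id, making every
  output deterministic.
* Each generator call runs a private RNG stream from its `seed` argument
  and restores the caller's RNG state — identical arguments give
  byte-identical outputs, and no global state leaks.

# Orchestration and reproducibility

`runPipeline(pipelineConfig(...), outDir)` chains
simulate/load → DE → intersection → network → hubs and subnetwork →
crosstalk/enrichment → optional single-cell QC → optional PPI/TF layer
integration, writing per-stage TSV/SIF/JSON outputs, structured filter
logs (before/after counts per stage), a `summary.json`, and the verbatim
configuration as `config.yaml`. Re-running from that file reproduces the
summary byte-for-byte. When no curated GMT is supplied, enrichment runs
against `simulateGeneSets()` so the stage is always exercised;
`integrate` layers (PPI, TF→target) are file inputs by design since
upstream database versions are not pinned.

# Problem sizes used by the test suite

The suite validates the statistical core on 1000 random instances per
statistic (and a full enumeration sweep for the hypergeometric tail), the
network builder against a brute-force all-pairs oracle on 50-gene
matrices, hub recovery on 100 replicates of the default configuration,
null calibration on a 4000-gene no-signal matrix and 500–1000 random
enrichment queries, and the QC cascade on ~190-cell, 1000-gene planted
datasets. These sizes were chosen to keep the full suite around a minute
on a laptop while leaving every Monte-Carlo band at three standard errors
or better.

# Known limitations

* The paired-comparison intersection is implemented for any number of
  comparisons but the synthetic study design generates one case/control
  contrast; two-comparison behavior is exercised with constructed tables.
* Edge p-values and DE p-values are deliberately unadjusted (matching the
  reproduced convention); interpret absolute edge counts accordingly.
* `expressionByGroup()` summarizes raw counts; it does not normalize for
  sequencing depth.
* The permutation-null agreement of the correlation p-value is exact only
  asymptotically; at $n = 10$ the conditional permutation distribution
  differs from the t reference by up to a few percent in p, which the test
  suite documents with an explicit small-sample allowance.
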