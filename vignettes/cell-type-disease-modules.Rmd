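---
title: "Cell type-specific gene networks and disease gene modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell type-specific gene networks and disease gene modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsnet)
```

## The problem

Many disease-associated genes are expressed in several cell types of a
tissue, yet pathology often manifests in specific cells. The working
hypothesis behind this package is that what matters for manifestation in a
cell type is not any individual gene but the presence of a *disease gene
module*: a connected set of disease-associated genes inside that cell type's
functional interaction network. ctsnet builds cell type-specific gene
networks from cell-annotated expression data plus a referenced
tissue-specific interactome, and tests candidate disease modules for
statistical significance.

## The model

**Cell type-specificity.** Expression counts are normalized to counts per
million (CPM) per cell, and averaged per annotated cell type. For gene $g$
and cell type $c$ among $k$ types, with $N_c$ cells of type $c$,

$$\mathrm{specificity}_{g,c} \;=\; \min_{r \neq c}
  \frac{\tfrac{1}{N_c}\sum_{i=1}^{N_c} \mathrm{exp}(i,g,c)}
       {\tfrac{1}{N_r}\sum_{j=1}^{N_r} \mathrm{exp}(j,g,r)},$$

the minimum fold change between the type of interest and every other type.
A value above 1 means the gene is more expressed in $c$ than in *all* other
types.

**Cell-type score.** Specificities are standardized per gene by the median
and interquartile range of the gene's specificity across all $k$ types:

$$\mathrm{score}_{g,c} \;=\;
  \frac{\mathrm{specificity}_{g,c} - \mathrm{median}_g}{\mathrm{IQR}_g}.$$

A positive score marks a type in which the gene is more specific than its
own median type; by construction at most $\lfloor k/2 \rfloor$ types can
score positive for one gene.

**Cell type-specific network.** From a referenced weighted interactome
(e.g. a tissue-specific functional network distributed as a gene1/gene2/
weight edge list), the lowest-ranked fraction of edges by weight is dropped
(default 20%), the network is restricted to the genes actually measured,
and for each cell type the subgraph induced by genes with
$\mathrm{score}_{g,c} > \text{threshold}$ is extracted. The threshold should
be positive so that retained genes exceed their own cross-type median; the
package default is 0 and values of 1 or 2 give strictly nested, sparser
networks — raising the threshold can only remove genes and edges, so stricter
modules are always subsets of looser ones.

**Module significance.** Disease genes are mapped onto each cell
type-specific network; connected components among them (size $\ge 2$ by
default) are candidate modules with observed size $S_{obs}$. Under the null
hypothesis that disease genes do not preferentially interact, $T$ genes
($T$ = number of mapped disease genes) are drawn uniformly without
replacement from the network's vertices and the largest connected component
among them, $S_{rand}$, is recorded; the default is 1000 replicates. The
permutation p-value is the strict tail fraction
$p = \#\{S_{rand} > S_{obs}\}/n_{perm}$, so every p is a multiple of
$1/n_{perm}$ and larger modules can never receive larger p-values under a
shared null. Benjamini–Hochberg FDR control is applied across all candidate
modules of the run, and modules with $q < 0.1$ are reported significant.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `drop_weight_fraction` | 0.2 | fraction of lowest-weight-ranked reference edges removed before subsetting |
| `score_threshold` | 0 | strict cutoff on $\mathrm{score}_{g,c}$; 0, 1, 2 give nested networks |
| `n_perm` | 1000 | permutation replicates per cell-type network |
| `fdr_cutoff` | 0.1 | significance cutoff on BH-adjusted p-values |
| `min_module_size` | 2 | smallest connected component counted as a candidate |
| `fdr_scope` | global | pool candidates across cell types (or per-cell-type) |
| `pseudocount` | FALSE | use $(n+1)/(n_{perm}+1)$ instead of $n/n_{perm}$ |

Design choices where the method description leaves room:

* **"Drop the last 20% by rank"** is implemented as a count-based removal of
  exactly $\lfloor 0.2\,m \rfloor$ edges, with ties broken by the canonical
  edge key. A value-percentile cut would be ambiguous under heavy weight
  ties; a rank cut is deterministic.
* **Duplicate edges** in a raw edge list keep the maximum weight — the
  conservative choice under a filter that removes low-weight edges.
* **Zero-mean ratios** in the specificity: $x/0 = +\infty$ for $x > 0$
  (it can only win the minimum if every reference mean is zero) and $0/0$ is
  skipped; a gene with no defined reference ratio gets `NA`. Genes whose
  median or IQR is infinite, or whose IQR is zero, get `NA` scores — note a
  gene expressed in exactly one type always lands in this case (its
  specificity row is $(\infty, 0, \ldots, 0)$), so exclusive markers are
  excluded from score-thresholded networks rather than passed through with an
  arbitrary value. Externally supplied score tables may still carry infinite
  scores, which pass any finite threshold.
* **Quantiles** use the linear-interpolation (type 7) convention, the
  default of most R installations, so external recomputations line up.
* **Strict inequality** in the p-value follows the tail-count definition
  $n/n_{perm}$; an optional add-one estimator is provided for users worried
  about zero p-values but is off by default for parity with the definition.
* **One null per (cell type, T)**: all candidates of one network share the
  same $T$, so a single null serves them all; nulls for successive cell
  types are drawn from seeds derived from the run seed, making the whole
  report reproducible byte for byte.
* **FDR scope** is not fully pinned down by the method description
  ("correction for multiple testing"); pooling all candidates of a run is
  the default and a per-cell-type option records the ambiguity.
* **Isolated qualifying genes** stay in the cell type-specific vertex set:
  they are legitimate draws for the permutation null, and $T$ counts disease
  genes present in the network, connected or not.

## The synthetic generators

`simulate_expression()` draws background counts from a negative binomial
with common mean (`base_mean` 5, `dispersion` 0.3 — variance
$\mu + \phi\mu^2$, the standard overdispersed model for UMI-like data;
$\phi = 0$ gives the Poisson limit) and multiplies the mean of each planted
marker by `fold` (default 4) in its home type only. Defaults — 1000 genes,
4 types, 60 cells per type, 5% markers per type — are chosen as a desk-scale
caricature of cortical snRNA-seq: enough cells that per-type means are
stable, few enough that sampling noise is visible. In the Poisson limit with
many cells, a marker's home-type specificity converges to `fold` exactly,
which the tests exploit as an oracle.

`simulate_network()` samples background edges uniformly among vertex pairs
(Erdős–Rényi-style; 500 vertices and 1250 edges by default, density ≈ 0.01)
and plants a module by wiring `module_size` disease genes with a random
spanning tree, guaranteeing a connected disease component. Remaining disease
genes scatter uniformly; weights are uniform on (0, 1]. Both generators are
deterministic given `seed`, and `write_fixtures()` emits the exact on-disk
formats the loaders consume.

What the generators deliberately do **not** emulate: dropout, batch and
library-size structure in the expression model, and degree heterogeneity
(scale-free tails, hubs) in the network model — no property the package
tests depends on the degree distribution, but power against hub-centred
modules in real interactomes is not characterized by these fixtures.
Passing tests therefore demonstrate correctness of the computations and
calibration under exchangeability, not performance on any real tissue.

## Statistical behaviour worth knowing

* **The score is scale-free.** Because each gene is standardized by its own
  IQR, the null distribution of the score does not shrink as measurement
  noise shrinks — among fully exchangeable genes, a fixed cutoff such as
  score > 1 is exceeded at an intrinsic rate (~12% of gene–type entries at
  $k = 4$). Thresholding selects *relatively* specific genes; it does not
  control an absolute error rate per gene. The package's calibration
  guarantee lives downstream, in the permutation test.
* **Null calibration.** With no planted module, across 200 generator runs
  at the default conditions, the fraction of runs reporting any significant
  module at FDR < 0.1 is about 0.09 (the acceptance script recomputes this).
* **Power.** A planted 10-gene module among 30 disease genes on the default
  background is detected with ~100% power and complete recovery of the
  planted genes.

## Problem sizes used by the tests

The test-suite and acceptance-script study sizes are the generator defaults
above: formula oracles on 50-gene × 5-type tables, the positivity bound on
10,000-gene tables, exact enumeration of all 220 3-subsets of a 12-vertex
graph against 10,000 permutation replicates, 1000 random p-vectors against a
step-up oracle, 200 null runs and 100 planted runs at 1000 permutations
each. These sizes give stable statistics in well under a minute apiece.

## Limitations

* Upstream quality control (cell filtering, doublets, cell-cycle effects,
  mitochondrial genes) is out of scope; the pipeline consumes an
  already-filtered count matrix.
* Very small cell types make per-type means noisy; the loader warns below
  10 cells per type but does not drop them.
* Candidate enumeration treats each cell type's network independently;
  cross-cell-type module structure is summarized only descriptively
  (Jaccard overlap of gene sets, Spearman correlation of scores).
* Functional (e.g. gene ontology) interpretation of module genes is left to
  external tools; reports export semicolon-joined gene lists and per-module
  edge lists for that purpose.
```{r example, eval = FALSE}
es <- simulate_expression(seed = 1)
ns <- simulate_network(seed = 1, genes = es$expr$genes,
                       planted_genes = es$truth$planted_markers$ct1[1:10])
paths <- write_fixtures(tempfile("fx"), es, ns)
cfg <- run_config(paths$matrix, paths$annotation, paths$network,
                  paths$disease, output_dir = tempfile("out"),
                  genes = paths$genes, cells = paths$cells)
report <- run_pipeline(cfg)
report
```
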