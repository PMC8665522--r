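---
title: "Inferring lncRNA-mRNA ceRNA networks and calling pivotal nodes"
author: "cernaPivot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-mRNA ceRNA networks and calling pivotal nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaPivot)
```

## The scientific problem

Long non-coding RNAs (lncRNAs) can act as competing endogenous RNAs
(ceRNAs): by sequestering shared microRNAs through miRNA response
elements they de-repress the mRNAs those miRNAs would otherwise silence.
The ceRNA hypothesis therefore predicts *positive* co-expression between
a sponge lncRNA and its de-repressed target mRNAs, mediated by shared
miRNAs. Given a small case-control bulk RNA-seq cohort (the package's
reference design is six tumor/normal pairs), the pipeline implemented
here reconstructs such a network and nominates its most central —
"pivotal" — nodes:

1. **Normalization.** Counts are converted to FPKM,
   $\mathrm{FPKM}_{gs} = 10^9 c_{gs} / (N_s L_g)$, with the library size
   $N_s$ taken as the column sum of the count matrix.
2. **DE screening.** Genes with $p < 0.05$ and $|\log_2 FC| > 1$
   (strict inequalities, raw p) are called differentially expressed;
   both thresholds are the field's conventional screen for this design.
3. **Separability evaluation.** PCA, K-means and a Gaussian mixture
   model assess whether the DE mRNA panel distinguishes tumor from
   control samples.
4. **Enrichment.** One-sided hypergeometric over-representation of DE
   mRNAs in gene-set collections, with the expression-trend score
   $z = (\mathrm{up} - \mathrm{down})/\sqrt{\mathrm{up} + \mathrm{down}}$
   over the DE members of each term.
5. **Network construction.** All (DE lncRNA, DE mRNA) pairs are scored
   by Pearson correlation of $\log_2(\mathrm{FPKM}+1)$ across all
   samples; edges with $p < 0.05$ and $r \ge 0.6$ survive, and are then
   cross-referenced against a miRNA-target table: an edge is kept only
   if its endpoints share at least one targeting miRNA. The surviving
   pairs plus their shared miRNAs form the mRNA-lncRNA-miRNA network.
6. **Pivotal nodes.** Degree, betweenness and closeness centrality are
   computed exactly; the tie-inclusive top-$k$ sets of the three metrics
   are intersected, and members of all three are the pivotal nodes.
7. **qPCR validation math.** Relative expression of validation plates
   is quantified by $2^{-\Delta\Delta C_t}$ with group comparison by
   Student's t-test on $\Delta C_t$.

Because cohorts of this kind are rarely deposited, the package ships a
synthetic-data module that generates the whole input bundle with known
ground truth, so every stage — and the pipeline end to end — is testable.

## The synthetic study design

`simConfig()` fixes the study conditions. The defaults describe the
reference design and are used by the test-suite and the acceptance
script:

| parameter | default | meaning |
|---|---|---|
| `n_pairs` | 6 | tumor/normal pairs (12 samples) |
| `n_mrna`, `n_lncrna`, `n_mirna` | 400 / 180 / 120 | feature counts |
| `nb_mean_log_mu`, `nb_mean_log_sd` | 5 / 1.5 | log-normal baseline NB means |
| `nb_dispersion` | 0.08 | NB dispersion $\phi$, $\mathrm{var} = \mu + \phi\mu^2$ |
| `de_fraction` | 0.1 | planted DE fraction |
| `de_log2fc` | 3 | planted effect magnitude |
| `module_size` | 8 | mRNAs co-regulated by the hub lncRNA |
| `module_rho` | 0.8 | target hub-module log-scale correlation |
| `shared_mirna_count` | 3 | miRNAs shared by hub and each module member |
| `geneset_count`, `geneset_size` | 50 / 25 | gene-set collection shape |
| `pair_log2_sd` | 0 | per-pair baseline offset (see below) |

The feature counts are scaled to desk size so that a full pipeline run
takes well under a second; a median baseline mean of $e^5 \approx 148$
counts with $\mathrm{sdlog} = 1.5$ and $\phi = 0.08$ is a typical bulk
RNA-seq shape at moderate depth. Gene lengths are drawn uniformly in
[200, 10000] bp, independent of expression — sufficient to exercise the
FPKM arithmetic, though real length-expression covariation is not
emulated.

**DE planting.** A `de_fraction` of genes receives a tumor-mean shift of
$2^{\pm\texttt{de\_log2fc}}$ with random sign. The hub lncRNA and its
module mRNAs are always part of the planted DE set, downregulated in
tumors (mirroring the common situation where a suppressed sponge drags
its targets down with it), and their baseline mean is anchored one
`sdlog` above the median so the planted structure is comfortably
expressed.

**Co-expression planting.** Hub and module members share a per-sample
latent factor on the log2 scale: each gets
$a z_s + b \varepsilon_{gs}$ with $a^2/(a^2+b^2) = \rho$ and total
biological log2-sd fixed at 1. Their *latent* correlation is exactly
$\rho$; counting (NB) noise dilutes the observed correlation, so
`module_rho` is an upper target that the empirical correlation
approaches as counts and sample numbers grow — monotone control, not
exact matching, which is all the downstream thresholds need.

**Pairing.** The generator supports a per-pair baseline offset shared
by the tumor and normal sample of a pair (`pair_log2_sd`), but defaults
it to 0. The downstream DE test is unpaired (as genome-wide screens on
this design usually are); a nonzero shared offset correlates the two
groups and makes the unpaired test conservative, which would break the
null calibration the test-suite asserts. Users simulating a truly
paired analysis can switch the offset on.

**miRNA tables and gene sets.** A pool of about
$2\times\texttt{shared\_mirna\_count}$ miRNAs targets the hub; each
module member draws `shared_mirna_count` of them, guaranteeing the
shared-miRNA support of every hub-module edge. Background
miRNA-target rows are drawn uniformly over the remaining genes, so
spuriously correlated background pairs only rarely find a shared miRNA
— that contrast is exactly what the cross-reference step exploits. The
first gene set draws at least 80% of its members from planted DE
mRNAs; the rest are uniform background sets.

**What passing tests do and do not show.** The generator emulates the
statistical *shape* of the design — overdispersed counts, log-normal
means, a correlated module, matched interaction tables — but not batch
effects, isoform structure, length-expression dependence, or the
biased, hub-heavy degree distributions of curated miRNA-target
databases. Recovery of the planted hub under these conditions shows the
machinery is correct, not that any particular real dataset would yield
a stable pivotal set.

## Numerical and design choices

**DE test.** Isoform-aware negative-binomial frameworks need read-level
data; at the gene level the package uses Welch's t-test on $\log_2(\mathrm{FPKM}+1)$, which is
deterministic, fast, and — as the test-suite verifies on 2000-gene null
simulations — calibrated (type-I error $0.05 \pm 0.015$, p-values KS
uniform). Zero-variance-in-both-groups genes get $p = 1$ when means are
equal and $p = 0$ flagged `degenerate` otherwise, avoiding NaN
propagation. The fold change uses pseudocount 1 inside
$\log_2((\bar x_T + 1)/(\bar x_C + 1))$ so silent genes stay finite.
Status is called on the raw p-value (the conventional screen for
six-pair cohorts); a BH-adjusted column is always reported and can
drive the call via `useAdjusted = TRUE`.

**Correlation edges.** Computed on all 12 samples pooled — pooling
maximizes $n$ and matches the case-control framing of the network; note
that pooling across a strong group effect inflates correlations among
same-direction DE genes, which is why the miRNA cross-reference (not
correlation alone) carries the specificity. Correlations use
$\log_2(\mathrm{FPKM}+1)$ for variance stabilization. The default sign
mode keeps only positive correlations ($r \ge 0.6$, inclusive), as
ceRNA theory predicts; `signMode = "absolute"` is available. The
cross-reference *requires* a shared miRNA by default
(`minShared = 1`); `annotateOnly = TRUE` merely records shared miRNAs,
for users who read the cross-reference as annotation.

**Centralities.** Betweenness is reported unnormalized, endpoints
excluded, each unordered pair counted once. Closeness uses the
Wasserman-Faust component-scaled form
$\frac{r-1}{n-1}\cdot\frac{r-1}{\sum d}$ (with $r$ reachable nodes),
which stays comparable across components of a disconnected graph;
isolated nodes get 0. Both equal a brute-force all-pairs BFS
path-counting oracle exactly in the tests. Top-$k$ sets are
tie-inclusive (everything at or above the $k$-th largest value),
trading exact cardinality for determinism. `k = 100` is the
study-scale convention; the pipeline default is `k = 10`, suited to the
desk-scale synthetic networks.

**GMM.** Two components with a single diagonal covariance shared across
components, EM to a relative log-likelihood tolerance of $10^{-6}$
(max 500 iterations), initialized from the K-means labels. The shared
diagonal structure is the most stable choice at $n = 12$ samples with
hundreds of features; the per-iteration log-likelihood trace is
returned and asserted non-decreasing. K-means uses `stats::kmeans` with
10 random restarts under a fixed seed. "Confident assignment" defaults
to posterior > 0.8, configurable — the cutoff is a reporting
convention, not a fitted quantity.

**Enrichment.** One-sided hypergeometric (Fisher upper tail), the
convention of the standard over-representation tools. The universe
defaults to all genes tested for DE rather than the genome — the
standard guard against detection bias — and is configurable. Both raw-p
and BH-adjusted significance readings are reported.

**qPCR.** The calibrator is the control-group mean $\Delta C_t$ per
target, which makes the control group's mean $\Delta\Delta C_t$ exactly
0 and its geometric-mean fold exactly 1. Replicates are averaged
arithmetically on the $C_t$ scale; amplification efficiency is fixed at
2. Group comparison is a Student's t-test on per-sample $\Delta C_t$
(folds are log-normal, so testing on the log scale is the standard
choice); it is numerically identical to a t-test on $\log_2$ fold.

## A worked run

```{r pipeline, message = FALSE}
cfg <- pipelineConfig(outdir = tempfile("cerna_"), seed = 1)
report <- runPipeline(cfg)
unlist(report$counts[c("de_mrna", "de_lncrna", "pivotal_nodes")])
report$truth$hub_lncrna_id
report$hub_in_pivotal
```

The run writes every intermediate artifact (counts, FPKM, DE table,
enrichment, edge lists, SIF, centralities, pivotal set, qPCR tables)
plus `report.json`, which records all parameters and the seed; rerunning
from the same config reproduces it byte for byte.

## Known limitations

- The DE test is a gene-level screen; isoform-level effects and
  dispersion shrinkage (as in NB GLM frameworks) are out of scope.
- miRNA expression is never observed — miRNAs enter only through the
  interaction table, as predicted partners.
- Correlation p-values are not multiplicity-adjusted by default
  (mirroring the screen's raw-p convention); a user applying the
  pipeline to larger cohorts should consider the BH option.
- The Venn-style pivotal intersection depends on $k$; tie-inclusive
  sets make it deterministic but its size is data-dependent.
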