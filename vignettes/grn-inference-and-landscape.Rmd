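---
title: "Bagged C3NET inference and the functional landscape of a gene regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bagged C3NET inference and the functional landscape of a gene regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnscape)
```

# The model and the pipeline

grnscape infers an undirected gene regulatory network (GRN) from a
genes-by-samples log2 expression matrix and then characterizes the
inferred network: its topology, the annotation terms whose genes are
unusually densely wired to each other, the shortest-path landscape of a
curated gene set (in the motivating application, census cancer genes in a
breast-tumor expression compendium), and chromosome pairs that carry more
inter-chromosome interactions than random gene placement explains.

## Mutual information from Pearson correlation

Dependence between two genes is scored by mutual information under a
bivariate-Gaussian working model: if $\rho$ is the sample Pearson
correlation of the two expression profiles, then

$$ I(\rho) \;=\; -\tfrac12 \log\!\left(1 - \rho^2\right) \quad \text{(nats).} $$

This "Pearson estimator" of MI is monotone in $|\rho|$, zero at
independence, and is clamped at $\rho^2 \le 1 - 10^{-12}$ so duplicated
profiles map to a large finite ceiling. The Gaussian working model is an
approximation — microarray expression is only roughly Gaussian after
normalization — but because the downstream decision rule only compares MI
values per gene and against a permutation null of the *same* statistic,
mis-specification of the marginal distribution affects power, not
validity.

## Significance: a pooled permutation null

Each observed MI is assigned a right-tail empirical p-value against a
null pool built by destroying dependence while keeping the marginals:
random gene pairs are drawn, one member's sample order is shuffled, and
the MI of the permuted pair is recorded (`mi_null()`). P-values use the
pseudo-count rule $(\#\{\text{null} \ge I\} + 1)/(n_{\text{pool}} + 1)$,
so they are never exactly zero and their resolution is set by the pool
size (default $10^5$; tests use smaller pools). The pool is estimated
once from the original dataset and shared by all bootstrap replicates:
the independence null does not depend on the resample, and pooling keeps
the p-value resolution constant at fixed cost.

## C3NET and the bootstrap ensemble

A single C3NET pass keeps, for every gene $g$, at most the single edge to
its maximum-MI partner $h(g) = \arg\max_{h} I(g,h)$, and only if that
maximal MI is significant after a Bonferroni correction with multiplier
$p$ (one independence test per gene, at level $\alpha = 0.05$ by
default). Argmax ties break toward the lexicographically smaller gene id
so runs are reproducible. The result is deliberately conservative: at
most $p$ edges, each anchored at a gene's strongest partner.

Bagging stabilizes this estimate. `B` bootstrap datasets (default 100)
are drawn by resampling *samples* with replacement — never genes, so
every replicate covers the same gene universe; genes that lose all
variance in a replicate contribute correlation 0 there. One C3NET network
is inferred per replicate, and each candidate edge's occurrence count
$k_e \in \{1,\dots,B\}$ becomes a test statistic: edge $e$ enters the
final network iff the one-sided binomial tail $P(X \ge k_e \mid B, p_0)$
is at most the ensemble level (default 0.05). The null probability $p_0$
is not dictated by the method; the default is the ensemble's mean edge
frequency over the union of observed edges,
$p_0 = \sum_e k_e / (B\,|E_{\text{union}}|)$, i.e. an edge must recur
significantly more often than a typical observed edge. A fixed $p_0$ can
be supplied through `pipeline_config(p0 = )` when an absolute recurrence
standard is wanted; results should always be reported together with the
$p_0$ used.

## Topology

`network_summary()` reports node and edge counts, the giant connected
component (GCC), the edge density $|E|/\binom{n}{2}$, and the mean
unit-weight shortest-path length over GCC vertex pairs (on an unweighted
graph Dijkstra distances reduce to breadth-first search; disconnected
pairs are excluded by restricting to the GCC — with ties on component
size broken toward the component holding the smallest gene id).

The degree distribution is fitted as a power law $P(k) \propto
k^{-\alpha}$. Two estimators are exposed:

* `method = "exact"` (default) maximizes the discrete (zeta) likelihood
  $\ell(\alpha) = -n \log \zeta(\alpha, x_{min}) - \alpha \sum_i \log
  k_i$ numerically, with the standard error from the observed Fisher
  information. This is the estimator of standard power-law practice and
  behaves well down to $x_{min} = 1$; on $10^4$ simulated degrees at
  $\alpha = 3.48$ it recovers the exponent to about $\pm 0.03$.
* `method = "approximate"` is the familiar continuity-corrected closed
  form $\hat\alpha = 1 + n / \sum_i \ln\!\big(k_i/(x_{min}-\tfrac12)\big)$.
  It agrees with the exact MLE once $x_{min}$ is moderately large
  (relative error below ~2% by $x_{min} \approx 10$) but is severely
  biased near $x_{min} = 1$ — for exponent 3.48 it returns values near
  2.25 — so it is provided for comparison, not as the default.

No claim is made that a particular published exponent is recoverable:
exponent estimates depend on the fitting method and the $x_{min}$ choice,
which is why both are explicit here, and an optional Kolmogorov–Smirnov
scan (`scan_xmin = TRUE`) selects $x_{min}$ from the data.

## GPEA: enrichment of edges, not genes

Gene-pair enrichment analysis asks whether an annotation term's genes are
more densely wired than chance. With $p$ network genes there are
$N = p(p-1)/2$ possible pairs, of which $m_{GO} = p_{GO}(p_{GO}-1)/2$
lie within a term of size $p_{GO}$; if the network has $n$ edges of which
$k$ fall within the term, the p-value is the upper hypergeometric tail

$$ p(k) \;=\; \sum_{i=k}^{m_{GO}}
   \frac{\binom{m_{GO}}{i}\binom{N-m_{GO}}{n-i}}{\binom{N}{n}}. $$

Terms are intersected with the network's gene universe before sizing
(genes without expression cannot form edges), filtered to sizes 3–999
inclusive (the conventional "larger than 2 and less than 1000" window),
and Bonferroni-corrected over the tested terms. When a census gene list
is supplied, each term additionally gets a *gene-level* hypergeometric
enrichment p-value for its census-gene count. The hypergeometric model
treats the $n$ edges as an exchangeable draw from the $N$ pairs, ignoring
degree heterogeneity; hub-induced clustering therefore inflates
enrichment of hub-containing terms, which is the standard caveat for this
family of tests.

## Census-gene landscape

For a curated gene set the package extracts the first-degree-neighbor
subnetwork of chosen seed genes, tabulates pairwise shortest-path lengths,
and runs an empirical *closeness test*: the null distribution is the
multiset of shortest-path distances over **all** GCC vertex pairs
(census pairs included — their contribution to the genome-scale null is
negligible and this matches the all-pairs denominator convention), and a
census pair at distance $d$ receives
$p = \#\{\text{null} < d\}/\#\text{null}$ with *strict* inequality,
followed by Benjamini–Hochberg correction. The strict form is the
literal definition and makes $p = 0$ attainable — every directly
connected pair ($d = 1$) is automatically at the extreme of the null.
That is a fidelity choice, not a statistical recommendation: for
FDR-safe screening use `smooth = TRUE`, which switches to
$(\#\{<d\}+1)/(n+1)$ and keeps p-values positive. Census genes outside
the GCC have no finite distances and are reported separately rather than
tested.

Components of directly connected census genes are read off the
census-induced subgraph. The all-census-pair shortest-path union network
collects *every* vertex and edge lying on *any* shortest path between
any census pair — using all shortest paths, not one arbitrary
representative, so that the degree ranking of intermediary genes is well
defined rather than an artifact of path tie-breaking.

## Chromosome cooperation

Edges are mapped to the 24 human chromosome labels (1–22, X, Y) through a
gene catalog, giving a symmetric count table $s_{ij}$ whose diagonal
holds intra-chromosome ("cis") counts; `intra_fraction()` is the
fraction of same-chromosome edges. To test whether a chromosome pair is
more densely connected than random gene placement explains, the
gene-to-chromosome assignment is permuted $E$ times over the network's
genes while the graph is untouched — conserving the total interaction
count, all structural properties, and the uneven chromosome sizes — and
each of the $300 = \binom{24}{2} + 24$ pairs is compared against its own
permutation distribution:

$$ p_{ij} \;=\; \frac{1}{E}\sum_{e=1}^{E} \mathbb{1}\!\left(s^e_{ij} \ge s_{ij}\right), $$

followed by Benjamini–Hochberg correction at $\alpha = 0.05$. Replicates
*tying* the observation are counted into the tail. This tie-inclusive
form is deliberate: with ties excluded, any pair whose observed count
equals its maximum attainable value — two single-gene chromosomes joined
by their only possible edge, an unpopulated chromosome stuck at zero, or
a single-chromosome network whose every permutation reproduces the same
counts — would receive $p = 0$ under the null, and in desk-scale
simulations (200 genes, 24 chromosomes, $E = 2000$) that produced about
one spurious BH discovery per run. With ties counted the same
simulations give essentially zero null discoveries while every planted
cooperating pair in the power simulations is still detected at $p$ near
$0$. A `smooth = TRUE` flag adds the usual $(x+1)/(E+1)$ pseudo-count.
The production default is $E = 10^5$; tests and examples use
$10^3$–$10^4$.

# The synthetic-data generator

Every stage is testable without external data through `simulate_study()`,
whose defaults are the package's reference study conditions:

* **Network**: `p = 100` genes, preferential-attachment ("scale-free")
  topology thinned to mean degree 1.5 — sparse and heavy-tailed like
  inferred GRNs.
* **Expression**: each planted edge carries its own latent factor; a
  gene is the sum of its incident edge factors plus independent noise,
  weighted so a degree-one pair attains correlation `edge_strength`
  (default 0.8) and hubs dilute per-edge correlation by
  $1/\sqrt{\text{degree}}$. *Marginal* correlation therefore tracks
  planted edges — matching what a marginal-MI method like C3NET can in
  principle recover, which is what makes recovery tests meaningful.
  A global multivariate model with a structured precision matrix would
  instead encode edges in *partial* correlations, and no marginal method
  should be expected to invert that. Values sit on a log2-like scale
  (baselines near 8, unit-scale variation), with `n_samples = 300`.
* **Annotations**: 50 terms of 5–20 genes; 5 planted terms are grown as
  connected neighborhoods of the truth network (guaranteeing excess
  within-term edges), the rest are uniform gene sets — a known positive
  and a calibrated null for GPEA.
* **Catalog and census**: genes are assigned to 24 chromosomes with
  linearly decreasing weights (uneven sizes, as in a real genome, and
  never an empty chromosome when enough genes exist); a census list of
  20 genes is drawn with 5-fold bias toward the first planted module.
  Chromosome cooperation is planted by rewiring a fraction of edges onto
  a chosen chromosome pair (`plant_cooperation()`), giving the
  permutation test a known positive.

What the generator does **not** emulate: probe-level Affymetrix
structure beyond a trivial many-probes-to-one-gene fan-out, batch and
tumor-heterogeneity effects, non-Gaussian expression marginals,
annotation hierarchies (no ancestor roll-up), and linkage between
chromosomal position and co-expression. Passing recovery tests therefore
demonstrates that the pipeline's statistics behave as designed under
their own assumptions — not that real tumor-compendium networks are
recovered at any particular accuracy.

Under the reference conditions (with `B = 20` bootstraps and a
$2\times10^4$ null pool) the final network recovers the planted edges
with F1 around 0.8 at precision near 1.0; the acceptance script
(`scripts/acceptance.R`) recomputes this at every run.

# Numerical and design notes

* **Determinism.** Every stochastic stage takes an explicit seed
  (`pipeline_config(rng_seed = )` end to end); a fixed configuration is
  bit-reproducible, and the caller's RNG stream is left untouched.
* **Clamps and boundaries.** $1-\rho^2$ is floored at $10^{-12}$ *after*
  the subtraction so the MI ceiling is exact; empirical MI p-values carry
  a $+1$ pseudo-count; `gpea_pvalue(k = 0)` is exactly 1; a zero-edge
  chromosome pair can never be called enriched.
* **Tie-breaks.** C3NET argmax ties go to the lexicographically smaller
  partner; GCC size ties go to the component holding the smallest gene
  id; result tables order ties by identifier.
* **Quantile normalization** delegates to the standard limma
  implementation (`ties = TRUE`): every column is mapped onto the row
  means of the column-sorted matrix, ties receiving the reference
  interpolated at their average rank. The map is idempotent on tie-free
  data; with ties whose blocks differ across columns a second pass can
  shift values marginally, which is inherent to averaged-rank tie
  handling. Inputs are expected as already log2-scaled probe intensities;
  platform-specific background correction is out of scope, and probes
  are collapsed to genes by the per-sample median *after* normalization.
* **Degenerate inputs** fail loudly and early: zero-variance genes
  (outside bootstrap replicates), missing values, unknown chromosome
  labels, empty probe maps, constant degree tails, seed genes absent
  from the network — each raises an error naming the offender.
* **Problem sizes.** Tests and the acceptance script run at
  $p \le 200$ genes, $E \le 2000$ permutations, $B \le 20$ bootstraps
  and $10^4$-draw estimator simulations — sizes chosen so the whole
  suite re-runs in a couple of minutes while every statistic still
  operates in the regime its asymptotics assume. Production-scale
  defaults ($B = 100$, $E = 10^5$, $10^5$-value null pools) remain the
  configuration defaults.

# Known limitations

The Gaussian-MI score detects monotone (effectively linear, after
rank-preserving normalization) dependence only. C3NET's at-most-one-edge
rule bounds recall for hub genes by construction; bagging recovers some
of it through neighbors' choices but the final network remains
conservative. The binomial aggregation treats member networks as
independent draws, which bootstrap replicates are not; $p_0$'s default is
data-driven and should be reported alongside results. GPEA inherits the
exchangeable-edges assumption noted above. The closeness test's strict
inequality is anti-conservative at the shortest distances by design
(fidelity to its definition); use the smoothed option when controlling
FDR matters more than replicating the literal definition.
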