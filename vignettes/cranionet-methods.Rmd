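---
title: "Skull networks, connectivity modules, and heterochrony: the methods behind cranionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skull networks, connectivity modules, and heterochrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranionet)
```

## The model

cranionet treats a skull as an undirected, unweighted graph: nodes are
bones (a fused pair of bones is one node), edges are physical contacts —
sutures or articulations. This abstraction deliberately discards
geometry: two skulls with identical contact patterns are identical
networks regardless of bone shapes or sizes. The payoff is that
integration and modularity become graph quantities that can be compared
across taxa and ontogenetic stages, and pushed through ordinary
multivariate and phylogenetic comparative statistics.

Input matrices are square 0/1 CSVs with bone labels on rows and columns.
Side information is carried in the labels themselves: `_L`, `_R`, `_M`
suffixes (case-insensitive) mark left, right, and midline elements, and
an unsuffixed label counts as midline. The supplementary spreadsheets of
published AnNA studies do not follow a single labelling scheme, so users
transcribing such matrices should map their bone names onto this
convention; any consistent naming works since only the suffix is parsed.
Validation is strict — non-square, asymmetric, non-binary or
duplicate-label input fails with the offending cell named — because a
silently mis-transcribed matrix is the main practical failure mode of
this kind of analysis. Disconnected graphs are rejected by default
(mean path length is undefined on them) with an explicit override for
deliberately split graphs.

## The ten descriptors

Six primary parameters: node count $N$, edge count $K$, density
$D = 2K/(N(N-1))$, mean clustering coefficient $C$, mean shortest path
length $L$, and degree heterogeneity $H$. Two conventions deserve
comment:

* $H$ is the standard deviation of node degrees divided by the mean
  degree. The AnNA literature sometimes calls this the "variance of
  connectivity", but it is a normalized dispersion, not a variance; the
  sample ($n-1$) standard deviation is the default, switchable to the
  population form via `heterogeneity = "population"`.
* Nodes of degree < 2 have no neighbour pairs; their local clustering is
  defined as 0 and included in the mean, which keeps $C$ defined on
  tree-like graphs. `clustering_isolates = "exclude"` drops them
  instead.

Four module parameters come from the clustering stage below: the
S-module count, the Q-module count, $Q_{max}$, and the parcellation
$P = 1 - \sum_s (N_s/N)^2$.

## Connectivity modules

Similarity between bones is the generalized topological overlap measure
(GTOM): bones sharing many neighbours likely belong to one module. For
order $m = 1$,
$t_{ij} = (|N(i) \cap N(j)| + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$;
higher orders substitute $m$-step neighbourhoods. The order defaults to
1 and is configurable — published analyses rarely state the order they
used, and order 1 is the measure's original form.

Bones are clustered by Ward.D2 on the dissimilarity $1 - t$, delegated
to `stats::hclust`, the same implementation the comparative literature
runs. The dendrogram is cut at every possible number of clusters
$k = 1..N$ and each cut scored with Newman's modularity
$Q = \sum_s [\, l_s/K - (d_s/2K)^2 \,]$; the partition maximizing $Q$ is
returned, with ties broken toward fewer modules (the conservative,
more-integrated reading).

S-modules ask a complementary question — is a candidate cluster's
internal cohesion statistically significant? For every dendrogram
cluster with at least 3 members, each member's internal contact count is
compared with its external count by a one-sided Wilcoxon rank-sum test
(internal > external), exact for small untied samples and
normal-approximated with tie correction otherwise. Two counting rules
matter:

* Clusters larger than half the network are not tested. With raw
  counts, any majority-size cluster wins the comparison by size alone
  (in a complete graph, a 5-of-8 cluster has internal counts 4 vs
  external 3 for every member), which would manufacture significance
  out of nothing but imbalance. A connectivity module spanning more
  than half the skull is also not a meaningful "module" of it.
* Significant clusters nested inside larger significant clusters are
  not double-counted: the canonical S-module count is the number of
  maximal significant clusters, with the total (nested) count reported
  alongside.

Left–right asymmetry is scored two ways. `asymmetry_score` counts the
bone pairs whose left and right copies occupy different modules — the
direct reading of "paired bones assigned to different modules". But on a
perfectly mirror-symmetric skull whose sides are linked only through
midline bones, deleting those midline bones (the unpaired-deletion
experiment, `drop_unpaired`) disconnects the sides, and antimeres then
*must* occupy different — mirrored — modules. The meaningful question in
that experiment is whether the module distribution is identical on the
two sides, i.e. whether the partition maps onto itself under the L↔R
relabeling; `partition_mirror_consistent` tests exactly that, and it is
the property the test suite asserts after the deletion experiment.

## Morphospace

Nine parameters enter the ordination ($N, K, D, C, L, H$, S-modules,
Q-modules, $Q_{max}$; parcellation is kept for the group tests but not
ordinated). They are natural-log transformed; $C$ and $Q_{max}$ can be
exactly 0 on degenerate graphs, in which case an offset of
$\varepsilon = 10^{-6}$ is added with a warning. Distances are Gower's:
range-normalized Manhattan, $d_{ij} = \frac1p \sum_v |x_{iv} -
x_{jv}|/\mathrm{range}_v$, with zero-range columns contributing zero
(warned) and the divisor kept at the full column count.

PCoA is classical scaling: double-center $-\tfrac12 J D^2 J$,
eigendecompose, scale eigenvectors by the square roots of the positive
eigenvalues. Gower distances need not be Euclidean, so negative
eigenvalues can occur; they are dropped and their summed magnitude
reported rather than corrected (Lingoes/Cailliez corrections change
every coordinate and are unnecessary when, as here, the negative part is
small relative to the positive spectrum — the result object makes that
check explicit). Axis signs are arbitrary in principle; each axis is
oriented so its largest-magnitude score is positive, making outputs
platform-stable.

## Comparative statistics

The Mann–Whitney test reports the standardized
$z = (U - n_1 n_2/2)/\sigma_U$ with tie-corrected $\sigma_U$ and *no*
continuity correction — the convention of the desktop statistics
packages classically used for this table family (a `continuity` toggle
exists). $|z|$ is the reported statistic, the sign kept alongside, since
published tables are ambiguous about signedness. The Kolmogorov–Smirnov
test uses the asymptotic two-sample p-value.

Relative skull size has two referents by design: a juvenile's size is
the percentage of its own species' adult skull-box volume
(length × width × height), while an adult's is the percentage of the
largest sampled adult's volume. OLS slopes of each parameter on these
covariates, and the ANCOVA F-test of the juvenile-vs-adult slope
contrast (interaction term; $df_1 = 1$, $df_2 = n_1 + n_2 - 4$),
separate ontogenetic from allometric signal.

PERMANOVA uses the distance-based pseudo-F (delegated to
`vegan::adonis2`), raw-label permutations, and
$p = (\#\{F^{perm} \ge F\} + 1)/(n_{perm} + 1)$ with 10,000 permutations
by default; pairwise two-group runs are Bonferroni-corrected by
multiplying p by the number of comparisons, capped at 1.

## The phylogenetic layer

`consensus_edges` averages branch lengths across a set of same-topology
trees (e.g. a relaxed-clock posterior sample), matching edges by the tip
set they subtend and failing loudly on any topology mismatch.
`split_ontogenetic_tips` replaces a species tip by a juvenile/adult
cherry whose pendant length is one year for birds and ten for
slower-growing archosaurs; cherries end at the original tip depth, so
ultrametric trees stay ultrametric.

pFDA whitens the predictors by $V_\lambda^{-1/2}$, where $V_\lambda$ is
the phylogenetic covariance with off-diagonals scaled by Pagel's
$\lambda$, then fits an ordinary LDA on the whitened training tips. The
$\lambda$ grid is $0, 0.01, \dots, 1$; each candidate is scored by
leave-one-out training misclassification and ties go to the smallest
$\lambda$ (the weakest phylogenetic correction). The original pFDA
literature optimizes a discrimination criterion but does not pin down
which; leave-one-out error is the choice here, which is why fitted
$\lambda$ values are comparable between runs of this package but not
directly against other implementations. The inverse square root is an
eigendecomposition with a $10^{-10}$ eigenvalue floor. At $\lambda = 0$
on a star tree the whitening is a scalar rescale, so results reduce
exactly to ordinary LDA — a property the test suite checks.

Ancestral states under Brownian motion are exact GLS:
$\hat\mu = (1'V^{-1}x)/(1'V^{-1}1)$ at the root and
$\hat a_k = \hat\mu + c_k'V^{-1}(x - \hat\mu 1)$ at node $k$, with
$c_k$ the node–tip shared path lengths. This closed form is the
implementation; `ape::ace`'s ML reconstruction serves as an independent
cross-check in the tests.

The heterochrony comparison reconstructs a trait twice — once from adult
tip values, once from juvenile values standardized to "hypothetical
hatchlings" (residuals from the trait-on-size OLS, shifted to the fitted
value at the youngest individual's relative size) — and compares the
standard deviations of the two sets of ancestral values: the smaller SD
marks the smoother, more parsimonious history. The companion
"log-transformed product of ancestral values" proxy is ill-defined in
sign for negative trait values (principal coordinates routinely are
negative); it is computed as $\sum \log|a_k|$ and flagged invalid
whenever any ancestral value is non-positive, rather than guessing an
intent.

## The synthetic generator

`make_skull` draws a bilaterally symmetric skull: left-side contacts are
drawn from a planted module plan ($p_{in} = 0.9$ within, $p_{out} =
0.05$ between, by default), mirrored exactly onto the right side;
midline bones are wired to both sides with one shared draw per side
pair; and each bone pair's antimeres contact each other across the
midline with probability $p_{cross} = 0.3$ (as premaxillae, frontals or
dentaries do in real skulls — without such contacts the unpaired-bone
deletion experiment would always disconnect the sides). Connectivity is
enforced by adding bridging edges in mirror-symmetric pairs. Default
sizes (12–14 pairs plus 4–5 midline bones, i.e. ~28–33 bones juvenile,
falling to ~18–25 after fusion) bracket the bone-count ranges of real
archosaur skulls.

`simulate_ontogeny` applies a random fusion schedule cumulatively;
contracting a contact can never disconnect the graph, so any schedule is
safe. `simulate_study` builds a whole study — per species one hatchling
skull, one sampled juvenile stage (uniform on 0.15–0.7 of ontogeny,
skull-box volume scaling linearly with stage so the stage fraction *is*
the relative volume), one adult, a per-species fusion count jittered
within ±2 of 10 so adult bone counts vary, and a Yule species tree
rescaled so the shortest terminal branch comfortably exceeds the
juvenile/adult pendant length.

What the generator emulates: bilateral symmetry with midline elements,
planted connectivity modules, monotone ontogenetic bone loss correlated
with relative size, and Brownian trait evolution on a clock tree with
juvenile/adult tip pairs. What it does not: real bone-name ontologies,
anatomically constrained contact geometry (beyond the antimere rule),
unequal module sizes, fossil sampling gaps, or measurement error in
skull-box dimensions. Passing tests therefore demonstrate that the
algorithms recover planted structure under realistic scales and noise —
not that any particular empirical dataset will behave as cleanly.

## Numerical and scale choices

Tests and the acceptance script run at deliberately modest sizes —
graphs of ≤ 15 nodes against brute-force oracles (200 replicates),
exhaustive dendrogram-cut checks at ≤ 10 nodes, 500-seed root-recovery
and 60-seed heterochrony simulations, a 15-species end-to-end study —
chosen so the full suite completes in well under a minute-scale budget
while still exercising every code path at the scale of real skull data
(tens of bones, tens of specimens). Degenerate inputs are handled
explicitly: all-tied samples give $z = 0, p = 1$; zero-range Gower
columns contribute zero with a warning; isolated nodes make GTOM
degenerate and error; constant covariates error in OLS and in the
juvenile substitution.

## Known limitations

* Only binary, undirected contact networks; no weighted sutures.
* Single-factor PERMANOVA; no covariate adjustment or multi-factor
  designs.
* Overlapping-community methods (e.g. OSLOM) are out of scope; the
  dichotomous cluster analysis cannot express a bone belonging to two
  modules, which is one candidate explanation for observed left–right
  module asymmetries.
* Brownian motion with a single rate is the only ASR model; no OU or
  rate-shift models.
* Fitted pFDA $\lambda$ values depend on the leave-one-out criterion
  above and should be compared only within this implementation.
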