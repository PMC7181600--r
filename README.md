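# cranionet

Anatomical network analysis (AnNA) of skull bone fusion, for comparative
morphologists studying how ontogeny reshapes skull architecture — for
example how the intense postnatal suture closure of crown birds turns a
reptile-grade skull of many loosely connected bones into a highly
integrated adult skull, and whether that change is a heterochrony
(peramorphosis) relative to the ancestral condition.

A skull is modelled as an undirected, unweighted graph: nodes are bones
(fused bones count as one unit), edges are sutures or articulations.
From one specimen's symmetric 0/1 adjacency matrix the package computes
the standard AnNA descriptor set

- *N*, *K* — numbers of bones and bone contacts,
- *D* = 2K / (N(N−1)) — density of connections,
- *C* — mean clustering coefficient,
- *L* — mean shortest path length,
- *H* — degree heterogeneity (SD of degrees / mean degree),

and the connectivity-module descriptors obtained by Ward.D2 clustering of
the generalized topological overlap matrix (GTOM): the number of
*Q*-modules at the dendrogram cut maximizing Newman's modularity

  Q = Σ_s [ l_s/K − (d_s/2K)² ],

the maximized *Q*max, the number of significant *S*-modules (one-sided
Wilcoxon rank-sum tests of each candidate cluster's internal vs external
contact counts), and the parcellation *P* = 1 − Σ_s (N_s/N)².

Around the per-specimen descriptors sit the comparative layers of a full
study: a Gower-distance PCoA morphospace over the log-transformed
parameters; Mann–Whitney (tie-corrected z, no continuity correction) and
Kolmogorov–Smirnov group tests; OLS regressions of each parameter on
relative skull size with ANCOVA slope comparisons; PERMANOVA;
phylogenetic flexible discriminant analysis (LDA after whitening by a
Pagel's-λ-scaled phylogenetic covariance, λ chosen by leave-one-out
error); and Brownian-motion ancestral state reconstruction (exact GLS)
with a juvenile-substitution workflow that standardizes juveniles to
"hypothetical hatchlings" via size-regression residuals and compares the
smoothness of the two reconstructed histories through the standard
deviation of ancestral values.

A synthetic-data module generates mirror-symmetric skulls with planted
modules, ontogenetic fusion schedules, and clock trees with Brownian
traits, so every stage of the pipeline is testable without any specimen
data.

## Worked example

```r
library(cranionet)

# a synthetic hatchling skull: 12 bone pairs, 4 midline bones, 3 modules
tpl <- skull_template(n_pairs = 12, n_midline = 4, n_modules = 3, seed = 1)
juv <- make_skull(tpl)
juv
#> bone_network: 28 bones, 75 contacts
#>   sides: left=12, midline=4, right=12

# fuse 8 sutures over ontogeny and compare the ten descriptors
sched <- make_fusion_schedule(juv, n_fusions = 8, seed = 2)
adult <- simulate_ontogeny(juv, sched, stages = 1)[[1]]$network
rbind(juvenile = skull_params(juv), adult = skull_params(adult))
#>           N  K         D         C        L         H S Q      Qmax         P
#> juvenile 28 75 0.1984127 0.7753401 2.671958 0.2927941 3 3 0.6090667 0.6658163
#> adult    20 44 0.2315789 0.7232937 2.468421 0.3566921 3 3 0.5444215 0.6550000
```

Fusion removes 8 bones and 31 contacts; density rises (integration), and
modularity Qmax falls — the ontogenetic trend the method is built to
measure. The module stage gives the partition itself:

```r
mod <- skull_modules(juv)
mod
#> module_partition: 3 Q-modules, Qmax = 0.6091
mod$asymmetry        # paired bones whose L/R copies split across modules
#> [1] 0
```

A whole study (8 species, each a juvenile/adult pair) through the
morphospace and group statistics:

```r
study <- simulate_study(n_species = 8, seed = 3)
tab   <- build_param_table(study$nets)
ord   <- morphospace(tab)       # log -> Gower -> PCoA
ord
#> pcoa_result: 16 specimens, 9 axes
#>   variance: PCo1=73%, PCo2=11.3%, PCo3=8.7%

stage <- ifelse(grepl("_juv$", rownames(tab)), "juvenile", "adult")
mann_whitney(tab$N[stage == "juvenile"], tab$N[stage == "adult"])
#> mwu_z : statistic = 3.432  p = 0.000599  (n = 8, 8)
permanova(dist(ord$coordinates), stage, nperm = 999, seed = 1)
#> permanova_F : statistic = 12.62  p = 0.001  (n = 8, 8)
```

Juvenile and adult skull networks occupy significantly different regions
of the morphospace (PERMANOVA pseudo-F = 12.6), and bone counts differ
strongly (|z| = 3.4) — the synthetic study reproduces the structure of a
real ontogenetic dataset. `run_pipeline()` performs all of the above plus
the pFDA and ancestral-state stages in one call and writes
CSV/JSON/Newick outputs with a digest manifest.

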