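# costructure

Co-structure analysis of two-layer bipartite ecological networks.

Many species interact through more than one network at once. The motivating
case is a Lepidoptera–plant assemblage in which the *same* species pool forms
two bipartite layers: caterpillars feeding on host plants (herbivory, an
antagonism) and adults nectaring on flowers (visitation, a potential
mutualism). Understanding whether the two layers are organised the same way —
whether generalist herbivores are also generalist visitors, and whether the
module a species belongs to in one layer predicts its module in the other —
is a prerequisite for predicting how species loss propagates across linked
networks. `costructure` implements that comparison as two statistical steps
for ecologists working with any pair of binary bipartite networks sharing
both species sets (larva/adult stages, pollinators/nectar robbers, temporal
snapshots, ...).

## The method

Each layer is a binary incidence matrix over the shared row guild (m species)
and column guild (p species); species recorded in only one layer are kept in
both with zero degree. Two questions are asked:

1. **Degree co-distribution.** For one guild, tabulate the contingency table
   `K[u, w]` = number of species with degree `u` in layer 1 and `w` in layer
   2 (raw degree values, zero included). Under independence the expected cell
   count is `n · p_u · p_w` from the marginal degree frequencies; the Pearson
   statistic `Σ (K − E)² / E` on `(|u|−1)(|w|−1)` degrees of freedom tests
   association, and the per-cell Pearson residuals `(K − E)/√E` mark degree
   combinations that are over- (r ≥ 2, strongly ≥ 4) or under-represented —
   the shading tiers of a residual-based mosaic plot (≈ α = 0.05 and
   α = 0.0001). A seeded fixed-margin Monte-Carlo p-value is available for
   these typically sparse tables.

2. **Module-composition similarity.** Each layer's symmetric (m+p)-node
   adjacency is partitioned by leading-eigenvector modularity maximization
   (recursive spectral bisection of the generalized modularity matrix, with
   Kernighan–Lin refinement; zero-degree species become singleton modules).
   The agreement of the two classifications is the normalized mutual
   information

   I(H,V) = −2 Σᵢⱼ N_ij log(N_ij N / (N_i. N_.j)) /
            [Σᵢ N_i. log(N_i./N) + Σⱼ N_.j log(N_.j/N)]

   where `N` is the confusion matrix of shared species between modules
   (I = 1: identical classifications; I = 0: independent). Because degree
   sequences alone constrain attainable similarity, the observed I is
   compared against a configuration-model null: both layers are repeatedly
   randomized by the curveball algorithm (exact degree preservation),
   modules re-detected, and I recomputed, yielding null quantiles and
   add-one empirical p-values (`p_ge`: is similarity higher than random?).

## Worked example

```r
library(costructure)
pp <- planted_pair(n_rows = 30, n_cols = 30, k_modules = 3, seed = 42)

layer_summary(pp$pair$layer1)
#> layer 'layer1': 30 x 30, L = 137, C = 0.152222, zero-degree rows = 0, cols = 0

independence_test(co_table(pp$pair, "rows"),
                  p_method = "simulate", n_sim = 999, seed = 42)
#> degree co-distribution independence test (rows guild)
#>   chi2 = 29.06, df = 36, p = 0.828 (simulate)
#>   residual range: [-1.22, 2.37]

nmi_null_test(pp$pair, n_replicates = 199, seed = 42)
#> module-composition similarity vs degree-preserving null
#>   observed I = 0.745  (null over 199 replicates)
#>   null range [0.0462, 0.245], quartiles [0.11, 0.164], median 0.141
#>   p_ge = 0.005 (higher than random?), p_le = 1, p_two = 0.01
```

Read: species degrees in the two layers are not associated beyond chance
(χ² p = 0.83), but the planted module congruence is clearly visible — the
observed module similarity I = 0.745 sits far above anything the
degree-preserving null produces (at most 0.245 in 199 replicates), so
p_ge = 0.005: these two layers share module composition beyond what their
degree sequences impose.

`run_full_analysis()` (or `costructure run`) chains all of the above from an
edge list or two incidence files and writes `report.json`, degree and mosaic
tables, per-layer module assignments, the module co-structure graph
(GraphML), and the null distribution, all reproducible from one seed.

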