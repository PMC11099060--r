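# onsetnet

Multiplex network analysis of disease onset gene groups.

## The problem

Muscular dystrophies (MDs) differ in where muscle weakness first appears:
distal muscles (hands and feet) or proximal muscles (limb-to-trunk). Some
genes cause only distal-onset disease when mutated, some only
proximal-onset, some both. `onsetnet` asks whether these three gene groups —
distal-only genes (DoGs), proximal-only genes (PoGs) and common genes
(CoGs) — encode functionally distinct protein modules, and provides the full
toolchain for that comparison:

* **Curation** of candidate gene lists by evidence level (Moderate / Strong /
  Definitive assertions, plus a literature whitelist) and assignment to the
  three disjoint onset groups (`dogs = distal \ proximal`,
  `pogs = proximal \ distal`, `cogs = distal ∩ proximal`).
* **Multiplex networks**: per-layer edge lists (e.g. protein–protein
  interactions, complexes, pathways) over a shared node universe; largest
  connected component on the aggregated graph; induced subnetworks;
  closeness centrality; GraphML/SIF export for Cytoscape.
* **Group distances**: the average shortest distance between gene sets,
  `mean{ d(a,b) : a ∈ A, b ∈ B, a ≠ b }`, with an empirical bootstrap null —
  the fraction of `n_random` uniform random gene sets of size `|B|` lying
  strictly closer to `A` than `B` does.
* **Multiplex random walk with restart (RWR)** on (node, layer) states:
  `p = r·s + (1−r)·T·p` with restart `r = 0.7`, inter-layer relocation with
  probability 0.5, power iteration to L1 tolerance 1e-10 (or an exact dense
  solve). Top-k non-seed genes form a group's network neighborhood.
* **Overlap significance** between two groups' neighborhoods by joint label
  randomization: `p_low` = fraction of permutations with overlap ≤ the real
  one.
* **Over-representation analysis**: upper-tail hypergeometric test against
  GMT annotation collections with Benjamini–Hochberg correction.
* **A planted-partition synthetic generator** (two communities + a bridging
  common-like group + matching GMT) so the whole pipeline runs and is tested
  without any external downloads.

User-facing functions take data frames and return tibbles; fitted result
objects have `tidy()` / `glance()` methods and `autoplot()` figures.

## Worked example

```r
library(onsetnet)

# The packaged curated MD gene lists reconstruct the 40-gene partition
glance(md_onset_genes("groups"))
#>   n_genes n_dogs n_pogs n_cogs
#> 1      40     11     22      7

# A synthetic bundle: 3-layer planted-partition multiplex + groups + GMT
b   <- generate_bundle(synthetic_config(rng_seed = 42))
lcc <- largest_connected_component(b$multiplex)
lcc
#> Multiplex network: 300 nodes, 3 layer(s)
#>   layer1         1194 edges
#>   layer2         1163 edges
#>   layer3         1212 edges

net <- aggregate_multiplex(lcc)
tab <- distance_table(net, b$groups, null_config(n_random = 500, rng_seed = 42))
distance_matrix(tab)
#>   group_a       distal_like proximal_like bridge random
#> 1 distal_like          1.73          1.98   1.30   2.12
#> 2 proximal_like        1.98          1.65   1.39   2.08
#> 3 bridge               1.30          1.39   1.38   1.73
#> 4 random              NA            NA     NA      2.35
```

Each planted group sits closer together (diagonal) than to random gene sets
(`random` column), and the bridge group — the common-gene analogue — is the
closest to both communities, exactly the centrality pattern the analysis is
designed to detect.

```r
sv <- rwr_multiplex(lcc, b$groups$distal_like)   # restart = 0.7
extract_neighborhood(sv, k = 5, seed_group = "distal_like")
#> RWR neighborhood of distal_like - top 5 genes
#>   gene    score  rank
#> 1 G0242 0.00625     1
#> 2 G0300 0.00559     2
#> 3 G0185 0.00531     3
#> 4 G0266 0.00481     4
#> 5 G0169 0.00429     5

tr <- truth_report(b); tr <- tr[tr$gene %in% lcc$nodes, ]
label_randomization_test(lcc, tr[, c("gene", "group")],
                         "distal_like", "proximal_like",
                         k = 50, n_rand = 200, rng_seed = 42)
#> Neighborhood overlap test (distal_like vs proximal_like, k = 50)
#>   real overlap: 7
#>   p_low (null <= real): 0  [200 randomizations]
```

The two community-seeded neighborhoods share only the 7 bridge genes, far
fewer than the ~20 genes shared under label permutation — the separation is
significant (`p_low = 0`). Finally, enrichment recovers the planted
annotations; the bridge group is significant for *both* community terms:

```r
head(tidy(enrich(b$groups$bridge, b$gmt)), 3)
#>   term_id         overlap p_adjusted significant
#> 1 sarcolemma_like       7    0.00220 TRUE
#> 2 sarcomere_like        7    0.00220 TRUE
#> 3 noise_term_4          2    0.465   FALSE
```

`run_pipeline(pipeline_config(...))` chains all stages on files (edge lists,
gene lists, GMT) and writes every table, network export and a reproducibility
manifest to an output directory; reruns with the same seed are
byte-identical.

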