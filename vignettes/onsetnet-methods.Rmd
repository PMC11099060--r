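---
title: "Methods: multiplex network analysis of onset gene groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex network analysis of onset gene groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetnet)
```

## The scientific question

Muscular dystrophies differ in where muscle weakness first appears: in the
distal muscles (hands and feet) or in the proximal muscles that connect the
limbs to the trunk. Some genes cause only distal-onset disease when mutated,
some only proximal-onset disease, and some both. `onsetnet` implements a
system-level comparison of these three gene groups — distal-only (DoGs),
proximal-only (PoGs) and common (CoGs) — asking whether the groups encode
functionally distinct protein modules. The package combines three strategies:

1. **Group-wise network distances.** If two groups of proteins take part in
   distinct processes, their genes should occupy different network
   neighborhoods, and each cohesive group should sit closer together than a
   random set of genes.
2. **Random walk with restart (RWR) neighborhoods.** The top-scoring genes of
   a walk restarting at a seed group summarise that group's network vicinity;
   non-overlapping neighborhoods for two groups indicate functional
   separation.
3. **Over-representation analysis.** A hypergeometric test against annotation
   collections (GMT format) characterises each group's cellular localizations
   and processes directly.

## Gene curation

Candidate genes from onset-specific diagnostic lists are retained only when a
curated gene–disease assertion of level *Moderate*, *Strong* or *Definitive*
exists for the same onset, or when the gene is on an explicit literature
whitelist. Any single qualifying record suffices; conflicting assertions for
the same gene are not reconciled, because evidence sources do not provide a
defined precedence order — this is a deliberate, documented choice rather
than a claim about curation practice. Symbols are canonicalized to uppercase
with no alias resolution (the input lists already carry final symbols).

Group assignment is pure set algebra: `dogs = distal \ proximal`,
`pogs = proximal \ distal`, `cogs = distal ∩ proximal`. The packaged curated
lists yield 40 genes split 11/22/7:

```{r}
glance(md_onset_genes("groups"))
```

## The multiplex network

A multiplex network is a set of layers (here typically protein–protein
interactions, molecular complexes and pathway co-membership) over one shared
node universe; a gene may be isolated within a layer. Layers are simple,
undirected and unweighted; weights in input files are ignored with a warning.

Two conventions matter downstream and are fixed package-wide:

* **Connectivity is evaluated on the aggregated (union-of-layers) graph.** A
  multiplex walker can switch layers at any node, so node sets that any layer
  connects belong together. The largest connected component (LCC) of the
  aggregated graph is extracted once and used in all analyses; equal-size
  ties are broken toward the component containing the lexicographically
  smallest symbol, so the operation is deterministic.
* **The node universe is frozen after LCC extraction.** Downstream modules
  validate membership against it and report (never silently drop) genes that
  are absent, because genes without any interaction cannot take part in
  network analyses.

Closeness centrality follows the per-component convention used by common
network-visualization tools: the reciprocal of a node's mean shortest-path
distance to the other members of its component, and 0 for isolated nodes.

## Average shortest distances and their null

The distance between gene sets $A$ and $B$ is the mean of shortest-path
lengths $d(a,b)$ over all pairs $a \in A$, $b \in B$, $a \neq b$; the
intra-group distance is the mean over unordered distinct pairs. This is the
plain all-pairs average, not the minimum-based separation statistic of
network medicine: the analysis asks how close two whole groups are, and the
replication of group-distance tables depends on this choice.

Significance is assessed with a bootstrap null: to judge the distance from
$A$ to $B$, draw `n_random` (default 2000) node sets of size $|B|$ uniformly
from the LCC nodes, and report the fraction whose distance to $A$ is
*strictly smaller* than the observed one. The assessment is directional — the
second argument is the randomized side — even though the distance itself is
symmetric. Three conventions are config-exposed because the method leaves
them open: the strict-versus-non-strict comparison, whether random sets may
intersect $A$ (they may, by default; no exclusion and no degree matching is
applied), and the random-set size (exactly $|B|$). A random draw identical to
a singleton reference set has no valid pair and is redrawn (in `empirical_p`)
or skipped (in `random_baseline`); consequently, on the 10-node path the
expected baseline distance from an end node to a uniformly drawn *other* node
is `mean(1:9) = 5`.

Calibration: with both groups drawn uniformly at random the empirical p-value
is approximately Uniform[0, 1]; the test suite checks this with a
Kolmogorov–Smirnov test over 200 repetitions on a sparse random graph.

## Multiplex random walk with restart

The walker lives on (node, layer) states. At each step it restarts from the
seed distribution with probability $r$ (default 0.7, a standard choice for
disease-gene prioritization); otherwise it either relocates to another
layer's copy of its current node (probability `interlayer_jump`, default 0.5,
uniform over the other layers) or walks to a uniformly chosen within-layer
neighbour. Nodes isolated in a layer can only relocate; nodes isolated in
every layer (impossible inside an LCC) send the walker back to the seeds.
The restart vector is uniform over seed nodes × layers. The stationary
system

$$p = r\,s + (1-r)\,T\,p$$

is solved by power iteration to an L1 tolerance of $10^{-10}$ (default cap
1000 iterations; non-convergence is flagged, not fatal), or exactly by a
dense linear solve (`engine = "direct"`). A node's score is the mean of its
layer-copy probabilities, renormalized to sum to 1 — rank-equivalent to the
sum. A single-layer multiplex reduces exactly to standard RWR, which is how
the single-layer replication setting is expressed.

Neighborhoods are the top-$k$ (default 50, with 100 as a consistency check)
non-seed genes by score, ties broken lexicographically so results are
deterministic. A group's own seeds are excluded — the neighborhood is what
the group points *to* — but other groups' genes may appear in it, which is
exactly what makes cross-group containment observable.

### Overlap significance by label randomization

The overlap statistic between two groups' neighborhoods is the raw
intersection size. Its null distribution comes from jointly permuting all
group labels over the network-present labeled genes (group sizes are
preserved by construction; genes absent from the network cannot seed a walk
and are excluded from the permutation universe). `p_low` is the fraction of
permutations with overlap less than or equal to the real one: small values
mean the groups' neighborhoods are *more separated* than labels-at-random
would produce.

Because hundreds of walks run on the same fixed network, the test
precomputes the resolvent kernel $(I - (1-r)T)^{-1}$ once and obtains each
permutation's scores by a matrix–vector product. This is the exact fixed
point of the iteration, not an approximation; the suite verifies kernel and
iterative scores agree to $10^{-8}$.

## Over-representation analysis

For query size $n$, term size $K$, background $N$ and overlap $k$, the raw
p-value is the upper tail $P(X \ge k)$ of the hypergeometric distribution.
The query is first intersected with the annotation background — by default
the union of all term gene sets ("only annotated genes"), with a custom
background as an option. P-values are Benjamini–Hochberg adjusted across all
tested terms and reported for terms with at least one overlapping gene.
Multiple-testing behaviour therefore follows the standard FDR convention
rather than any tool-proprietary threshold, and adjusted p-values are not
expected to match numbers produced by web services with bespoke corrections.
No ontology-hierarchy propagation or representative-term clustering is
performed.

## The synthetic generator

Real interactome snapshots are version-bound and large; the generator
instead produces data with the *statistical structure the analysis assumes*,
so every stage is exercisable offline:

* Each layer is an independent planted-partition (stochastic block) graph
  over `n_genes` (default 300) genes: two communities of 60 with
  within-community edge probability `p_intra = 0.15` and background
  probability `p_inter = 0.01` per layer. Three layers with the same block
  structure but independent draws emulate "same nodes, different
  interactions". At these defaults the aggregated LCC covers essentially all
  genes and within-community aggregated edge density is
  $1-(1-0.15)^3 \approx 0.39$ — cohesive but far from a clique.
* A distal-like group (11 genes) is sampled inside community 1 and a
  proximal-like group (22) inside community 2, mirroring the 11/22/7 onset
  split. A bridge group (7 genes, drawn from the background pool) models the
  common genes: each bridge gene connects to members of *both* communities
  and to the other bridge genes with probability `bridge_attachment`
  (default 0.3) per layer. The bridge group is thus multifunctional — wired
  into both modules — and mutually cohesive, which reproduces the empirical
  pattern that the common group is the most central and has the smallest
  intra-group distance.
* The GMT contains one term per community covering that community's genes
  *plus the bridge genes* (common genes carry both localizations), and
  noise terms of 10–40 random genes up to `n_terms` (default 10).

Bundles are deterministic given `rng_seed`, down to byte-identical files.
Setting `p_intra = p_inter` (and `bridge_attachment` to the same value)
removes the planted *network* structure, and the distance and overlap
effects vanish — the negative control. Note the enrichment signal does not
vanish under this control: it is carried by the GMT's membership structure,
not by edges.

What the generator does **not** model: the heavy-tailed degree distributions
of real interactomes, degree-correlated annotation, inter-layer degree
correlation, and literature bias. Passing the planted-recovery tests
therefore shows the machinery is correct and sensitive at realistic effect
sizes, not that any biological conclusion transfers to a particular
interactome snapshot.

## Pipeline reproducibility and problem sizes

`run_pipeline()` chains curation → multiplex assembly → LCC → subnetwork and
centralities → distance table → RWR neighborhoods → overlap tests →
enrichment, writing a manifest with every parameter. One global seed
deterministically derives a per-stage seed from the stage name, so a stage
rerun standalone with its derived seed reproduces its pipeline output;
reruns of the whole pipeline are byte-identical.

Default analysis parameters follow the study conventions: restart 0.7,
neighborhoods of 50 and 100, 2000 random sets per distance null, 1000 label
permutations per overlap test. The automated test suite runs the same
machinery at reduced Monte-Carlo sizes chosen to keep sampling error well
below the tested margins (20 generator seeds, 200 permutations, 500 random
sets), which the planted effect sizes comfortably exceed, as the margins
reported by the tests show.

## Known limitations

* All-pairs mean distance is sensitive to group outliers; no minimum-based
  or degree-aware variant is provided.
* The bootstrap null draws uniform random gene sets; degree-matched or
  annotation-aware nulls are out of scope, so hub-heavy groups will look
  closer than degree-matched chance would suggest.
* The inter-layer coupling (uniform relocation with one jump probability) is
  one member of a family of multiplex RWR couplings; the probability is
  config-exposed, but other coupling topologies are not implemented.
* Evidence curation handles a closed classification vocabulary and performs
  no disease-ontology matching.
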