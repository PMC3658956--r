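---
title: "Methods: cross-dataset co-expression meta-analysis with immunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset co-expression meta-analysis with immunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunet)
```

## The problem

Immune-response genes can be discovered functionally: a gene whose
expression rises together with known immune genes across many independent
infection or stimulation experiments is itself a strong immune-response
candidate, whether or not it carries an immune annotation. immunet
implements this idea as a meta-analysis over a *compendium* of normalized
(log2, RMA-style) microarray datasets: each dataset is one experiment with
its own control and treated arrays, its own tissue, pathogen and batch
level.

The obstacle is exactly those batch levels. Pooled Pearson correlation
across a multi-experiment compendium is dominated by between-dataset
baseline differences, not by the response of interest. The statistic at
the core of the package avoids this by construction.

## Within-group correlation

For two probesets with expression vectors $X$ and $Y$ over $n$ arrays
partitioned into $k$ datasets (group $j$ holding $n_j$ arrays), the
within-group correlation is the sample-size weighted average of the
per-dataset Pearson correlations:

$$ r_w \;=\; \sum_{j=1}^{k} \frac{n_j}{n}\, r_j, \qquad
   r_j = \operatorname{cor}\big(X^{(j)}, Y^{(j)}\big). $$

Each $r_j$ is computed within one experiment, so any per-dataset constant
(batch offset, tissue baseline) cancels exactly; $r_w$ responds only to
co-variation around each experiment's own means — in these designs,
chiefly the shared response to that experiment's stimulus. The engine is
tested for exactly this invariance, for the single-group reduction to
plain Pearson, for per-group positive-affine invariance, and against a
hand-evaluated two-group example ($r_w = 3/7 - 4/7 = -1/7$).

Degenerate groups (a probeset flat within one dataset) are handled by a
policy: the default `skip_and_renormalize` drops the group from the pair's
average and renormalizes the weights over contributing groups, which keeps
pairs comparable when one dataset is uninformative; a strict `undefined`
mode is available. Groups need at least 3 arrays for a non-degenerate
Pearson estimate, enforced at the sample-sheet level.

Pairwise computation standardizes each probeset within each group and
accumulates blocked inner products (`chunk_size` rows at a time, default
200), which bounds working memory without changing the result; the blocked
path is tested to agree with the naive per-pair formula to $10^{-12}$.

## Graph and clustering

Pairs with $r_w$ at or above the edge threshold become edges of an
undirected weighted graph. The default threshold is 0.52, the value that
empirically maximized cluster size while retaining annotation enrichment
in the analysis this package reproduces; the comparison is inclusive
($\geq$), with a $10^{-12}$ numeric guard so exact-fraction correlations
sitting on the boundary are not lost to last-bit rounding. Since the
threshold is positive, negative correlations never enter the graph — it is
a similarity graph.

The graph is clustered with a from-scratch Markov Cluster (MCL)
implementation. Nodes are ordered lexicographically; self loops are set to
each node's maximum incident weight (stabilizing odd-cycle parity, the
conventional choice); columns are normalized to a stochastic flow matrix;
then expansion (matrix squaring) and inflation (entrywise power, default
1.8, followed by column renormalization) alternate, pruning entries below
$10^{-5}$, until the largest entrywise change falls below $10^{-8}$ or 200
iterations. Clusters are read off the attractor structure: nodes retaining
diagonal mass are attractors, attractors connected by surviving flow form
attractor sets, and each node joins the set holding most of its column
mass (ties to the set with the lexicographically smallest attractor). The
procedure is bit-deterministic and invariant to edge order. Cluster
numbering is canonical — decreasing size, ties by smallest member id — so
"cluster 1" is always the largest cluster. Clusters below
`min_cluster_size` (default 3) are kept but flagged unclustered, so the
partition total is preserved.

The pruning and convergence settings are conventional rather than
prescribed; both are exposed as parameters. Inflation controls
granularity, and the suite checks coarse monotonicity (more inflation
never fewer clusters on a planted partition).

## Cluster characterization

**Enrichment.** For each cluster and each term with at least one
annotated background element, the package reports the overlap $a$, the
fold enrichment $(a/m)/(A/N)$, and a mass-based two-tailed exact p: the
sum of hypergeometric probabilities of all tables with the same margins
whose point probability does not exceed the observed one (the convention
of standard two-sided exact tests, against which it is verified, alongside
a brute-force enumeration oracle for all margins with $N \le 60$). The
EASE variant — decrement the observed cell by one before computing — is
emitted side by side; it is conservative whenever the observed overlap
lies above the hypergeometric mode, which is the over-representation
situation it was designed for (below the mode the decrement moves the
table *toward* significance, so no blanket "EASE $\geq$ Fisher" claim is
made). Benjamini–Hochberg q-values are computed within each cluster across
its terms by default (each cluster is one family of tests); a global mode
is available. The background universe defaults to all probesets of the
post-QC matrix and is configurable, since enrichment folds depend on it.

**Profiles.** A cluster's expression profile is the per-array mean over
members. The default `centered` mode removes each member's within-dataset
mean first, so profiles show response relative to each experiment's own
baseline; `raw` mode reproduces the alternative of averaging raw
normalized values.

**Activation.** Per dataset, the activation effect is the difference of
profile means, treated minus control, in log2 units. Its one-sided p-value
comes from permuting condition labels within the dataset (default 1000
permutations, add-one estimator, seeded). A dataset is called *activated*
when p falls below `alpha` (default 0.05) **and** the effect exceeds
`min_effect` (default 0.5 log2 units). The effect-size floor is a
deliberate design choice, in the spirit of fold-change thresholds in
differential-expression practice: a permutation test has exact size
$\alpha$ under the null, so across the dozens of cluster-by-dataset null
combinations a compendium produces, p-values alone would generate false
"activations" at rate $\alpha$ by construction. Requiring a biologically
meaningful shift as well makes the call robust; genuine activation in
these data is far larger than half a doubling.

## Array quality control

Post-normalization QC scores each array on three matrix-level metrics:
Kolmogorov–Smirnov distance between the array's value distribution and
the pooled distribution; one minus the median inter-array Spearman
correlation; and the MAD of the array's relative log expression (values
minus per-probeset medians). An array is an outlier on a metric when it
exceeds the upper boxplot fence (Q3 + 1.5 IQR) across arrays — a standard,
parameter-free rule — and *an array failing more than one metric is
removed*. Probe-level metrics (MA plots, spatial images) need raw data the
pipeline does not own; the three analogs preserve the decision rule at the
matrix level. If removals shrink a dataset below the minimum group size,
the whole dataset is dropped with a warning.

## The synthetic compendium

Because the original 188-array compendium is not an input, validation
runs on a generator whose defaults define the study conditions: 8 datasets
of 6 control + 6 treated arrays (96 arrays), 800 probesets — 60
*core-response* probesets responding in all datasets, 40
*subset-response* probesets responding in 3 of 8 datasets, 30 *cell-type*
probesets with tissue baseline and shared abundance but no treatment
response, and 670 background probesets. This mirrors the 8-experiment
structure of the original analysis at a cost of seconds rather than hours;
per-experiment sizes in the original differ and are not reconstructed.

The value for probeset $g$ on array $i$ of dataset $d$ is

$$ x_{gi} = \mu_g + b_{gd} + \ell_g f_{c(g),d}\,T_i\,R_{c(g),d}
          + \ell_g \kappa u_{c(g),i} + \varepsilon_{gi}, $$

with baseline $\mu_g \sim N(7, 1.5^2)$, batch offsets
$b_{gd} \sim N(0, 1)$, loadings $\ell_g \sim N(1, 0.1^2)$, shared
per-dataset treatment factors $f \sim N(2, 0.3^2)$ (log2 units — about a
four-fold induction), treatment indicator $T_i$, response indicator $R$,
latent per-array class factors $u$ with scale $\kappa = 1$, and noise
$\varepsilon \sim N(0, 0.3^2)$. Two structural choices deserve note:

* **Responses are a shared factor times a loading**, not independent
  per-probeset shifts. The within-group correlation detects
  *co-response*; independently differentially expressed probesets would
  not correlate and could never cluster.
* **The subset and cell-type classes carry a latent co-expression
  factor** ($\kappa$). A class responding in only a fraction $f$ of
  datasets is bounded near $r_w \approx f$ without it, so at the 0.52
  threshold the subset class could never form a cluster; and the cell-type
  class, whose very signature is correlated abundance without treatment
  response, needs within-dataset covariation to exist as a graph
  community at all. The latent factors are centered within every
  dataset-by-condition cell, so planted *non*-responses are realized
  exactly in the sample rather than only in expectation — the planted
  truth is the truth of the generated data, which is what recovery tests
  should score against.

All draws occur in a fixed order and are scaled by their standard
deviations afterwards, so identical configurations give byte-identical
compendia and changing one variance component reuses the same underlying
draws for the others (this is how batch-invariance is tested). A planted
"immune" term covers the core probesets, plus 20 random decoy terms, for
enrichment testing.

What the generator does **not** emulate: probe-level intensities and RMA
itself, missing values, heavy-tailed or intensity-dependent noise,
correlated noise between classes, time-course structure within datasets,
and partial overlap between planted modules. Passing recovery tests
therefore shows the machinery is correct under the assumed model, not that
real compendia are this clean; on real data the threshold and inflation
interact with noise in ways the planted design does not probe.

## Comparative-immunome conventions

* **Family expansion/contraction** uses strict inequalities on functional
  counts (pseudogene counts, the parenthetical numbers of the source
  table, are excluded): expanded means count $> 1.25\times$ the reference
  species' count, contracted $< 0.75\times$. A family absent from the
  reference but present in a species is treated as expanded (the ratio is
  undefined; presence-from-absence is an expansion). The row universe of
  any tally is an explicit `row_filter` argument, because subfamily rows
  overlap their inclusive parents and published tallies depend on the row
  set chosen.
* **Venn queries** distinguish marginal queries (constrained species only)
  from the 15 exclusive regions; the bundled 597-gene ortholog fixture is
  synthetic — a consistent completion of the published marginal counts
  into exclusive regions, labelled as such in the file.
* **Duplication classification** calls a candidate artifactual when
  nucleotide identity $\geq$ 98.5% (operationalizing "approximately 99%";
  exposed as a parameter) *and* placement is tandem-proximal: same
  scaffold, or same chromosome within 1 Mb nearest-coordinate distance
  (the source gives no window; 1 Mb is a generous tandem-cluster scale).
  High-identity pairs on *different* chromosomes are classed artifactual
  but flagged `needs_verification` — they are the problematic category
  that demands directed follow-up. Identity below the cutoff is a true
  duplication regardless of placement.
* **Percentages** are rounded half away from zero at the precision of the
  quantity being reported (integer by default, one decimal where the
  source prints one).

## Reproducibility

Every stochastic step takes an explicit seed; the pipeline fans a single
global seed out to per-stage seeds by fixed offsets, so one integer
reproduces a whole run. Artifact writers emit deterministic row order, and
the run manifest records an md5 digest per artifact; two runs with the
same config are byte-identical. The test suite and the acceptance script
use the desk-scale problem sizes quoted above (96 arrays, 800 probesets,
five seeds for recovery claims), chosen so a full validation runs in well
under a minute while keeping every planted class large enough for stable
recovery.

## A worked run

```{r example, eval = FALSE}
comp <- generate_compendium(compendium_config(seed = 1))
edges <- network_from_compendium(comp$matrix, comp$samples)   # threshold 0.52
clusters <- run_mcl(edges)                                    # inflation 1.8
table(clusters$cluster)
#>  1  2  3
#> 60 40 30
enr <- enrich_clusters(clusters, comp$term_map,
                       background = rownames(comp$matrix))
subset(enr, cluster == 1 & term == "GO:IMMUNE")[, c("a", "m", "fold", "q")]
#>    a  m     fold            q
#> 1 60 60 13.33333 1.103115e-90
activation_calls(comp$matrix, comp$samples, cluster_members(clusters, 1),
                 seed = 2)
#> activated in all 8 datasets, effects ~2 log2 units
```

## Known limitations

* The MCL attractor interpretation assigns overlapping attractor mass by
  a largest-mass rule; pathological near-ties could flip assignments
  between platforms with different BLAS rounding, although the
  lexicographic tie-break makes this deterministic for exact ties.
* The enrichment background never propagates GO ancestors; term maps are
  used as given.
* QC metrics are matrix-level analogs; arrays with probe-level artifacts
  that survive normalization invisibly will not be caught.
* The activation permutation test assumes exchangeability of arrays
  within a dataset; paired or time-course designs violate this and would
  need a tailored null.
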