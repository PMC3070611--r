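---
title: "Methods: mining differential pathways from integrated interaction networks"
author: "pathminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining differential pathways from integrated interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathminer)
```

## The problem

Tumor cells that survive platinum-based chemotherapy (cisplatin,
carboplatin) often do so through coordinated changes across signaling and
metabolic pathways — reduced drug accumulation, increased DNA-adduct
repair, altered apoptosis signaling — rather than through single genes.
`pathminer` implements a network-mining strategy for nominating such
chemoresistance-associated pathways: integrate curated gene/protein
interactions into one directed network, enumerate candidate paths between
biologically chosen seed genes, and rank those paths by how strongly their
member genes are differentially expressed between chemosensitive and
chemoresistant samples.

## The model, stage by stage

### Network integration and cycle condensation

Interaction tables (the flat form of parsed pathway and regulation
databases) are merged into a labeled directed network $N_B = (V, E,
\delta)$: vertices are official gene symbols (aliases resolved first, so
the same gene never enters twice), arcs carry an interaction kind, and
duplicated (source, target, kind) triples collapse to a single arc.
Undirected interactions such as protein binding expand to two arcs that
share one interaction identity, so they are not double-counted.

Transcriptional regulation is frequently cyclic — genes that regulate each
other, or themselves — and cycles break the notion of a *simple* shortest
path. Condensation replaces each cyclic group by one supernode before
path search. Two modes are provided because the granularity of merging is
a genuine design choice:

* `scc` (default): merge every strongly connected component with at least
  two vertices. The quotient graph is provably acyclic, so simple-path
  semantics hold for arbitrary cyclic regulation, not just pairwise
  loops.
* `two_cycle`: merge only groups chained through mutual-regulation pairs,
  reproducing the pairwise merging of, e.g., the AR/DDIT3 mutual pair;
  longer cycles survive.

Self-loops (auto-regulation) are deleted in all modes: they cannot lie on
a simple path. When a path is later scored, supernodes are expanded so
each member gene contributes individually.

### k-shortest simple paths

Between every ordered pair of seed vertices the package enumerates up to
$k$ simple paths with Yen's algorithm, using unit (hop-count) arc weights
by default; scoring happens *after* identification, so the search phase
deliberately carries no expression information. A user-supplied weight
vector or function is accepted for experimentation.

Two reproducibility choices matter and are tested:

* Ties among equal-weight paths are broken by the lexicographic order of
  the vertex-label sequence (byte order, locale-independent). The
  returned list is therefore the exact prefix of the full enumeration of
  simple paths sorted by (weight, label sequence), which is how the test
  suite checks it against brute-force enumeration.
* The shortest-path subroutine itself returns the lexicographically
  smallest minimum-weight path, constructed greedily against distances to
  the target. With strictly positive weights a minimum-weight completion
  can never revisit the prefix, so the construction is exact; zero-weight
  arcs are accepted but the lexicographic guarantee assumes positive
  weights (unit weights in all defaults).

Default $k = 5$: small enough that candidate sets stay interpretable,
large enough to capture near-shortest routes; it is a plain argument
everywhere.

### Differential-expression scoring

Per gene, a two-sided two-sample t-test compares resistant against
sensitive samples. The default is the pooled-variance Student test
(`welch` optional); the statistic is oriented resistant minus sensitive.
Genes with zero variance in both groups cannot be tested and are flagged:
equal means give $p = 1$, unequal means the floor $p = 10^{-16}$.

P-values convert to z-scores through the upper-tail inverse normal CDF,

$$z_m = \Phi^{-1}(1 - p_m),$$

so uniform p-values map to standard-normal z-scores and smaller p-values
give larger z. Inputs are clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-16}$ because $\Phi^{-1}$ diverges at the endpoints;
the clamp is far outside any attainable p-value from small-sample tests.

A pathway containing genes $m = 1 \dots k$ aggregates to

$$z_A = \frac{1}{\sqrt{k}} \sum_{m=1}^{k} z_m,$$

the size-corrected sum: under the null every $z_m$ is standard normal, so
$z_A$ is standard normal *for any pathway size*, which is what makes
pathways of different lengths comparable and a single score threshold
meaningful. A raw-sum mode is kept for the literal reading in which no
correction is applied; the choice is a flag (`normalization`). Genes on a
path that were not measured are excluded from both the sum and $k$
(rather than imputed at $p = 0.5$), so unmeasured genes neither help nor
penalize a pathway; the count of exclusions is reported. No
multiple-testing correction enters the scoring — the convention is raw
$p < 0.05$ — but a Benjamini–Hochberg column is available for reports.

The line-graph transform is provided for the edge-weighted view of the
same information: interactions become vertices, two interactions are
adjacent when they share a gene, and the shared gene's z-score weights
the connecting edge. For arcs sharing both endpoints the
lexicographically first shared gene labels the edge.

### Pathway intersection between conditions

To ask whether two conditions (e.g. two cancers) share a resistance
mechanism, pathway sets are intersected by symbol correspondence —
subgraph isomorphism is NP-hard in general, and exact label matching
sidesteps it. Vertices correspond when they carry the same official
symbol; supernodes correspond when their member sets overlap, and results
are reported at the member-symbol level so edge endpoints always appear
in the result's vertex set. Two modes:

* `strict` (default): an arc survives only if the other input has an arc
  of the same kind, in the same direction, between corresponding
  endpoints — vertex labels *and* edge labels must agree.
* `relaxed`: an arc survives whenever both endpoints correspond. The
  selection is applied to both inputs and the union kept, which makes
  the operation commutative; the strict result is always a subset of the
  relaxed one.

Set-level intersection runs over the Cartesian product of two pathway
sets, discards empty results and collapses duplicates, recording which
pathway pairs produced each surviving mechanism.

### Centrality of candidate genes

Genes of filtered pathways are cross-checked against an independent
reference network by two classic measures, both on the simplified
undirected projection (directions dropped, parallel arcs collapsed,
loops removed):

* scaled betweenness, $C_B(i) = \frac{2}{(n-1)(n-2)} \sum_{s \ne t \ne i}
  \sigma_{st}(i) / \sigma_{st}$, the Freeman normalization that keeps the
  value in $[0,1]$ for any network; disconnected pairs contribute 0;
* degree centrality, $\deg(i)/(n-1)$.

The report flags genes exceeding the network-wide arithmetic means of
both measures — the working signal for hub-node candidates. The exact
normalization constant of the betweenness scaling was an open choice; the
Freeman form is adopted because it is the standard one satisfying the
bounded-by-1 requirement. Published centrality means depend entirely on
the reference snapshot used, so no numeric reference values are asserted
anywhere; correctness is established against brute-force all-pairs
counting instead.

## The synthetic study design

Everything above is validated without external data through a generator
whose defaults *are* the study conditions:

* network: 20 genes, 40 directed arcs; a planted regulatory path of 5
  genes whose endpoints are the designated seeds; 2 planted
  mutual-regulation pairs (to exercise condensation); 2 extra competitor
  seeds among the background genes;
* expression: Gaussian with equal variance in both groups (exactly what
  the pooled t-test assumes, making power analytically checkable),
  baseline 8, $\sigma = 1$, 3 samples per group — a minimal two-group
  chemosensitivity design; planted genes shift by $\Delta = 2\sigma$ in
  the resistant group (when $\sigma = 0$ the shift is $\Delta$ itself, so
  the degenerate zero-variance branch of the t-test stays reachable);
* one integer seed drives everything; identical specs give byte-identical
  fixture files.

Two construction rules make the design identifiable by construction:
background arcs never touch planted-path vertices (in either direction)
and never form accidental mutual pairs. Consequently the planted route is
the *unique* path between its endpoints, every competitor pathway mined
between the extra seeds is a pure null path, and the planted cycle count
is exact. An earlier construction that allowed background arcs out of
planted vertices produced competitor paths sharing the planted signal —
superpaths containing the entire planted path plus diluting genes — which
confounds the ranking property the generator exists to test; the
isolation rule removes that confound and was adopted as the design. The
cost is a candidate set that is sometimes small (the planted path plus a
handful of null paths), which is the intended regime: the recovery
property measures whether scoring ranks a true differential pathway above
null pathways, not whether path search wins a lottery against its own
near-duplicates.

What the generator does *not* emulate: microarray probe-level artifacts,
batch effects, heavy-tailed or correlated noise, scale-free topology
(available only as future work — the background is Erdős–Rényi), or
database-scale networks. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration at desk scale, not performance on
real curated databases.

## Numerical choices and degenerate inputs

* p-value clamp $\varepsilon = 10^{-16}$; degenerate-gene p-value floor
  the same.
* Shortest-path optimality comparisons use an absolute slack of $10^{-9}$
  on accumulated weights to absorb floating-point drift.
* Lexicographic orderings are byte-order (`method = "radix"`), never
  locale-dependent.
* `source == target` gives the degenerate one-vertex path; seed pairs
  collapsing into one supernode are skipped and logged.
* Empty interaction files parse to empty networks; empty gene sets are an
  argument error for scoring.
* Problem sizes in the validation suite were chosen to keep the full
  brute-force oracles exact and affordable: random graphs of at most 8
  vertices for path enumeration, 10 for centrality, 12 for reachability;
  200 replicates for recovery; 10,000 draws for null calibration; 1,000
  genes for the t-test size check.

## Known limitations

* Yen's algorithm here targets the modest networks of a focused study;
  the spur loop re-queries distances per deviation and would need a
  lazy-deletion heap implementation for genome-scale graphs.
* Strict intersection compares arcs by exact kind labels; semantically
  close kinds (e.g. `unspecified` vs `metabolic`) never match.
* The alias table is single-valued by contract; conflicting mappings
  across source databases must be reconciled upstream.
* Centrality is unweighted; weighted-shortest-path betweenness is out of
  scope.
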