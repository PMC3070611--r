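# pathminer

Mining chemoresistance-associated pathways from integrated gene/protein
interaction networks.

## The problem

Resistance to platinum-based chemotherapy (cisplatin, carboplatin) arises
from coordinated changes across signaling, regulatory and metabolic
pathways rather than from single genes. `pathminer` is a toolkit for the
systems-biology workflow that nominates such pathways:

1. **Integrate** heterogeneous interaction tables (protein binding,
   positive/negative regulation, metabolic reactions) into one
   deduplicated directed network `N_B = (V, E, δ)`, with gene aliases
   resolved to official symbols.
2. **Condense** cyclic regulation (genes regulating each other) into
   supernodes so simple-path search is well defined — by strongly
   connected components (default) or by mutual-regulation pairs.
3. **Mine** the k shortest simple paths between every ordered pair of
   seed genes (user-interest genes, resistance-implicated transcription
   factors, DNA-damage/repair genes, differentially expressed genes)
   with Yen's algorithm, deterministic lexicographic tie-breaking.
4. **Score** each candidate pathway from two-group expression data:
   per-gene two-sample t-tests give p-values `p_m`, converted by
   `z_m = Φ⁻¹(1 − p_m)`, and aggregated size-correctedly as
   `z_A = Σ z_m / √k`, so pathways of all sizes share a standard-normal
   null scale; pathways are filtered by threshold and top-n.
5. **Intersect** pathway sets from two conditions by gene-symbol
   correspondence (strict mode also matches interaction kinds and
   direction) to expose shared resistance mechanisms.
6. **Rank** candidate genes on a reference network by scaled betweenness
   centrality `C_B(i) = 2/((n−1)(n−2)) · Σ σ_st(i)/σ_st` and degree
   centrality `deg(i)/(n−1)`, flagging genes above both network means as
   hub-node candidates.

A synthetic-data module generates networks with a planted differential
pathway and planted regulatory cycles plus matched two-group expression
data, so every stage is testable end to end without any download.

## Worked example

Generate a synthetic study (20 genes, 40 arcs, a planted 5-gene pathway
shifted by 2σ in the resistant group, 3 samples per group) and run the
full pipeline:

```r
library(pathminer)

spec <- synthetic_spec(seed = 9)
fx <- end_to_end_fixture(spec, "demo")
res <- run_pipeline(fx$files$interactions, fx$files$seeds, "demo_out",
                    expression = fx$files$expression,
                    groups = fx$files$groups,
                    threshold = -Inf, quiet = TRUE)

paste(fx$truth$path, collapse = " -> ")   # the planted ground truth
#> "G06 -> G19 -> G03 -> G12 -> G16"

for (s in res$filtered) print(s)
#> <scored_pathway> G06 -> G19 -> G03 -> G12 -> G16  score 4.121 (k = 5)
#> <scored_pathway> G13 -> G01+G02+G05+G07+G08+G09+G10+G11+G14+G15+G17+G20  score 0.3364 (k = 13)
```

The planted pathway ranks first with aggregate score `z_A = 4.12` — five
genes whose differential-expression z-scores sum to `4.12·√5 ≈ 9.2` —
while the competitor path through a large condensed regulatory component
(the `+`-joined supernode) scores near 0, as a null pathway should. The
per-gene table underneath shows why:

```r
gs <- res$scores
head(gs[order(gs$p), c("gene", "p", "z", "statistic")], 4)
#>  gene      p    z statistic
#>   G06 0.0022 2.85      6.99
#>   G03 0.0122 2.25      4.35
#>   G20 0.0370 1.79      3.08
#>   G07 0.0424 1.72      2.94
```

Planted genes (here G06, G03) surface with small p-values; the positive
`statistic` is the pooled t-statistic oriented resistant minus sensitive.
`demo_out/` contains the condensed network, all scored pathways, the
filtered set and a manifest of every resolved parameter; the same
configuration always reproduces byte-identical outputs.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/pathminer.R simulate --genes 20 --arcs 40 --seed 9 --out demo
Rscript inst/cli/pathminer.R run --interactions demo/interactions.tsv \
    --expr demo/expression.tsv --groups demo/groups.tsv \
    --seeds demo/seeds.txt --threshold -100 --out demo_out
```

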