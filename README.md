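# acumine

Association-rule and network mining of acupoint prescription corpora.

Acupuncture trials for a given condition each report an *acupoint
prescription* — the set of standardized points (WHO-style codes such as ST36
"Zusanli", CV12 "Zhongwan") needled in the treatment arm. Treating each
prescription as a transaction turns the trial literature into a market-basket
problem: which points are used most, which combinations co-occur beyond
chance, and which small set of points forms the *core prescription* around
which the rest of the repertoire is organized. `acumine` implements that
pipeline for researchers doing prescription data mining, with functional
dyspepsia (where the analysis singles out ST36 + CV12) as the worked case.

## What it computes

Given a corpus of `n` prescriptions over a vocabulary of points:

* **Frequency analysis** — per-point usage counts, with the percent column
  under either denominator convention (share of all usages, or transaction
  support `count / n`).
* **Apriori association rules** — level-wise frequent-itemset search and
  rules `A => c` with a single-item consequent, reported with the
  rule-table conventions used in this literature:
  support = antecedent's joint transaction support `supp(A)`,
  confidence = `supp(A ∪ {c}) / supp(A)`,
  expected confidence = `supp(c)`, and
  lift (the "enhancement coefficient") = confidence / expected confidence,
  with lift > 1 indicating positive co-selection dependence. Default
  thresholds: support ≥ 20 %, confidence ≥ 80 %.
* **Co-prescription network** — weighted undirected graph with an edge
  wherever two points are co-prescribed at least `min_weight` times; degree,
  unnormalized betweenness (Brandes), classical closeness
  `(n−1)/Σd`, max-normalized eigenvector centrality (power iteration),
  Watts–Strogatz clustering coefficient `C`, mean shortest-path length `L`,
  and a small-world assessment comparing the observed `L/C` with the mean
  over an Erdős–Rényi `G(n, m)` ensemble.
* **Core selection** — k-core decomposition (peeling); the maximum core
  ranked by degree (ties: betweenness, then prescription frequency) yields
  the core set, and its top two members the reported core combination.
* **Synthetic corpora** — a generator with a planted core pair,
  cluster-structured co-selection blocks and sparse noise, plus closed-form
  expected supports and an end-to-end `recovery_experiment()` that measures
  how often the full pipeline recovers the planted pair.

The four printed summary tables of the functional-dyspepsia study (42-point
frequency table, 17 association rules, 39-node degree sequence in three
clusters, 11-row core-point centrality table) ship as plain-text fixtures;
`verify_fixtures()` recomputes every desk-recoverable identity in them.

## Worked example

```r
library(acumine)

corpus <- generate_corpus(synthetic_config(seed = 20260929))
corpus
#> <acu_corpus> 46 prescriptions, 40 acupoints, 295 total usages

head(frequency_table(corpus, "n_transactions"), 5)
#>   code count percent
#> 1 CV12    40   86.96
#> 2 ST36    37   80.43
#> 3 ST25    27   58.70
#> 4  LR3    24   52.17
#> 5  SP4    21   45.65

head(format_rules(association_rules(corpus)), 3)
#>   antecedent consequent support confidence expected_confidence lift
#> 1       CV12       ST36   86.96      82.50               80.43 1.03
#> 2       ST36       CV12   80.43      89.19               86.96 1.03
#> 3       ST25       CV12   58.70      92.59               86.96 1.06

g <- build_graph(cooccurrence_matrix(corpus), min_weight = 3)
small_world_report(g, n_replicates = 200, seed = 1)
#> <small_world_report> 22 nodes / 103 edges
#>   observed: L = 1.558, C = 0.755, L/C = 2.064
#>   G(n,m) baseline (200 replicates, seed 1): L = 1.559, C = 0.443, L/C = 3.518

kc <- kcore_decomposition(g)
sel <- select_core(centrality_table(g), cores = kc,
                   freq = frequency_table(corpus, "n_transactions"))
attr(sel, "core_combination")
#> [1] "CV12" "ST36"
```

Reading: the planted pair dominates the frequency table; every emitted rule
clears the 20 % / 80 % thresholds with lift above 1; the co-prescription
network's `L/C` (2.06) sits well below its random baseline (3.52), the
small-world signature of prescriptions organized around core points; and the
maximum k-core ranked by degree returns the planted combination CV12 + ST36.

A thin CLI over the same functions is at `inst/scripts/acumine.R`
(subcommands `mine`, `simulate`, `fixtures`, `network`).

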