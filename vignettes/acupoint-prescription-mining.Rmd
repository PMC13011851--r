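---
title: "Mining acupoint prescriptions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining acupoint prescriptions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acumine)
```

## The problem and the data model

Acupuncture trials for one condition each contribute an *acupoint
prescription*: the complete set of standardized points needled in the
treatment arm. `acumine` treats every prescription as a transaction over a
vocabulary of WHO-style codes (`ST36`, `CV12`, extra points like `EX-HN5`).
Prescriptions are **sets**: bilateral needling and repeated mentions of the
same point collapse to one code, so a count of 41 for ST36 means "41
prescriptions use ST36", never "needled 41 times". Raw names are resolved
through a case- and space-insensitive alias map (`standardize_name()`,
`default_name_map()`); anything already in code syntax passes through
unchanged, which makes standardization idempotent and keeps the vocabulary
open beyond the shipped 42-point map.

The analysis chain is: frequency analysis, Apriori association-rule mining,
co-prescription network construction, small-world assessment, and k-core /
centrality based selection of the core point combination. Each stage is a
plain function; `run_pipeline()` orchestrates them into one seeded,
reproducible run.

## Rule metrics and their conventions

Two support conventions coexist in this literature and the package exposes
both explicitly:

* Frequency tables usually report a point's share of **all point usages**
  (`denominator_mode = "total_usages"`).
* Rule tables report **transaction support** — fractions of prescriptions.

For a rule `A => c` (single-item consequent, antecedent up to
`max_antecedent` items, default 2):

* **support** (as printed in the rule tables this package mirrors) is the
  *antecedent's* joint transaction support `supp(A)`, not the joint support
  of `A ∪ {c}`. This is deliberate and verifiable: the printed support
  columns of the 17-rule fixture back-solve exactly to antecedent counts
  over a 46-transaction corpus (e.g. 69.57 % = 32/46, the antecedent's
  frequency-table count), which is impossible under the rule-support
  convention. A rule is emitted iff `supp(A) >= min_support` **and**
  `confidence >= min_confidence`.
* **confidence** = `supp(A ∪ {c}) / supp(A)`.
* **expected confidence** = `supp(c)`, the consequent's unconditional
  transaction support.
* **lift** (the "enhancement coefficient") = confidence / expected
  confidence; values above 1 mean the antecedent raises the consequent's
  selection probability. Internally all fractions are kept exact; the
  reporting layer (`format_rules()`, `rule_lift(..., digits = 2)`) rounds
  half-away-from-zero to two decimals, matching how printed tables round
  (`round_half_up()`; base `round()` is half-even and would disagree on
  exact halves).

Default thresholds are support ≥ 20 % and confidence ≥ 80 %, the
conventional operating point in acupoint-prescription mining; both are plain
arguments. Support comparisons use a `1e-12` slack so that counts sitting
exactly on the threshold are never excluded by floating-point noise.

The Apriori search itself is the classic level-wise algorithm (candidate
join on a shared prefix, downward-closure pruning, support counting against
an incidence matrix). The test suite checks it against exhaustive
enumeration on 100 seeded corpora with up to 12 items and 50 transactions —
small enough that the brute-force oracle is itself trivially correct.

## The co-prescription network

`build_graph()` connects two points iff they are co-prescribed in at least
`min_weight` transactions (default 1); the weight is the raw co-occurrence
count. Points left with no edge are dropped as isolates, which is also the
mechanism by which very rare points fall out of published networks. The
threshold is exposed because it is a genuine analysis choice: raising it
trades coverage for stability (see the recovery experiment below).

Centrality conventions follow the published core-point tables:

* **degree** — incident edge count (unweighted);
* **betweenness** — unnormalized shortest-path betweenness, each unordered
  pair counted once, endpoints excluded (Brandes accumulation; hub values
  well above 1, as in the printed tables);
* **closeness** — classical `(n−1) / Σ d(v, u)`. On a disconnected graph it
  is computed per component and flagged with a warning; the published
  networks are connected, so defaults match their tables. A useful printed
  identity: in a connected 39-node network where all of a hub's
  non-neighbors are at distance two, closeness is `38 / (deg + 2·(38−deg))`,
  and all 11 printed closeness values satisfy it to 6 decimals
  (`verify_fixtures()`).
* **eigenvector** — power iteration on the binary adjacency matrix, rescaled
  so the maximum score is exactly 1 (the printed tables' normalization;
  unit-norm scaling would not put the top hub at 1). Tolerance `1e-10`,
  cap 1000 iterations, non-convergence is an error carrying the count.

**Small-world assessment.** `C` is the mean Watts–Strogatz local clustering
coefficient, with degree < 2 nodes contributing 0 (a global-transitivity
variant was considered and rejected as the default because the mean-local
form is what network toolkits report by default; the per-node values are
exposed via `local_clustering()` if a user wants transitivity instead). `L`
is the mean shortest-path length over unordered connected pairs. The null
model is the uniform Erdős–Rényi `G(n, m)` ensemble with matched node and
edge counts (default 1000 replicates, seeded Mersenne-Twister); random
replicates can be disconnected, so their `L` is measured on the largest
component. A prescription network organized around core points shows
`L/C` far below its random baseline, because clustering stays high while
paths stay short. The baseline is *reported, never asserted against printed
baseline values*: the published random-network figures for the
functional-dyspepsia graph (L = 4.159, C = 0.067) are not reproducible from
`G(39, 213)` (whose expected clustering is ≈ 2m/n(n−1) ≈ 0.29), so the
generating model behind those printed values is unknown. The package's
acceptance checks therefore only verify the printed *arithmetic*
(1.722/0.82 → 2.1; 4.159/0.067 → 62.075) and the qualitative flag
(observed ratio far below baseline).

**Communities and layout.** Community structure is weighted Louvain
modularity maximization (via igraph, resolution 1.0, fixed seed —
determinism is part of the contract; the partition is reporting-level
context, not an input to core selection). The layout is a standard
Fruchterman–Reingold schedule in a unit-area frame (`k = sqrt(area/n)`,
attractive `d²/k`, repulsive `k²/d`, linear cooling from `0.1·sqrt(area)`),
seed-reproducible, and used only for export — no metric depends on
coordinates.

## Core selection

`kcore_decomposition()` peels minimum-degree nodes to assign each node its
coreness; the maximum core (the maximal subgraph in which every node keeps
at least `k_max` neighbors inside it) is the densely interconnected backbone
and defines the core prescription set. `select_core()` ranks the members by

1. degree (descending),
2. betweenness (descending, rounded at `1e-9`),
3. prescription frequency (descending),
4. closeness, eigenvector, then code.

The frequency tie-break (step 3) is a deliberate design choice. In dense
co-prescription graphs several saturated hubs can tie *exactly* on degree
and betweenness (nodes adjacent to everything have mathematically identical
betweenness), and a lexicographic fallback would then make the "core
combination" an accident of code spelling. Prescription frequency is one of
the selection's declared score components, separates true high-usage cores
from incidentally saturated neighbors, and is invariant to graph
thresholding. The betweenness rounding exists for the same reason:
mathematically tied values must not be ordered by floating-point residue.
The top two ranked members form the reported core combination, the headline
pair of this kind of analysis.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` plants the structure the pipeline is designed to
detect. Per prescription, independently:

* with probability `p_core` both core points are included jointly (else each
  enters independently at `p_core_single`) — joint support is the planted
  signal;
* each co-selection block activates with its `activation` probability, and
  an active block contributes each of its items with probability
  `p_within` — this mimics syndrome-style point groupings and creates the
  clustered network structure;
* every remaining item enters independently at `p_noise`;
* empty draws are redrawn (prescriptions are non-empty by definition), a
  truncation whose effect on the closed-form expectations of
  `planted_truth()` is negligible at realistic parameters (the empty-draw
  probability is far below 1e-3) and is therefore ignored in those formulas.

Defaults mirror the observed scale of the functional-dyspepsia corpus,
chosen once: 46 transactions (the denominator implied by the printed rule
supports, all integers over 46) over the 42-point vocabulary; core pair
ST36+CV12 at joint inclusion 0.63 (≈ 29/46) with singleton inclusion 0.5;
three blocks echoing the three printed network clusters — the frequent
co-stars (PC6, LR3, ST25, SP4; activation 0.8, within 0.5), a mid-frequency
block (ST44, BL20, BL21, ST40, SP9; 0.4, 0.5) and a low-frequency block
(BL18, ST21, CV4, ST37, CV13; 0.3, 0.5); remaining items at `p_noise = 0.03`,
matching the long tail of points used once or twice in 46.

What the generator does **not** model: trial-level covariates (country,
diagnostic criteria, comparator), reporting and publication bias,
syndrome-differentiation logic that makes point choices *conditionally*
dependent on patient presentation, and longitudinal prescribing. Passing
recovery tests therefore show that the pipeline's inference logic is sound
under the assumed independence-plus-blocks structure — they do not show that
a real literature corpus satisfies that structure.

## The recovery experiment

`recovery_experiment()` generates replicate corpora, runs the full pipeline
(mining → network → k-core/centrality → core selection) on each, and reports
the fraction whose selected top-2 equals the planted pair. Its per-replicate
graph uses an edge-support floor of `min_weight = ceiling(0.05 · n)` —
an edge must be realized in at least 5 % of prescriptions. This is the
package's own methodological choice, made on variance grounds: at
`min_weight = 1`, edge presence is dominated by singleton co-occurrences of
noise items, so unweighted degree (the primary ranking key) becomes a noisy,
tie-prone statistic; a support-proportional floor makes the graph reflect
reproducible co-selection. `run_pipeline()` itself keeps the permissive
default of 1 so that descriptive analyses see every co-occurrence.

Under the strong-signal regime (planted joint support 0.7, 200
transactions, noise 0.02, three blocks) the pipeline recovers the planted
pair in 100/100 seeded replicates; under an i.i.d. null (every point at
p = 0.2, nothing planted) recovery is 0/100 — selection does not
hallucinate a core pair from unstructured data. Both figures are recomputed
by the test suite at every run.

## Numerical and testing choices

* RNG: Mersenne-Twister everywhere, named in config metadata; every
  stochastic function takes an explicit seed and restores the caller's RNG
  state.
* Orderings are always deterministic: numeric key, then lexicographic code.
* Reported percentages/lifts: 2 dp, half-away-from-zero; raw fractions kept
  internally.
* Oracle suites (run on every test invocation): Apriori vs exhaustive
  enumeration on 100 corpora (≤ 12 items, ≤ 50 transactions); BFS distances
  vs Floyd–Warshall, Brandes betweenness vs an adjacency-power path-count
  oracle, closeness, power-iteration eigenvector vs dense
  eigendecomposition, and local clustering vs triangle counting on 100
  connected random graphs of up to 15 nodes, at 1e-8; k-core nesting and the
  defining within-core degree bound on every decomposition, cross-checked
  against igraph. Problem sizes keep the brute-force oracles trivially
  correct and the whole suite fast.
* The printed-table fixtures are stored verbatim, including their known
  internal inconsistencies: the frequency table's percent column implies
  conflicting denominators and sums to 261 against a printed total of 260,
  and one degree-table label (`KT3`) is a printed typo. No operation claims
  to reproduce those cells; `verify_fixtures()` checks only the identities
  that genuinely hold.

## Known limitations

* The original corpus is not published; its transaction count is reported
  inconsistently (25 in one place, 21 in another, while the rule supports
  imply 46). Corpus size is therefore a free input everywhere, never
  hard-coded.
* The published 39-node network's edge list is not printed, so exact
  reproduction of its betweenness values, path length (1.722), maximum-core
  membership (11 nodes) or community assignment is not attempted; those
  quantities are validated structurally (oracles, identities) and on
  synthetic data instead.
* Closeness on disconnected graphs is a per-component convention, flagged —
  comparing such values across components is not meaningful.
* Community detection delegates to Louvain; with `resolution = 1` very small
  cliques attached to a large dense core can be absorbed rather than split.
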