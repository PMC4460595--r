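---
title: "Classifying proteins with similarity-network graph pyramids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying proteins with similarity-network graph pyramids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsnet)
```

## The problem

Homology-based function prediction assigns a query protein to a known family
and inherits that family's annotation. The standard shortcut — take the single
best database hit — uses only the *global* feature of the similarity space and
fails exactly where it matters most: closely related families whose members
cross-hit each other, and remote homologs whose best direct hit is weak.
`ppsnet` instead models each family as a protein–protein similarity (PPS)
network and asks a structural question: *how does the query reshape each
family's network when it is attached?* Weak ("local") similarities, which a
best-hit method discards, participate through the network topology — the same
intuition that makes intermediate-sequence search work, but with graph
structure controlling the false positives that naive transitivity would
propagate.

## From alignment statistics to edge weights

A pairwise match is summarised by two numbers that carry overlapping but
distinct information: the bit-score (alignment quality on a search-space-free
scale) and the E-value (expected chance hits at that score). They are fused
into one nonnegative weight,

$$eb = -\ln(E)\cdot \text{bitscore}, \qquad
EB = eb \cdot H(eb),$$

where $H$ is the Heaviside step with $H(0)=1$. Hits with $E \ge 1$ collapse
to 0 — "no detectable similarity" — and a zero weight never forms an edge.
Three plumbing decisions are worth stating because the construction does not
dictate them:

* **Log base.** Natural log, the convention of E-value statistics. It is a
  configurable argument of `eb_score()`; any base only rescales all weights
  and leaves every threshold-relative quantity unchanged.
* **Underflow.** Aligners report `E = 0` below their floating-point floor;
  the E-value is clamped to `1e-180` before the log so the score stays finite
  and order-correct.
* **Asymmetry.** Reciprocal searches and multiple HSPs give several numbers
  per pair; an undirected edge needs one. `similarity_table()` keeps the
  maximum EB over both directions — the strongest evidence wins.

Scores can come from any tool emitting 12-column tabular hits
(`read_blast_tabular()`), from a generic 4-column TSV, or from the built-in
`align_pair()`: an exact affine-gap Smith–Waterman (gap of length $k$ costs
`gap_open` $+ k\,\cdot$ `gap_extend`) with Karlin–Altschul statistics
(BLOSUM62, 11/1, $\lambda = 0.267$, $\kappa = 0.041$ by default), so a
FASTA-only workflow needs no external search tool. It performs no heuristic
seeding, which is fine at package scale and exact by construction.

## The graph pyramid

Each family $c$ with training sequences $V^c$ becomes a weighted undirected
graph whose edge weights are EB-scores (zero diagonal). The pyramid is a
ladder of thresholds $t_1 < \dots < t_n$; at level $t$ the surviving graph
keeps edges with weight $\ge t$ (the closed Heaviside boundary) and is
treated as *unweighted*. Levels are nested: higher levels retain only the
strongest, near-global matches, lower levels expose the weak local structure.
`train_model()` quantizes $(0, w_{\max}]$ — the observed edge-weight range of
the training graphs — into `n_levels` uniform steps. Quantizing the *weight*
range (rather than the range of any feature value) is a deliberate reading:
thresholds act on edges, and a single ladder keeps every feature's levels
commensurable.

Five graph-structured features summarise a level, each with an explicit
degenerate convention:

| feature | definition | convention |
|---|---|---|
| AC | mean local clustering coefficient | $C_n = 0$ when $\deg n < 2$ |
| RC | density among vertices of degree $> r$ | 0 when fewer than 2 such vertices |
| SM | number of vertices with degree $\ge p$ (star centres) | — |
| TR | triangle count, $\operatorname{tr}(A^3)/6$ | exact integer, checked |
| GE | $\sum_i |\lambda_i(A)|$ (graph energy) | 0 for an edgeless view |

Star motifs count degree $\ge p$ rather than $= p$: a query that strengthens
an existing hub should register as increased star evidence, and the $\ge$
convention makes $\Delta SM \ge 0$ under attachment (monotone, like
$\Delta TR$). Graph energy is computed on the *binary* adjacency of the view,
consistent with the adjacency used for triangle counting; a weighted variant
(`weighted_ge = TRUE`) exists because the geometric "spread" intuition behind
the feature references edge lengths, but the binary form is the default and
the tested path. Eigenvalues come from the symmetric solver with no
small-eigenvalue cutoff (they contribute nothing to the sum).

The classification signal is always a *delta*: attach the query to a family
graph, view both graphs at $t$, and take
$\Delta f = f(\text{augmented}) - f(\text{original})$.

## Hierarchical voting

`classify()` funnels candidates through the features:

1. **AC shortlist.** Scan the AC ladder top-down; at the first level where
   some class has $\Delta AC > T_{AC}$, keep *all* such classes ($t^*$ is
   that level). Strong matches qualify high — that is the global-feature
   regime.
2. **RC refinement.** Same descent over the shortlist with $\Delta RC(r) >
   T_{RC}$, where $r$ is 3 on the lower half of the RC ladder and 5 on the
   upper half (hubs must be "richer" where the graph is denser; the exact
   changeover is not dictated by the construction, so the midpoint is used).
3. **SM and TR votes.** Within the RC survivors, each feature descends its
   own ladder to the first level where some candidate has a positive delta
   and keeps the $k$ most influenced classes there ($k = 3$ by default:
   small enough to prune, large enough for the pooled mode to be
   meaningful). Classes with $\Delta \le 0$ never vote.
4. **GE arbiter.** Over the SM/TR union, graph energy votes at the *lowest*
   level of its ladder — high thresholds leave the graph too sparse for the
   spectrum to move, dense low-level graphs are where energy discriminates —
   again by $k$-max. (`ge_descend = TRUE` makes it descend like the others.)
5. **Decision.** The label is the mode of the pooled vote multiset. A tie
   triggers a $k=1$ re-vote of SM and TR (free: deltas are memoised); a
   persistent tie falls to the single class with the largest $\Delta GE$;
   and if no unique class can be named the result is `NA` — an explicit
   no-decision, never a guess. All argmax ties break by ascending label so
   results are bit-reproducible.

Two boundary choices deserve a note. First, qualification is *strict*
($\Delta > T$, not $\ge$): with the default $T = 0$ a class whose feature
does not move at all must not qualify, otherwise a query with no similarity
to anything would "qualify" everywhere at the top level and the no-decision
path could never fire. Second, when the AC stage finds nothing at any level,
the classifier falls back to graph energy alone over all families — the
lowest-level, densest-graph regime is the only place left to look — and
reports `tie_path = "ge_only"`.

The majority-voting baseline (`method = "majority"`) lets every feature scan
*all* families over its own ladder and nominate one class; the prediction is
the mode of the five votes. It is the natural non-hierarchical reference for
both accuracy and cost. Cost is compared by counting (feature, class, level)
delta evaluations (`compare_efficiency()`), a machine-independent proxy;
within one classification each distinct triple is computed and counted once.

Secondary thresholds default to $T_{AC} = T_{RC} = 0$; `tune_secondary()`
grid-searches them on a validation split when spurious weak interactions
need suppressing.

## Incremental learning

`classify(update = TRUE)` attaches every decided query to its predicted
family graph before the next query is classified — instance-based learning
with no retraining. The update equals a from-scratch rebuild on the enlarged
member list, other families are untouched, and the threshold ladders stay as
quantized at training time (so results remain comparable across the run).
Updates apply to every *decided* query, right or wrong, because truth is
unknown at deployment; `update_only_confident = TRUE` restricts updates to
tie-free decisions. This is where weak-training regimes gain the most: each
absorbed query densifies its family's network for the queries that follow.

## What the synthetic benchmark emulates — and what it does not

`simulate_score_network()` generates score-level families directly, no
sequences involved: intra-family pairs get log-normal EB-scores
(`meanlog = mu_in`), thinned to `edge_keep_frac` with retention probability
proportional to $((\deg_i + 1)(\deg_j + 1))^{\gamma}$ — the
rich-gets-richer mechanism that concentrates edges onto hubs, as observed
when real similarity networks are thresholded — and a `cross_frac` fraction
of inter-family pairs gets weaker log-normal scores (`meanlog = mu_out`).
About 10% of members per family are withheld as labelled queries. The
defaults are the package's study conditions, chosen once:
`mu_in = log(2000)` (EB of order $-\ln(10^{-9})\cdot 100$, a solidly
significant hit), `sigma = 0.5`, `mu_out = mu_in - 4*sigma` (clearly
separable but overlapping tails), `hub_gamma = 1`, `edge_keep_frac = 0.7`,
`cross_frac = 0.05`. The generator is a pure function of its arguments, seed
included.

What it does **not** emulate: E-value statistics of a real search engine,
correlated cross-hits between specific family pairs (cross edges are
independent), heterogeneous family sizes, or any sequence-level signal.
Passing benchmarks here demonstrates that the machinery recovers planted
structure under hub-dominated, separable conditions — not field performance
on a curated orthology database, which depends on that database and a real
aligner. `simulate_sequences()` (one random ancestor per family,
independent per-site substitutions, no indels) exists to exercise the
FASTA-to-scores path end to end, not to model evolution.

Problem sizes used by the test suite and the acceptance script — 20 families
of 30 members with 10% held out for the main benchmark; the same at 80%
held out (20% training) over 5 seeds for the incremental-vs-batch
comparison; 200 random graphs of at most 12 vertices for the feature
oracles — are the package's own choices, small enough to check everywhere
by brute force while large enough for the pyramid, the funnel and the
baselines to behave non-trivially.

## Numerical and degenerate-input choices

* Edge survival is `weight >= t` with `H(0) = 1`; a stored weight of 0 is
  identical to an absent pair at every threshold, including `t = 0`.
* Vertices keep insertion order; an attached query is always the last
  vertex, so adjacency matrices are reproducible and the original weights
  are recoverable by dropping the last row/column.
* `trace(A^3)/6` is asserted to be an integer; a non-integer value means a
  broken adjacency invariant and raises an internal error rather than a
  silent rounding.
* An all-zero training weight set has no pyramid and is an error, not an
  empty ladder.
* Model persistence is plain text: a JSON manifest plus one dense TSV
  weight matrix per family. Dense is deliberate — family graphs are small
  and the format stays human-diffable.

## Limitations

* Feature evaluation is quadratic-to-cubic in family size (dense matrix
  products, eigendecompositions); the design targets families of tens to a
  few hundred members, not whole-database graphs.
* The ladder slices (AC/RC high, SM/TR middle, GE low) encode a
  precision-by-level argument, not a learned placement; `slices` overrides
  them but nothing fits them automatically.
* Incremental updates never re-quantize the ladders, so a long update run
  whose scores drift above the training maximum leaves the top of the
  pyramid underpopulated.
* Votes are unweighted and uncalibrated; no probability attaches to a
  decision.
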