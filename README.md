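# ppsnet

Protein family classification with similarity-network graph pyramids.

## The problem

Assigning a function to an unannotated protein usually starts with homology:
find the family the sequence belongs to and inherit that family's
annotation. The common shortcut — classify by the single best database hit —
uses only the strongest *global* match and breaks down for closely related
families (whose members cross-hit each other) and for remote homologs (whose
best direct hit is weak). `ppsnet` is for people who want a
classification that also exploits the *weak* similarities: it models every
family as a protein–protein similarity (PPS) network and classifies a query
by how it perturbs each family's network structure, examined level by level
down a hierarchy of edge-weight thresholds (a *graph pyramid*).

## The method

Pairwise alignment statistics are fused into one nonnegative edge weight,
the EB-score

    EB(s1, s2) = eb · H(eb),   eb = −ln E(s1, s2) · bitscore(s1, s2),

where `H` is the Heaviside step (`H(0) = 1`). Each family `c` becomes a
weighted undirected graph `G(V^c, E^c)`; at pyramid level `t` edges with
weight `≥ t` survive and the view is treated as unweighted. Five
graph-structured features (GSF) summarise a view — average clustering
coefficient (AC), rich-club coefficient `φ(r)` (RC), star-motif count of
power `p` (SM), triangle count `tr(A³)/6` (TR), and graph energy `Σ|λᵢ(A)|`
(GE) — and the classification signal is the change `Δf(c, t)` each feature
shows when the query is attached to family `c`.

Classification is hierarchical voting: AC shortlists families at the highest
level `t*` where `ΔAC > T_AC`, RC refines the shortlist, SM and TR vote for
the `k` most influenced survivors, GE arbitrates at the bottom of the
pyramid, and the mode of the pooled votes decides — with a deterministic
tie-break cascade and an explicit no-decision outcome instead of a guess.
Decided queries can be folded back into their predicted family
(instance-based incremental learning). Scores come from 12-column tabular
hit files, generic TSVs, or the built-in exact affine-gap local aligner
(BLOSUM62 + Karlin–Altschul statistics), so FASTA-only runs need no
external tools.

See the methods vignette (`vignettes/graph-pyramid-classification.Rmd`) for
the model, parameter meanings and design decisions.

## A worked example

```r
library(ppsnet)

# a small hand-checkable family graph
g <- example_clustered_graph()
v <- threshold_view(g, 1)
avg_clustering(v)
#> [1] 0.8666667      # 13/15: centre contributes 1/3, the four leaves 1 each
rich_club(v, r = 1)
#> [1] 0.6            # 3/5: 6 edges among the 5 vertices of degree > 1
triangles(v)
#> [1] 2

# a synthetic hub-structured benchmark: 5 families, 10% held out as queries
sim <- simulate_score_network(n_families = 5, family_size = 12, seed = 42)
model <- train_model(sim$table, sim$families)
model
#> <gp_model: 5 families, 55 sequences, 10 pyramid levels (max EB 7722)>

preds <- classify(model, sim$table, queries = sim$queries$query_id)
preds[, c("query_id", "predicted", "tie_path", "t_star_ac", "n_evaluations")]
#> # A tibble: 5 × 5
#>   query_id  predicted tie_path t_star_ac n_evaluations
#>   <chr>     <chr>     <chr>        <dbl>         <int>
#> 1 fam01_s03 fam01     ge_only      4633.            30
#> 2 fam02_s09 fam02     ge_only      4633.            30
#> 3 fam03_s10 fam03     ge_only      4633.            30
#> 4 fam04_s06 fam04     ge_only      4633.            30
#> 5 fam05_s03 fam05     ge_only      4633.            30

glance(evaluate_predictions(preds, sim$queries))
#> # A tibble: 1 × 8
#>       n    cd    wd    nd precision accuracy misclassified feature_evaluations
#>   <int> <int> <int> <int>     <dbl>    <dbl>         <int>               <int>
#> 1     5     5     0     0         1        1             0                 150
```

Every query lands in its true family (`cd` = correct decisions, `wd` =
wrong, `nd` = no decision; precision is `cd / (cd + wd)`). The `tie_path`
column records which decision route fired: here the strong matches are so
far above the upper pyramid levels' clustering threshold band that the
energy arbiter decides directly; `t_star_ac` reports the highest level at
which each query interacts. `n_evaluations` counts (feature, class, level)
delta evaluations — the funnel's cost currency, compared against plain
majority voting by `compare_efficiency()`.

A command-line front end over the same functions is installed at
`inst/cli/ppsnet` (subcommands `build`, `classify`, `evaluate`, `simulate`,
`tune`, `sweep`).

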