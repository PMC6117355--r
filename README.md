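# cea — combination-based gene set enrichment analysis

`cea` is an R package for functional enrichment analysis of gene lists
(from bulk or single-cell transcriptomics, or any source of "active"
genes) that scores **combinations of annotation terms** instead of single
terms. Single-term over-representation rankings are redundant — the top
hits usually describe the same genes — and no single term explains a whole
active list. `cea` collapses each term combination into a *pseudo
composite term*, the union of its gene sets, tests that union with the
one-sided Fisher (hypergeometric) test, and searches for enriched
combinations with a randomized greedy algorithm over a multi-objective
set-cover model.

## The model in brief

For an active set $U_G$ inside a universe $U$, a combination
$X$ of terms $S_1,\dots,S_m$ has $S(X)$ annotated genes, $t(X)$ of them
active, and composite p-value $P(\mathrm{Hypergeom}(|U|, S(X), |U_G|) \ge
t(X))$. The search model is

$$\max\; t(X) \qquad \min\; S(X) - t(X),$$

whose Pareto front (at most $|U_G|+1$ points) provably contains the
minimum-p combination. Each front point is an NP-hard enrichment set cover
problem; `cea` approximates it with a weighted randomized greedy: gene
weights $w(e) = 1/|N_e|$ (coverage frequency), term weights
$w(S) = \sum_{e \in S \cap U_O} w(e)$, and at each step a term is drawn
uniformly from those whose cost-effectiveness
$w(S_i)/|(S_i \cap U_G)\setminus C|$ is within $(1+d)$ of the minimum
(defaults $d = 1$, 500 repeats; $d = 0$ is deterministic greedy). All
prefixes of all repeats are pooled into a solution landscape, filterable
by size, p-value and coverage. Exact brute-force oracles
(`enumerate_best_pvalue()`, `solve_escp_exact()`, `exact_pareto()`)
certify the heuristic on small instances, and an evaluation module
measures result redundancy (Wang semantic similarity, resampled ASS
background) and specificity (annotated-gene counts, ontology levels).

## Worked example

A synthetic benchmark with 10 disjoint planted terms (their union is the
active list) plus 5 noise active genes among 300 terms and 2,000 genes:

```r
library(cea)
inst <- make_planted_instance(n_genes = 2000, n_terms = 300, k_planted = 10,
                              noise_active = 5, seed = 42)
inst
#> cea_planted: 10 planted terms (720 genes) + 5 noise active genes; 300 terms, 2000-gene universe

sols <- run_cea(inst$active, inst$db, d = 1, repeats = 500, seed = 42)
sols
#> cea_solutions: 1299 distinct combinations (sizes 1-15), best p = 0 at size 10

best10 <- filter_solutions(sols, size = 10)[1, ]
setequal(best10$members[[1]], inst$planted)
#> [1] TRUE
c(neg_log10_p = -best10$log10_p, coverage = best10$coverage)
#> neg_log10_p    coverage
#>       553.6       0.993
nrow(pareto_front(sols))
#> [1] 6
```

The best size-10 combination is exactly the planted set, its composite
p-value underflows double precision (hence `log10_p`, computed in log
space: here $p = 10^{-553.6}$), and its coverage is 0.993 — everything but
the 5 noise genes. `landscape_table(sols)` exports one row per combination
(size, $-\log_{10} p$, coverage, members) for plotting; the per-size
maximum of $-\log_{10} p$ rises to size 10 and falls beyond it, the
characteristic shape of the solution landscape.

Real data enter through standard formats: `load_gmt()` /
`load_universe()` for annotations, `load_obo()` for the ontology,
`derive_active_genes()` for the top-100-by-t-test recipe on a two-group
expression matrix, `single_term_scan()` for the classical per-term
baseline with BH adjustment.

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "cea.R", package = "cea")`:

```sh
Rscript cea.R simulate --preset planted --seed 42 --out sim
Rscript cea.R run --gmt sim.gmt --active sim.active.txt \
        --universe sim.universe.txt --d 1 --repeats 500 --seed 42 \
        --size 10 --out res          # res.solutions.tsv, res.best.tsv
Rscript cea.R evaluate --terms terms.txt --gmt sim.gmt --obo go.obo \
        --method wang --reps 100000 --seed 1 --out ev
Rscript cea.R derive-active --expr expr.tsv --groups groups.tsv \
        --gmt anno.gmt --top-n 100 --out active.txt
```

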