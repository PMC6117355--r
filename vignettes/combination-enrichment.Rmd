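---
title: "Combination-based enrichment analysis: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combination-based enrichment analysis: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cea)
```

## The problem

Classical over-representation analysis tests each annotation term in
isolation: for a term annotating $K$ of $N$ universe genes, of which $k$ fall
in an active list of $n$ genes, the one-sided Fisher (hypergeometric) p-value
is $P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$. Single-term
rankings are notoriously redundant — the top of the list is typically a
cluster of overlapping terms explaining the same genes — and no single term
is expected to explain a whole active list.

This package scores term *combinations* instead. A combination
$X \subseteq \{1,\dots,m\}$ is collapsed into a **pseudo composite term**,
the union $\cup_{i \in X} S_i$ of its gene sets, and that union is tested
with the same hypergeometric tail. Enumerating all $2^m$ combinations is
hopeless, so the search is organized around a multi-objective set-cover
model:

$$\max \; t(X) \qquad \min \; S(X) - t(X)$$

where $S(X)$ is the number of genes annotated by the combination and $t(X)$
the number of those that are active. Covering more active genes and
annotating fewer inactive ones are conflicting goals; the combination with
the smallest composite p-value is always Pareto-optimal for this pair, so it
suffices to search near the Pareto front. Since $0 \le t(X) \le |U_G|$, the
front has at most $|U_G| + 1$ points. Fixing the coverage with a constraint
$t(X) \ge \alpha\,|U_G|$ turns each front point into an NP-hard set-cover
variant (the enrichment set cover problem), which the package solves
approximately with a randomized greedy algorithm and exactly, for small
instances, by enumeration (`solve_escp_exact()`, `exact_pareto()`).

## The randomized greedy search

Each gene gets weight $w(e) = 1/|N_e|$, where $N_e$ is the set of terms
annotating $e$: ubiquitously annotated genes are cheap, rarely annotated
ones expensive. A term's weight $w(S) = \sum_{e \in S \cap U_O} w(e)$ sums
the weights of its *inactive* genes. At each step, with $C$ the active genes
already covered, every candidate term has cost-effectiveness

$$\frac{w(S_i)}{|(S_i \cap U_G) \setminus C|},$$

the inactive-gene penalty per newly covered active gene (infinite when the
term adds no uncovered active gene — such terms are never selectable, and
terms never overlapping $U_G$ are pruned up front). The plain greedy
algorithm would take the minimum $\sigma$; here one term is drawn *uniformly
at random* from all terms within $(1+d)\sigma$, which lets repeated runs
escape the local minima the deterministic path gets stuck in. With $d = 0$
the algorithm degenerates to deterministic greedy. After every addition the
current prefix (members, $S(X)$, $t(X)$, coverage, p-value) is recorded; the
run stops when no term can add an uncovered active gene. Active genes no
term annotates are reported as a diagnostic, not an error — an active list
is never fully explainable.

`run_cea()` repeats this `repeats` times and pools every prefix of every
run, deduplicated by member set, into the solution landscape. Defaults are
$d = 1$ and `repeats = 500`; larger $d$ explores more but needs more
repeats. Repeat $r$ is seeded with `seed + r`, so the pool is a pure
function of the master seed and independent of execution order.

Design choices worth stating explicitly:

* **Eligibility band is boundary-inclusive**, and uniform sampling is used
  because no other distribution is implied by "within $(1+d)\sigma$".
  When $\sigma = 0$ (some candidate has zero weight, e.g. a term entirely
  inside $U_G$), the band $(1+d)\cdot 0$ collapses to the zero-cost
  candidates regardless of $d$.
* **Every prefix is recorded**, not just each run's final solution: the
  landscape needs combinations at every size, and a prefix of a good run is
  itself a meaningful combination.
* **No size constraint in the model.** Size selection happens only in
  `filter_solutions()`; this matches the model's design and explains why
  very small combinations can score worse than single-term ranking.
* **Combination p-values are reported raw**; only the single-term baseline
  scan (`single_term_scan()`) carries a Benjamini–Hochberg adjustment, with
  minimum-rank ("competition") tie handling so ranks are reproducible.
* **Log-space tails.** P-values of strong composite terms underflow double
  precision long before they stop being informative; every solution carries
  `log10_p` computed via the log-space tail, and landscape plots use it.

```{r example}
inst <- make_planted_instance(n_genes = 2000, n_terms = 300, k_planted = 10,
                              noise_active = 5, seed = 42)
sols <- run_cea(inst$active, inst$db, d = 1, repeats = 500, seed = 42)
sols
best10 <- filter_solutions(sols, size = 10)[1, ]
setequal(best10$members[[1]], inst$planted)
```

The per-size maximum of $-\log_{10} p$ rises while the search assembles the
coherent planted structure and falls once additional coverage can only be
bought with individually unenriched terms — the characteristic
rise-then-fall of the solution landscape:

```{r landscape}
lt <- landscape_table(sols)
tapply(lt$neg_log10_p, lt$size, max)
```

## Redundancy and specificity evaluation

To quantify how redundant an identified term set is, `average_similarity()`
computes the ASS — the mean of all $\binom{n}{2}$ pairwise semantic
similarity scores. Pairwise similarity is the graph-based Wang (2007)
measure on the is_a DAG: every ancestor $t$ of a term $A$ receives an
S-value, $S_A(A) = 1$ and $S_A(t) = \max\{0.8 \cdot S_A(t')\}$ over the
children $t'$ of $t$ within $A$'s ancestor graph, and

$$\mathrm{sim}(A,B) =
  \frac{\sum_{t \in T_A \cap T_B} (S_A(t) + S_B(t))}
       {\sum_{t \in T_A} S_A(t) + \sum_{t \in T_B} S_B(t)}.$$

The is_a decay weight 0.8 is the measure's conventional default. An
annotation-overlap Jaccard index is provided as a DAG-free fallback; the
method used is recorded in the output. Terms absent from the DAG are
dropped from the ASS with a logged count rather than scored zero.

Because a raw ASS has no scale, `background_distribution()` resamples term
sets of the same size uniformly from *all* candidate terms (not only
identified ones) and reports the empirical distribution; the default is
100,000 draws (tunable — the package's own tests use 2,000, where the mean
is already stable to well under three standard errors across seeds).
Specificity is summarized by the annotated-gene count and the ontology
level — the *longest* is_a path to the root, root at level 0 — via
`term_level()` and `specificity_summary()`.

## Active-list derivation and the synthetic benchmark

`derive_active_genes()` follows the standard recipe for two-group
expression data: per-gene two-sample t-test, sort ascending by p, take the
top 100 (tunable), then keep the genes with at least one annotation. Points
that the recipe leaves open and how they are resolved here: the t-test is
Welch by default (a pooled-variance option exists) and two-sided; ties at
the cutoff are broken by gene id so the cut is reproducible; constant rows
get p = 1 and sort last; and the annotation filter is applied *after* the
top-$n$ cut, so the resulting active set may have fewer than $n$ genes.

The synthetic benchmark (`make_synthetic_db()`, `make_planted_instance()`)
emulates the structure the method is meant to exploit: a universe of 2,000
genes, 300 terms with log-uniform sizes in [5, 200] (mean about 53,
comparable to functional annotation databases), 10 mutually disjoint
planted terms whose union is the active list, plus 5 noise active genes
outside it standing in for experimentally spurious actives. Planted terms
are carved from the universe up front, which guarantees disjointness at any
density; decoys are uniform random subsets, which produces the incidental
overlaps that make cover instances non-trivial. With no noise the planted
set is a zero-objective exact cover and provably optimal; the package's
exact oracle certifies this on small instances. What the generator does
*not* emulate: correlated term hierarchies (decoys are unstructured),
gene-level annotation bias, or expression-derived active lists with
marginal effect sizes — so recovery results on the benchmark bound the
method's behaviour on clean planted structure, not its power on weak
signals.

Problem sizes used in the test suite and acceptance script were chosen so
the exact oracles stay exact: oracle comparisons run on instances with at
most 15 terms, 40 genes and 8 active genes (where full enumeration is
instant), recovery and landscape checks on the full 2,000 x 300 benchmark
with the default $d = 1$, 500 repeats.

## Numerical and degenerate-input notes

* The coverage constraint is discretized as
  $t(X) \ge \lceil \alpha |U_G| \rceil$ since $t$ is integral.
* Oracle tie-breaks are deterministic: smaller size first, then
  lexicographic member ids; the Pareto front keeps the lexicographically
  smallest member set among geometrically identical solutions.
* The empty combination ($t = 0$, objective 0) anchors the exact Pareto
  front; `coverage()` of an empty combination is 0 by definition.
* An active list with no annotated gene is an error for the optimizer
  ("nothing to cover"); a *partially* uncoverable active list is not.
* Gene identifiers are matched as exact strings; no alias resolution is
  attempted. The default universe is the union of annotated genes in the
  loaded GMT, overridable with an explicit universe file — a species-wide
  universe is not operational without an external database.

## Limitations

Optimality is not guaranteed — the underlying cover problem is NP-hard and
the randomized greedy is a heuristic; on the small-instance battery it
attains the exhaustive optimum in about 95–97% of instances, and the exact
oracles exist precisely to measure that gap. The benchmark's recovery rates
should not be read as power estimates for real expression data. Wang
similarity depends only on the is_a graph; information-content measures
(Resnik, Lin) are out of scope, as are id mapping, evidence-code filtering
and expression preprocessing.
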