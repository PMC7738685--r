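---
title: "Overlapping driver module discovery: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlapping driver module discovery: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driveways)
```

## The model

Somatic driver mutations concentrate in functional pathways, and two genes
of the same pathway are rarely mutated in the same tumor: one hit is usually
enough to perturb the pathway, so a second carries no selective advantage.
`driveways` turns this into a module score. Let $G=(V,E)$ be a
protein–protein interaction network over gene symbols and let $S_i$ be the
set of cohort samples in which gene $g_i$ is mutated. For a gene set
$M \subseteq V$:

$$
\mathrm{COV}(M) = \frac{\left|\bigcup_{g_i \in M} S_i\right|}
                       {\left|\bigcup_{g_j \in V} S_j\right|},
\qquad
\mathrm{MEX}(M) = \frac{\left|\bigcup_{g_i \in M} S_i\right|}
                       {\sum_{g_i \in M} |S_i|},
\qquad
\mathrm{MS}(M) = \mathrm{COV}(M)\times\mathrm{MEX}(M).
$$

Coverage rewards modules that explain many tumors; mutual exclusivity is 1
exactly when the per-gene sample sets are pairwise disjoint and decays as
samples accumulate multiple hits. The product couples them so that neither
can be traded away entirely. A *solution* is an ordered set $D$ of modules
maximizing $\mathrm{ODMSS}(D) = \sum_{M \in D} \mathrm{MS}(M)$ subject to:
each induced subgraph $G(M)$ connected; modules pairwise distinct as gene
sets; $|M| \ge \delta_m$ for all $M$; and $\sum_{M\in D} |M| = \delta_s$.
Modules may share genes — the constraint on $\delta_s$ counts genes with
multiplicity, which is what allows partial overlaps in a legal solution.

The coverage denominator is fixed once per analysis as the union over $V$,
where $V$ is the set of network genes that survive the mutation-frequency
filter. Genes present in the mutation data but absent from the network can
therefore never enter modules, and genes asked about but absent from the
profile contribute empty sample sets. This convention lets the same scoring
code evaluate arbitrary reference pathways.

## The greedy heuristic

Exact optimization is intractable in general (the problem embeds a
connected-subgraph selection with a knapsack constraint), so discovery uses
a seed-and-extend heuristic.

**Seed ranking.** Genes mutated in less than `min_mut_fraction` (default 1%)
of the cohort are removed — the comparison is a strict `<` against the
unrounded threshold, so 1 mutation in 100 samples survives at 1%. Each
remaining network gene $g$ is scored by $\mathrm{MS}(N_e(g))$, the module
score of $g$ together with its direct neighbors, and seeds are sorted
nonincreasingly. Ties break by descending mutated-sample count, then
lexicographically — determinism was preferred over any attempt at a
smarter tie rule.

**Candidate set.** While growing module $M$, a neighbor $g_i \in N(M)
\setminus M$ is a growth candidate iff

1. $\left|\bigcup_{g_k \in M \cup \{g_i\}} S_k\right| \big/ \sum_{g_k \in M} |S_k| > t$, and
2. $\deg(g_i, M)\,/\,\overline{\deg}(g_i) > 1/d$,

where $\deg(g_i, M)$ is $g_i$'s degree in the subgraph induced by
$M \cup \{g_i\}$ and $\overline{\deg}(g_i)$ averages $\deg(g_i, M_q)$ over
the earlier modules $M_q$ that contain $g_i$. Condition (1) demands enough
fresh coverage relative to the module's accumulated mutation mass;
condition (2) admits an already-placed gene only when it is at least
$1/d$-times as connected to the current module as to its previous homes.
A gene in no earlier module passes (2) vacuously (there is nothing to
compare against), as does a gene whose average prior degree is zero.
Membership in earlier modules never excludes a candidate — that is
precisely what makes overlapping output possible.

**Growth.** Each step evaluates every candidate singly; *all* tied
maximizers are added together (the candidate-evaluation order is
lexicographic, so ties are deterministic). Competing with the addition is
the best removal: non-seed genes whose individual removal keeps $G(M)$
connected, again with tied maximizers removed together. If removing the
whole tied group would disconnect the module, only the lexicographically
first is removed — the joint rule mirrors addition but must not break the
connectivity invariant. Whichever of the two variants improves
$\mathrm{MS}(M)$ more is committed; equal improvements go to the addition
(biasing toward coverage growth). Growth stops at the first step with no
strict improvement. Because every accepted step strictly increases MS over
a finite family of reachable modules, termination is guaranteed; the
implementation asserts strict monotonicity at run time and exposes the
accepted-MS trace.

**Assembly.** Modules are grown from the highest-ranked seed not already
inside an output module. A finalized module smaller than $\delta_m$, or
equal to an earlier module, is discarded with its seed consumed.
Construction stops as soon as total size reaches $\delta_s$; the last
module is kept whole, so the total may overshoot by at most
$|M_{\text{last}}| - 1$. Truncating the final module would destroy its
no-improvement fixed point, which we judged worse than a bounded overshoot.
Module sizes are deliberately *not* hard-capped at $2\delta_m - 1$: the
parameter $t$ achieves the same size control with more flexibility.

**Parameter search.** `optimize_params()` evaluates `build_module_set()` at
up to `n_evaluations` (default 30) points of the $(t, d)$ box (defaults
$t \in [0.8, 1.2]$, $d \in [2, 5]$) and returns the evaluated point with
the best ODMSS. The default strategy is Bayesian optimization — a
squared-exponential Gaussian-process surrogate over the unit box, initial
design by maximin Latin hypercube, length-scale chosen by marginal
likelihood over a short grid, and expected-improvement acquisition
maximized over a random candidate pool. A deterministic grid strategy
shares the same interface for fully reproducible sweeps. Both are
deterministic given `rng_seed`; a failed evaluation scores $-\infty$ and is
skipped.

## The exact solver

For small instances `solve_exact()` finds a provable optimum: enumerate all
connected induced subgraphs with admissible sizes (each generated exactly
once from its lexicographically smallest vertex by anchored extension),
score each by MS, and run a 0/1 dynamic program over (entry, total size)
with the recurrence $c[i,j] = \max(c[i-1,j],\; c[i-1, j-|M_i|] +
\mathrm{MS}(M_i))$. Treating each catalog entry as usable at most once
makes the distinctness constraint automatic while leaving overlapping
entries freely combinable. Infeasible cells carry an explicit $-\infty$
marker, and an unreachable $\delta_s$ is returned as a typed infeasibility
result rather than an error. Entries without any mutated gene score 0 (the
continuous extension of MS); a catalog cap (default $10^6$) guards against
accidentally huge instances.

By default the size window is restricted to $[\delta_m, 2\delta_m)$. The
motivation is a splitting argument: for any bipartition of a module's gene
set, $\frac{(x+y)^2}{a+b} \le \frac{x^2}{a} + \frac{y^2}{b}$ (with $x, y$
the part unions and $a, b$ the part sums) shows that splitting never lowers
the summed score, so large modules look unnecessary. We found this is *not*
universally true under the full constraint set: in rare instances every
connected bipartition of the oversized module with both parts $\ge \delta_m$
collides with a module already in the solution, and distinctness blocks the
split. `verify_lemma_window()` computes both optima and reports whether
they agree (they do on the overwhelming majority of random instances; a
concrete lossy instance is kept in the test suite). When a certified
optimum matters, run with `enforce_lemma_window = FALSE`.

## Evaluation measures

Predicted modules are compared against reference pathway collections (GMT,
optionally restricted to known cancer genes and size-filtered at
$\delta_m$) under three similarity measures:

* **Overlap score** $|M_i \cap R_j|^2 / (|M_i|\,|R_j|)$ — 1 iff identical,
  0 iff disjoint.
* **Hypergeometric q-value** — the upper-tail probability of an
  intersection at least as large as observed, drawing $|M_i|$ genes from a
  universe containing $|R_j|$ successes, Benjamini–Hochberg-adjusted over
  all module×pathway tests as one family (the correction scope is a
  convention; pooling is the conservative reading). Edge weights are
  $-\log_{10} q$ with $q > 0.05$ zeroed; the boundary $q = 0.05$ itself
  counts as significant, and $q$ exactly 0 (underflow) is clamped to the
  smallest positive double before the log. The universe defaults to the
  analyzed network's genes and is configurable.
* **GO consistency** — Jaccard similarity of the unions of
  level-standardized GO terms. Annotations are standardized to one depth of
  the ontology: terms at the target depth are kept, deeper terms are
  replaced by *all* their ancestors at that depth, shallower terms are
  dropped. Depth is the length of the shortest `is_a` path from the
  namespace root; `part_of` edges are ignored and all three namespaces are
  used unless the annotation input restricts them. Both choices are
  conventions where reasonable alternatives exist (longest-path depth,
  per-namespace analysis); they are documented, deterministic, and
  idempotent at a fixed level.

**Matching.** The module–pathway similarity matrix defines a *complete*
bipartite graph, zero-weight edges included. `mmr()` finds a
maximum-cardinality matching of maximal total weight and averages the
matched edge weights over $\min(\#\text{modules}, \#\text{pathways})$
edges. Keeping the zero edges is the point: if only one of $k$ predicted
modules matches anything, the mean is $1/k$, not 1 — dropping zero edges
would let a mostly-useless prediction score perfectly. The denominator is
the matching cardinality, the only consistent reading on a complete
bipartite graph.

**Best-match precision/recall.** Row maxima give each module its best
pathway (precision side), column maxima give each pathway its best module
(recall side), and the aggregate F1 is the *product* of the two averages —
not a harmonic mean.

**Gene-level ROC.** Modules are accumulated in rank order until the number
of unique genes first reaches each cutoff; TPR is the fraction of reference
driver genes recovered and FPR the fraction of non-reference background
genes included.

## The synthetic benchmark

`generate_synthetic()` plants `n_modules` connected modules (sizes drawn
from `module_size_range`, consecutive modules sharing exactly
`overlap_genes` genes) in a network with dense in-module wiring (a random
spanning tree guarantees connectivity, plus Bernoulli(`p_in`) edges) and
sparse Bernoulli(`p_bg`) background edges. Each module owns a sample block;
every block sample receives a mutation in exactly one module gene, so
within-module mutual exclusivity is exactly 1 before noise and scoring
tests have closed forms. Blocks of different modules may share samples and
default to the whole cohort: each patient then carries one driver mutation
per planted module. This cross-module co-occurrence is the signal the
module score relies on — mutations are exclusive within a pathway but
co-occur freely across pathways — and it is what makes crossing a planted
boundary unprofitable for MS and the partition identifiable. (With
pairwise-disjoint blocks no sample ever carries two mutations, exclusivity
is globally perfect, and a greedy maximizer of coverage×exclusivity
correctly but uselessly merges everything it can reach.) A gene shared by
$k$ modules takes a $1/k$ weight in each of its blocks' partitions so its
total mutation mass matches an interior gene's — a shared driver is not
mutated twice as often, and without this damping its inflated mass is
absorbed early and distorts growth. Passenger noise adds independent
per-gene-per-sample mutations at `passenger_rate`. Every planted gene is
guaranteed at least one mutated sample so the frequency filter cannot
silently delete planted structure. Generation is fully deterministic given
`rng_seed`, and the caller's RNG state is restored.

What the generator does *not* emulate: mutation-rate heterogeneity across
genes and samples, copy-number alterations, tumor purity, hypermutators,
and the heavy-tailed degree distribution of real interactomes. Passing the
benchmark therefore shows that the pipeline recovers the idealized
structure the score targets, not that it will match any particular clinical
dataset.

## Numerical choices and problem sizes

* All scores are computed in double precision; test equality assertions use
  absolute tolerance $10^{-12}$.
* The growth loop treats MS differences below $10^{-12}$ as ties, so
  floating noise can neither stall nor loop it; a hard iteration cap exists
  purely as an internal safeguard.
* Tie-breaks everywhere are lexicographic on gene symbols (after the
  documented primary keys), making every code path deterministic.
* Degenerate inputs are typed errors, not silent results: an empty coverage
  denominator, a module with no mutated gene, empty sets in the overlap
  score, an empty similarity matrix.

The shipped test suite exercises: the exact solver against brute-force
enumeration on 200 random instances of up to 8 nodes ($\delta_m = 2$,
$\delta_s \le 6$) plus the size-window comparison on the same family; the
greedy pipeline on ten seeds of the default benchmark (60 genes, 300
samples, 5 modules of sizes 4–6, one shared gene between consecutive
modules) and ten noiseless two-triangle instances where its output is
compared against the exact optimum; matching against a permutation oracle
on matrices up to 7×7; and hypergeometric tails against full draw
enumeration for universes up to 12. These sizes keep the whole suite and
the acceptance script comfortably within a couple of minutes on a single
CPU while still covering every code path the package exposes.

## Known limitations

* The restricted-window exact solve can, in rare instances, miss the true
  optimum (see above); the unwindowed mode is the certificate.
* The greedy heuristic inherits the usual local-search caveats: the
  all-tied-maximizers addition rule can momentarily lower the per-step
  gain relative to a single best addition, and the seed-anchored modules
  mean a poorly ranked seed list degrades output quality.
* MITAB/PSI-XML interaction formats and MAF mutation files are not parsed;
  inputs are pre-converted to the documented TSV/GMT/OBO forms. Gene
  identity is the raw case-sensitive symbol, with no alias resolution.
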