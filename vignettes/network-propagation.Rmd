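---
title: "Ranking disease-associated enhancers by multiplex-heterogeneous network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking disease-associated enhancers by multiplex-heterogeneous network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Curated disease–enhancer associations are sparse: most enhancers have no
documented disease link. `enhrank` treats prediction as label
propagation on a joint network of diseases and enhancers, under the
biological assumption that enhancers regulating common target genes, or
sharing sequence features, tend to be involved in related diseases.

Three networks are built:

1. **Disease similarity.** Diseases are mapped (one term each) onto an
   ontology DAG carrying gene annotations. For a term $t$, the
   information content is $IC(t) = -\log\big(f(t)/f(\mathrm{root})\big)$
   where $f(t)$ is the number of *distinct* genes annotated to $t$ or
   any descendant. The similarity of two terms is the maximum $IC$ over
   their shared ancestors (each term counts as its own ancestor), i.e.
   the IC of the most informative common ancestor. Pairs with positive
   similarity become weighted edges.
2. **Shared-gene enhancer network (gEnhNet).** For enhancers $e_i, e_j$
   with $n_i$ and $n_j$ target genes of which $k$ are shared, out of a
   universe of $n$ genes (all genes annotated to any enhancer in the
   catalog), the upper-tail hypergeometric probability of an overlap at
   least as large is computed; pairs with $p \le 0.05$ (raw, no
   multiple-testing correction — the convention of the method; BH is
   available but off by default) get an unweighted edge. The p-value is
   kept as an edge attribute for audit only.
3. **Sequence-similarity enhancer network (sEnhNet).** A symmetric
   non-negative percent-identity matrix is ingested; the diagonal is
   dropped, enhancers with zero similarity to everything are pruned, and
   the remaining positive scores are used as edge weights as-is
   (column normalization makes within-layer scale irrelevant).

The two enhancer layers, aligned onto the union of their node sets
(missing nodes padded as isolated), form a multiplex with
supra-adjacency

$$A^M = \begin{pmatrix}(1-\delta)A^{gene} & \delta I\\ \delta I & (1-\delta)A^{seq}\end{pmatrix},$$

and the bipartite association matrix $B$ (one identical copy per layer)
couples it to the disease block, giving the full supra-adjacency
$A = \begin{pmatrix}A^M & B^{MH}\\ (B^{MH})^\top & A^D\end{pmatrix}$.

The walk iterates $P_{t+1} = (1-\gamma)\,M P_t + \gamma P_0$ with a
column-stochastic operator $M$, entry $(i,j)$ being the probability of
moving *to* $i$ *from* $j$ — the only reading consistent with
left-multiplication in the update. The restart vector places
$(1-\eta)\tau$, $(1-\eta)(1-\tau)$ and $\eta$ of the mass uniformly on
the seed enhancers' gene-layer replicas, their sequence-layer replicas,
and the seed disease(s) respectively. Candidates are ranked by their
steady-state probability summed over replicas.

## Parameters

| parameter | role | default |
|---|---|---|
| `gamma` | restart probability of the walk | 0.5 |
| `delta` | inter-layer jump probability in the multiplex | 0.5 |
| `tau` | restart weight of the gene layer vs the sequence layer | 0.5 |
| `lambda` | probability of crossing the bipartite coupling | 0.5 |
| `eta` | restart weight of the disease side | 0.5 |
| `alpha` | gEnhNet significance cutoff | 0.05 |

All walk parameters default to 0.5, the fixed setting under which the
method is reported stable; `sweep_parameters()` re-evaluates any of them
over a grid (default $\{0.1, 0.3, 0.5, 0.7, 0.9\}$) with folds held
fixed across settings, so comparisons are paired.

`eta` deserves a note: the restart split between enhancer and disease
seeds is not pinned down by the published parameterization, so the
neutral 0.5 is used. Likewise `lambda` is only ever reported at 0.5; we
give it the standard heterogeneous-RWR semantics (the probability of
switching between the enhancer multiplex and the disease sub-network
through bipartite links) under the default `"jump"` normalization. A
`"literal"` mode that column-normalizes the assembled supra-adjacency
directly (ignoring `lambda`) is provided for sensitivity checks, since
the two conventions genuinely differ and either is defensible. In both,
the multiplex block is normalized as assembled, so `delta` interacts
with node degree.

## Numerical choices

* **Convergence.** The iteration stops when the L1 change drops below
  `tol = 1e-10` (well below score differences of interest), or flags
  non-convergence after `max_iter = 1000` and returns the best iterate.
  `rwr_solve()` computes the exact fixed point
  $(I - (1-\gamma)M)P = \gamma P_0$ as an independent oracle; the two
  agree to better than $10^{-8}$ in the test suite.
* **Dangling columns.** A node isolated everywhere would break column
  stochasticity; its column is resolved as the restart distribution
  (equivalent to an immediate restart), which preserves the simplex
  without inventing edges.
* **Ties.** Candidate ties are broken lexicographically by enhancer id,
  so rankings are reproducible byte-for-byte.
* **Replica combination.** An enhancer's two replica probabilities are
  summed (rank-identical to the mean). A geometric mean was rejected:
  nodes isolated in one layer would always score zero.
* **IC conventions.** Natural log (rankings are invariant to the base,
  which is configurable); $f(t)$ deduplicates genes across the
  descendant closure so $p(t) \le 1$ is guaranteed; terms with
  $f(t) = 0$ get an infinite-IC sentinel and are excluded from
  similarity rather than propagating infinities.
* **Similarity-matrix ingestion.** Mildly asymmetric matrices (e.g.
  from numeric round-trips) are symmetrized by averaging when the worst
  discrepancy is within `1e-6` of the matrix maximum; anything larger is
  rejected with the offending pair reported.
* **Surrogate aligner.** The built-in percent-identity scorer uses
  global alignment with unit match and zero mismatch/gap scores (the
  maximal number of matched columns over the tie-broken alignment
  length, diagonal moves preferred, operands in canonical order so the
  score is exactly symmetric). It exists so tests and fixtures need no
  external aligner; real analyses ingest an aligner's matrix output.
* **Coordinates.** Intervals are 0-based half-open internally (BED
  native); rendered identifiers are 1-based inclusive, the convention of
  curated enhancer labels. Strand is ignored throughout; the genome
  build is carried as metadata only.

## Cross-validation protocol

Per disease with at least three known enhancers, the known set is split
into three folds differing in size by at most one (1–1–2 for four
enhancers). In each round the held-out associations are **removed from
the bipartite coupling** before the transition operator is built —
otherwise the held-out answer leaks straight through $B$ — training
enhancers (plus the query disease) seed the walk, and held-out enhancers
are scored against all universe enhancers not known-associated with the
disease. Fold AUCs (Mann–Whitney form, ties counting one half) are
averaged per disease, then unweighted across diseases. Fold assignments
derive deterministically from the master seed and the disease id.

## What the fixture generator emulates — and what it does not

`generate_fixture()` produces a complete toy dataset: a binary-tree
ontology (25 terms) whose leaves carry 4 genes each, 8 diseases mapped
to leaves, and 60 enhancers in 6 modules of 10. Each module owns a
disjoint pool of 20 genes; an enhancer carries each own-pool gene with
probability `p_in = 0.7` and each foreign gene with `p_out = 0.03`, so
within-module target overlap is hypergeometrically significant and
cross-module overlap is not. Sequences derive from one random ancestor
per module (module-specific lengths 80–380 bp, 5% point mutations);
distinct module lengths are what keeps cross-module percent identity low
under the alignment-based scorer, since unrelated equal-length
nucleotide sequences already share substantial identity by chance.
Each disease receives 5 associations drawn from one module (signal
regimes) or uniformly (null regime). Regime `B` shuffles the
enhancer-to-sequence assignment (gene layer informative only), regime
`C` shuffles the target-set assignment (sequence layer only). These
sizes keep a full replicate — generation, three networks, 24
cross-validated walks — at roughly a third of a second, so the test
suite's replicate loops (20 signal, 50 null, 20 + 20 single-signal)
finish in about a minute.

Passing these tests shows that the machinery recovers planted block
structure through either layer and stays at chance under the null. It
does **not** show performance on real data: real enhancer catalogs have
heavy-tailed target-set sizes, overlapping and nested modules,
similarity matrices from a real aligner rather than the surrogate, and
disease ontologies far deeper than the toy tree. The published network
sizes and cross-validated AUCs for the real catalogs are therefore audit
references to check against when real inputs are supplied, not
quantities the fixtures reproduce.

## Limitations

* Enhancer–gene links are taken as given (no tissue or cell-type
  specificity, no chromatin-interaction evidence); the shared-gene layer
  inherits whatever biases the source catalog carries.
* Exactly two enhancer layers are wired (gene + sequence); the assembly
  code is written against a layer list, but additional layers are not
  exposed.
* Downstream evidence gathering (GWAS lookup, LD pruning, pathway
  enrichment of candidates) depends on external services and is out of
  scope; `rank_novel()` emits target genes alongside candidates so such
  lookups can be run on its output.
* Dense base-R matrices are used throughout: right-sized for catalogs of
  hundreds to a few thousand enhancers, not for genome-scale multiplexes.
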