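---
title: "Distributed gene order distances: model, estimator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed gene order distances: model, estimator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Prokaryotic chromosomes are circular, and their gene order decays under
inversions and transpositions. The distributed gene order distance treats
the *circular order of small, well-separated ortholog samples* as the
observable. One draw selects `k` ortholog pairs (six by default, five as a
lighter variant) uniformly without replacement from the orthologs shared
by two genomes, subject to a spacing rule, and asks whether the `k` genes
occur in the same circular order in both genomes. A genome has no
distinguished origin or reading direction, so "same order" means equality
of the two cyclic sequences up to rotation *and* reflection, and strand is
ignored. The raw distance is the failure fraction `D = k_fail / n` over
`n` valid draws.

Two design facts follow directly from the combinatorics:

* Six labels admit exactly `60 = 5!/2` circular arrangements (rotations
  and reflections identified), so exactly `12` of the `720` linear orders
  pass the test against any fixed reference. Both counts are verified by
  exhaustive enumeration in the test suite (`circular_order_classes()`).
* Hence two genomes with independently random gene orders still agree with
  probability `1/m`, `m = 60`, and `D` saturates at `(m-1)/m = 59/60 ≈
  0.983` rather than 1. For five genes `m = 12` and the ceiling is `11/12`.

The spacing rule requires every pair of drawn orthologs to be at least
`min_gap` genes apart (circular index distance, default 5) **in both
genomes**. Its purpose is biological: genes of one operon travel together,
so adjacent-gene conservation would be dominated by operon structure
rather than genome-scale order. We read "5 genes away" as circular index
separation `>= 5` (i.e. at least four intervening genes); the parameter is
configurable.

### Corrections

As with nucleotide distances, the observable saturates and must be mapped
to an additive scale. With `a = (m-1)/m`:

* **Adapted Jukes-Cantor**: `D_JC = -a * ln(1 - D/a)`. Monotone, zero at
  zero, undefined for `D >= a` — which happens routinely for distant
  genome pairs.
* **Tajima series**: the falling-factorial analogue
  `sum_{i=1..k} k^(i) / (i a^(i-1) n^(i))` with `k^(i) = k!/(k-i)!`.
  Because the unbiased moments `k^(i)/n^(i)` replace the powers `D^i`,
  the sum is finite for every `k <= n`; it agrees with the logarithm to
  within 0.01 for `D` up to 0.9 at `n = 10^6` (asserted in tests) and
  remains usable at and beyond the saturation point, at the price of very
  large, noisy corrections there.
* **Simple logarithm**: `D' = -ln(1 - D)`, the computationally cheapest
  transform. The five-gene distance corrected with the six-gene constant
  `m = 60` tracks `-ln(1-D)` closely (within 2% below `D ≈ 0.7`,
  drifting to ~5% by `D = 0.9`), which is why the five-gene variant is a
  practical stand-in for it.

Numerical choices: the Tajima sum is accumulated by the term recurrence
`t_{i+1} = t_i * (k-i)/(n-i) * i/(i+1) * m/(m-1)` and truncated when the
relative term falls below `1e-12` (or at `i = k`). Terms decay
geometrically for `D` well below `a`; near saturation the truncation can
require on the order of `10^5` terms, which is still immediate.

## The Monte Carlo sampler

`sample_raw_distance()` performs `n_iter` *valid* draws per replicate
(default 100,000; 100 replicates per pair by default, poolable to 10
million draws). Draws violating spacing in either genome are discarded and
redrawn — they do not count toward `n`, keeping `D` a proper conditional
frequency. If a probe of 10,000 attempts yields a valid fraction below
0.001, the sampler aborts with an "unsatisfiable spacing" error (for
example, six positions pairwise `>= 5` apart cannot exist on a 20-gene
circle).

Determinism: every `(genome pair, replicate)` gets its own RNG substream
derived from the base seed by string hashing (`derive_seed()`), so results
are independent of execution order, replicates are independent by
construction, and a rerun of the same configuration is byte-identical
(asserted on the full pipeline in the tests).

Multi-replicon genomes: the default `largest` mode keeps only the largest
replicon of each genome (lexicographic tie-break). The `per-replicon` mode
instead draws a replicon pair with probability proportional to its number
of co-resident shared orthologs and then draws all `k` orthologs from that
pair; replicon pairs sharing fewer than `k` orthologs get zero weight.
Linear contigs are handled by degrading the order test to linear order
(identity or reversal, no wrap-around); a mixed circular/linear pair is
tested linearly.

`exact_raw_distance()` enumerates *all* spacing-valid `k`-subsets (refusing
beyond `10^7`) and returns the exact expectation the sampler estimates; the
test suite requires `|D_hat - exact| < 3 SE` across seeds, and an
independent membership-style implementation of the order test guards the
rank-arithmetic one used in the vectorized hot path.

## The synthetic-data generator

`random_genome()`, `apply_events()`, and `evolve_along_tree()` produce
circular genomes diverging by inversions (reversing a circular segment and
flipping strands — exercising the strand-independence contract) and
optionally transpositions. Gene content is conserved exactly by every
event, and descendants keep ancestral gene ids, so orthology between
simulated genomes is the identity map. What the generator deliberately
does **not** emulate: gene gain and loss, duplication, horizontal
transfer, operon structure, or the replication-axis bias of real
inversions. Passing tests therefore demonstrate correctness of the
estimator and pipeline under the rearrangement model, not robustness to
annotation noise or reticulate evolution.

Segment lengths default to geometric with `p = 0.05` (mean ~20 genes):
most fixed rearrangements are local, and this regime yields a gradual,
measurable divergence axis. The `uniform(1..L/2)` option models the
occasional genome-half inversion; under it a 1000-gene genome reaches
order randomization within a few dozen events, which makes it the right
control for saturation behaviour but useless as a gradual divergence dial.

### Study conditions used by the validation experiments

Problem sizes were chosen so the whole suite runs in minutes while keeping
each experiment statistically decisive:

* **Saturation**: two 1000-gene genomes with independently shuffled
  orders, `k = 6`, `min_gap = 5`, 100,000 draws; `D` must sit within 3
  standard errors (~0.0012) of 59/60.
* **Sampler-vs-oracle**: 30-gene fixtures with `min_gap = 2` (on a 30-gene
  circle, `min_gap = 5` admits only the five equally spaced hexagons),
  exhaustive enumeration against 50,000-draw estimates, three seeds.
* **Topology recovery**: a balanced 8-leaf phylogeny with terminal
  branches of 15 expected inversions and internal branches of 40 (root
  split 20+20), 1000-gene genomes, 5000 draws per pair, 20 seeds, success
  being exact (RF 0) NJ recovery from Tajima-corrected distances in at
  least 18 of 20. The branch lengths come from a power consideration:
  a branch of `b` Poisson events realizes `b ± sqrt(b)`, so internal
  branches must carry enough events that the split signal exceeds both
  this process noise and the sampler noise (`SE(D) ≈ 0.005` at 5000
  draws); internal branches of ~15 events fail irrecoverably on a few
  seeds even with near-exact distances, while 40-event internals are
  recovered reliably.
* **Monotonicity**: mean Tajima-corrected distance over five *cumulative*
  event trajectories (checkpoints every 50 events, 0 to 500) must be
  rank-correlated with the event count at Spearman > 0.95. Cumulative
  trajectories are essential: independent realizations per checkpoint
  carry trajectory-to-trajectory process variance that swamps the
  flattening trend near saturation.

## Trees, support, agreement, and the hierarchical builder

Neighbor joining is delegated to `ape::nj()`, the standard Saitou-Nei
implementation; `nj_tree()` adds strict input checking (at least three
taxa, no undefined entries — callers must prune or impute pairs whose
correction was undefined) and clamps negative branch-length estimates to
zero, transferring the deficit to the sibling branch. Tie-breaking inside
NJ follows ape's deterministic internal order rather than an explicit
lexicographic rule; identical inputs give identical trees, which is the
property the pipeline relies on. Midpoint rooting is `phangorn::midpoint()`
(two-leaf trees special-cased; all-zero branch lengths rejected as
undefined).

Robinson-Foulds distances and replicate support both rest on one primitive,
`bipartition_keys()`: the canonical label-set encoding of each non-trivial
split. RF is the symmetric difference of key sets after restriction to the
shared leaf set (undefined below four shared taxa; "congruent" in this
package always means restricted RF 0, vacuously true below four shared
taxa). The implementation is cross-checked against `phangorn::RF.dist` in
the tests. Support counts, in the replicate-resampling sense, annotate
each internal edge of a pooled-distance reference tree with the number of
replicate-matrix NJ trees containing the same bipartition — this is
resampling of the Monte Carlo estimator, not a data bootstrap.

Finding the largest taxon subset on which a collection of trees agrees is
NP-hard for more than two trees, so `agreement_subtree_exact()` does an
exhaustive largest-first subset search (refusing above 20 taxa, and
returning *all* maximum agreement sets), while
`agreement_subtree_heuristic()` greedily deletes the taxon whose removal
most reduces total pairwise RF conflict (lexicographic tie-break) until
all restricted pairs agree. The heuristic's output is always a valid
agreement set; on perturbation fixtures of up to 12 taxa it stays within
two taxa of the exact optimum (asserted over 50 fixtures). At realistic
scale it approximates, not reproduces, what an exhaustive search would
find.

The hierarchical builder formalizes "grow trees from the distances you
trust most". Distances are ranked ascending (ties broken by pair label;
undefined entries last and excluded from the graph). Walking down the
list, each included pair may complete cliques of four or more taxa whose
pairwise distances are all present; each such clique gets an NJ tree from
the full submatrix. A candidate is rejected if incongruent with any
retained tree; otherwise it is retained, absorbing retained trees it
contains, and pairwise combination is attempted by building NJ on the
union taxon set, kept only when the union tree's restrictions reproduce
both originals and stay congruent with the rest of the ledger. Two
under-specified points were resolved as follows: only cliques containing
the newly added pair are (re)built at each rank, and combination is
attempted against every ledger entry in order once per admission. Each
retained tree records the rank at which it first formed and the rank of
the last pair incorporated. The second round (`add_single_taxa()`) visits
outside taxa in order of their best-ranked distance to any tree member and
accepts an addition only if the NJ tree on the union leaves the prior
topology unchanged, repeating until a full pass accepts nothing. On fully
additive inputs the procedure provably has nothing to reject and returns
the generating tree (asserted over random instances); a constructed
adversarial taxon whose distances pull opposite ends of the tree together
is rejected in both rounds.

## Orthology and gene content

`reciprocal_best_hits()` consumes standard 12-column tabular similarity
hits in both directions, collapses multiple HSPs per (query, subject) to
the maximum bitscore, and pairs `a` with `b` only when each is the other's
unique top-scoring hit; an exact bitscore tie for the top disqualifies the
query (deterministic and conservative — whether the original analyses
ranked by bitscore or E-value is not documented, and bitscore is the
tabular standard). Gene content similarity `S` is the shared ortholog
count over the gene count of the smaller genome, computed genome-wide
(content is not replicon-restricted even when order sampling is) and after
exclusion masks; distance is `-ln S` or `1 - S`. `correlate_matrices()`
performs the ordinary least-squares comparison between any two distance
matrices over their shared genome pairs, with an optional threshold on the
predictor, as used to compare order distances with rRNA or protein
distances supplied in PHYLIP square format.

## Degenerate inputs and failure modes

* Fewer shared orthologs than `k`, or no replicon pair sharing `k`
  orthologs in per-replicon mode: estimation error.
* Spacing unsatisfiable: detected by the rejection probe, reported as such.
* `D >= (m-1)/m`: the logarithmic corrections signal "undefined" rather
  than returning infinities; matrix assembly stores NA and `nj_tree()`
  refuses NA entries explicitly, so saturated pairs must be pruned,
  imputed, or corrected with the Tajima series (the pipeline default).
* Ribosomal-gene style exclusions are masks on the genome record
  (`exclude_genes()`); masked genes leave both the order sampling pool and
  the content counts, and the sampler's optional audit log (one line per
  counted draw: gene ids, positions, verdict) supports composition
  analyses of the sampled sets.

## Known limitations

The estimator assumes one-to-one orthology and ignores paralogy; the
simulator omits content evolution entirely; agreement subtrees at scale
are heuristic; and the hierarchical builder's clique scan is quadratic in
taxa per rank, fine for hundreds of taxa but not thousands. Horizontal
transfer of large blocks imports conserved order and is indistinguishable
from vertical signal by construction.
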