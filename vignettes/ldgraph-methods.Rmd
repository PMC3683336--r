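---
title: "Modelling fine-scale LD with decomposable graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fine-scale LD with decomposable graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldgraph)
```

## The model

Linkage disequilibrium is usually summarized marginally, pair by pair.
`ldgraph` instead models the *joint* distribution of all SNPs on a
chromosome as a discrete Markov network restricted to the decomposable
class: the dependence graph is chordal, so the maximum likelihood estimate
factorizes in closed form over cliques and separators of a junction
forest,

$$\hat f(x_V) \;=\; \frac{\prod_{C} \hat p(x_C)}{\prod_{S} \hat p(x_S)},$$

with clique and separator probabilities estimated by relative cell counts.
An absent edge between two SNPs means conditional independence given some
intervening set (the global Markov property). That conditional — rather
than marginal — notion is what makes the graphs incisive: two loci
flanking a polymorphic site may be strongly associated marginally yet
conditionally independent given it, and the graph shows only the edge
structure that cannot be explained away.

The data are an `N x p` complete matrix of small integer codes: unphased
genotypes (0/1/2, ALT-allele counts) or phased haplotypes (0/1, two rows
per individual, so the effective sample size is twice the number of
individuals — intentionally so, since the criterion's `N` is the number of
rows supplied). Missing values are a hard error; imputation belongs to
dedicated external tools.

## Model selection

Graphs are scored by `IC(G) = -2\hat\ell_G + \alpha\,\dim(G)` with
`alpha = log N` (BIC, default; consistent and conservative) or `alpha = 2`
(AIC). Model dimension is the classical parameter count
`sum_C (prod r_v - 1) - sum_S (prod r_v - 1)`. Two practical choices
deserve a note:

* **Level counts.** `r_v` is the number of *observed* codes in column v,
  not the theoretical 2 or 3. A monomorphic column then contributes zero
  dimension and zero information to any move, so such columns are retained
  with a warning instead of being dropped — their incident edges simply
  never enter the model.
* **Dimension mode.** In sparse tables not all nominal parameters are
  estimable. The default (`nominal`) uses the formula above, which is what
  the single-edge dimension difference
  `(r_a - 1)(r_b - 1) prod_{s in S} r_s` assumes; an `observed` mode
  replaces each level-count product by the number of observed
  configurations (inclusion–exclusion for deltas). Both are exposed;
  nominal is the default because it is the convention the criterion's
  consistency results are stated for, and because the adjustment used in
  practice varies between implementations.

The search is greedy and stays inside the decomposable class throughout.
The *forward* phase starts from the **skeleton** — edges between
physically adjacent SNPs — and repeatedly adds the eligible edge with the
most negative `d_IC`, where a move's deviance change is `-2 N \hat I(a;b|S)`
(empirical conditional mutual information given the would-be clique's
separator). Starting from the skeleton, rather than the empty graph, bakes
the physical ordering into the search space: a distal pair can only become
adjacent once enough intermediate edges exist to avoid chordless cycles,
so only *local* LD is modelled and spurious long-range edges are
implicitly suppressed. The *backward* phase prunes any edge (skeletal ones
included) whose removal improves the criterion — adjacent SNPs are not
always in LD (recombination hotspots, assembly errors), and zero-height
cuts in the pruned graph are direct evidence of such breaks.

Eligibility of a single-edge move is tested in O(neighbourhood) time: an
edge (a, b) can be added iff the common neighbourhood `S = N(a) ∩ N(b)` is
complete and separates a from b (or the endpoints lie in different
components); it can be removed iff `S` is complete. In both cases
`{a, b} ∪ S` is the unique clique hosting the move, and `S` its scoring
separator — the contract is chordality of the perturbed graph, which the
test suite enforces by exhaustive enumeration on up to six vertices. Ties
between equally scoring candidates are broken by the lexicographically
smallest pair, purely for cross-platform determinism; the criterion is
silent about ties and they are vanishingly rare on real data.

## The fast (blockwise) algorithm

The forward phase dominates the cost for chromosome-scale p. The fast
variant runs it independently on overlapping blocks of `L` SNPs (default
100) with overlap `K` (default 20), each block from its own internal
skeleton, then folds the block estimates left to right. At each fold the
cut point is

$$m^* = \max\{w : (v, w) \in \text{cumulative edges},\; v \le s - 1\},$$

where `s` is the block start: cumulative edges with right endpoint at most
`m*` are kept, block edges reaching beyond `m*` are taken from the new
block. The rationale is that a *marginal* model over a block sees the
boundary of the omitted variables as spuriously associated, so each
estimate is trusted only away from its own boundary. If `m*` reaches the
new block's right-looking edges the overlap was too small; this is a
warning, not an error — the run proceeds, and choosing `K` at least about
twice the expected maximum width avoids it. Stitching can create chordless
cycles, so the folded graph is re-triangulated by maximum cardinality
search (MCS, lowest-index tie-breaking; fill edges from the elimination
game along the reverse visit order) before the ordinary backward phase
runs on the full data. For fixed `L` the whole construction is linear in
p, which the test suite checks as a wall-clock ratio rather than an
absolute time.

A single left-to-right fold (cumulative graph playing the role of block 1)
is the only part of the multi-block generalization that is not forced by
the two-block rule; it is fixed here for determinism.

## Complexity and diversity summaries

For each inter-SNP interval i the *height* counts edges spanning it and
the *width* their maximal index span; `h_i = 0` certifies full
independence of the left and right segments, `h_i = 1` independence given
the single flanking SNP. Haplotype diversity is measured by the entropy
`H = -sum f_i log f_i` of distinct-row frequencies in sliding windows
(default 7 SNPs, natural logarithm throughout — reported values depend on
this base, so it is worth stating prominently). Windows are assigned to
the interval at their centre (ties to the left; the assignment is a
convention fixed for determinism) when grouping median entropies by height
or width. Sample trees give an exact trie summary of local haplotypes, and
`pairwise_ld()` provides conventional r² matrices (squared Pearson
correlation of codes; for phased 0/1 data this is the classical haplotype
r², for genotypes the composite analogue).

## Simulation and the synthetic generator

`fit_model()` + `sample_model()` simulate from any fitted model by
traversing each junction tree from the clique containing its
lowest-indexed vertex, drawing the root clique from its table and each
child's new variables from the conditional given the drawn separator.
Separator consistency of the tables is asserted whenever a model is
constructed, which is exactly the condition under which this sampler is
exact.

`random_ld_model()` generates the stated synthetic world for testing:
skeleton plus `n_extra` random decomposability-preserving edges of span at
most `max_width`, with clique tables drawn root-to-leaf from symmetric
Dirichlet distributions (concentration 1 by default; smaller values give
more skewed, stronger-LD tables). It emulates the *local*, bounded-width
structure of chromosome-wide LD graphs and gives exact knowledge of the
generating model. It does **not** emulate several features of real panels:
allele-frequency spectra shaped by demography, LD decay with physical
distance, genotyping error, or tables estimated from a real population —
in particular, a Dirichlet(1) table routinely produces edges whose
conditional dependence is too weak to detect at moderate N. A green
recovery test therefore establishes that the search finds what the data
support, not that every generated edge is recoverable: in the package's
own structure-recovery experiment (p = 200, 40 extra edges, N = 4000, ten
seeds) the median false-inclusion rate is 0, while the median
false-negative rate is about 0.06 — and post-hoc scoring shows the missed
edges would not improve the criterion if added, i.e. they are
statistically invisible at that sample size rather than missed by the
search.

## Numerical choices and degenerate inputs

* Natural logarithms everywhere; criterion values in nats.
* `0 log 0 = 0` in likelihoods, entropies and mutual information; CMI is
  clamped at 0 against floating-point negatives.
* The incremental IC tracked across greedy moves is recomputed from
  scratch at the end of each phase and must agree within `1e-6`
  (relative); disagreement is surfaced as a warning on the fit result.
* Monomorphic columns: retained, zero-dimension (see above); their r² is
  reported as 0 with a `monomorphic` flag rather than NA.
* Empty separator sets (disconnected components) contribute nothing to
  likelihood or dimension; cross-component additions are always legal with
  an empty conditioning set.
* Graph files are 1-based; a `# p:` header preserves trailing isolated
  vertices through round-trips.

## Known limitations

* Greedy search finds a local optimum of the criterion; the backward pass
  can in principle re-open a profitable addition, which a single
  forward-backward sweep (by design, following the reference algorithm)
  will not revisit.
* Only local LD is modelled; long-range or inter-chromosomal association
  is out of scope, as are phasing and imputation.
* The layout heuristic (alternating-sign excess degree, exponentially
  smoothed left to right with `lambda = 0.7`) is a deterministic,
  dependency-light stand-in for a layered graph layout; it preserves the
  diagnostic reading — flat where serial, displaced where complex — but
  not any particular rendering.
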