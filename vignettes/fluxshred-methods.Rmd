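---
title: "Flux-weighted ShReD modularity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-weighted ShReD modularity: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxshred)
```

## The problem

Modularity analysis asks which parts of a network form cohesive functional
units. For metabolism, almost all graph-based analyses use a single static
topology, yet the engagement of each enzyme changes with the physiological
state. `fluxshred` implements a reaction-centric, flux-aware modularity
method: the nodes of the graph are reactions (enzymes), an edge runs from
reaction $R_i$ to $R_j$ when a product of $R_i$ is a reactant of $R_j$, and
the *distance* of that edge reflects how strongly the two reactions are
engaged with each other under a measured flux distribution. Metabolites are
deliberately not module members — they are shared resources — and cofactors
(ATP, NAD(H), NADP(H), CoA) are retained as edge mediators because they are
the carriers of exactly the long-range cycles this method is built to
detect.

## Shortest Retroactive Distance (ShReD)

The cyclical coupling of a reaction pair $(i, j)$ is measured by the
Shortest Retroactive Distance,

$$\mathrm{ShReD}_{ij} = d(i \to j) + d(j \to i),$$

the length of the shortest directed path each way: the shortest cyclical
route through both reactions. Pairs with no route in one direction are
*unreachable* and carry no value. The two legs are independent shortest
paths and may share edges; nothing in the definition requires the combined
route to be a simple cycle.

Three edge-distance schemes are supported:

* **unit** — every edge has distance 1; ShReDs measure pure topology.
* **flux** — the distance from any producer of metabolite $M$ to a consumer
  $R_j$ is the inverse of $R_j$'s share of $M$'s production:
  $D_{ij} = \sum_k v_k c_k \,/\, (v_j |c_j|)$, where the sum runs over the
  producers of $M$. A consumer drawing 60 of 100 units sits at distance
  $100/60 = 1.67$. The metabolite pool is treated as homogeneous, so the
  distance is identical no matter which producer the edge leaves — even a
  producer contributing 0.01 of 100 units is assumed to send 70% of that
  trickle to a consumer drawing a 70% share. Both sides are scaled by the
  stoichiometric coefficients so that the reciprocal distances of a
  metabolite's consumers always sum to exactly 1 (a property the test
  suite enforces).
* **degree** — the distance is the number of distinct reactions consuming
  the mediating metabolite; a static connectivity-based comparator that
  needs no flux data.

Because flux distances are inverse shares, a near-zero flux produces an
arbitrarily long edge, and a ShReD through it could exaggerate differences
between fluxes that are statistically indistinguishable from zero. ShReDs
are therefore **capped** (default 100, configurable): larger values are
recorded at the cap with a `capped` status. Reactions with flux below
`zero_tol` (default $10^{-9}$ in flux units, needed as a division floor)
keep their node but contribute and draw no edges.

When several metabolites mediate the same ordered reaction pair, the
collapsed distance is the minimum — under shortest-path semantics the
longer parallel edges can never be used — with ties broken by lexicographic
metabolite id so exports are deterministic. Whether one should instead
aggregate parallel interaction strengths is a legitimate sensitivity
question; the minimum is the only choice consistent with shortest-path
semantics, so the alternatives are not implemented.

## The rank-based modularity matrix

Flux weighting skews ShReD distributions strongly to the right (amino-acid
reactions carrying negligible flux produce enormous distances), so the
arithmetic mean is not a usable "expected" distance. Each pair is instead
*ranked* against the ShReDs involving either of its members:

$$V_{ij} = \ln \frac{p_{ij}}{1 - p_{ij}},$$

where $p_{ij}$ is the fraction of comparable ShReDs involving $R_i$ or
$R_j$ (excluding the pair itself) that are longer than
$\mathrm{ShReD}_{ij}$. Capped entries participate at the cap value;
unreachable pairs are excluded from numerator and denominator and get no
matrix entry. A pair out-ranked by 10 of its 25 comparables has
$p = 0.4$ and $V = -0.41$. $p$ is clamped to
$[p_\mathrm{floor}, 1 - p_\mathrm{floor}]$ with $p_\mathrm{floor} = 0.01$,
so the most extreme entries are $\pm 4.60$ — on the same order as the rest
of the matrix. (The clamp is symmetric by construction; only the lower
floor is strictly required, but an unclamped $p = 1$ would be infinite.)

**Tie handling.** Ties are counted with mid-ranks: a comparable ShReD equal
to $\mathrm{ShReD}_{ij}$ contributes $1/2$ to the "longer" count. This
choice matters. With capped values all ties concentrate at the cap, and a
subnetwork whose ShReDs are all equal must be *neutral* ($p = 0.5$,
$V = 0$, no rank-enriched split exists) rather than extreme: counting ties
as "not longer" would assign every pair of an all-tied subnetwork the floor
value $-4.60$ and drive the optimizer toward arbitrary balanced splits of
subnetworks that contain no ranking information at all. Mid-ranks keep the
matrix antisymmetric around the median ($V(p) = -V(1-p)$) and leave the
worked-example arithmetic untouched when no ties are present. Because $p$
depends only on ranks, $V$ is invariant under uniform rescaling of all
ShReDs (also property-tested).

## Maximizing the modularity score

A bipartition is an assignment vector $s \in \{-1, +1\}^n$ scored by

$$Q = \sum_{i \ne j} V_{ij} s_i s_j = s V s^\top$$

(ordered pairs, diagonal excluded, undefined entries contributing zero; the
sum over ordered pairs is the literal quadratic form — the maximizer is
unchanged if unordered pairs are used, only the magnitude of $Q$ halves).
$Q$ is invariant under $s \to -s$.

Subnetworks of up to 8 nodes are solved exactly by enumerating the
$2^{n-1}$ sign-distinct assignments. Larger subnetworks use a genetic
algorithm with the following defaults: population 100, truncation
selection of the top 60% by $Q$, uniform-agreement crossover (elements on
which both parents agree are inherited; disputed elements are drawn
uniformly), 20% per-element sign-flip mutation on offspring, and
termination when the ordinary-least-squares slope of the population's mean
$Q$ over the last 20 generations has absolute value below 0.05 (hard stop
at 500 generations). The best assignment ever seen is returned, so the
reported $Q$ never decreases. Two implementation details worth knowing:

* parents are retained (elitist truncation); full generational replacement
  with a 20% per-element mutation rate is too disruptive to converge on
  instances of ~20 nodes and up;
* because $s$ and $-s$ encode the same partition, the second parent is
  sign-aligned to the first before crossover. Without this, two parents
  encoding the identical partition as complementary vectors would breed an
  essentially random child.

Each partition call derives its own RNG stream from the global seed and
the module id, so whole trees are reproducible end to end. A
leading-eigenvector solver (`spectral_bipartition()`) is included purely
as a comparator; on the instances the test suite generates it never beats
the exact optimum and the GA reaches the exact optimum in at least 95% of
seeded trials on instances small enough to enumerate.

## The hierarchical module tree

The recursion at each node set:

1. split into weakly connected components (red, "component" links) if
   there are several;
2. for a connected subnetwork of two or more reactions, *recompute* the
   ShReD matrix on the induced subgraph (paths may not leave the
   subnetwork being partitioned), build $V$, and maximize $Q$;
3. accept the bipartition (black, "partition" links) only if the best
   $Q$ is strictly positive and at least one daughter still contains a
   directed cycle (a strongly connected component of two or more nodes);
4. stop at singletons or when no acceptable bipartition exists.

Requiring only *one* daughter to keep a cycle lets single reactions peel
off a large subnetwork without blocking its further partitioning. The
$Q > 0$ requirement is the natural stop rule: a non-positive optimum means
no rank-enriched split exists. Depth and height of a module count black
links only. Reusing the root-level ShReD matrix at deeper levels instead
of recomputing is available as a switch (`recompute_shred = FALSE`) for
sensitivity comparison only.

## Scoring and comparing partitions

* **Homogeneity index** of a module: the fraction of its reactions
  belonging to its most common canonical pathway group; summarized as an
  unweighted mean per height (height 0 = terminal modules).
* **Partition score** $H_{ij} = (\mathit{Shared} - 1) \cdot
  \tfrac12 (1/m_i + 1/m_j)$, where $\mathit{Shared}$ counts the hierarchy
  levels containing both reactions and $m$ is each reaction's terminal
  black-link depth. $H = 0$ means immediate separation; $H = 1$ means
  co-assignment down to equal terminal depth. `fluxshred` counts the root
  and black partition modules in $\mathit{Shared}$ and treats red
  component modules as bookkeeping: since component formation adds a
  module without adding depth, counting red modules would push $H$ above 1
  exactly when a partition disconnects a daughter while the pair stays
  together, breaking the score's stated range. With black-only counting,
  $\mathit{Shared} - 1 \le \min(m_i, m_j)$ and $H \in [0, 1]$ always
  (property-tested on randomly partitioned fixtures). Reactions isolated
  before any black partition ($m = 0$) get $H = 0$ by convention.
* **Robust pairs**: a pair whose $H > 0.7$ and root-network $V > 3.0$
  (strict inequalities) in every examined metabolic state. Pairs whose
  root ShReD is unreachable have no $V$ coordinate and are excluded and
  reported separately.
* **H-V distance** between states: each state's $H$ and $V$ coordinates
  are divided by that state's mean (over defined pairs), and the per-pair
  Euclidean distance between normalized coordinates is reported. If a
  coordinate's mean is numerically zero the implementation falls back to
  the mean absolute value with a warning; if that is also zero it stops
  with a diagnostic.

## Flux estimation

When only exchange-rate measurements are available, fluxes are estimated
by minimizing the sum of squared differences between measured and computed
exchange rates subject to the steady-state balances $S v = 0$ over
internal metabolites — no metabolic objective is assumed. The equality
constraints are eliminated with an orthonormal null-space basis and the
reduced least-squares problem is solved by pseudoinverse, which yields the
minimum-norm optimum when the problem is underdetermined; the dimension of
the optimal set is reported as the remaining degrees of freedom.
Irreversible reactions driven negative are pinned to zero and the system
re-solved (iterative pinning rather than a full active-set method: pins
are never released, which is sufficient for the sign-feasibility cases
this workflow encounters and is always verified against the balance
residual). Measurements can optionally be weighted by inverse variance.
The intended primary workflow remains consuming published flux tables
directly; the estimator exists for states where only exchange rates were
measured. Boundary handling: metabolites appearing only in exchange
reactions are external and excluded from the balances; exchange reactions
are auto-detected as one-sided equations.

## Synthetic fixtures: what they emulate and what they do not

`make_figure7a()` and `make_figure7b()` reproduce the two canonical
edge-weighting situations (one producer with two consumers; two producers
feeding one homogeneous pool), closed with boundary reactions so that
$S v = 0$ holds exactly. `make_figure8_like()` is a five-reaction
cofactor-mediated cycle. `make_random()` plants `cycle_count` directed
reaction cycles joined in a chain by *pairs* of opposed bridge reactions;
because each bridge pair is itself a closed flux mode, every generated
state satisfies $S v = 0$ exactly by construction rather than by fitting.
Defaults: 12 cycle reactions, 2 cycles, cycle fluxes drawn uniformly from
50–150 (a realistic central-carbon-to-side-path contrast), bridge flux 1%
of the smaller adjoining cycle flux.

These fixtures emulate the *structure* the method targets — strong
cyclical coupling within modules, weak coupling between them — but not
several features of real metabolic networks: no shared cofactor pools
spanning modules, no reversible reactions in the generated states, no
measurement noise, and bridges that are topologically sparse. That last
point matters for interpreting the recovery benchmark: because the planted
cycles are also *topologically* obvious, unit-weighted partitioning
recovers them essentially perfectly, so the flux-vs-unit comparison on
these fixtures tests parity rather than superiority. Passing it shows the
flux-weighted pipeline does not *lose* planted structure; it cannot show
the flux-weighted scheme's advantage on networks whose topology is
misleading, which is the situation real flux data addresses.

## Known limitations

* **Cap-induced ties.** With very weak bridges (ratio ~0.01), every
  cross-module ShReD exceeds the cap and ties at 100. The modularity
  matrix then carries no information about *which* modules belong
  together, the root $Q$ landscape can have exactly tied global optima
  with different downstream consequences, and a daughter subnetwork whose
  comparable ShReDs are all tied is neutral ($V \equiv 0$), so recursion
  stops there. On the randomized recovery battery this occasionally
  leaves two planted cycles merged in one leaf, which is why the
  flux-weighted agreement can fall marginally below the unit-weighted
  ceiling on a few seeds. This is a property of the capped rank statistic
  under these conditions, not of the optimizer; raising the cap
  (`cap` is configurable everywhere) restores the ranking signal.
* **GA stochasticity.** On subnetworks above the exhaustive threshold
  (8 nodes), different seeds can land on different near-optimal splits.
  Trees are seed-reproducible, but biological conclusions should be drawn
  from features stable across seeds (the robust-pair machinery exists for
  exactly this reason).
* **Problem sizes.** The test suite works at desk scale by design: random
  oracle graphs of 3–8 nodes (where exhaustive path enumeration and
  assignment enumeration are feasible), planted-cycle fixtures of 9–18
  cycle reactions, and a 72-reaction single-cycle network for the
  pair-count check. The algorithms themselves are exact at any size;
  runtime grows with the all-pairs shortest-path recomputation per
  recursion level (~10² nodes is comfortable).
* **No SBML.** Models are flat TSV/JSON tables; genome-scale exchange
  formats are out of scope.
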