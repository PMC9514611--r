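---
title: "Graph evaluation of Laplace-transformed coalescence times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph evaluation of Laplace-transformed coalescence times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfcoal)
```

## The model

`gfcoal` works with the structured coalescent: a sample of lineages drawn
from a set of demes, traced backwards in time through pairwise coalescence
(within a deme, at rate $\lambda_d = N_{ref}/N_d$ per pair), unidirectional
migration (each lineage in the source deme moves along a declared route at a
constant per-lineage rate), and at most one *discrete* event — a population
split which, viewed backwards, is a mass migration moving every lineage of
its source demes into a destination deme at a fixed time $T$. Time is
measured in units of $2N_{ref}$ generations, so all rates are relative to
the pairwise coalescence rate in the reference deme.

The quantity of interest is the joint distribution of the total branch
length $L_k$ of every *branch type* $k$ — the equivalence class of branches
labeled by the samples they subtend. With phase information a sample of $n$
lineages distinguishes $2^n - 2$ types; labeling samples only by their deme
of origin collapses types to per-deme subtended-count vectors, and
discarding root information folds each type with its complement relative to
the full sample. Both reductions are pure relabelings of the dummy
variables, so the same machinery covers the phased/rooted and the
folded/unphased regimes.

Under an infinite-sites mutation model at scaled block rate $\theta$
(mutations mark type $k$ at rate $\theta/2$ per unit branch length), the
probability of observing $k_i$ mutations on each type within a short
non-recombining block is a multivariate Poisson mixture over $(L_1, \dots,
L_K)$. The Laplace transform
$f^\star(\omega) = E[e^{-\sum_k \omega_k L_k}]$ makes this computable: the
transform of an interval length is exactly the probability that a Poisson
marking process leaves the interval unmarked, and the mixture probabilities
are, up to sign and scale, Taylor coefficients of $f^\star$.

## The state graph as a computational graph

All coalescent histories of the sample form a single rooted directed acyclic
graph over states $\Omega = (\Omega_1, \dots, \Omega_D)$, the per-deme
collections of extant lineages. States that are equal as label multisets
are merged (for unphased samples this is what keeps the graph polynomially
smaller than the space of fully labeled histories). Every edge carries a
competing-risk factor
$$f^\star_a = \frac{p_a \cdot r}{q_a \cdot r}, \qquad
  r = (\lambda, \delta, \omega),$$
where $q_a$ counts, for the parent state, the multiplicity of every
possible event *and* the number $o_k$ of extant branches of each type, and
$p_a$ is one-hot on the realized event. Because transforms of sums of
independent waiting times multiply, the full transform is the sum over all
root-to-absorption paths of the product of edge factors. `buildStateGraph()`
generates this recursively (BFS order, equations deduplicated by their
$(p, q)$ value); `evaluateLaplace()` computes the path-product sum without
enumerating paths by the propagation algorithm: visiting nodes children
first, each node adds its children's values and multiplies its own —
addition before multiplication, which is what makes series propagation
affordable later.

For models without a discrete event the computational graph is simply the
edge-to-node dual of the state graph, so its node count equals the
state-graph edge count. For the structural summaries printed by
`graphStats()` we report both the number of states and the number of
computational-graph nodes; the latter is the natural size measure of the
evaluation problem.

### Discrete events

A discrete event is first treated as a competing exponential process with
dummy rate $\delta$; conditioning on the event happening at time $T$ then
amounts to an inverse Laplace transform in $\delta$ of $f^\star/\delta$.
Along any path, only the equations up to and including the $\delta$-edge
contain $\delta$, each as a factor $1/(c_i + \delta)$ with
$c_i = c_i(\omega)$ the total continuous rate of its state. The collapse
(`collapseGraph()`) therefore replaces each distinct path prefix by a
single node valued
$$L^{-1}\Big[\prod_i \frac{1}{c_i + \delta}\Big](T)
  = \sum_i e^{-c_i T} \prod_{j \neq i} \frac{1}{c_j - c_i},$$
the partial-fraction closed form, with two refinements:

* **Paths that absorb before the event fires.** In an isolation-with-
  migration model all lineages can coalesce in the migration sink while the
  split is still pending. Such a path has no $\delta$-edge, and the global
  $1/\delta$ factor survives; it is handled uniformly as an extra pole at
  $c = 0$. This convention is what makes the transform equal 1 at
  $\omega = 0$ for every $T$.
* **Repeated and near-repeated poles.** The distinct-pole formula divides
  by $c_j - c_i$. Poles closer than $10^{-9}$ (relative) are grouped and
  evaluated with the confluent formula: the Taylor coefficients $B_r$ of
  the remaining product around the repeated pole are generated by a
  logarithmic-derivative recursion over power sums, giving terms
  $B_r T^{m-1-r} e^{-c T}/(m-1-r)!$ for a pole of multiplicity $m$. Exact
  repeats (identical $(b, o)$ vectors) are detected structurally; distinct
  first-degree polynomials that merely collide *numerically* at the
  expansion point are refused with an error suggesting a rate
  perturbation, since no stable expansion exists there in double
  precision.

A related numerical fact: as $T \to 0$ the partial-fraction terms cancel to
order $T^{m-1}$, so for large pole sets no double-precision evaluation of
the closed form retains full relative accuracy at very small $T$; the
matrix-exponential cross-check in the test suite is run for $T \ge 0.5$
where the formula carries better than $10^{-9}$ relative error. Split
times of applied models live in this comfortable regime.

## Mutation-configuration probabilities

`bsfsProbabilities()` tabulates
$$P(k) = (-\theta/2)^{\sum_i k_i}\, c_k,$$
where $c_k$ is the Taylor *coefficient* (not derivative) of the transform
at multi-index $k$ around the expansion point $\omega_i = \theta/2$. The
sign/scale convention follows from writing the Poisson mixture as
derivatives of $E[\prod_i e^{-\omega_i L_i}]$ at $\omega = \theta/2$; it is
pinned by the $n = 2$ closed form $P(k) = \theta^k/(1+\theta)^{k+1}$ and by
the Monte-Carlo cross-check. Coefficients are stored instead of
derivatives throughout because they are smaller by $\left(\sum_i k_i\right)!$ and
accumulate less rounding error.

Each computational-graph node is expanded into a truncated multivariate
series over $k \le k_{max}$: non-inverted equations are reciprocals of
first-degree polynomials, with coefficients
$$(-1)^s \frac{s!}{\prod_i k_i!} \frac{\prod_i o_i^{k_i}}{f(\omega_0)^{s+1}},
  \qquad s = \sum_i k_i,$$
and collapsed nodes are assembled from exponential blocks
$c^s \prod_i o_i^{k_i} e^{c f(\omega_0)}/\prod_i k_i!$ and reciprocal
blocks via truncated products. Propagation uses multi-index convolution for
multiplication and elementwise addition. Every inner summation — the
convolution sums and the summation over poles — uses compensated (error-
free-transformation) summation, because coefficient terms alternate in
sign and are prone to catastrophic cancellation in exactly the situations
of interest.

### Structural zeros and the residual bins

Configurations whose positively counted branch types can never jointly
occur on one genealogy have probability zero. Compatibility is decided at
the level of branch-type support sets by one backwards sweep over the state
graph: a set $U$ is realizable from a state iff $U$ minus the types present
in that state is realizable from one of its children. The resulting family
is downward closed, and only configurations over compatible supports are
computed or stored (`configArrayLayout()` keeps a dense mask up to $10^7$
slots and an index map above). This rule is exact: a support is flagged
compatible precisely when some genealogy realizes it, which we verified
independently by exhaustively enumerating all labeled tree topologies on
small samples and by checking that every computed table is normalized with
exactly the flagged entries positive. The simulation estimator provides the
complementary guarantee on real runs: no observed configuration is ever a
predicted structural zero, and predicted zeros receive zero mass in every
replicate.

Counts above $k_{max,i}$ land in a residual bin per type. The probability
of a cell whose residual set is $S$ is computed by inclusion–exclusion
over marginal tables: for each $R \subseteq S$ the root series is rebuilt
with $\omega_i = 0$ for the types being integrated out (removing their
marking process entirely), and the within-bound masses are subtracted. The
cost of all $2^{|S|}$ marginal propagations is modest because unmarked
types collapse their series dimension to one. The full array, residual
bins included, sums to 1 up to accumulated float error (tested at
$10^{-8}$).

With phase information, configurations that differ by a permutation of
same-deme sample labels are equiprobable; `equiprobableClasses()` exposes
the induced partition. The exact engine computes all coefficients in one
propagation, so the partition serves as a consistency check (class members
must receive equal probabilities — tested) and as metadata for downstream
consumers rather than as a compute-saving device.

## The Monte-Carlo estimator

`simulateBranchLengths()` draws genealogies under literally the same event
semantics as the graph: competing exponentials, uniform choice among
pair/lineage instances, the discrete event applied deterministically at
$T$. `estimateBsfs()` converts each replicate's per-type lengths $t_i$
into the exact per-replicate configuration distribution
$\prod_i \mathrm{Pois}(k_i;\, \theta t_i/2)$ (residual bins take the
Poisson tail), so each replicate sums to one and the average is unbiased
with computable standard errors. Replicate $r$ reseeds R's RNG from a
deterministic function of `(seed, r)`, so a run with more replicates
extends rather than reshuffles an earlier one.

The simulator emulates the modeled process only: no recombination within a
block, no finite-sites effects, no missing data or genotyping error, and
mutations are never placed (lengths suffice). Agreement between the exact
and simulated tables therefore validates the algebra and the graph
construction, not the adequacy of the demographic model for any real data
set.

## Parameters, defaults, and benchmark sizes

* `theta` — scaled block mutation rate $4 N_{ref}\mu$ per block; the
  marking rate per type is $\theta/2$. No default: it sets the scale of
  everything.
* `kmax` (default 2 per type) — truncation of the per-type mutation count;
  array size grows as $\prod_i (k_{max,i}+2)$ and series cost roughly as
  $\prod_i \binom{k_{max,i}+2}{2}$.
* Migration `rate` — per-lineage, in units of $2N_{ref}$ generations; a
  per-generation probability $m$ converts as $2 N_{ref} m$.
* Split `time` — same units; a time in generations converts as
  $T/(2N_{ref})$.
* The bundled isolation-with-migration benchmark fixture uses two demes of
  relative size $1$ and $0.6/1.3$ descending from an ancestral deme of
  relative size $1.5/1.3$, migration rate $1.82$, split time $3.846$ and
  $\theta = 1.152$, with the first deme as reference — chosen to be
  representative of applied two-population inference settings.

The test suite exercises models up to 4 unphased samples per deme for
structural quantities and up to 2 per deme (4 branch types, $4^4$ arrays)
for full exact tables, with 1000–2000 simulation replicates for the
stochastic cross-checks; these sizes keep the whole suite within a
half-minute while covering every code path, and the package handles larger
models (e.g. 3 per deme, $4^7$ arrays) in minutes.

## Known limitations

* At most one discrete event, and no migration routes forming directed
  cycles (bi-directional migration is rejected at model construction).
  Both are structural: cycles would break the finite path decomposition,
  and the closed-form inversion is per-event.
* State space, path count, and configuration arrays all grow exponentially
  with sample size; the practical exact-table regime is small samples per
  deme — which is also where blockwise linked information is most valuable
  relative to the plain site frequency spectrum.
* Series propagation for discrete-event models duplicates pre-event
  equations across collapsed prefixes, so split models are substantially
  more expensive than pure-migration models of equal state count.
* All production arithmetic is double precision with compensated
  summation; no arbitrary-precision fallback is provided.
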