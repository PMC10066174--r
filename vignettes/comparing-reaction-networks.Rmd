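---
title: "Comparing stochastic reaction networks under a cone preorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing stochastic reaction networks under a cone preorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrncmp)
```

## The model and what is being compared

A stochastic chemical reaction network is a continuous-time Markov chain
$X$ on a state space $\mathcal{X} \subseteq \mathbb{Z}_+^d$ of molecule
counts. Each reaction has a reactant vector $v^-$, a product vector $v^+$
and a propensity $\Lambda_{(v^-,v^+)}(x)$; reactions sharing a net vector
$v_j = v^+ - v^-$ aggregate into the direction rate
$\Upsilon_j(x) = \sum_{(v^-,v^+)\colon v^+-v^-=v_j} \Lambda(x)$. Mass-action
propensities are $\kappa \prod_i (x_i)_{(v^-)_i}$ with falling factorials
computed exactly in integer arithmetic before scaling by $\kappa$; other
kinetics (occupancy-limited and Hill-type terms in the chromatin circuits)
are written in a whitelisted arithmetic grammar — `+ - * /`, integer
powers, numeric literals, species/parameter names and
`hill(x, K, h) = x^h / (K^h + x^h)` — so no arbitrary code is ever
evaluated from a network file. The boundary contract
$x + v_j \notin \mathcal{X} \Rightarrow \Upsilon_j(x) = 0$ is enforced
mechanically when a network is compiled onto an enumerated space.

Two parameterisations $\Upsilon$ and $\breve\Upsilon$ on the same space
and the same direction list are compared through the preorder
$x \preccurlyeq_A y \iff A(y-x) \ge 0$ of a user-chosen matrix $A$ with no
zero row. The package checks sufficient conditions under which the two
chains admit a coupling that preserves this order pathwise, almost surely,
from any ordered pair of starts; monotonicity of mean first passage times
(for increasing or decreasing targets) and of stationary probabilities of
increasing sets then follow, and both are also computed exactly by sparse
linear algebra as a cross-check.

Choosing $A$ is a modelling act: each row scores a direction of progress
(e.g. "less substrate", "more product"), and the useful matrices for the
boundary-based checks are integer with $Av_j \in \{-1,0,1\}^m$. The
package deliberately does not search for $A$; the bundled examples record
the matrices that express their scientific questions, and a manual recipe
(solve $\langle A_{i\cdot}, v_j \rangle = b_{ij}$ with
$b_{ij} \in \{-1,0,1\}$ chosen by which transitions should cross, leave or
parallel each slice) covers new networks.

## The three checkers, and how they relate

`check_general` scans every ordered pair $x \preccurlyeq_A y$: directions
whose jump from $y$ exits the cone $K_A + x$ must satisfy
$\breve\Upsilon_j(y) \le \Upsilon_j(x)$, and directions whose jump from
$x$ would overtake $y$ must satisfy the reverse inequality.
`check_boundary` restricts the scan to the slices
$\partial_i(K_A+x)$ where $\langle A_{i\cdot}, y-x\rangle = 0$, which
suffices when every $Av_j$ has entries in $\{-1,0,1\}$ (jumps can then
never skip a slice). `check_grouped` weakens the per-direction comparisons
to grouped sums over $G^k = \{j : Av_j = \eta^k\}$.

One relationship deserves emphasis because it is easy to get backwards: a
boundary pass implies both a grouped pass and a general pass, but a
grouped pass does **not** imply a general pass. The grouped conditions are
a genuinely different sufficient criterion, and the bundled relay network
is the counterexample: with equal route rates its grouped sums are ordered
for any cross-link rate, while the per-direction comparisons (boundary and
general alike) fail. Both roads, when passable, imply the generator
inequalities that `massey_oracle` checks by brute force, which is how the
test suite validates all of them against each other on random instances.

Violations are returned as witnesses — the pair $(x, y)$, the slice, the
direction or group, and both sides of the failed inequality — and the test
suite re-evaluates reported witnesses numerically to guarantee they are
genuine rather than artefacts of the scan.

## The coupled simulator

The constructive side uses uniformization. A shared rate
$\lambda = (1 + 10^{-3})\, n \max\{\sup_x \sum_j \Upsilon_j(x),
\sup_x \sum_j \breve\Upsilon_j(x)\}$ is chosen; the strict inequality is
what the construction needs, and the small fixed margin keeps acceptance
probabilities as high as possible without ever sitting on the boundary.
Both chains share one Poisson($\lambda$) arrival stream and one uniform
draw per arrival. The draw $u$ selects candidate direction
$j = \lfloor un \rfloor + 1$ and the jump is accepted iff $u$ falls in the
half-open interval $[(j-1)/n,\ (j-1)/n + \Upsilon_j(x)/\lambda)$; in the
grouped scheme each group owns a block of $[0,1)$ with its members'
acceptance intervals stacked end to end, so a single draw couples whole
groups. Half-openness makes the map total and unambiguous; the
probability-zero draw $u = 1$ is defined to self-loop. Because the
acceptance intervals for the two chains are nested exactly when the
checked inequalities hold, ordered skeleton states stay ordered — the
simulator asserts the order at every event and treats a violation under
verified conditions as an internal error, which is the property the
acceptance run measures over ensembles.

Reproducibility: each pair in an ensemble uses a seed derived
deterministically from the master seed and the pair index, so results are
independent of execution order. R's built-in generator is used with
per-pair reseeding; this implements the keyed-stream contract without a
dedicated counter-based generator.

## Truncation semantics

Countably infinite spaces are handled by the sup-norm ball
$\mathcal{X}_M = \{x : \|x\|_\infty \le M\}$, in two deliberately distinct
flavours:

* **freeze** (default for compiled pairs): rates keep their full values on
  $\mathcal{X}_M$, chains may step into a one-step collar where every rate
  is zero, and the first exit time is recorded. This mirrors the limit
  argument that extends the coupling to non-exploding infinite chains, so
  condition reports on bounded pairs are labelled "verified on truncation
  M" and quantify over core states only. Ordering statements are reported
  per pair, with exited pairs flagged (and excluded where the analysis
  says so); `couple_paths(auto_extend = TRUE)` doubles $M$ (at most five
  times, fresh derived seed, with a warning) when a horizon outgrows the
  ball.
* **box** (used by generators and the random fixtures): any rate whose
  target leaves the ball is zeroed, giving a proper finite chain. A frozen
  chain has no stationary law, so stationary and first-passage analyses
  use this restriction surrogate; `stationary()` reports the probability
  mass within one transition of the truncation boundary as the trust
  diagnostic, and `stationary_truncated()` doubles $M$ until that mass
  drops below $10^{-8}$.

## Numerical choices

* Preorder and boundary tests are exact for integer $A$ and integer
  states; real-valued matrices fall back to a $10^{-9}$ absolute
  tolerance, because the slice test $\langle A_i, y-x\rangle = 0$ must not
  be corrupted by floating point.
* Propensity inequalities count as violated only beyond a relative
  $10^{-9} \max(1, |\mathrm{lhs}|, |\mathrm{rhs}|)$, since propensities are
  floating point while the underlying inequalities are exact in rationals.
* Generators are sparse (`Matrix`); stationary laws replace one balance
  equation by the normalisation constraint and solve directly;
  irreducibility is verified first via strong connectivity (`igraph`), and
  reducible chains are refused with their closed classes named.
* Mean first passage times solve $Q_{\setminus\Gamma} h = -1$; states that
  can wander into a closed set disjoint from the target receive $+\infty$
  explicitly (never a singular-solver error). Hitting-time *distributions*
  are computed exactly by making the target absorbing and evaluating
  transient probabilities with the uniformized power series, truncated
  when the neglected Poisson tail is below $10^{-12}$.
* State spaces are enumerated by breadth-first closure from the origin
  along transitions with positive propensity, in both directions, with a
  candidate admitted only where every rate law evaluates to a finite
  nonnegative value. The validity predicate is what keeps spaces cut out
  by occupancy constraints (the chromatin circuits, where a naive $\pm v_j$
  closure would step outside the region on which the kinetics make sense)
  exactly right without separate declarations. Enumeration order is
  lexicographic, hence bit-for-bit reproducible; a configurable cap
  (200000 states) turns runaway enumerations into an instructive error.
* Group order and the permutation $\sigma$ follow first occurrence along
  $j = 1..n$, so the grouped acceptance intervals are identical across
  runs.

## The random-instance generator

`random_network()` emulates the *structural* variety the checkers must
face — up to 3 species, up to 6 small-stoichiometry mass-action reactions,
perturbed rate constants, a random integer $A$ with entries and images in
$\{-1,0,1\}$ (enforced by rejection, restarting from an incremented seed
if the budget is exhausted) — on box-truncated spaces of at most 14 states
so the exponential-cost oracle stays exact. It does not emulate real
biochemical parameter scales, stiff rate separations, high molecule
counts, or non-mass-action kinetics; passing the oracle sweep therefore
validates the *logic* of the checkers (their implications and witness
reporting), not the package's behaviour on data-scale models, which the
worked examples and their closed forms cover instead.

## Problem sizes used by the checks

The shipped verification runs use 500 coupled pairs per network to
horizon 10 for the pathwise-ordering fractions (closed enzyme pair;
open enzyme pair truncated at $M = 30$ counting non-exiting pairs;
chromatin pair), 5000 coupled pairs against 5000 plain-simulation runs
and the exact transient law for marginal fidelity (chi-square at
$\alpha = 0.001$, three Monte-Carlo standard errors per state), 50 random
instances for the oracle sweep, and truncation $M = 40$ for the
product-form comparison, which agrees with the sparse solve to better
than $10^{-6}$ in sup-norm. These sizes keep every check exact or
statistically well-powered at desk scale.

## Known limitations

* Verification is exhaustive, hence $O(|\mathcal{X}|^2 m)$ pairwise scans:
  practical to a few thousand states (a warning fires at 20000). The
  conditions themselves are algebraic; for symbolic families one verifies
  a sufficiently large truncation and argues growth by hand, as the
  bundled infinite-state examples do.
* The grouped scheme requires integer $A$ with $Av_j \in \{-1,0,1\}$;
  nothing is attempted for general real cones beyond `check_general`.
* Exited (frozen) pairs carry no information past their exit time; for
  horizons where exits are common, raise the bound rather than reading
  the flagged fractions.
* No tau-leaping or diffusion approximations: the simulator is exact
  uniformization, whose cost scales with $\lambda t$, i.e. with the
  worst-case total rate over the truncated space rather than the typical
  one.
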