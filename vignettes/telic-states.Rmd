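---
title: "Telic state representations: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telic state representations: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telic)
```

This vignette documents the model behind the package, the conventions it
fixes where several readings are defensible, and the numerical choices that
shape its behaviour.  It is the place to look when a result depends on a
definition rather than on code.

## The model

An agent interacts with a one-dimensional world for `T` discrete unit steps,
starting at position `start` (default 0).  Its behaviour is open-loop: a
policy is a pair $(\mu, \sigma)$ in a two-parameter Gaussian random-walk
family, and the *experience distribution* a policy induces is the law of the
trajectory it generates.  Positions are unbounded reals; there are no walls
and no absorption.

Two parameter conventions are supported, because goal geometry and step
geometry pull in different directions:

* **endpoint** (default): each step is $N(\mu/T, \sigma^2/T)$, so the
  terminal position is exactly $N(\mathrm{start} + \mu, \sigma^2)$.  The
  worked scenarios place unit-width goal regions at terminal displacements
  of $\pm 2$ and thread named policies such as $(1, 1)$ between the origin
  and those regions; that geometry is coherent only when $\mu$ lives on the
  terminal scale.
* **per_step**: each step is $N(\mu, \sigma^2)$, terminal position
  $N(\mathrm{start} + T\mu, T\sigma^2)$.  This matches a literal reading of
  "position update step" and is kept as a configuration switch
  (`environment_spec(param_convention = "per_step")`); no analysis in the
  package depends on which one is active.

A **goal** names pairwise-disjoint closed intervals on the line, designates a
target, and fixes reach semantics.  The default semantics is *terminal*
(position at step `T` inside the region), for which reach probabilities are
exact Gaussian CDF differences; *first passage* (any step `1..T`, start
excluded) is available through the Monte-Carlo estimator only, since the
Gaussian random walk has no elementary first-passage law for an interval.
Region boundaries are closed: landing exactly on an edge counts.

The goal induces a scalar **preference score**
$$\mathrm{score}_g(\pi) = P_\pi(\text{reach } g) - \max_{g' \neq g}
P_\pi(\text{reach } g'),$$
the familiar probability difference when there are two regions, and the bare
reach probability when there is one.  Competing regions are aggregated with
a max so that the two-region case reduces to the pairwise difference while
three or more regions remain well defined.  Policies with equal scores are
*goal-equivalent*; the score induces a total preorder (`rank_policies()`
reports tied ranks at exact equality, with a `1e-12` float guard).

## Telic states and their granularity

At sensitivity $\epsilon \in (0, 1)$, the telic state of region $g$ is
$$S_g = \{\pi : \mathrm{score}_g(\pi) \ge \epsilon\},$$
with an inclusive threshold, and the residual state $S_0$ collects every
policy that clears the threshold for no region.  Since
$\mathrm{score}_g \ge \epsilon > 0$ already forces $g$ to be the
score-maximising region, the states are disjoint and the representation is a
partition.  Ties in the argmax (possible only below threshold resolution)
are broken by the goal's fixed region order.

States are represented both intensionally (the score predicate, used by
`classify_policies()` and by the continuous polish) and extensionally on a
rectangular $(\mu, \sigma)$ grid, which is the search surface for every
optimisation.  The default grid is $301 \times 151$ over
$\mu \in [-3, 3]$, $\sigma \in [0.5, 2]$ — steps of 0.02 and 0.01 — chosen
to cover the policy tiles of the worked scenarios while keeping a full grid
sweep around a quarter of a second; unit tests use a $61 \times 31$ grid
with the same bounds.  Curve values computed on a $201 \times 101$ grid
agree with the default grid within 0.02, which the test suite asserts.

Smaller $\epsilon$ means a *larger* goal state: nestedness
($\epsilon_1 \le \epsilon_2 \Rightarrow S_g(\epsilon_2) \subseteq
S_g(\epsilon_1)$) is a theorem of the construction and a property test.  A
consequence worth stating explicitly is the direction of the
complexity–granularity curve: the capacity needed to reach a state is
non-decreasing in $\epsilon$, hence non-increasing in $-\log\epsilon$, and
tends to zero as $\epsilon \to 0$ because the growing state eventually
contains policies arbitrarily close to the default.  Empty states (large
$\epsilon$) are legal — they arise mid-refinement — and are reported with
zero counts rather than dropped; projecting onto one raises a
`telic_empty_state` error, and curves record such sensitivities as infinite
points in their metadata.

## Policy complexity and projection

Complexity is Gaussian KL divergence from the default policy
$\pi_0 = (0, 1)$, with three convention axes fixed by
`complexity_config()`:

* **level** — `endpoint` (default) compares terminal laws; `trajectory`
  compares full trajectory laws, which for open-loop policies is exactly
  `T` times the single-step KL (the steps are i.i.d., so the joint
  divergence factorises; this identity is tested, not assumed).
* **direction** — `forward`, $KL(\pi \| \pi_0)$ (default), under which the
  projection onto a state is the standard I-projection of $\pi_0$; or
  `reverse`.
* **base** — `bits` (default; capacity bounds are quoted in bits) or
  `nats`.

All eight combinations are first-class because the worked scenarios'
printed anchor policies could not be reconciled with any single one of
them; the dual-goal figures are treated as qualitative, and the package's
own numbers are derived from its stated conventions.  The tiny-grid test
fixture checks the projection and feasibility machinery against exhaustive
enumeration under all eight.

`information_projection()` minimises complexity over the state's grid
members, then optionally polishes the optimum with a deterministic
Nelder–Mead pass (relative tolerance $10^{-6}$, 200 iterations) on a
penalised objective; a candidate that drifts outside the state is bisected
back along the segment to the feasible grid start, and the polish is kept
only when it is a member strictly cheaper than the grid optimum.  Grid ties
break by smaller $|\mu - \mu_0|$, then smaller $\sigma$, then smaller
$\mu$, so results are reproducible bit for bit.  Analyses that must be
exactly grid-verifiable (the tradeoff curves, the acceptance computations)
run with `refine = FALSE`.

`nearest_feasible_policy()` searches the capacity-`δ` ball around the
anchor for the policy nearest the target state, where distance is the
smallest $KL(m \| \pi)$ over state members $m$ at the configured level and
base (a score-shortfall distance, $\max(0, \epsilon - \mathrm{score})$, is
available behind a flag).  The anchor itself is always a candidate, so the
feasible set is never empty and $\delta = 0$ degenerates to evaluating the
distance at the anchor.

## Controllability, splitting and re-anchoring

A representation is **telic controllable** with respect to
$(\pi_0, \delta, N)$ when every non-residual state is reachable from
$\pi_0$ by a chain of at most $N + 1$ policy changes, each leg landing
inside a telic state of the representation and costing at most $\delta$
relative to the previous anchor.  Three decisions here were genuinely open
and are worth recording:

* **Hops land on state members, not only on projections.**  A direct leg
  lands on the information projection of the anchor onto the target.  An
  intermediate leg, however, may land on *any* member of a telic state
  within capacity — implemented as the within-capacity grid policy,
  belonging to a non-residual state, that is nearest the target.  Had
  intermediate anchors been restricted to information projections of the
  current anchor, an intermediate state containing the anchor would project
  back onto the anchor itself and could never serve as a stepping stone;
  at small capacities the inserted waypoint state always contains the
  default policy, so that reading makes every repair vacuous.  Under the
  implemented reading the repair narrative goes through: the agent adopts
  the waypoint policy (a member of the inserted state), re-anchors, and
  continues.
* **Residual policies are not anchors.**  Chains transition *between telic
  states*; a hop that lands in $S_0$ is not a hop the representation can
  name, so such candidates are excluded.  This is what forces a split: the
  capacity-bounded policy nearest an unreachable target typically sits in
  $S_0$ until a waypoint state is built around it.
* **Progress requirement.**  Each hop must strictly reduce the distance to
  the target.  This guarantees termination of the recursive chain search
  and makes its result deterministic.

`split_state()` repairs an unreachable state by computing the
capacity-bounded policy $\pi^*$ nearest to it, inserting a waypoint region
of the target's width centred at $\pi^*$'s terminal mean, and rebuilding
the representation.  Waypoint regions are *second tier*: they never compete
in the preference scores of the original goal regions, and a policy is
assigned to a waypoint state only when it belongs to no original goal
state.  This keeps every existing goal state exactly intact — each split
adds one state and carves it out of the residual — which is what makes the
repair monotone.  (A waypoint that competed on equal terms would eat into
the target state it is meant to serve: in the shifted scenario it would
push the target state's boundary from $\mu \approx 0.8$ out to
$\mu \approx 2.2$ and leave it unreachable at any budget.)  By
construction $\pi^*$ is a member of the inserted state and costs at most
$\delta$, so the projection of the current default onto the new state is
within capacity; this postcondition is asserted at run time.  Splitting a
state that is already reachable raises `telic_split_not_needed`; an
inserted state empty on the grid raises `telic_degenerate_split`.

`refine_until_controllable()` alternates a controllability check (always
judged from the *original* default with the given hop budget) with a split
of the unreachable state whose projection from the current anchor is
cheapest.  After a split the default is re-anchored.  Two re-anchoring
modes exist because the source material names both: the default mode adopts
the waypoint policy $\pi^*$ itself — the policy the new region is centred
on, and the one the narrative describes the agent as actually adopting —
while `reanchor = "projection"` adopts the information projection of the
current default onto the inserted state.  The projection mode is kept for
completeness, but at small capacities the inserted state contains the
current default, making that projection the default itself; it is therefore
not the mode under which the repair demonstrably progresses.  Refinement
aborts with `telic_no_convergence` (carrying the partial result) when a
split fails to reduce the worst remaining gap, when a target is within
capacity of the re-anchored default yet still blocked by the hop budget, or
after `max_iter` (default 10) splits.

## Estimators, seeds and determinism

Analytic reach probabilities are Gaussian CDF differences and are used
everywhere a terminal-mode probability is needed.  The Monte-Carlo
estimator simulates full trajectories (`n_mc` defaults to $10^5$) under a
named seed, evaluates any region and either reach mode on the same batch
(common random numbers), and is validated against the closed forms at
three standard errors in the test suite.  Trajectory simulation draws
through `withr::with_seed`, so the global RNG state is never touched;
identical `(policy, env, n, seed)` reproduce batches bit for bit, and
`run_scenario()` outputs are byte-identical across reruns of the same
configuration — JSON results carry the package version, a hash of the
canonical configuration, and every seed, but no timestamps.

## The scenario generator and what it does not emulate

The packaged scenarios (`generate_fixture()`, `inst/extdata/`) pin the
study conditions: horizon $T = 30$, start 0, unit-width regions at
$2$ and $-2$ (`dual_goal`), the target recentred at $2.5$ with capacity
$0.25$ bits (`shifted_goal`, chosen so the shift actually exceeds the
capacity and exercises the repair path), sensitivity $\epsilon = 0.1$, hop
budget $N = 1$, 500 trajectories for simulation displays, and a
$5 \times 5$ grid (`tiny_grid`) small enough for exhaustive enumeration.
The generator produces exactly the stylised world the theory is stated in:
open-loop Gaussian policies on an unbounded line.  It does not emulate
state-dependent (closed-loop) policies, non-Gaussian or heavy-tailed step
noise, walls or absorbing boundaries, two-dimensional or graph-structured
environments, or learning of the environment model itself.  Passing tests
therefore certify the framework's internal machinery — partitions,
projections, capacity logic, repair — not its fit to any empirical
behavioural data.

## Known limitations

* Goals must be representable by the scalar score; arbitrary preference
  relations over experience distributions are out of scope.
* Telic states are grid-extensional; boundaries are resolved to grid
  resolution (plus the local polish), not analytically.
* The chain search is greedy in the distance to the target.  At the hop
  budgets of interest ($N \le 1$, where the direct and one-hop cases are
  exhaustive up to the choice of waypoint) this is exact for practical
  purposes, but for large $N$ it is not a complete search over all chains,
  and the all-pairs variant of controllability (mutual reachability between
  every ordered pair of states) is not implemented.
* Minimum-split repair is not attempted; the refinement inserts one
  waypoint per iteration along the cheapest infeasible direction.
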