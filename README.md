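# telic

Goal-directed state representation for cognitive agents: **telic states** are
equivalence classes of experience distributions that an agent's goal renders
interchangeable.  This package constructs telic state representations over
the policy space of a one-dimensional random-walk navigation task, measures
the information-theoretic cost of moving between them, and repairs
representations that an agent with bounded capacity cannot traverse.  It is
aimed at computational cognitive scientists studying goal-conditioned
abstraction, bounded rationality and intrinsically motivated learning.

## The model

An agent lives on the real line and behaves open-loop for `T` discrete steps.
A policy is a pair (μ, σ); under the default *endpoint* convention each step
is drawn `N(μ/T, σ²/T)`, so the terminal position is exactly
`N(start + μ, σ²)` (a *per-step* convention, step `~ N(μ, σ²)`, is also
available).  A **goal** names disjoint interval regions on the line — in the
worked scenarios unit-width regions centred at `x_R = 2` and `x_L = −2` —
and induces a scalar preference score over policies,

```
score(π) = P(reach target region) − max over competing regions P(reach region),
```

with terminal-time reach probabilities available in closed form from the
Gaussian CDF.  A **telic state** `S_g` collects the policies whose score
toward region `g` is at least a sensitivity `ε`; policies clearing the
threshold for no region form the residual state `S0`.  The partition of the
(μ, σ) plane at sensitivity ε is the **telic state representation**.

**Policy complexity** is the Kullback–Leibler divergence `KL(π ‖ π0)` between
a policy's induced distribution and the default policy `π0 = (0, 1)`, in
bits.  The **information projection** of `π0` onto a telic state is the state
member minimising this complexity.  A state is *reachable* under capacity `δ`
when its projection costs at most `δ` bits, and a representation is **telic
controllable** with respect to `(π0, δ, N)` when every telic state can be
reached by a chain of at most `N + 1` policy changes, each landing in a telic
state and costing at most `δ` relative to the previous anchor.  When a state
is out of reach, `split_state()` inserts an intermediate *waypoint* state
centred on the capacity-bounded policy nearest the target, and
`refine_until_controllable()` iterates this repair, re-anchoring the default
on the waypoint policy, until the representation is controllable.

## Worked example: a goal shift that outruns the agent's capacity

Shift the right-hand goal region from 2 to 2.5 and hold the agent to
`δ = 0.25` bits per policy change:

```r
library(telic)

env  <- environment_spec(horizon = 30)
goal <- goal_spec(list(R = region(2.5), L = region(-2)), target = "R")
rep  <- build_representation(goal, telic_rule(0.1), env, policy_domain())
rep
#> <telic_representation> epsilon = 0.1, 45451 grid policies, states:
#> # A tibble: 3 × 2
#>   state     n
#>   <chr> <int>
#> 1 S0    10700
#> 2 SR    15488
#> 3 SL    19263

cfg <- complexity_config()          # KL(pi || pi0) on terminal laws, bits
information_projection(rep, "SR", cfg, refine = FALSE)
#> # A tibble: 1 × 5
#>   state    mu sigma complexity refined
#>   <chr> <dbl> <dbl>      <dbl> <lgl>
#> 1 SR     0.82  1.07      0.492 FALSE
```

The cheapest member of `SR` costs 0.492 bits — unreachable at `δ = 0.25`.
One refinement pass repairs the representation:

```r
res <- refine_until_controllable(rep, cfg, capacity_bound(0.25),
                                 hop_budget(1), refine = FALSE)
res
#> <telic_refinement> 1 split(s); inserted: SM; final controllable
#> # A tibble: 2 × 4
#>      mu sigma  step leg_complexity
#>   <dbl> <dbl> <int>          <dbl>
#> 1  0     1        0          0
#> 2  0.56  1.13     1          0.250

res$report$chains$SR
#> # A tibble: 2 × 5
#>     leg    mu sigma complexity landing
#>   <int> <dbl> <dbl>      <dbl> <chr>
#> 1     1  0.56  1.13     0.250  SM
#> 2     2  0.8   1.16     0.0335 SR
```

A waypoint state `SM`, centred on the capacity-bounded policy (0.56, 1.13),
is inserted between the default and the shifted target: the agent first
adopts that policy (0.250 bits), re-anchors, and then reaches `SR` for a
further 0.034 bits.  The final four-state representation `{S0, SL, SM, SR}`
passes `is_telic_controllable()` at `N = 1` from the original default.

`autoplot()` methods draw the score map with state outlines
(`autoplot(rep, cfg, delta = 0.25)`), trajectory fans
(`plot_trajectories()`), and both tradeoff curves
(`complexity_granularity_curve()`, `goal_complexity_curve()`).  Scenarios
can also be driven from YAML files — see `load_scenario()`,
`run_scenario()` and the thin command-line wrapper in `inst/cli/telic.R`;
packaged configurations live in `inst/extdata/`.

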