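---
title: "Boldness, leadership and the snowdrift foraging game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boldness, leadership and the snowdrift foraging game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r}
library(boldsim)
```

## The model

A group of $N$ agents repeatedly faces a foraging task: an obstacle blocks
the way to a food source and must be pushed aside by one or more cooperating
agents. Each agent $i$ carries a single personality trait, its *boldness*
$s_i \in (0,1)$, which plays three roles at once.

**Initiation.** Each task starts with a race. Agent $i$ draws an
exponentially distributed *decision time* $t_i^D$ with rate $s_i$ (mean
$1/s_i$); the agent with the shortest decision time becomes the *initiator*.
A standard property of independent exponentials makes the winning
probability proportional to boldness,
$$\Pr\left(t_m^D = \min_i t_i^D\right) = \frac{s_m}{\sum_{i=1}^N s_i},$$
and the winning time itself exponential with rate $\sum_i s_i$. Bolder
agents initiate more often and groups of bolder agents initiate sooner.

**Following.** Once an initiator appears, each of the other $N-1$ agents
independently joins the push as a *follower* with probability $1 - s_i^2$,
or abstains as a *free-rider* with probability $s_i^2$: boldness and
responsiveness to someone else's initiative are inversely related, with the
quadratic giving shy agents a near-certain tendency to follow.

**Payoffs.** The initiator and its followers are cooperators (C-players),
free-riders are defectors (D-players). With task outcome $r \in \{0, 1\}$,
$$p_C = r b - c, \qquad p_D = r b, \qquad b > c > 0,$$
an $N$-player snowdrift structure: cooperation is costly, its benefit is
shared, and free-riding pays whenever the task succeeds anyway.

**Learning.** After each task only the initiator updates its trait,
$$s_j \leftarrow r\lambda + s_j(1 - \lambda), \qquad \lambda \in (0,1),$$
a linear reinforcement rule: success pulls the initiator's boldness toward
1, failure toward 0. Under a constant outcome $r$ the trait follows the
closed form $s(k) = r + (s(0) - r)(1-\lambda)^k$, which the test suite uses
as an exact oracle on forced-outcome environments.

An agent is classified *bold* when $s_i > 0.7$ and *shy* when $s_i < 0.3$
(strict inequalities).

## The task environment

The physical environment is abstracted into a success-probability table:
the chance that a task succeeds given the obstacle level ($O_1$–$O_4$,
realized as obstacles of 1.6–2.9 kg) and the number of cooperators $n_C$.
A single Bernoulli draw per task replaces the duration-dependent physical
push; failure by timeout is absorbed into the probabilities.

Only a few cells of the empirical table are published as exact statements: a
lone cooperator succeeds on $O_1$ 17% of the time and never on the heavier
obstacles; two cooperators always clear $O_1$ but none of the others; six
always succeed. `default_success_table()` pins those cells and fills the
rest with a deterministic threshold rule — success probability 1 at or above
per-obstacle cooperator thresholds 2/3/4/5 for $O_1..O_4$, 0 below:

```{r}
default_success_table(6)
```

The fill is a declared stand-in for the unpublished full matrix, chosen to
respect both monotonicity constraints (nondecreasing in $n_C$, nonincreasing
in difficulty) and the observation that the hardest obstacle is cleared
almost surely by 5–6 cooperators. Any explicit matrix can be supplied
instead, via `success_table()` or the `success_table` key of a run
configuration; `validate_success_table()` reports every monotonicity
violation at load time rather than throwing on the first.

## Study conditions and defaults

The default configuration reproduces the reference experimental settings: a
group of $N = 6$, $b = 2$, $c = 1$, evolutions of 200 tasks, update rates on
the grid 0.4–0.9, initial traits drawn i.i.d. uniform on $(0,1)$, and five
replicate runs per condition. Summary statistics are computed over the last
100 of the 200 tasks, where the evolution has stabilized; `run_sweep()`
aggregates replicate means and standard errors per $(\lambda,$ level$)$
cell. All sweep results below use those sizes; a full two-rate, four-level,
five-replicate sweep is 40 evolutions (8,000 stage games) and runs in
seconds.

```{r}
sw <- run_sweep(game_params(), c(0.4, 0.9), obstacle_levels(),
                replicates = 5, base_seed = 1)
sw$by_cell[, c("lambda", "level", "mean_n_coop", "mean_n_bold",
               "diversity", "success_rate")]
```

The characteristic phenomena are visible directly: harder tasks recruit more
cooperators and leave fewer bold agents; the larger update rate produces a
higher diversity of initiator shares on the hard task (a stable leader
emerges) and a higher success rate.

## Summary statistics

For a window $W$ of tasks, `summarize_evolution()` reports the mean
boldness, mean bold count $n_B$, mean cooperator count $n_C$, the success
rate, the mean winning decision time, and per-capita per-task cost
$c\,n_C/N$ and pay-off $\sum_i \pi_i / N$. Each agent's initiator share is
$p_i = \#\{k \in W : I_k = i\} / |W|$, and the diversity index is their
population standard deviation
$$d_I = \sqrt{\frac{1}{N}\sum_{i=1}^N \left(p_i - \bar p\right)^2},$$
zero when all agents initiate equally often and maximal at
$\sqrt{N-1}/N$ ($\approx 0.373$ for $N = 6$) when a single agent initiates
every task. Two normalization choices are deliberate: the divide-by-$N$
(population) form of the standard deviation is used exactly as defined, not
the sample form; and cost/pay-off are reported per capita per task, which
makes values comparable across group sizes (the identity
per-capita pay-off + per-capita cost $= r b$ holds task by task and is
asserted in the tests). $p_i$ and $d_I$ use the same trailing window as all
other statistics; pass an explicit position vector (e.g. `window = 81:120`)
for other windows.

## The reference model

`run_reference_model()` strips out the personality machinery: each agent's
strategy $\hat s_i \in (0,1)$ is simply its probability of cooperating, with
no initiator, no race and no decision time. With evolution enabled, every
cooperator updates $\hat s_i$ by the same reinforcement rule with the shared
outcome $r$ (the update rate barely influences the outcome there; 0.9 is the
conventional choice). Two corner conventions are ours: a task with zero
cooperators counts as a failure with zero payoff for everyone (the only
reading consistent with the payoff rule), and the `initiator` /
`decision_time` columns of a reference record are `NA` by contract. We make
no claim about the direction in which the converged common strategy moves
with task difficulty — the implementation runs the stated mechanics and
reports whatever they produce; under the default table on the hard task the
strategies collapse toward zero participation and the success rate with them,
which is what the personality model is being contrasted against.

## Numerical and design choices

* **Tie-break.** Equal decision times have probability zero under continuous
  sampling, but for degenerate inputs the lowest agent index wins,
  deterministically.
* **Open-interval guard.** Mathematically the update keeps traits strictly
  inside $(0,1)$; in double precision a long success streak would round the
  trait to exactly 1 (and a failure streak underflow to 0). Updates are
  clamped to the nearest representable interior doubles, so validation of
  the open interval also holds numerically. The clamp sits ~$10^{-16}$ from
  the boundary and is invisible at the tolerances of any reported statistic.
* **Deterministic outcomes.** `sample_outcome()` draws no random number when
  the table probability is exactly 0 or 1, so forced environments do not
  perturb the RNG stream alignment of otherwise-identical runs.
* **Seeding.** A run is fully determined by its integer seed: the seed
  initializes R's global RNG stream, initial traits are drawn from it, and
  each task consumes it in a fixed order (race, role draws, outcome draw).
  Sweep replicates use `derive_seed(base_seed, lambda, level, j)`, a
  documented arithmetic hash kept below $2^{31}$, so any cell can be re-run
  in isolation.
* **Fast race mode.** `race = "fast"` samples the initiator directly from
  the proportional-boldness law and the winning time from the
  exponential-minimum law instead of simulating all $N$ clocks. The two
  modes are distributionally equivalent (the tests check both against the
  same laws) but produce different streams; the explicit race is the default
  because the individual decision times are part of the recorded data.
* **Bold count timing.** Each task record stores the trait vector *after*
  the initiator's update, and `n_bold` is computed from that snapshot, so a
  record row is a consistent picture of the post-task state.
* **Follower independence.** Follower/free-rider draws are independent
  across non-initiators; a follower's choice does not depend on how many
  others have already joined. This is the memoryless reading of the
  per-agent rule, and the only one implemented.

## What the simulator does and does not emulate

The simulator reproduces the game-theoretic and learning layers exactly, and
replaces the physical layer (hydrodynamics, pushing forces, the 60 s task
limit, robot hardware variability) with the success table. Consequences to
keep in mind when comparing against hardware experiments:

* Quantities that depend only on the model mechanics — the initiator law,
  payoff identities, trait trajectories, adaptation to schedule changes —
  transfer directly, and the tests pin them with analytic oracles.
* Quantities that depend on the environment's fine structure (exact success
  rates, the precise level of $d_I$) inherit the threshold fill of the
  unpinned cells, so they match hardware results qualitatively, not
  numerically. Passing tests show the mechanics are right, not that the
  stand-in environment equals the physical one.
* There is no spatial motion, no partial-task interruption, and no
  inter-agent communication channel (the modelled system forbids one).

## Limitations

Success probabilities are stationary given (level, $n_C$); hardware wear,
battery state or hydrodynamic interference between pushing robots would make
them drift. The reference model's zero-cooperator convention, while the only
consistent one, is not empirically grounded. And with $N = 6$ the diversity
index lives on a coarse simplex — comparisons of $d_I$ across group sizes
should use the $\sqrt{N-1}/N$ maximum as the natural scale.
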