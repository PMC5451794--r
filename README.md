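# boldsim

Agent-based simulator of leadership emergence in a small cooperative group,
for researchers in collective animal behaviour, evolutionary game theory and
swarm robotics who want a seeded, fully configurable desk-scale model of
personality-driven division of labour.

## The model

A group of *N* agents repeatedly forages: each task, an obstacle of
difficulty *O₁–O₄* must be pushed aside by enough cooperators. Each agent
*i* has one evolving personality trait, boldness *sᵢ* ∈ (0,1):

- **Initiator race** — agent *i* draws an exponential decision time with
  rate *sᵢ*; the fastest agent initiates. The winner is agent *m* with
  probability *sₘ / Σᵢ sᵢ*, and the winning time is exponential with rate
  *Σᵢ sᵢ*.
- **Roles** — every other agent independently follows the initiator with
  probability 1 − *sᵢ*², else free-rides.
- **Snowdrift payoffs** — cooperators (initiator + followers) get
  *r·b − c*, free-riders *r·b*, where *r* ∈ {0,1} is the task outcome and
  *b > c > 0* (defaults *b* = 2, *c* = 1).
- **Reinforcement** — only the initiator learns:
  *sⱼ ← rλ + sⱼ(1 − λ)*, λ ∈ (0,1).
- **Environment** — success is a Bernoulli draw from a (level × cooperator
  count) probability table; the shipped default pins the published cells
  (a lone pusher clears O₁ 17% of the time, two always clear O₁, none of
  the heavier obstacles falls to fewer than its threshold of 3/4/5
  cooperators, six always succeed).

Runs of 200 tasks are summarized over the last 100: mean boldness, bold
count *n_B* (traits > 0.7), cooperator count *n_C*, success rate, decision
time, per-capita cost and pay-off, each agent's initiator share *pᵢ*, and
the diversity index *d_I* = population s.d. of the *pᵢ* (0 = shared
leadership, √(N−1)/N ≈ 0.373 = a single fixed leader for N = 6).

A reference model without personality traits (each agent simply cooperates
with probability *ŝᵢ*, optionally updated by the same rule) is included for
contrast, along with replicate sweeps over λ and difficulty, a
changing-difficulty schedule (60 easy / 60 hard / 80 easy), and lossless
CSV/JSON export of complete task records.

## Worked example

```r
library(boldsim)

params <- game_params()                 # N = 6, b = 2, c = 1, lambda = 0.9
sched  <- make_schedule(fixed = "O4")   # 200 tasks on the hardest obstacle
rec    <- run_evolution(params, sched, seed = 42)
summarize_evolution(rec)
#> Summary over tasks 100-199 (100 tasks):
#>   success rate     0.990
#>   mean boldness    0.337   bold agents 2.00
#>   cooperators n_C  4.99   diversity d_I 0.232
#>   decision time    0.510
#>   per-capita cost  0.832   pay-off 1.148

round(summarize_evolution(rec)$initiator_shares, 2)
#> [1] 0.50 0.01 0.00 0.00 0.49 0.00
```

On the hardest task the group self-organizes: nearly five of six agents
cooperate per task, only two stay bold, and initiation concentrates on two
agents (d_I = 0.232 of a 0.373 maximum) while the rest become reliable
followers — which is why 99% of tasks succeed. A sweep makes the
difficulty and learning-rate trends explicit:

```r
sw <- run_sweep(game_params(), c(0.4, 0.9), obstacle_levels(),
                replicates = 5, base_seed = 1)
sw$by_cell[, c("lambda", "level", "mean_n_coop", "mean_n_bold",
               "diversity", "success_rate")]
#>   lambda level mean_n_coop mean_n_bold diversity success_rate
#> 1    0.4    O1        2.38        4.56    0.0703        0.932
#> 2    0.4    O2        3.10        3.84    0.1075        0.932
#> 3    0.4    O3        4.01        2.66    0.0934        0.774
#> 4    0.4    O4        4.89        1.84    0.1744        0.816
#> 5    0.9    O1        2.03        4.96    0.0683        0.992
#> 6    0.9    O2        3.05        3.94    0.1098        0.988
#> 7    0.9    O3        4.00        3.00    0.1693        0.996
#> 8    0.9    O4        5.00        2.00    0.2356        0.996
```

Harder tasks recruit more cooperators and leave fewer bold agents; the
larger update rate yields more role diversity and higher success on hard
tasks.

A command-line front end wraps the same functions:

```sh
Rscript scripts/simulate.R run --seed 42 --out results/
Rscript scripts/simulate.R sweep --lambdas 0.4,0.9 --levels O1,O4 --out results/
Rscript scripts/simulate.R reference --evolve --seed 1 --out results/
```

See `vignettes/boldness-leadership.Rmd` for the full account of the model,
the success-table stand-in, and the numerical choices.

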