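---
title: "Methods: embodied and game-theoretic stag hunt evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embodied and game-theoretic stag hunt evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staghunt)
```

## The scientific question

In the stag hunt coordination game, two hunters each choose between a hare
— a small but guaranteed reward — and a stag, which pays far more but only
if both hunters commit to it. Hare-hare is the risk-dominant equilibrium,
stag-stag the payoff-dominant one. Classical evolutionary analyses encode
the choice in a single binary locus, so one mutation turns a solitary
hunter into a perfectly competent cooperator, and the transition from the
solitary to the cooperative equilibrium only requires drift to lift the
cooperator frequency above the invasion threshold. `staghunt` implements
both that single-locus model and an embodied alternative in which the
hunting strategy is not a label but a behaviour: a wheeled agent steered by
an evolved neural network must find prey, commit to a stag, and physically
coordinate with its partner. Comparing the two under one evolutionary
regime quantifies how much the mechanics of behaviour impede the evolution
of mutualistic cooperation.

## The embodied model

**Arena and agents.** An 800 x 800 square arena with solid walls contains
two hunters and 18 stationary prey (9 hares, 9 stags, maintained by
same-kind respawn at a random free position after each capture). Every
agent is a solid disk of diameter 14. Hunters are differential-drive
vehicles: the controller's two outputs set the wheel speeds
`v = (2 o - 1) v_max` (so wheels can run backward; the all-zero controller
stands still), the heading changes by `(v_R - v_L) / d` with the wheel base
equal to the body diameter `d`, and the centre advances by the mean wheel
speed along the new heading. `v_max` defaults to 2 units/step, enough to
cross the arena a few hundred times per episode. Hunters move sequentially
in id order within a step; a moved hunter is clamped inside the walls
(per-axis) and pushed out of any overlapped disk along the
centre-to-centre axis to exact contact, sliding along a wall when both
constraints are active. Prey never move.

**Sensors.** Each hunter carries 12 proximity sensors spaced every 30
degrees around the body, reporting `max(0, 1 - d / 28)` where `d` is the
surface-to-obstacle distance along the sensor ray (walls and agent bodies
alike; range 28 = twice the diameter), and a camera of 12 rays spread
evenly across a 90 degree forward cone. A camera ray reports four values
about the first agent disk it intersects: two type bits
(none = 00, hunter = 01, hare = 10, stag = 11), a proximity
`max(0, 1 - d / diag)` normalised by the arena diagonal — camera rays have
unbounded range, so a bounded monotone mapping is needed — and a presence
bit distinguishing "no target" from "far target". A ray that reaches a
wall keeps the wall proximity but zero type and presence bits. Twelve
evenly spaced rays admit no exactly central ray; the two innermost rays
straddle the heading at ±3.75 degrees.

**Controller and genome.** The controller is a fully connected multi-layer
perceptron: 61 inputs (12 proximity + 48 camera + a constant bias of 1), 8
sigmoid hidden units, 2 sigmoid outputs. Genes live in [0, 1] and map
linearly to weights in [-5, 5]; `w_max = 5` saturates the sigmoid
comfortably and is the conventional range in evolutionary robotics. The
fully connected 61-8-2 architecture implies
`61 * 8 + (8 + 1) * 2 = 506` weights, including one bias weight per output
from the hidden layer; the genome length is always derived from the
configured architecture, and the architecture is configurable so that
reduced-input variants (for example a camera-only 49-8-2 network, which
lands on 410 weights) can be instantiated.

**Capture rule.** Each prey keeps one counter. The counter increments on
every step in which at least one hunter's centre is within the catching
distance (28 units — set equal to the proximity-sensor reach so that a
catching hunter can always sense its prey; the distance is configurable)
and resets to zero on a step with no hunter in range. This
consecutive-presence reading fits a rule phrased as "remains close
enough"; a cumulative-counter variant is available behind the
`cumulative_capture` flag. When the counter reaches 800 the prey is
captured; the capture is cooperative exactly when both hunters are in
range at that final step, so cooperation can occur even if one partner
arrived only for the last step. Every participant receives the full
reward-table entry (rewards are never split): hare 50 regardless, stag 500
cooperatively; under the baseline table a stag taken alone is removed but
pays nothing (a failed hunt), and under the solitary-stag-reward table it
pays 50. Both hunters may progress counters of different prey
simultaneously; two prey completing on the same step are processed in prey
id order.

## The evolutionary regime

A constant population of 20 genomes evolves for 3000 generations under a
Wright-Fisher model — the fitness-proportionate selection of evolutionary
robotics. To evaluate one individual, it is paired 5 times with a partner
drawn uniformly among the other 19 (a fresh draw each time, so partners
can recur) and plays 5 episodes of 20,000 steps per pairing; fitness is
the individual's total food divided by the 25 episodes. Only the focal
individual's payoff counts toward its fitness — the partner is evaluated
in its own 25 episodes. Each next-generation slot draws its parent with
probability proportional to fitness (uniform fallback when every fitness
is zero, e.g. before any prey is caught); every offspring is a mutated
clone — no recombination, no elitism. Mutation hits each gene
independently with probability 5e-3, adds a draw from `N(0, 0.1^2)` and
clips to [0, 1]; clipping (rather than reflection) keeps the gene law
simple at the boundary. The mutation scale follows the parameter-table
value `N(0, 0.01)` (variance 0.01, so sigma 0.1); a sigma of 0.2 also
circulates for this setup and is available via `mutation_sigma`.

Experiments that start from competent solitary hunters first evolve the
population in an arena stocked only with hares (same total prey count).
The length of that phase is not pinned down by the published record;
`pre_generations` defaults to 1000, long enough for hare-hunting
performance to plateau at the full scale, and the desk profile uses 50.
In clonal mode every episode pairs an individual with an exact copy of
itself (genetic relatedness 1), the standard clonal-selection regime.

## The single-locus baseline

The game-theoretic comparison keeps every evolutionary parameter and swaps
the genome for one binary locus, hare or stag. A bout pays the hare player
the hare reward unconditionally; a stag player earns 500 when the partner
also plays stag and the solitary-stag reward (0 under baseline) otherwise
— the failed attempt still counts as a hunted prey in the metric
denominator, mirroring the embodied convention where a solo-killed stag is
a removal. Each evaluation is 5 partner draws x 5 bouts; mutation flips
the locus with probability 5e-3 per individual per generation (the locus
reuses the per-gene rate, since the published parameters do not name a
separate flip rate; one bout per "simulation" is likewise a choice, and
both are configurable). Selection and the stag-percentage metric go
through the identical `wright_fisher_select()` and `stag_proportion()`
code paths as the embodied model; the per-generation loop is vectorised
but its payoff kernel is the same `gt_payoff_matrix()` that `gt_bout()`
consults, and the test suite asserts the two routes agree bout by bout.

Under random matching the replicator dynamics give an interior invasion
threshold

$$p^* = \frac{\text{hare}_\text{solo} - \text{stag}_\text{solo}}
             {\text{stag}_\text{coop} - \text{stag}_\text{solo}},$$

the cooperator frequency at which a stag hunter's expected payoff equals
the hare payoff: 0.1 for the baseline rewards, collapsing to 0 once a
solitary stag pays as much as a hare. `replicator_threshold()` returns
this closed form, and a property test verifies that large-population
no-mutation runs seeded just above and below `p*` fix to stag and hare
respectively.

### Why the one-locus transition is not certain here

With fitness-proportionate selection and focal-only payoffs, a lone stag
mutant in an all-hare population earns exactly zero and leaves no
offspring. A transition therefore needs at least two stag mutants in the
same generation (probability about `C(20,2) (5 \times 10^{-3})^2 \approx
4.4 \times 10^{-3}` per generation) of which at least one draws the other
among its five partner draws (about 42% per such event), followed by
survival of the young stag lineage through drift. Across 3000 generations
this compounds to a per-run transition probability of roughly 0.85–0.9
under the defaults, not certainty; about one run in eight never leaves the
solitary equilibrium. Model variants in which bout payoffs accrue to both
participants, or with more partner draws, make lone cooperators easier to
rescue and push the probability toward 1. We keep the focal-only
convention because it is the one the embodied evaluation uses, and report
the transition count as measured.

## Metrics and statistics

The headline metric is the percentage of stags hunted successfully
(cooperatively) among all prey hunted,
`100 * coop_stags / (hares + coop_stags + solo_stags)`, defined as 0 for
an empty denominator. Failed solitary stag hunts sit in the denominator —
they are prey removals and are plotted as their own bar in
last-generation summaries; `include_failed = FALSE` switches to the
alternative convention. Per generation the run record keeps the
population mean of this percentage (each individual's 25-episode aggregate
first, then the mean over individuals), mean fitness and mean per-episode
prey counts; the final generation also keeps the full per-episode count
table, from which `last_generation_summary()` computes per-run means and
standard deviations.

Between-condition comparisons use the Mann-Whitney U test on the per-run
final-generation stag percentages: midranks for ties, exact two-sided
p-values by the full null distribution of U when the pooled sample has at
most 12 untied observations, and the normal approximation with tie and
continuity corrections otherwise (p = 1 when the variance collapses
entirely). Two-sided p-values are used throughout. The implementation is
checked against a complete enumeration oracle and against
`stats::wilcox.test`.

Coordination behaviour is summarised by a circling statistic: the mean
absolute per-step change of the bearing from one hunter to the other,
wrapped to `(-pi, pi]` and symmetrised. A pair orbiting a common centre at
angular velocity `w` rad/step scores `w`; parallel straight motion and
stationary pairs score 0. Successful cooperators in this model
characteristically orbit one another while closing on a stag, so evolved
cooperative pairs score well above solitary hunters.

## Determinism and random streams

A run takes one master seed; every stochastic consumer (genome
initialisation, placement, pairing, episode worlds, Wright-Fisher
sampling, mutation) draws from its own labelled substream
(`make_rng(seed, label)`), so runs are bit-reproducible end to end and
each component can be driven independently in tests. Episode-internal
randomness (initial placement and respawns) runs on a dedicated
Mersenne-Twister inside the C++ engine, seeded from the episode's
substream; uniform deviates are produced by an explicit bit mapping so
results do not depend on standard-library internals.

## Numerical choices and degenerate inputs

* Collision resolution iterates disk pushes and wall clamps with an exact
  wall-slide when both constraints are active, stopping when a pass
  changes nothing (at most 16 passes); contacts carry a 1e-9 slack in the
  squared distance so a freshly projected contact does not re-trigger.
  In a corner squeeze that cannot satisfy every contact the walls win.
* Ray-disk intersection uses the standard quadratic closed form; an
  origin inside a disk reports distance 0, and disks whose centre lies
  behind the origin are rejected early.
* `stag_proportion(0, 0, 0)` is 0 by convention; zero-fitness populations
  select parents uniformly; mutation at probability 0 is the identity.
* Placement rejection-samples uniformly over the interior with at least a
  body radius of wall clearance and no disk overlap, erroring after a
  bounded number of rejections ("arena too crowded") rather than looping
  forever.
* Genome length mismatches are rejected with the configured architecture
  in the message, so the 506-vs-410 ambiguity surfaces loudly rather than
  silently misindexing weights.

## Problem sizes used by the tests

The published scale — 30 runs x 3000 generations x 25 episodes x 20,000
steps with 20 agents — is on the order of 10^10 controller evaluations per
run and is a cluster workload, kept as the package default so those runs
are exactly expressible. The test suite and worked examples run a desk
profile chosen to exercise every code path at a few percent of the cost: a
200 x 200 arena, 2000-step episodes, 200-step captures, 6 prey, population
10 and 50 generations (and 50 generations of hare-only pre-evolution).
At this scale hare-hunting fitness roughly doubles over the pre-evolution
phase, which is what the smoke test asserts. The single-locus model is
cheap and always runs at the full published scale.

## What the synthetic worlds do and do not show

The generator reproduces the study conditions: stationary prey, a fixed
prey mix, noiseless sensors, deterministic physics, and a two-hunter
arena. It does not model moving or evasive prey, sensor noise, more than
two hunters, or any communication channel — so green tests certify the
implementation of this model, not the robustness of its conclusions to
those richer settings. Conclusions about real cooperative hunting carry
the usual caveats of evolutionary robotics: the fitness valley between
solitary and coordinated strategies is a property of this
genotype-phenotype mapping, and mechanisms such as communication or
leader-follower asymmetries, deliberately out of scope here, could
reshape it.

## A worked desk-scale example

```{r example, eval = FALSE}
cfg <- desk_profile(condition_config("baseline"))
pop <- pre_evolve_hare_only(cfg, seed = 1)     # 50 hare-only generations
run <- evolve(cfg, seed = 1, initial_population = pop)
glance(run)
autoplot(run)

gt <- gt_evolve(condition_config("gt-baseline"), seed = 1)
tail(tidy(gt))
```

The corresponding full-scale experiment is
`run_experiment("baseline", n_runs = 30, base_seed = 0, profile = "paper",
out_dir = "runs/baseline")`, which writes per-generation CSV records, a
genome snapshot per run, a condition summary and a reproducibility
manifest.
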