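---
title: "The encounter game behind perceptual crossing: model, threshold, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The encounter game behind perceptual crossing: model, threshold, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpgame)
```

## The task being modelled

In the Perceptual Crossing Paradigm (PCP) two participants, call them Alice
and Bob, each move an avatar along a shared, invisible one-dimensional line
(topologically a ring) and receive binary haptic feedback whenever their
avatar overlaps an object. Each participant can feel three things: a private
static object; the partner's avatar (contact is mutual -- both players feel
it); and the partner's *shadow*, a lure that copies the partner's avatar at
a fixed spatial offset (the toucher feels it, the shadowed partner feels
nothing). The task is to find the partner. The shadow makes this hard:
locally it is indistinguishable from the real partner, except that it can
never respond to you.

`pcpgame` models each *encounter* with an unknown object as a choice between
two strategies: **L**, engage less (sense in passing, cheap in time), and
**M**, engage more (actively interact, costing `tau` times as long). A
player's overall disposition is summarised by `alpha`, the probability of
playing M on any given encounter.

## The encounter model

Let `rho_XY` be the probability that the focal player detects the partner
during one encounter with them, when the focal player plays X and the
partner plays Y. With a prior probability (default 1/3) that an encountered
unknown object is the partner at all, one probe yields

    p_L(alpha) = prior * ((1 - alpha) rho_LL + alpha rho_LM)
    p_M(alpha) = prior * ((1 - alpha) rho_ML + alpha rho_MM)

The two strategies are compared *at constant time cost*: an M-probe costs
`tau` L-probes, so the passive player gets `tau` independent tries,

    P_L = 1 - (1 - p_L)^tau        (geometric compounding)
    P_M = p_M

and the benefit of engaging is `g(alpha) = P_M - P_L`. Two standing
assumptions reduce the four probabilities to three numbers: a passive
partner is equally (un)detectable whatever you do (`u = rho_LL = rho_ML` --
there is nothing to interact with, so extra time does not help), and the
gain from reciprocated engagement is a ratio `w = rho_MM / rho_LM`.

```{r}
probs <- reduced_probs(u = 0.04, rho_lm = 0.1, w = 3.5)
benefit_g(encounter_params(alpha = c(0, 0.5, 1), tau = 3), probs)
```

Engaging alone is always costly (`g(0) < 0` whenever `tau >= 2` and
`u > 0`): against a passive partner an M-probe burns time that three
L-probes would have used better. Against a sufficiently engaged partner the
sign flips.

## The critical threshold delta

Whether the sign *can* flip at all depends on `w`. `delta_threshold()`
defines delta operationally as the infimum of `w` for which `g(alpha) > 0`
for some `alpha`, located by an alpha-grid scan plus bisection on `w` (the
maximum benefit is strictly increasing in `w`, so bisection is exact to its
tolerance; the benefit is cheap, so no derivative methods are needed).

```{r}
delta_threshold(rho_lm = 0.1, tau = 3, u = 0.04)
```

When the benefit is increasing in `alpha` at the threshold, the scan maximum
sits at `alpha = 1` and delta has the closed form
`(1 - (1 - prior * rho_lm)^tau) / (prior * rho_lm)`, which expands to
`tau - choose(tau, 2) * prior * rho_lm + ...` -- just below `tau`. The test
suite uses the closed form as an independent oracle. Two caveats we arrived
at while verifying the implementation, worth recording:

* the often-quoted sufficient condition for `g` increasing in `alpha`
  (`rho_MM - rho_ML > rho_LM - rho_LL >= 0`) is not in fact sufficient:
  compounding multiplies the L-side slope by up to `tau`, so the correct
  sufficient condition is `rho_MM - rho_ML >= tau * (rho_LM - rho_LL)`.
  Property tests sample from that regime.
* delta is a property of the model formulas; for large `rho_LM * tau` it
  can exceed the feasibility bound `1 / rho_LM` (where `rho_MM` would pass
  1), in which case no admissible probability set attains a positive
  benefit. The bisection therefore runs on raw arithmetic and leaves
  feasibility to the caller.

`alpha_cutoff()` gives the complementary quantity: for `w > delta`, the
partner engagement level above which switching to M pays. It decreases as
`w` grows.

## The landscape and the 2x2 game

`payoff_landscape()` evaluates `g` or the joint detection probability
`P(alpha_A, alpha_B) = alpha_A P_M(alpha_B) + (1 - alpha_A) P_L(alpha_B)`
on a grid; `reproduce_figures()` writes the four canonical grids
(`fig3.csv` ... `fig6.csv`) as full-precision CSV. Grid choices: 201 points
per axis (sub-second, finer than visual resolution); `w` in [1, 6];
`rho_LM` in [0.01, 0.28]. The upper bound 0.28 is deliberate: at `w = 2.8`
the region where engaging pays only reaches down to `rho_LM` around 0.205
(set `3 - rho + rho^2/9 = 2.8` from the closed form at `tau = 3`), so an
axis stopping at 0.2 would misleadingly show no positive region at all,
while the shared `w = 3.5` panel requires `w * rho_LM <= 1`, ruling out
0.3.

Binarizing engagement into "low alpha" and "high alpha" turns the encounter
into a symmetric 2x2 game whose payoffs are the joint detection
probabilities:

```{r}
game <- binarize_game(probs, tau = 3)  # quadrant centres 0.25 / 0.75
game
pure_nash(game)
classify_game(game)
ordinal_ranks(game)$row
```

At the canonical parameter set the game is an **Assurance game** (stag
hunt): two strict pure Nash equilibria, both-low and both-high, with
both-high Pareto-dominant -- not a Prisoner's Dilemma, because unilateral
engagement is not tempting, it is the *worst* cell. The structure is robust
to how the binarization is drawn (any `alpha_low <= 0.25`,
`alpha_high >= 0.75` at these parameters; the suite checks a grid of both).
Interestingly, the model also predicts a narrow Prisoner's-Dilemma band
below delta (around `w = 2`), where engaging is strictly dominated yet
mutual engagement would still beat mutual passivity.

Design notes: equilibria are reported as weak best responses with a
strictness flag, so degenerate inputs do not crash; ordinal ties get average
ranks plus a flag, and `classify_game()` refuses tied games ("other", with
a warning) rather than guessing. The default binarization uses the quadrant
centres since the binarized options mean "favouring" a strategy rather than
committing to it; the corners (0, 1) are available and are what
`validate_model()` uses, because the simulator estimates probabilities from
pure strategies only.

## The agent-based simulator

`simulate_trial()` implements the world directly: a ring (default
circumference 600 units) carrying both avatars, two private static objects,
and the two shadows at +48 units. Contact is binary overlap within 4 units.
The controller is deliberately minimal, with no pro-social prior:

* **Scanning**: move at `scan_speed` (2 units/step) with persistent
  direction, reversing with probability `turn_prob` (0.01) per step.
* **Contact onset** while scanning opens a probing episode against the
  touched object (nearest object on simultaneous onsets, ties to the lower
  object id): with probability `alpha` an engaged episode, else a passive
  one.
* **Passive probe (L)**: 50 steps of sensing *in passing* -- the agent
  keeps moving. This choice matters: a halting passive probe makes the
  agent trivially easy for an engaged partner to orbit (driving `rho_LM`
  toward 1 and `w` toward 1) and freezes mutual L-L contact into a single
  onset; either effect destroys the empirical game structure.
* **Engaged probe (M)**: `tau * 50` steps oscillating about the
  stimulation site at `engage_speed` (2.5), reversing whenever contact with
  the probed object is lost, confined within `engage_range` (30 units) of
  the anchor.
* All motion carries small Gaussian speed noise (`speed_jitter`, sd 0.5).

An episode scores a *detection* only if the probed object is the partner's
avatar (false positives are excluded by construction, mirroring the model's
no-type-I-error assumption) and the stimulation was rich enough: at least
`onset_min = 3` distinct contact onsets and at least `contact_frac = 0.3`
of the nominal window in contact. Only reciprocated oscillation delivers
that combination reliably; a lone engaged agent orbiting a transient
passerby, or two passive agents crossing cleanly, usually cannot.

The speed noise is the simulator's honest stand-in for human motor
variability, and it is load-bearing: two passive agents moving
co-directionally converge slowly and rattle in and out of contact, which is
what gives mutual non-engagement its small but non-zero detection rate --
the very quantity that makes both-low a genuine equilibrium rather than a
degenerate one.

Geometry and kinematics are not taken from any measured apparatus; they
were chosen once, at design time, so that a trial (6000 steps) yields a
healthy number of encounters with all three objects and the qualitative
assumption set below holds, and then frozen. All are exposed as
`world_config()` keys for sensitivity analysis.

## Estimating the detection probabilities

`estimate_rhos()` runs seeded trials for the four pure strategy pairs and
estimates each `rho_XY` as detected avatar-episodes over avatar-episodes,
with Wilson 95% intervals. One `std::mt19937_64` stream per (seed,
condition, trial, agent) makes every number exactly reproducible.
`validate_model()` then feeds the estimates back through the model and
checks the assumption set:

* `rho_MM > rho_LM`: reciprocated engagement helps;
* `rho_LM >= rho_LL`: an engaging partner is easier to feel even passively;
* `rho_LL ~ rho_ML` (overlapping intervals): engaging an unresponsive
  partner is no better than passing by;
* `w_hat > delta`: the induced game should be -- and at the defaults is --
  an Assurance game.

At the default configuration with 500 trials per pair (a few seconds of
compute) the estimates land around `rho_LL ~ 0.02-0.03`,
`rho_LM ~ 0.085`, `rho_ML ~ 0.02`, `rho_MM ~ 0.75`, giving `w_hat ~ 8.5`,
comfortably above `delta ~ 2.9`. A world with `tau = 1` (no time-cost
asymmetry) removes the compounding advantage of L and the assurance
structure with it.

## What the simulator does and does not show

The simulator emulates the *structure* of the PCP world -- the three object
types, one-sided shadow stimulation, binary contact, and the
time-cost asymmetry between probing styles -- with a deliberately crude
controller. It does not emulate human movement kinematics, learning across
trials, the click decision, or perceptual-awareness reports. Passing the
validation therefore shows that the Assurance structure emerges from the
world's interaction geometry plus a time budget, without any cooperative
disposition built into the agents; it does not show that human participants
realise these particular probability values.

Other known limitations: detection is scored by a fixed mechanical
criterion (onset count and contact fraction), so the estimated
probabilities shift with those thresholds (they are config keys precisely
so this can be probed); the 1/3 prior is an input to the model stage, not
estimated from the trace (the empirical share of avatar episodes is close
to but not exactly 1/3, since engaged windows consume time unevenly across
objects); and episodes truncated by the end of a trial are dropped rather
than scored.

## Numerical choices

Bisection tolerances: 1e-6 on `w` for `delta_threshold()` (with a 1e-12
positivity guard against roundoff in `1 - (1 - p)^tau` at `tau = 1`), 1e-9
for `alpha_cutoff()` via `uniroot()` after a 201-point sign scan. The
compounded probability uses the closed form `1 - (1 - p)^tau`; the test
suite holds it to the explicit series at 1e-12 over random draws. Landscape
CSVs are written at 17 significant digits so re-reading reproduces the
in-memory doubles exactly.
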