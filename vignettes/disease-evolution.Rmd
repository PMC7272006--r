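---
title: "Modelling disease evolution and diagnosis in stochastic reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease evolution and diagnosis in stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reactodx)
```

## The model

`reactodx` treats a living system as a mass-action chemical reaction network
of `N` species with copy numbers `0 <= X_i <= X_max` and `M` reaction nodes
(a reversible node contributes two directed reactions with independent
rates). A directed reaction `r` with reactant coefficients `nu-_r` and
product coefficients `nu+_r` fires with propensity

    eta_r(X) = kappa_r * prod_{i in L_r} choose(X_i, nu-_r(i)) / Omega^{|L_r| - 1},

the mass-action combination count scaled by the system volume. The ensemble
dynamics is simulated exactly with the Gillespie algorithm: waiting times are
exponential in the total propensity and the next reaction index follows the
cumulative-propensity inversion. Following the source model's accounting, a
*population* of `N_pop` independent, identical copies of the network is
advanced in *iterations* of `M` reaction events per copy, and all
probability estimates (marginals, joints, sign frequencies) are sample
averages over copies and averaging iterations.

Some species are *externally driven* signals: they gate reactions as
reactants but their counts are never changed by a firing, and across the
population their counts are uniform on `[0, X_max)`. The biological picture
is a population of cells exposed to heterogeneous but (on the relevant time
scale) persistent input levels.

*Health* is defined functionally: each signal species `i` has an assigned
set of response species `R(i)`, and the network's objective is

    E = sum_{i in S} mean_{j in R(i)} MI(X_i, X_j),

the summed mutual information transmitted from signals to their responses.
The healthy network is a local maximum of `E` over the reaction rates,
found by a zero-temperature Monte Carlo search (propose a joint uniform
perturbation of all rates, re-simulate, accept only improvements).

*Disease* is a reverse simulated annealing of the rates. A defect pattern
`D` marks a subset of reaction nodes. At step `t`, each defective node
mutates its rates by `+/- delta_kappa` with probability
`alpha(t) = min(1, t/tau_alpha)`; the mutated network is re-simulated and
the mutation is accepted if the objective does not decrease, or with
probability `exp(beta(t) * dE)` otherwise, where
`beta(t) = max(0, beta0 (1 - t/tau_beta))`. Early in the process mutations
are rare and harmful ones are rejected (a large inverse temperature plays
the role of a surveillance mechanism); late in the process mutations are
frequent and accepted freely, so the network drifts away from its optimum.
Interacting defect pairs combine their rates additively, as independent
Poisson processes, plus an interaction term
(`combine_defect_rates()`).

*Diagnosis* works on medical signs: the macroscopic state of a disease
realization at step `t` is the vector of binarized coarse activities
`S_i = sign(<X_i> - X_i*)` with thresholds `X_i* = X_max/2`. The D1S1 model
assumes marginally independent defects (uniform prior over the `M`
elementary defects, exactly one present) and conditionally independent
signs, with time-indexed conditionals `Pr_t(S_i = +1 | D_r)` estimated as
Laplace-smoothed frequencies over training realizations of the disease
dynamics; the healthy cohort provides `Pr_t(S_i | no defect)`. Given `N_O`
observed signs of a held-out realization, the maximum-a-posteriori
elementary defect is the diagnosis. Accuracy is summarized one-vs-rest over
trials and the trade-off between residual function and diagnostic
confidence,

    L(t : N_O) = lambda E(t)/E(0) + (1 - lambda) sqrt(AC(t : N_O) - 1/2),

is maximized over `t` to suggest an intervention time.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `x_max` | 1000 | copy-number cap, order of realistic molecule counts; relaxation times scale with it |
| `kappa` bounds | (0, 2) | dimensionless rate range within which the dynamics shows its non-trivial phases |
| `n_pop` | 1000 | population copies; statistical error of means and sign frequencies scales as `1/sqrt(n_pop * dt_av)` |
| `dt_eq`, `dt_av` | 200, 200 | per-window equilibration and averaging iterations |
| `n_bins` | 10 | equal-width count bins per axis for joint histograms |
| `delta_kappa` | 0.05 | mutation step of the defect dynamics |
| `beta0` | 100 | initial inverse temperature; with objective changes of order 0.01-0.1 nats, `beta0 = 100` makes early harmful mutations effectively always rejected |
| `tau_alpha`, `tau_beta` | 100 | schedule time scales; their ratio selects the sharp vs two-stage degradation regime |
| `t_max` | 500 | disease-evolution steps |
| pseudocount | 1 | Laplace smoothing of sign conditionals, preventing degenerate zero likelihoods |

## What the synthetic generator emulates, and what it does not

The catalog (`catalog_network()`) provides ten small signalling topologies:
single and parallel conversion chains with externally driven heads, coupled
through shared reactions, shared species, connecting links or cycles, up to
a three-pathway, 13-species, 6-node network. The published source of these
topologies describes them only at the level of panel captions, so the
catalog contains caption-faithful renderings (pathway count, coupling
style, species/reaction counts, signal/response assignments); the exact
stoichiometries are this package's own choices and are documented in the
catalog source.

The generator emulates: stochastic copy-number fluctuations, graded
signal-response transmission, slow network degradation by rate drift, and
cohort-level sign statistics. It does not emulate: transcriptional
regulation or non-mass-action kinetics (Hill/Michaelis-Menten), spatial
structure, cell division, structural mutations (the species set and
reaction pattern are fixed), or measurement noise on the signs. Passing
tests therefore demonstrate the internal consistency of the modelling
chain, not fidelity to any particular biological pathway.

## Numerical choices

**Driven species are drawn once, at population initialization**, and held
fixed per copy. The source description only requires the driven counts to be
uniformly distributed at all times, which this scheme satisfies. The
alternative - redrawing the driven counts every iteration - makes the
instantaneous signal independent of every response sample, so the
signal-response mutual information vanishes identically; with it, the
healthy-state optimization would have no gradient to climb. Member-persistent
signals are also the biologically sensible reading: each copy experiences its
own external condition, and transmission is measured across the population.

**Stationarity.** Response species relax towards their signal-conditioned
levels over a number of events that scales with `x_max` (empirically about
`15 x_max` events for the single chain). Runs that start from a fresh
uniform population are pre-equilibrated for `dt_init` iterations before any
statistics are collected, and the disease dynamics carries the population
state across steps, so each short per-step window measures a stationary (or
adiabatically tracking) ensemble.

**Objective estimation.** Mutual information uses the plug-in estimator on
`n_bins = 10` equal-width count bins (the raw joint over `x_max^2` states is
not estimable at these sample sizes); its positive bias is shared by healthy
and defective conditions and cancels in all comparisons. Natural logarithms
throughout.

**Monte Carlo acceptance with noisy objectives.** Both the healthy search
and the disease loop compare a freshly estimated `E_new` against the stored
`E_old` without re-simulating the incumbent. This mirrors the stated
algorithms and admits a known noise-induced uphill bias; it is acceptable
here because all downstream comparisons are between cohorts simulated the
same way. On rejection the rates revert but the chemical population state
keeps evolving (an organism does not reset when a mutation fails to fix);
with per-step re-equilibration the choice is weakly consequential.

**Sign conventions.** Coarse activities use the one-standard-deviation dead
zone around `X* = X_max/2`; the binary signs used by the diagnostic model
binarize at `X*` with ties mapped to `-1`. A mutation event on a reversible
node perturbs both directions with independent signs under a single
`alpha(t)` draw. Mutated rates are clipped into the open rate interval.

**Accuracy accounting.** The one-vs-rest confusion counts are aggregated
with positive and negative cases weighted equally (the balanced form of the
`(P_true + N_true)/(P_total + N_total)` ratio, to which it is identical
when the case totals balance). This keeps the chance level at exactly 1/2
for any number of defect classes, matching the stated random-diagnosis
baseline; the raw ratio is available as `accuracy_from_counts()`. In the
intervention objective, `sqrt(AC - 1/2)` is clamped at zero when sampling
noise puts `AC` below chance.

**Comparing the two annealing regimes.** The qualitative dichotomy between
the slow-mutation/fast-acceptance regime (a single transition that, once
begun, completes) and the fast-mutation/slow-acceptance regime (an early
shallow erosion followed by a long protected plateau) is summarized by two
cohort statistics: the first-stage erosion of the fast-mutation regime at
mid-time, and the final objective, which is far lower for the
slow-mutation regime because its protective inverse temperature has fully
annealed away while the other regime's has not. The precise *onset step* of
degradation is not a stable discriminator at desk scale - both regimes
begin eroding at statistically indistinguishable times, and their measured
onset ordering varies from seed to seed. For these comparisons the
per-step averaging window is lengthened (`dt_av = 100`) so that the
Metropolis rule responds to the true per-mutation objective change rather
than to estimator noise: with a noisy objective, a large inverse
temperature no longer rejects harmful moves reliably and the two regimes
artificially converge.

## Desk-scale study conditions

The test suite and `scripts/acceptance.R` rerun the whole pipeline at
reduced problem sizes chosen to preserve the relevant dimensionless ratios
(relaxation events per disease step relative to `x_max`, schedule time
scales, rate bounds):

* annealing-regime cohorts: single-chain network, `x_max = 200`,
  `n_pop = 1000`, per-step windows of 25 + 25 iterations (25 + 100 for the
  two-regime comparison, see above), `dt_init = 6000`, `t_max = 300`,
  20 realizations per condition;
* diagnosis cohorts: two-pathway network, `x_max = 100`, `n_pop = 150`,
  windows 25 + 25, `dt_init = 3000`, `tau_alpha = tau_beta = 100`,
  `t_max = 300`, 20 training and 40 evaluation realizations per elementary
  defect, all `N` signs observed;
* healthy optimization: 50 zero-temperature steps, proposal half-width
  0.15, evaluation windows of 1500 + 500 iterations at `n_pop = 300`.

The full-scale conditions of the source setting (`x_max = 1000`,
`N_pop = 1e5`, `dt_eq = dt_av = 200`, at least 100 realizations,
`t_max` of several hundred) remain the package defaults.

## Known limitations

* The healthy state is a *local* optimum from a random start; different
  seeds give different healthy networks, and all disease cohorts are
  defined relative to one fixture network.
* The plug-in MI estimator is biased upward at small sample sizes; only
  comparisons and ratios should be interpreted.
* With signs defined from population means, a "patient" is one realization
  of the disease dynamics (one cohort member with its own population); the
  model does not diagnose single molecular trajectories.
* Multi-defect diagnosis (`|D| > 1`) and history-based likelihoods over
  sign trajectories are out of scope; the interaction-rate combination is
  provided, but interacting-defect cohorts are not part of the standard
  pipeline.
* The iteration convention (a fixed number of events per copy per
  iteration) couples nominally independent pathways through event
  competition; this is a property of the source accounting, kept
  deliberately.
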