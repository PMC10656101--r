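---
title: "Sequential-sampling models of perceptual difficulty judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential-sampling models of perceptual difficulty judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffjudge)
```

## The problem

When an observer views two patches of colored random dots and must report
*which patch is easier to judge* (blue- vs yellow-dominant), they are making a
metacognitive decision about difficulty, not about color. `diffjudge`
implements a family of sequential-sampling models of that judgment, the
machinery to fit them to choice/RT data by simulation-based maximum
likelihood, Bayesian model comparison across observers, and the
reward-rate-optimal stopping policy for the same task, along with generators
for synthetic datasets that emulate the two experimental designs the models
target.

The stimulus variable is the signed color coherence $C^\pm = 2(p_{blue} -
0.5)$; its magnitude $C = |C^\pm|$ (the color strength) sets difficulty. The
experimental set uses six strengths $\{0, 0.128, 0.256, 0.384, 0.512,
0.64\}$ with both dominance tags, giving 12 signed levels; the $\pm$ tag on
zero is explicit because it decides which response is rewarded.

## The color drift diffusion model

Momentary color evidence is accumulated into a decision variable with
discrete updates

$$\Delta DV_t = \mu\,\Delta t + \mathcal{N}(0, \Delta t), \qquad
  \mu = \kappa\,(C^\pm + C_0),$$

so the DV has unit variance after one second of accumulation (a scaling
convention: any other variance can be absorbed into the remaining
parameters). The bias $C_0$ is an offset in coherence, not in the starting
point, which is the appropriate form when difficulty varies across trials.
Accumulation stops at a logistic collapsing bound

$$B(t) = \frac{u}{1 + e^{a (t - d)}},$$

which equals $u/2$ at $t = d$ and decays to zero; $a = 0$ gives a flat bound
at $u/2$. RT is the crossing time plus a Gaussian non-decision time
(mean $T_{nd}$, SD fixed at 0.05 s).

### Choice/RT densities

`fp_choice_rt_density()` computes the joint density over (choice boundary,
decision time) by forward propagation of the *discrete-time* process on a
uniform DV grid: each step convolves the surviving density with the exactly
binned Gaussian step kernel (CDF differences, with tail mass folded into the
end taps so each step conserves probability to machine precision) and then
absorbs all cells at or beyond $\pm B(t)$. This is the probability law of
the same process that `simulate_first_passage()` draws from, up to the DV
discretization, which is why the two agree closely (KS distance well below
0.02 at $10^5$ trials) without any tuning.

Numerical choices:

* time step 0.5 ms by default (the fitting convention for this model);
* DV step `u/200` by default (at least 200 cells per bound height) and
  never larger than $\sqrt{\Delta t}$ — a coarser grid cannot resolve the
  one-step kernel and is rejected as a configuration error;
* the discrete-time process crosses with a small overshoot of order
  $\sqrt{\Delta t}$, so closed-form agreement tightens as $\Delta t$
  shrinks; at 0.5 ms the flat-bound choice probability is reproduced to
  about 0.2% and the mean decision time to well under 2% for bounds around
  1, and the oracle tests refine the step to 0.1 ms for the smallest
  bounds, where the relative error is harshest;
* Gaussian non-decision convolution truncates the (numerically negligible,
  $<10^{-6}$ for $T_{nd} \ge 0.2$ s) mass below zero RT and renormalizes,
  so likelihoods stay proper densities.

## The four difficulty models

All difficulty models run two accumulators, one per stimulus, with drift
$\mu_x = \kappa C_x^\pm$ (no color bias) and *serial time multiplexing*:
updates alternate between the stimuli every 5 ms step (S1 on odd steps), so
each stimulus is sampled for half of real time and decision times are about
twice those of parallel integration. They differ in the decision statistic
to which the collapsing bound is applied:

* **race** — each DV races to its own $\pm B(t)$; the first crossing's
  owner is chosen. Both DVs are checked every step because a collapsing
  bound can overtake an idle DV.
* **difference** — the bound is applied to $|DV_{S1}| - |DV_{S2}|$.
* **two-step** — a mini color decision first: the DVs race to a
  low threshold $B_{mini}$ (flat for 2 s, then a sharp collapse forces the
  decision by the current signs, random on an exact zero). The crossing DV
  takes the sign of its bound; the other is signed by its value at
  $t_{mini}$. Thereafter the bound applies to
  $\mathrm{sign}_1 DV_{S1} - \mathrm{sign}_2 DV_{S2}$; the main bound
  collapses from $t = 0$ but no difficulty choice can occur before
  $t_{mini}$.
* **absolute momentary evidence** — increments are rectified,
  $\Delta DV = |\mu \Delta t + \mathcal{N}(0, \Delta t)|$, so both DVs are
  positive and increasing; the bound applies to $DV_{S1} - DV_{S2}$.

Conventions shared by all simulators: simultaneous crossings and exact-zero
sign decisions are resolved by the trial's RNG; trials that reach the 5 s
response deadline are resolved by the sign of the decision statistic and
flagged `terminated_by = "horizon"` so likelihood code can treat them
explicitly.

### A note on the absolute vs difference model at matched parameters

At a hard–hard (0:0) pair the two models' decision statistics have the
*same* marginal variance, $(1 - 2/\pi)t$: rectified increments have variance
$(1-2/\pi)\Delta t$ and accumulate independently, while the difference of
absolute DVs has full per-step variance $\Delta t$ but mean-reverts. Because
the difference statistic has the higher local volatility, it reaches a
matched bound *sooner*; simulations at any bound setting we examined show
the difference model faster at 0:0 when parameters are identical. The
often-quoted intuition that rectified accumulation produces faster hard–hard
responses is a statement about models at their own fitted parameters (the
absolute model underestimates hard–hard RTs relative to data), not about an
identical-parameter comparison, and the corresponding acceptance expectation
fails by design of the dynamics. We keep the faithful dynamics rather than
the slogan.

### Known color, confidence, controlled duration

With known dominance the statistic becomes $s_1 DV_{S1} - s_2 DV_{S2}$ with
the true sign tags: a 1D diffusion whose drift depends on the pair only
through $|C_1| - |C_2|$, which is why matched-$\Delta C$ pairs are
indistinguishable in RT and why responses are faster than the unsigned
difference statistic on average.

The confidence-difference model replaces DVs by log-odds confidence:
`build_confidence_map()` tabulates $\mathrm{logit}\,P(C^\pm > 0 \mid dv,
t)$ by marginalizing Gaussian likelihoods over the discrete signed set with
a uniform prior (tagged zeros contribute half mass to each color). The map
is antisymmetric in $dv$, zero at $t = 0$, clipped at $\pm 10$, gridded at
$dv$ step 0.025 and the simulation time step with bilinear interpolation.
Confidence grows supra-linearly with DV, so an easy–easy pair develops a
large confidence difference quickly — this model compresses the RT range
far more than the difference model.

In the controlled-duration paradigm an 80 ms sensory buffer holds both
streams in parallel; past it the stimuli share time equally:

$$T_{dur} = \begin{cases} T_{stim} & T_{stim} \le T_{buf} \\
T_{buf} + (T_{stim} - T_{buf})/2 & \text{otherwise.} \end{cases}$$

Both DVs then advance on the shared sampled-time clock up to $T_{dur}$ with
the collapsing bound evaluated on that clock (the bound's time axis during
externally controlled viewing is not pinned down by the task description;
we use the accumulation clock and state it here). If no bound is crossed,
the choice is the sign of the statistic at offset, ties random.

### Serial vs parallel integration

A parallel integrator (both DVs updated every step, unit variance per
second each) reproduces the serial model on the same real-time axis after a
DV-space rescaling: each serial DV at real time $t$ is distributed as
$1/\sqrt2$ times a unit-variance diffusion with drift $\kappa C/\sqrt2$, so

$$\kappa_p = \kappa_s / \sqrt2, \qquad u_p = u_s \sqrt2,
\qquad a_p = a_s, \qquad d_p = d_s$$

is an exact pathwise equivalence for every statistic built from the DVs.
`serial_to_parallel()` exposes the exponent ($\kappa_s 2^{-e}$, $u_s 2^e$;
default $e = 1/2$) so the mapping can be probed empirically; the test suite
confirms KS $< 0.02$ at $e = 1/2$ and a strong failure at the naive $e = 1$
reading ($\kappa_s/2$, $2u_s$), which circulates in rendered copies of the
transformation where the radical is lost.

## Simulation-based fitting

The likelihood of (choice, RT) data is built from simulation: for every
condition (signed coherence pair) the model is simulated (1000 trials per
condition by default; tests and the acceptance script use 120–200 and say
so here deliberately — the properties they check are scale-robust), and
each cell's RT sample is smoothed with an Epanechnikov kernel, scaled by
the cell's choice probability, and floored at $10^{-5}\,s^{-1}$ so an
observation outside the simulated support is penalized but never
$-\infty$. The bandwidth is a Silverman-style rule per (condition, choice)
cell, $h = \max(2\Delta t,\; 2.34\,\hat\sigma\, n^{-1/5})$ with
$\hat\sigma = \min(s, \mathrm{IQR}/1.34)$.

Fitting minimizes the negative log-likelihood with **common random
numbers**: the simulation stream is pinned to a fixed seed across optimizer
iterations, making the objective deterministic (and bit-reproducible, which
the tests assert). The optimizer is a bounded derivative-free contract:
uniform random presearch over the box, then Nelder–Mead on a logistic
transform of the box from the best presearch points, with one fresh-simplex
restart to guard against simplex collapse. Box bounds: $\kappa \in (0,
40]$, $u \in (0, 10]$, $a \in [0, 10]$, $d \in [0, 5]$, $T_{nd} \in [0.1,
1]$, $B_{mini} \in (0, 3]$.

Because $T_{nd}$ only shifts simulated RTs, it is profiled out: the
objective evaluates the NLL on a grid of $T_{nd}$ values (step 0.01 s by
default) and returns the minimum. This halves the search dimension at
negligible cost and does not change the likelihood being maximized.

### What is and is not identifiable

Parameter recovery at the first experiment's scale (1152 trials) pins
$\kappa$ well (relative error typically under 10%). The bound shape and
$T_{nd}$, however, lie on a likelihood ridge: a higher, earlier-collapsing
bound with a shorter non-decision time reproduces the generating model's RT
distributions almost exactly (KS $\approx 0.02$ against the truth at one
probe condition) and its smoothed likelihood sits within a fraction of a
nat of the truth's at 2000 simulations per condition. A more thorough
optimizer therefore lands anywhere along the ridge, and a $\pm 0.05$ s
recovery target for $T_{nd}$ is not attainable from these data — the
corresponding acceptance expectation is left failing rather than loosened,
and this section is the documentation of why.

### Model comparison

`bic()` is the standard $-2\log L + k \log n$; group comparison sums BICs
over participants. `exceedance_probabilities()` implements random-effects
Bayesian model selection: per-participant log evidences (approximated by
$-BIC/2$) enter variational fixed-point updates of a Dirichlet over model
frequencies, and the exceedance probability of each model — the posterior
probability that it is the most frequent in the population — is estimated
by Monte Carlo sampling from the fitted Dirichlet. Identical evidences give
uniform exceedance; a model better by $\Delta BIC = 10$ for every one of 20
participants exceeds 0.95.

Model recovery (`run_model_recovery()`) classifies refitted synthetic
datasets by lowest BIC. The race, difference and absolute models separate
cleanly (15/15 at the suite's scale: a 5-level signed grid, 1150 trials,
two optimizer starts). The two-step model is intrinsically confusable with
the difference model — its mini-decision stage is brief at reasonable
$B_{mini}$ and the extra parameter wins or loses by optimizer noise at
desk scale — so it is excluded from the scaled-down classifier and its
confusability is documented here rather than asserted.

## The reward-rate-optimal policy

The task is a POMDP whose belief state is $\langle t_{S1}, t_{S2},
DV_{S1}, DV_{S2} \rangle$. With strict alternation (S1 on even slices) the
two times are determined by the slice index, so the solver stores one
$DV_{S1} \times DV_{S2}$ matrix per slice. Components:

* the coherence posterior $P(C \mid dv, t) \propto \mathcal{N}(dv \mid
  \kappa C t, t) P(C)$ over the discrete set (prior uniform; the
  known-color variant replaces the signed set by the six unsigned
  strengths, so strongly negative evidence indicates a *low* coherence,
  not a negative one);
* the belief that choosing S1 is correct, $b(s, S1) = \sum_{C_1, C_2}
  P(C_1 \mid s) P(C_2 \mid s)\,\omega(C_1, C_2)$ with $\omega$ awarding 1
  when $|C_1| > |C_2|$, 0.5 on ties, 0 otherwise;
* sampling transitions: a mixture over the sampled stimulus's posterior of
  binned Gaussians with mean shift $\kappa C \Delta t$ and variance
  $\Delta t$, discretized by CDF differences with tail mass accumulated in
  the edge bins, so each kernel row sums to one exactly;
* Bellman backward induction over slices: the value of a state is the max
  of the two terminal values $b R_c + (1 - b)(R_n - t_p \rho) - (t_{nd} +
  t_w)\rho$ and the continuation value $E[V_{n+1}] - \rho \Delta t$; the
  terminal slice admits only terminal actions;
* the reward rate $\rho^*$ solves $V(s_0; \rho) = 0$ by bisection on
  $[0, R_c/(t_{nd}+t_w)]$ to $|V(s_0)| < 10^{-3}$ (at most 40 iterations);
  posteriors and kernels are $\rho$-independent and precomputed once.

Grid defaults: $\Delta t = 0.05$ s, $\Delta DV = 0.1$, DV range $\pm 6$
(wide enough for $\kappa = 13$; edge bins accumulate any escaping mass),
horizon 5 s of sampling, matching the task deadline. $\Delta DV$ must not
exceed $\sqrt{\Delta t}$ or the one-step kernel is unresolved
(configuration error). Policy simulation snaps the continuous DV state to
the nearest grid node for the lookup and adds the constant $t_{nd}$ to
decision time (no non-decision jitter in this model — the choice the
simulation contract documents).

At the headline parameters ($\kappa = 13$, $R_c = 1$, $R_n = 0$, $t_p = 1$
s, $t_{nd} = 0.4$ s, $t_w = 0.5$ s) the solved policy yields accuracy
monotone in $|\Delta C|$, the magnitude effect (hard–hard slower than
easy–easy), and continue regions that become disjoint late in the trial:
near the origin it eventually pays to guess, while off-diagonal states
still sample.

Fitting the four descriptive models to $2\times10^4$ trials simulated from
this policy, the race model is far worst and the difference model clearly
beats the absolute model — the policy behaves like a comparison of signed
evidence differences. One caveat worth recording: at the suite's fit depth
the difference model ranks first outright, but deeper optimization (more
starts and simulations) lets the two-step model edge past it by roughly
0.02 nats per trial. The policy's decision times live on the 0.05 s slice
lattice with a hard floor of one slice plus $t_{nd}$, and the two-step
model's mini-decision stage is the only descriptive mechanism that can
produce such a floor, an advantage its extra parameter can buy once the
optimizer finds it. The difference-first ranking should therefore be read
as the behavior of the bulk RT distribution, not of its leading edge.

## Synthetic designs

`design_exp1_difficulty()` builds the RT-task session: all $12 \times 12$
signed pairs balanced exactly (8 repeats each at the default 1152 trials),
shuffled per seed, blocks of 96, sessions split 3 + 9 blocks.
`design_exp2()` builds the two-color experiment's conditions: unknown color
uses the full signed grid, known color the same-sign $6 \times 6$ pairings
(half the blocks blue, half yellow); equal-strength cells appear at one
third the frequency of other cells, exactly by construction, and we count
the 0:0 pairs among them (they are equal-strength by definition).
Controlled-duration designs attach the six durations $\{0.1, 0.15, 0.25,
0.45, 0.85, 1.65\}$ s with an exactly uniform marginal. The $\pm$ tag on
zero coherence is drawn uniformly per trial and stored. Feedback follows
the task's rule: on equal-strength pairs, "correct" is designated at
random.

What the generator deliberately does **not** emulate: miss trials and
their re-insertion (simulated agents always respond), attentional lapses,
sequential or learning effects, and any non-stationarity in $\kappa$ —
so green tests certify the implementation against its own model class, not
against idiosyncrasies of human data.

## Problem sizes in the test suite

The acceptance tests run the closed-form oracle on a $3\times3$ grid (time
step 0.1–0.5 ms, refined where the bound is smallest); FP-vs-MC
equivalence at $10^5$ trials; model signatures at $10^4$ trials per
condition; known-color reductions at $2\times10^4$; parameter recovery
over 10 replicates of session-scale datasets (1150 trials on a 5-level
signed grid, $\pm\{0, 0.256, 0.64\}$ plus signs) with 4 optimizer starts
and 150 simulations per condition; model recovery over 5 datasets per
generating model at the same scale with three diverse starts and 200
simulations; and the optimal-policy analyses at $2\times10^4$ simulated
trials. The 5-level grid keeps every diagnostic cell of the full design
(the criss-cross corners plus one intermediate strength — dropping the
intermediate levels entirely was piloted and destroys the
difference/absolute distinction) at a fifth of the likelihood cost. These
sizes are the package's desk-scale defaults; all thresholds are stated on
the properties, not on the sizes.

## Known limitations

* The smoothed likelihood is biased at kernel-bandwidth scale; fitted
  bound-shape parameters inherit the ridge discussed above.
* The FP propagation is first-order in $\Delta t$ through the crossing
  overshoot; use a smaller step when absolute bound heights are small.
* The optimal-policy solver assumes strict alternation and a discrete
  coherence prior; continuous priors or free sampling orders are out of
  scope.
* The confidence model rebuilds its map at every candidate $\kappa$ during
  fitting, which makes it the slowest model to fit by a wide margin.
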