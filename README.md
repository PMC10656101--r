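# diffjudge

Sequential-sampling models of **perceptual difficulty judgments**: deciding
which of two simultaneous perceptual decisions is the easier one, before (or
without) making either decision.

The package is aimed at computational cognitive scientists who model choice
and reaction time with accumulator models. It covers the full analysis
stack for a two-patch color task in which observers judge which patch of
colored random dots has the clearer color dominance:

* a single-accumulator **color drift diffusion model** with a logistic
  collapsing bound — Monte Carlo simulation and grid-propagated
  (Fokker-Planck-style) choice/RT densities with Gaussian non-decision time;
* four competing 2D accumulator models of the **difficulty judgment** —
  race, difference, two-step, and absolute momentary evidence — as serial,
  time-multiplexed integrators, plus known-color, confidence-difference,
  and controlled-duration (sensory-buffer) variants;
* **simulation-based maximum likelihood** fitting (Epanechnikov-kernel
  smoothed likelihoods, common random numbers, bounded derivative-free
  multi-start optimization), BIC / group BIC, and random-effects
  **exceedance probabilities**;
* the **reward-rate-optimal stopping policy** as a belief-state MDP over
  ⟨t₁, t₂, DV₁, DV₂⟩ solved by backward induction with bisection on the
  reward rate;
* generators for **synthetic trial tables** that emulate the two
  experimental designs (balanced 12×12 signed-coherence pairs; same-sign
  known-color blocks; equal-strength down-weighting; controlled duration
  set), with CSV round-trip I/O.

## The models in brief

Evidence for stimulus *x* accumulates as ΔDV = κC±ₓΔt + N(0, Δt) (unit
diffusion variance per second), alternating between the two stimuli every
step. A trial ends when the model's decision statistic reaches a logistic
collapsing bound B(t) = u / (1 + exp(a(t − d))):

| model      | decision statistic                         |
|------------|--------------------------------------------|
| race       | either DV against its own ±B(t)            |
| difference | \|DV₁\| − \|DV₂\|                          |
| two-step   | sign₁DV₁ − sign₂DV₂ after a mini color decision at ±B_mini |
| absolute   | DV₁ − DV₂ with rectified increments \|κCΔt + N(0,Δt)\| |

The optimal policy maximizes correct choices per unit time: posteriors over
the discrete coherence set per stimulus, belief b(s, S1) that S1 is the
easier patch (ties count half), and Bellman backward induction with the
reward rate ρ found by bisection on V(s₀) = 0.

See the methods vignette (`vignettes/difficulty-models.Rmd`) for the full
model definitions, numerical choices, and identifiability notes.

## Worked example

```r
library(diffjudge)

pars <- difficulty_params(kappa = 10,
                          bound = collapsing_bound(u = 2.5, a = 1.5, d = 1.5),
                          tnd_mean = 0.35)

trials <- function(c1, c2) data.frame(c1 = rep(c1, 10000), c2 = c2)
hh <- simulate_difficulty("difference", pars, trials(0, 0),       seed = 1)
ee <- simulate_difficulty("difference", pars, trials(0.64, 0.64), seed = 2)
eh <- simulate_difficulty("difference", pars, trials(0.64, 0),    seed = 3)
round(c(hard_hard = mean(hh$rt), easy_easy = mean(ee$rt),
        easy_hard = mean(eh$rt), p_s1_easy_hard = mean(eh$choice == "S1")), 3)
#>      hard_hard      easy_easy      easy_hard p_s1_easy_hard
#>          2.329          1.959          1.089          1.000

sol <- solve_reward_rate(optimal_config(kappa = 13))
round(c(rho = sol$rho, V0 = sol$V0), 4)
#>     rho      V0
#>  0.5545 -0.0002
```

The difficulty-difference model shows the magnitude effect (equal-difficulty
pairs are answered faster when both stimuli are strong: 1.96 s vs 2.33 s)
and near-certain choices when only one stimulus is easy. The optimal-policy
solver returns the reward rate (correct choices per second) at which the
value of starting a trial is zero — the calibration point of the optimal
urgency.

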