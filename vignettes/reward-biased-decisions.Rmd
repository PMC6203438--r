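---
title: "Reward-biased decisions: model, surfaces, and the satisficing learner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-biased decisions: model, surfaces, and the satisficing learner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardDDM)
```

## The problem

In a response-time random-dot motion discrimination task with asymmetric
rewards, a subject reports the perceived motion direction with an eye
movement; correct choices toward one side earn a large juice reward and
toward the other a small one, with the large-reward side alternating
between blocks of 30–50 trials (the `LR-Left` and `LR-Right` reward
contexts).  Subjects bias their choices toward the large-reward option,
and the interesting scientific questions are *how* that bias is
implemented in the decision process, how close it comes to maximising
reward, and what learning rule could produce the specific pattern of
deviation from the optimum.  `rewardDDM` implements that full analysis
chain against synthetic sessions, so each stage can be validated with
known ground truth.

## The decision model

The core model is a drift-diffusion model (DDM) with two
context-dependent bias parameters.  Motion evidence at signed coherence
$C$ (negative leftward, positive rightward) drives an accumulator with
unit-variance Gaussian noise per second:

$$ dx = k\,(C + me)\,dt + dW, $$

starting at $a z$ between absorbing bounds $0$ (left choice) and $a$
(right choice).  The six parameters per reward context are the bound
height $a$, the evidence scaling $k$, non-decision times $t_0$ (left)
and $t_1$ (right) added to the first-passage time, the *decision-rule
bias* $z \in (0,1)$ (start point as a fraction of $a$; $z > 0.5$ favours
rightward choices), and the *momentary-evidence bias* $me$ in
signed-coherence units, added to the stimulus evidence at every step
($me > 0$ favours rightward).  The unit-variance noise convention fixes
the scale of all parameters; fitted magnitudes of order $a \approx 1.5$,
$k \approx 5$ are typical for monkey data on this task.

Choice probabilities, unconditional and bound-conditioned mean decision
times, and the first-passage density all have standard closed forms for
this process; the density uses the small-time and large-time series
expansions with the usual term-count switching rule (truncation
tolerance $10^{-7}$).  We verified the closed forms against numerical
integration of the density before adopting them, and the test suite
holds them against Monte-Carlo simulation throughout.

### Numerical choices

* **Simulation.** Trials are simulated by Euler–Maruyama steps
  (`dt` default 0.5 ms, censoring horizon 30 s) with a Brownian-bridge
  within-step crossing test.  The plain Euler scheme misses excursions
  between grid times and therefore under-detects bound crossings — an
  $O(\sqrt{dt})$ bias equivalent to widening each bound by
  $\approx 0.58\sqrt{dt}$, which is large enough to be detected when
  comparing $10^5$ simulated trials against the analytic results.  The
  bridge test (crossing probability $e^{-2(b-x)(b-y)/dt}$ per step and
  bound) removes that bias to $O(dt)$, so the simulator can serve as an
  honest independent oracle for the analytic formulas.
* **Collapsing bounds.** The collapsing-bound variant sets the distance
  between bounds to $a/(1+e^{\beta t-d})$.  Only the distance is
  specified by that form; we collapse both bounds symmetrically toward
  the midpoint of the initial interval and hold the start point fixed.
  This is an assumption, not a derived fact; with $\beta = 0$ the
  process reduces (distributionally) to a fixed-bound DDM with bound
  distance $a/(1+e^{-d})$, which the tests exploit.  Its likelihood has
  no closed form and is estimated by simulation with common random
  numbers and a kernel density per choice-by-coherence cell; these fits
  are slow and noisier than the analytic fixed-bound path.
* **Fitting.** Sessions are fitted per reward context by maximising the
  summed log first-passage density over single trials (L-BFGS-B, box
  bounds $a\in(0.3,5)$, $k\in(0.5,40)$, $z\in(0.05,0.95)$,
  $me\in(-0.6,0.6)$, non-decision times $(0.02,0.6)$ s), from a
  moment-based start plus Latin-hypercube restarts.  RTs at or below
  the smallest admissible non-decision time are pre-screened with a
  warning.  Reduced variants fix $z = 0.5$ (`me_only`) or $me = 0$
  (`z_only`).

### Model comparison

The reference analysis used hierarchical Bayesian fitting and DIC; this
package fits per-session maximum likelihood, so model comparison uses
BIC (AIC is also reported).  The decision logic is preserved: because
information criteria can favour complexity, `compare_models()`
calibrates the observed full-minus-reduced difference by
simulate-and-refit — taking each reduced model's fit as ground truth,
simulating trial-matched datasets, refitting all variants, and
reporting the expected difference under the reduced truth.  A negative
observed difference together with non-negative expected differences
under the reduced truths is evidence for genuine involvement of both
bias parameters.

## Psychometric characterisation

Choice data alone are summarised by a lapse-bounded logistic,

$$ P(\text{right}) = \lambda + (1-2\lambda)\,
   \frac{1}{1+e^{-\beta\,(C-\alpha)}}, $$

with one shared lapse $\lambda \in [0, 0.45]$ and context-specific bias
and sensitivity ($\alpha_0$, $\alpha_0+\alpha_{rew}$; $\beta_0$,
$\beta_0+\beta_{rew}$).  We share the lapse across contexts because the
reported lapse medians are zero and a context-split lapse is not
identifiable at session size.  A sequential-bias extension adds
$I_{seq} I_{rew}\,\alpha_{seq}$ to the bias, where $I_{seq}$ flags the
previous trial's type (choice to the large/small-reward target,
correct/error) and $I_{rew} = \pm 1$ encodes the current context; the
term is tested with a 1-df likelihood-ratio test, warm-started from the
base optimum so optimiser noise cannot inflate the statistic.  The test
is well calibrated at realistic session sizes (about 1000 trials); at a
few hundred trials the small-sample likelihood-ratio distribution is
visibly heavier than $\chi^2_1$, which is why the calibration suite
uses 1000-trial sessions.

`optimal_delta_bias()` provides the purely psychometric optimality
benchmark: the difference in horizontal shift between the two contexts'
curves that would maximise expected reward per trial given the fitted
sensitivities, the coherence set and the reward ratio.  The shift is
decomposed as equal-and-opposite offsets of the two curves; the
benchmark only depends on their difference.

## Reward surfaces and optimality

`compute_surface()` maps expected reward per trial (`RTrial`) or per
second (`RR`) over a grid of $(me, z)$ combinations (default
$me \in [-0.6, 0.6]$, $z \in [0, 1]$; $z$ is evaluated just inside the
open interval at the grid edges), holding the non-bias parameters and
the task economics fixed.  The analytic engine uses the closed-form
choice probabilities and conditional mean times; the Monte-Carlo engine
mirrors the simulation-based procedure (1000 trials per
coherence-by-direction cell by default) and is retained for collapsing
bounds and as a cross-check.  For `RR`, each trial costs its mean RT
plus the inter-trial interval plus the error probability times the
timeout; whether the timeout replaces or adds to the ITI is not
specified by the task description, and we add it.  `RTrial` is by
definition independent of both.

Surface features follow the reference analysis: the grid argmax
(`RTrial_max`), the patch of nodes at $\ge 97\%$ of the maximum whose
area (in grid-node units, the analogue of pixels) measures the
tolerance for deviations from optimality, and the patch orientation —
the angle of its principal axis from vertical, computed by PCA of the
node coordinates in grid-index units, positive when the patch top tilts
toward positive $me$.  Near-circular patches are flagged isotropic with
orientation reported as 0.  `reward_summary()` interpolates the surface
bilinearly at fitted biases to give `RTrial_predict` and the
predicted-to-max ratio; `conditional_optima()` gives the conditionally
optimal value of one bias given the other.

With the published mean non-bias parameters of the mid-sensitivity
animal and reward ratio 1.91, the `RTrial` optimum sits at $me^* < 0$,
$z^* < 0.5$ for `LR-Left` and mirrored for `LR-Right` — both biases
favouring the large-reward choice — and the fitted published biases
land at about 98.5% of the attainable reward, matching the reported
near-optimality.  `scripts/acceptance.R` recomputes exactly these
optima.

## The satisficing learner

The observed pattern — $me$ over-adjusted toward the large reward, $z$
adjusted toward the *small* reward — is explained by gradient ascent on
the session's reward surface from an over-biased start, stopping as
soon as the session's achieved reward level is reached
(`RTrial_predict`, computed from the fitted parameters, not the
realised reward stream).  Four starting-point variants are implemented:
`over_me` ($me_0 = \mp 0.9 \times$ the session's highest coherence,
adaptive sign; $z_0$ at the across-context midpoint of the fits),
`over_z` ($z_0 = 0.1$ or $0.9$; $me_0$ at midpoint), `over_both`, and
`neutral`.  The ascent takes fixed-length steps (default 1/200 of the
grid diagonal) along the bilinearly interpolated finite-difference
gradient; step size, interpolation and tolerances are our choices —
the procedure is defined graphically in the source analysis — and the
tests check that halving the step moves endpoints by less than one grid
cell.  Endpoints are classified by the sign of $me$ (vs 0) and $z$ (vs
0.5) relative to the large-reward side, with boundary ties broken to
adaptive.

On surfaces built from the published mean parameters, only the
`over_me` start produces the observed joint signature
($\Delta me > 0$, $\Delta z < 0$, with deltas defined as `LR-Right`
minus `LR-Left` so that positive favours the large reward); `over_z`,
`over_both` and `neutral` starts all fail to reproduce it.  This is the
package's main qualitative reproduction and is asserted in the
acceptance suite.

## The synthetic world

`generate_session()` emulates the task structure the analysis assumes:
reward contexts alternating in blocks of 30–50 trials; directions and
coherences (default $\pm\{0.032, 0.064, 0.128, 0.256, 0.512\}$) drawn
uniformly at random within blocks; the first two trials of each block
at the highest coherence, mimicking the signalled block change, and
flagged `excluded` as in the source analysis; choices and RTs from the
context's ground-truth DDM with a 50 ms minimum-latency floor enforced
by resampling (truncation would distort the RT density); rewards by
context and correctness.  Defaults use a reward ratio of 1.91 (the
printed mean for the mid-sensitivity animal; printed means for the
three animals were 1.34, 1.91 and 2.45).  The inter-trial interval is
not printed in the task description; we use 2 s, typical for this
preparation, and the error timeout defaults to 3 s (a printed value).
Neither affects `RTrial`.  Zero coherence is excluded (the task's sets
contain none), so correctness is always defined.
`generate_cohort()` scales sensitivity $k$ by a per-session multiplier
to emulate across-session sensitivity changes and jitters the remaining
parameters uniformly with configurable half-width; no generative model
across sessions is specified by the source analysis, so uniform jitter
is a deliberate minimal choice.

What the generator does *not* emulate: fixation breaks and aborted
trials, eye-position traces, within-block learning dynamics, or any
sequential choice dependence (unless injected through the psychometric
test fixtures).  A green test therefore establishes that the estimators
and benchmarks are correct for the stated generative world, not that
the world captures every feature of animal behaviour.

## Known limitations

* Collapsing-bound likelihoods are Monte-Carlo approximations; use
  generous `n_mc` and expect slower, noisier fits.
* The satisficing learner operates on the static per-session surface;
  trial-by-trial reinforcement learning within blocks is out of scope.
* No across-trial parameter variability (drift, start point,
  non-decision time) is modelled, matching the reference model.
* Per-session maximum likelihood replaces hierarchical shrinkage;
  estimates from very short sessions are correspondingly noisier.
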