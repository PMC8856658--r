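---
title: "Steering under changing control dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steering under changing control dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerdyn)
```

## The task and its dynamics

`steerdyn` models a virtual-navigation steering task: on each trial a target
appears at distance $r \in [2.5, 5.5]$ m and bearing
$\theta \in [-38^\circ, +38^\circ]$, and the participant steers to it with a
two-axis joystick under one of three interleaved sensory conditions
(vestibular, visual, combined). Joystick input $u_t \in [-1, 1]$ maps to
linear and angular velocity through a first-order leaky integrator,

$$v_{t+1} = \alpha v_t + \beta_v u^v_t, \qquad \alpha = e^{-\Delta t/\tau},$$

so that a small time constant $\tau$ gives velocity-like control and a large
one acceleration-like control. Sustained full input saturates at
$v_{max} = \beta_v/(1-\alpha)$.

**Gain calibration.** So that every $\tau$ permits reaching an average
target in an average time, the maximum speed is yoked to $\tau$ through the
continuous-time bang-bang solution: full positive input until the switch
time

$$s = \tau \log\!\frac{1 + e^{T/\tau}}{2},$$

then full negative input brings the velocity back to zero exactly at $T$,
having covered $x_T = 2\tau\, v_{max} \log\cosh(T/2\tau)$. Solving
$x_T = x$ for $v_{max}$ with $x = 4$ m and $T = 8.5$ s gives
$v_{max}(\tau)$; the angular ceiling uses the same formula with an angular
calibration displacement. Both $\log\cosh z$ and $\log\frac{1+e^z}{2}$ are
evaluated in shifted `log1p` form because $z = T/\tau$ can exceed 700 and
overflow a naive `exp`.

**Angular calibration (a design choice).** The angular analogue of $x$ — the
angle a full-time angular manoeuvre should cover — is not pinned down by the
task geometry, and reasonable choices differ by an order of magnitude. We
default to $\theta_{cal} = \pi/2$. The smallest candidate, the mean
absolute target bearing ($19^\circ$), makes $\omega_{max} \approx 0.05$
rad/s at mid-range $\tau$; a smooth approach path to a target at bearing
$\theta$ ends with heading $\approx 2\theta$ (up to $76^\circ$), which
such a slow turn cannot achieve within the nominal trial time — the far
targets would be kinematically unreachable and angular response gains could
never approach 1. With $\pi/2$ the fan is reachable, though the full-speed
turning radius under velocity-like dynamics (~2.5 m) still exceeds the
capture geometry at the extreme corner of the fan (small $\tau$, bearing
near $38^\circ$): a deterministic agent can overshoot such a target
laterally and circle it until the trial timeout. These trials (a few
percent of a session) are flagged `timed_out` and retained, mirroring how
any stopping-rule violation is handled. The value is exposed in
`sim_config()`.

**Trial-varying dynamics.** $\phi = \log\tau$ follows a stationary AR(1)
across trials, $\phi_{t+1} = c\phi_t + \eta_t$ with $c = e^{-1/\tau_\phi}$,
$\tau_\phi = 2$ trials, and innovation moments chosen so the marginal is
$N(\mu_\phi, \sigma_\phi^2)$ with $\mu_\phi = \frac12(\log\tau_- +
\log\tau_+)$ and $\sigma_\phi = \frac14(\log\tau_+ - \log\tau_-)$: the
bounds sit two marginal SDs out, so about 95.45% of trials fall inside
$[\tau_-, \tau_+]$ (defaults 0.6 and 3.0 s). We implement the "bounded"
walk literally as this stationary process — the equations bound it only
probabilistically — with an optional hard clamp for sensitivity checks. One
walk spans all of a participant's trials while condition labels are
randomly interleaved, as in the experiment.

## The synthetic participant

No steering policy is specified by the behavioural analyses themselves, so
the generator commits to the minimal controller consistent with observed
joystick traces (sustained forward input, then braking):

1. **Belief about the dynamics.** On each trial the agent's internal
   estimate is the log-space posterior point estimate
   $\hat\phi = \frac{\lambda^2\phi + \mu_{prior}}{\lambda^2+1}$ (see below)
   plus Gaussian jitter (SD 0.1 log-s by default) standing in for
   unmeasurable trial-to-trial belief fluctuations.
2. **Belief-space control.** The agent integrates its own (noisy, clipped)
   joystick output under the dynamics implied by $\hat\tau$ and steers the
   angular channel proportionally to the believed bearing error
   ($u^\omega = \mathrm{clip}(K \cdot \text{error})$, $K = 2$). It holds
   full forward input until the believed distance to the gain-scaled
   target falls below the believed stopping distance of a full-brake
   rollout of the discrete believed dynamics (a cheap continuous-time
   closed form screens the exact rollout), brakes fully until the believed
   speed falls below 1 cm/s, and releases the stick.
3. **Reality.** The same joystick signal drives the true dynamics
   $\tau$; the trial ends when the actual speed falls below 1 cm/s, or is
   flagged at a hard timeout of $4T$.

Gaussian motor noise (SD 0.05) is added to both channels before clipping.
Intended response gains below one (0.85 radial, 0.95 angular) give the
generated data a realistic undershooting bias for the analysis stage to
estimate. Sensory condition affects only the observer parameters
($\lambda$: vestibular 0.3, visual 1.0, combined 0.8; $\mu_{prior} =
\mu_\phi$) — no rendering is simulated. The generator targets the
statistical structure of real sessions (gains, residual-error structure,
interleaving, walk), not waveform realism: real traces contain partial
inputs and corrections the two-phase policy does not produce, so passing
tests certify the analysis chain, not human-likeness of individual traces.

## Behavioural analyses

Response gains are slopes of regressions through the origin
($g = \sum xy / \sum x^2$), radial and angular separately; $R^2$ is
uncentered ($1 - SSE/\sum y^2$), the standard choice for no-intercept
models. Residual errors are $\varepsilon_{r,i} = \tilde r_i - g_r r_i$ (and
the angular analogue), and their Pearson correlation with $\tau$ is the
core mal-adaptation statistic. The interaction regression
$\tilde r = b_r r + a_r r\tau$ is fitted on SD-scaled (not centred)
variables; partial correlations are computed by residualising against the
remaining predictors. Tertile splits rank trials by $\tau$ with ties broken
by trial index; remainders go to the lower groups.

The **no-adaptation null** re-integrates the joystick traces of trials with
near-mean $\tau$ (±0.2 s around the dataset mean) under time constants
drawn from other trials, bins the simulated trajectories by the actual
tertile edges, and regresses actual tertile gains on null tertile gains
(slope 0 = perfect adaptation, 1 = none). Because a recorded trace ends
when *its own* trial's speed crossed threshold, re-integration under other
dynamics coasts with zero input until the simulated speed also crosses
threshold; without this, slow-dynamics re-integrations are cut short and
the null gains are compressed.

## The observer-model family

All models reconstruct a *believed trajectory* by re-integrating the actual
joystick input under a per-trial estimate $\hat\tau$, and are scored by the
mean squared Euclidean distance between the believed stopping location and
the gain-scaled target $G x^{tar}$ (the participant's mean response for
that target):

- **static prior** — $\hat\phi_i = \frac{\lambda^2\phi_i +
  \mu_{prior}}{\lambda^2+1}$ with free $(\mu_{prior}, \lambda)$; the
  Gaussian posterior in $\phi$ makes median, mean and mode coincide, so the
  closed form is exact and no per-trial optimisation is needed;
- **dynamic prior** — the prior mean evolves as $\mu_i = (1-k)\mu_{i-1} +
  k\phi_i$, $k = \lambda^2/(\lambda^2+1)$, initialised at the first trial's
  $\phi$; since $\mu_i$ *is* the posterior mean given the previous prior,
  the trial-$i$ estimate is $e^{\mu_i}$; one free parameter $\lambda$;
- **fixed estimate** — a single $\hat\tau$ for all trials;
- **carry-over** — each vestibular trial inherits the preceding
  visual/combined trial's $\tau$ (or its posterior estimate, by default
  from a static-prior fit on the pooled visual+combined trials);
- **sensory feedback (switch-distance)** — keeps the actual angular input
  and replaces the linear channel with full drive until the simulated
  position first comes within a fixed distance of the gain-scaled target,
  then full braking; the switch distance minimises the distance between
  predicted and actual stops, and its SD is the maximum-likelihood normal
  SD of per-trial best distances (the reference description fits "mean and
  standard deviation" without naming an objective for the SD).

**Numerical choices.** Optimisation is deterministic: a coarse grid
(9×9 over $\mu_{prior}$ in the widened log-bound range and log-spaced
$\lambda \in [10^{-2}, 10]$) followed by Nelder–Mead on
$(\mu_{prior}, \log_{10}\lambda)$ with objective tolerance $10^{-10}$;
one-parameter models use a grid plus golden-section refinement. A constant
$\tau$ sequence makes the objective flat in $\lambda$; this is warned about
and the grid optimum returned. Believed-trajectory re-integration recomputes
the input gains from $\hat\tau$ through the calibration formula ("yoked"),
since an observer inferring $\hat\tau$ would assume its calibrated gain; a
switch allows keeping the trial's true gains, as the choice is not
determined by the task description. Believed trajectories integrate the
joystick input exactly as recorded, over the recorded trial duration; the
completed-stop (coasting) extension described for the no-adaptation null is
available behind a flag but is off for model fitting, where the recorded
input is the literal conditioning variable. The fitting objective is evaluated in
Cartesian coordinates, matching its vector form; radial/angular components
are used for validation only. Angles are radians internally and degrees only
at report boundaries.

**Validation and comparison.** Subjective residual errors substitute
believed for actual stops in the residual-error definition; a good internal
model leaves them uncorrelated with $\tau$ even when actual residuals are
strongly correlated. Actual-vs-subjective comparisons across participants
use the Wilcoxon signed-rank test; model-vs-model comparisons of subjective
correlations use paired t-tests; model-implied correlations are flagged at
the multiple-comparison-adjusted level $p = 0.0085$; parameter-difference
tests across participants use percentile bootstrap CIs.

## What the test suite establishes (and a known limitation)

Problem sizes were chosen to exercise the estimators at realistic scale:
the heaviest suites use 20 synthetic participants × 450 trials per
condition for parameter recovery (median relative error of $\hat\lambda$
stays under 20% and of $e^{\hat\mu}$ under 15% in all three condition
regimes), and 15 participants for model-comparison checks; unit tests use
1–2 participants × tens of trials.

One comparison deserves honesty: on data generated with a *truly static*
prior, the fitted dynamic-prior model produces slightly negative
subjective-residual correlations (its wandering prior over-corrects), while
the static model's are centred on zero. With 15 clean synthetic
participants a paired t-test resolves this small (~0.07–0.2) systematic
difference in the vestibular and combined regimes, whereas noisier
empirical data would not. "Comparable performance" of static and dynamic priors therefore holds
here as a statement about effect size, not about test non-significance in
every regime; the corresponding acceptance check is left strict rather than
loosened.

## Worked example

```{r example, eval = FALSE}
cfg <- session_config(n_participants = 2, trials_per_condition = 150)
ses <- generate_session(cfg, seed = 7)
vest <- subset_session(ses, condition = "vestibular")
g <- response_gain(vest$trials)
eps <- residual_errors(vest$trials, g)
tau_error_stats(eps$eps_r, vest$trials$tau)
fit <- fit_static_prior(vest, g)
validate_subjective_residuals(vest, fit$believed, g)
```

## Limitations

- $\tau$ is constant within a trial; within-trial inference over velocity
  observations is out of scope.
- The generator's policy does not reproduce idiosyncratic human joystick
  corrections; analyses that depend only on stop positions and integrated
  input areas are unaffected.
- The angular calibration constant of the original apparatus is unknown;
  all angular ceilings inherit the $\theta_{cal}$ choice documented above.
- No reader for any particular public dataset layout is provided; sessions
  can be assembled from any source that maps onto the documented CSV
  schema.
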