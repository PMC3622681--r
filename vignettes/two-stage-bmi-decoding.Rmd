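---
title: "Two-stage BMI decoding with an optimal feedback control prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage BMI decoding with an optimal feedback control prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofcbmi)
```

## The problem

In an instructed-delay center-out task a subject is cued one of four
peripheral targets, waits through a 1 s delay, and on a go cue moves a
cursor from the center to the cued target.  The task is unforgiving: the
trial fails if the cursor first touches any *incorrect* target disk or runs
past a 3 s time-out.  A brain-machine interface (BMI) replaces the limb:
binary spike events, binned at 5 ms, drive the cursor directly.

`ofcbmi` implements a two-stage decoder for this setting, together with a
closed-loop simulator so the full stack can be exercised and tested with
synthetic spikes only:

1. **Target decoding.** Delay-period spiking (the last 800 ms before the go
   cue; the first 200 ms after cue onset are discarded for visual latency)
   is modeled per neuron as a homogeneous Poisson process whose rate
   depends on the cued target.  A maximum-likelihood decoder picks the
   target with the largest ensemble Bernoulli log-likelihood
   (`decode_target_ml()`).
2. **Trajectory decoding.** Peri-movement spiking is modeled per neuron as
   a point process whose log intensity is linear in cursor position and
   velocity (`fit_kinematic_model()`).  A feedback-controlled point
   process filter (FC-PPF) combines these observations with a prior over
   reach trajectories derived from linear-quadratic-Gaussian (LQG) optimal
   feedback control toward the stage-1 target.  Because the subject — not
   the decoder — chooses the movement duration, a bank of FC-PPFs over a
   coarse duration grid runs in parallel and is mixed by per-bin predictive
   likelihood (the FC-P-PPF, `fc_p_ppf_decode()`).

Two baselines support comparisons: the RW-PPF (`rw_ppf_decode()`), which is
the same filter with the control term removed (a smoothness-only
random-walk prior and no target information), and a ridge regression of
position on the history of 100 ms sliding-window firing rates
(`select_ridge_model()`).

## The movement prior

The plant is a planar point mass behind a first-order muscle stage; per
dimension,

$$\dot p = v,\qquad \dot v = (f - b\,v)/m,\qquad \dot f = (u - f)/\tau,$$

with the standard biomechanical constants $b = 10$ N s/m, $\tau = 40$ ms,
$m = 1$ kg (`plant_params()`).  The state is the 6-vector
$(p_x, p_y, v_x, v_y, f_x, f_y)$.  Discretization is by exact zero-order
hold at the 5 ms bin (`discretize_plant()`); ZOH is exact for linear
time-invariant dynamics at any step, so no stability or accuracy
considerations constrain the bin width.  Process noise enters on the force
channels only, $W = \mathrm{diag}(0,0,0,0,\sigma_f^2,\sigma_f^2)$.

The reach cost is quadratic in tracking form around the goal state
$x^\* = (d^\*, 0, 0)$:

$$J = \sum_{t=1}^{T} u_t' R\, u_t + (x_T - x^\*)'\, Q_T\, (x_T - x^\*),
\qquad Q_T = \mathrm{diag}(1, 1, w_v, w_v, w_f, w_f),$$

so the terminal penalties encode end-point accuracy, stopping and muscle
relaxation while the running term encodes energetic efficiency.  The
finite-horizon gains $L_t$ come from the standard backward Riccati
recursion (`solve_lqg()`); they depend only on steps-to-go, are computed
offline once per (target, duration) pair, and define both the subject model
of the simulator and the decoder prior

$$x_t = A x_{t-1} + B u_t + w_t, \qquad u_t = -L_t (x_{t-1} - x^\*).$$

Noiseless rollouts of this prior are straight with bell-shaped speed
profiles — the canonical signatures of natural reaching — and this is a
tested property (`rollout_prior()`).

### Choosing the weights

Workspace units are dimensionless with a reach distance of 0.1, which puts
the plant constants on a ~10 cm scale; the target radius (0.025) and
distance are package choices, since only relative geometry is observable in
the source task.  The default weights $w_v = 10^{-2}$, $w_f = 10^{-4}$,
$r = 10^{-7}$ were fixed once so that the noiseless 0.6 s rollout ends
within well under 5% of the reach distance, stops, and keeps the bell
shape.

`calibrate_weights()` implements an alternative, behavior-driven weighting:
it rescales $w_v$, $w_f$, $r$ until the Monte-Carlo averages of the four
cost terms over noisy rollouts agree within a factor of two (outer
bisection on $r$, within which the effort-to-position ratio is monotone,
plus damped matching of the terminal weights).  With purely additive motor
noise this parity is only reachable in a low-effort regime that tolerates a
slack reach (about a third of the reach distance of terminal scatter):
control effort is pinned near 500 N²·steps by the task itself, so matching
it to a squared position error of order $10^{-4}$ would require either
giving up accuracy or a degenerate deadbeat controller.  Signal-dependent
motor noise — under which effort parity and accuracy coexist — is out of
scope here, so the balanced weights are provided and tested as a documented
procedure but are *not* the decoding defaults.

### Calibrating the motor noise

The force-noise scale is fixed by behavior, not by assumption:
`calibrate_state_noise()` bisects $\sigma_f$ until unassisted noisy
rollouts, run under the task protocol (intended durations drawn from the
duration grid, terminal gain frozen past the horizon, path scored against
the full task rules including the incorrect-touch penalty), succeed on
about 90% of reaches.  At the default geometry this gives
$\sigma_f \approx 3.18$ N per 5 ms step (`default_sigma_f()`), and
simulated manual sessions then succeed on roughly 85–95% of trials, the
regime of a trained subject.  Scoring against the full task rules matters:
an endpoint-only criterion ignores lateral excursions into neighboring
disks, and an anytime-entry criterion never binds because the feedback law
eventually recovers any excursion.

## Encoding models and their fits

Delay rates are per-(neuron, target) maximum-likelihood constants — spike
count over exposure in the 800 ms window — floored at 0.1 spikes/s because
the decoder takes logs of $\lambda\Delta$ (`fit_target_model()`; the fit
equals a Poisson GLM with log link and target-indicator design, and a test
checks that equivalence against `stats::glm`).

Peri-movement tuning, $\lambda = \exp(\alpha + \beta'(p_x,p_y,v_x,v_y))$,
is fitted per neuron by a damped Poisson IRLS (tolerance $10^{-8}$, at most
100 iterations, $10^{-6}$ ridge on the normal equations for ill-conditioned
designs), with covariates standardized internally and coefficients reported
in native units; `stats::glm` serves as the independent oracle in the test
suite rather than as the implementation, so the solver and its cross-check
stay distinct.  Coefficient p-values use the asymptotic normal theory;
significance is Bonferroni-corrected across all (neuron, coefficient) tests
at family level 0.05, and each neuron is classified as position-only,
velocity-only, both, or untuned.  Everywhere the intensity is used as a
per-bin event probability it is clamped so $\lambda\Delta \le 0.95$.

## The filter recursions

Each bin the FC-PPF predicts through the closed loop,

$$\hat x_{t|t-1} = A\hat x_{t-1|t-1} + B u_t,\qquad
\Sigma_{t|t-1} = (A - BL_t)\,\Sigma_{t-1|t-1}\,(A - BL_t)' + W,$$

with $u_t = -L_t(\hat x_{t-1|t-1} - x^\*)$ computed from the previous
posterior mean — the decoder's proxy for the cursor state the subject sees
perfectly.  Closed-loop covariance propagation follows from the prior
being the feedback-controlled state model itself; an open-loop variant is
exposed behind a switch (`ppf_predict(closed_loop_cov = FALSE)`) for
sensitivity checks, since the source derivation does not pin this down.

The update folds one bin of binary spiking in information form, with
$\tilde\beta_c$ the tuning vector embedded in state space (zeros on force)
and $\lambda_c$ evaluated at the predicted mean:

$$\Sigma_{t|t}^{-1} = \Sigma_{t|t-1}^{-1} +
\sum_c \lambda_c\Delta\,\tilde\beta_c\tilde\beta_c',\qquad
\hat x_{t|t} = \hat x_{t|t-1} + \Sigma_{t|t}
\sum_c \tilde\beta_c(\Delta N_c - \lambda_c\Delta).$$

The correction is the innovation "spike minus predicted spike
probability"; with no (or untuned) neurons the posterior is exactly the
prediction, and the filter degrades gracefully to the prior path — a
tested property.  A dense-grid Bayes oracle on a 1-D toy pins the update to
$10^{-3}$ relative accuracy, and replacing the Bernoulli likelihood with a
linear-Gaussian one reduces the recursion to a Kalman filter, verified
against an independently coded covariance-form filter.

Covariances are symmetrized after every step and eigenvalue-clipped at
$-10^{-10}$; singular information matrices fall back to a $10^{-9}$ ridge.

### The duration mixture

The prior depends on the movement duration $T$, which the decoder cannot
know.  A coarse grid $\{0.4, 0.6, 0.8, 1.0, 1.2\}$ s (well inside the 3 s
time-out, centered near the ~0.5 s natural acquisition time of the
simulator) indexes parallel FC-PPFs.  Each bin, each active filter
multiplies its mixture weight by its predictive likelihood

$$\log p(\Delta N_t \mid N_{1:t-1}, T_i) \approx
\log p(\Delta N_t \mid \hat x_{t|t})
+ \log \mathcal N(\hat x_{t|t};\, \hat x_{t|t-1}, \Sigma_{t|t-1})
+ \tfrac12 \log\det(2\pi\,\Sigma_{t|t}),$$

a Laplace approximation assembled purely from moments the filter has
already computed (verified against numerical quadrature to $10^{-2}$).
Weights live in log space with log-sum-exp normalization; filters whose
horizon has elapsed drop out of the mixture, the longest filter persists
past the grid with its terminal gain frozen (avoiding an output
discontinuity), and a total underflow resets the active weights to uniform.
The combined estimate is the weight-averaged posterior mean.  On spikes
simulated at a true grid-point duration, the true duration's weight is
modal at movement end in roughly two thirds of runs.

## The simulator

`make_population()` draws a ground-truth population: 20 neurons with
log-normal baselines around 5 spikes/s; 48% target-tuned (multiplicative
cosine-of-preferred-target modulation, mean log-depth 0.4); 47%
kinematically tuned with random preferred directions, split 57/15/28% into
position-only / velocity-only / both.  The sizes and fractions are the
reported statistics of multielectrode premotor recordings in this task;
the tuning magnitudes are scaled to the workspace (roughly a factor-e rate
swing across the reach) so that a 20-neuron ensemble decodes the target at
about 80% — the regime the source recordings operate in.  Given these
conditions, everything else is measured, not assumed: encoding fits on
simulated sessions recover the planted rates and gradients within three
standard errors (a tested identifiability property).

Manual (training) trials draw the cued target uniformly and the intended
duration uniformly from the grid, roll the noisy LQG reach until disk entry
or time-out, and thin spikes per 5 ms bin: target rates during the full 1 s
instruction epoch (only the last 800 ms are decoded), kinematic rates along
the realized states during movement.

Closed-loop trials wire any per-bin decoder into the loop.  Each movement
bin the simulated subject reads the *displayed* (decoded) cursor position —
perfect visual feedback — slaves the position components of its internal
state to it while keeping its own intended velocity and force, issues its
LQG control toward the cued target, advances its internal state, and emits
spikes from the kinematic model at that internal state.  This is the
minimal realization consistent with modeling the BMI as the controlled
plant: spikes must encode intent, feedback must be of the display.  Its
known consequence is that position-tuned cells carry no information about
a *mis-decoded* target in closed loop (their signal agrees with the
decoder's own output by construction), so closed-loop corrections ride on
the velocity- and force-tuned minority.  Real neurons under BMI control
re-aim and adapt in ways no open-loop-trained model constrains; this
assumption is the declared modeling choice, not a claim about cortex.

Reference decoders bound the harness: an oracle that replays the noiseless
prior to the cued target scores 100%, a frozen cursor scores 0%.

## What the tests do and do not show

The suite checks the machinery against independent oracles (series-expanded
matrix exponentials, grid searches, dense-grid posteriors, quadrature,
normal equations, an independently arranged Riccati fixed point, a textbook
Kalman filter), the behavioral properties of the prior, chance-level
constructions (an uninformative target decoder sits at 25%; ridge decoding
from rates shuffled across time and trials scores at or below the 25% task
chance), parameter recovery, and reduced-scale directional comparisons.
Simulated sessions use 60–200 trials, 10,000 draws for the chance
classifier, and 100 seeded runs for the duration-mixture check; these sizes
keep the full suite within a few minutes while leaving binomial slack well
inside the asserted margins.

Two directional claims deserve honesty about their scope.  First,
two-stage versus stage-1-alone in closed loop: because closed-loop
corrections ride on the velocity-tuned minority (see above), the margin is
small — at the ~80% stage-1 operating point corrections outweigh the
filter's spike-jitter losses in the paired 200-trial comparison the suite
runs, but the margin is a few percentage points and population draws with
near-saturated stage-1 accuracy can invert it.  Second, the ridge baseline here is *smoother* than
the two-stage estimate, opposite to the source finding on real recordings:
with 20 modestly tuned synthetic neurons, cross-validation selects a large
ridge penalty, shrinking the ridge output toward the mean position, while
the correctly specified FC-P-PPF (prior noise equal to the subject's
calibrated motor noise) carries per-bin spike jitter.  We deliberately do
not shrink the decoder's prior noise to manufacture smoothness; the
random-walk ablation remains about twice as rough as the two-stage
estimate, and both effects are reported as computed.

Passing tests demonstrate internal correctness and the stated directional
properties *under the simulator's assumptions* — stationary tuning, no
learning, no spike history effects, Poisson variability, perfect epoch
boundaries.  They do not certify performance on real recordings.

## Numerical choices, degenerate inputs, limitations

- Rate floor 0.1 spikes/s; intensity clamp $\lambda\Delta \le 0.95$; exact
  Bernoulli bin likelihood $\log(1-\lambda\Delta)$ for empty bins rather
  than the $-\lambda\Delta$ Poisson approximation (exact for binary bins,
  and the oracle is matched to it).
- Exact ML ties in target decoding break uniformly at random with the
  session generator, avoiding positional bias; a fixed seed reproduces the
  choice.
- Disk entry uses closed disks at bin endpoints; at 5 ms bins intra-bin
  interpolation would change acquisition times by at most one bin.
- Leave-one-out is the cross-validation scheme throughout (target
  accuracy, neuron dropping, ridge model selection).  The ridge CV freezes
  standardization and position means at the session level so fold Gram
  matrices can be reused; it holds one Gram matrix per trial in memory, so
  long-history selections should use a few tens of trials.
- Sessions serialize to a directory of plain-text files (JSON metadata,
  sparse long-format spike CSV, kinematics CSV) with fixed-format numeric
  printing, so re-serialization is byte-identical.
- Not modeled: signal-dependent motor noise, spike-history terms,
  acceleration covariates, adaptation or learning across trials, autonomous
  epoch detection, and the weighted multi-target mixture extension.
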