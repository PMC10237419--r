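---
title: "Models and methods behind splitbelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splitbelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitbelt)
```

# The scientific problem

When a person walks on a split-belt treadmill with one belt running twice
as fast as the other, their stepping pattern is perturbed and then adapts
over hundreds of strides. Two summary outcomes track this adaptation:
step length asymmetry (SLA), the normalised difference between the step
lengths taken when the fast-belt leg and the slow-belt leg strike,

$$\mathrm{SLA} = \frac{L_{fast} - L_{slow}}{L_{fast} + L_{slow}},$$

and the mechanical work rate each leg delivers to the centre of mass and
to the moving belt. Adaptation of both is well described by a sum of two
exponentials — a *fast* component that decays within tens of strides and
a *slow* component that decays over hundreds — and the question the
package's default analysis addresses is whether the two timescales differ
between people who meet the 150 minutes/week exercise guideline (MOVE)
and people who do not (notMOVE).

# The adaptation model

For outcome $y$ of participant $i$ in group $g$ at step or stride $t$:

$$y_{it} = c_g + b_i + a_{f,g}\, e^{-t/r_{f,g}} + a_{s,g}\, e^{-t/r_{s,g}} + \varepsilon_{it},
\qquad b_i \sim N(0, \sigma_{id}^2),\ \varepsilon_{it} \sim N(0, \sigma^2).$$

$c_g$ is the group plateau (the value the outcome would reach as $t \to
\infty$), $a_{f}, a_{s}$ the initial values of the fast and slow
components, $r_{f}, r_{s}$ their growth rates in steps (SLA) or strides
(work rates), and $b_i$ a participant-level random plateau offset. The
candidate ladder comprises four models: one or two exponents, with
coefficients pooled or differing by group; all four carry the random
plateau. The simplest adequate model is chosen by AIC, with BIC and
likelihood-ratio tests reported and any disagreement surfaced rather than
resolved silently.

## Exact marginal likelihood

Because the random effect enters additively, participant $i$'s marginal
distribution is multivariate normal with mean given by the group curve
and covariance $\sigma^2 I + \sigma_{id}^2 J$ ($J$ the all-ones matrix).
The log-likelihood is therefore available exactly through the rank-one
Woodbury and determinant identities:

$$\Sigma^{-1} = \frac{1}{\sigma^2}\Big(I - \frac{\sigma_{id}^2}{\sigma^2 + n\sigma_{id}^2} J\Big),
\qquad \log|\Sigma| = (n-1)\log\sigma^2 + \log(\sigma^2 + n\sigma_{id}^2).$$

No Laplace or PQL approximation is involved, which makes an independent
adaptive-quadrature integration of the random effect a *strict* oracle:
the test suite requires agreement to $10^{-6}$ on randomly drawn small
instances.

## Fitting

`fit_ml()` maximises this likelihood with a profiled parameterisation:
for fixed growth rates and variance ratio $\lambda =
\sigma_{id}^2/\sigma^2$, the linear coefficients $(c_g, a_{f,g}, a_{s,g})$
solve a closed-form generalised least-squares system and $\sigma^2$
profiles out, so the numerical search runs only over the log growth rates
and $\log\lambda$. This is an exact reparameterisation of the full
maximisation, and it is what makes replicate-level simulation studies
(e.g. 20-replicate model-selection checks) affordable: a two-exponent
group fit on 26,336 observations takes well under a second without
standard errors.

Numerical choices:

* Growth rates and variance components are optimised on the log scale,
  enforcing positivity without constraints; rates are bounded to
  $[0.3, 50\,L]$ ($L$ the series length) to keep the profiled GLS system
  well conditioned.
* Residual sums of squares are computed directly from the data matrix
  rather than via quadratic-form shortcuts, which cancel catastrophically
  when a near-singular design meets large provisional coefficients.
* Multi-start policy: the rate grid $r_f \in \{5, 20\}$, $r_s \in
  \{100, 400\}$ plus a centre start (five starts; one-exponent models use
  a five-point rate grid); the best optimum is kept.
* The two components are label-canonicalised so $r_s > r_f$; a fit whose
  rates collapse (ratio < 1.05) is flagged degenerate rather than
  silently reported.
* Standard errors come from the observed information (numeric Hessian of
  the exact marginal log-likelihood at the optimum), with the delta
  method mapping $\log r$ to $r$.

Group differences in coefficients are tested with Wald t statistics from
the joint covariance, on $n_{obs} - k$ degrees of freedom. A two-sample
test on fitted fixed effects is not literally defined, so the Wald
contrast is the package's choice; with tens of thousands of observations
it is indistinguishable from a z test.

With large slow-component rates relative to the observation window the
slow exponential is close to linear and $(c, a_s, r_s)$ become jointly
weakly identified; estimates of $r_s$ then carry large standard errors
(hundreds of strides), which is faithfully reflected in the reported
uncertainty rather than hidden by regularisation.

# The synthetic cohort

The generator stands in for an undeposited experimental data set. Its
defaults are the study conditions of the design it emulates: 19 MOVE and
13 notMOVE participants; 823 steps per participant (the common
truncation length, giving $32 \times 823 = 26{,}336$ SLA observations);
work outcomes stride-indexed at $\lfloor 823/2 \rfloor = 411$ strides;
generating coefficients and the two variance components for all five
outcomes taken at full precision from the published two-exponent group
fits; belt speeds 1.5/0.75 m/s (the 2:1 ratio, near the cohort's mean
fast speed); body mass $N(70.3, 13^2)$ kg truncated at 40 (the published
cohort mean; the SD is the generator's own realistic choice, as no SD was
published). Every draw derives from one integer seed via fixed
per-outcome offsets, so runs are byte-identical under a fixed seed and
individual outcome series can be regenerated in isolation.

## Raw-signal synthesis

`generate_raw_trial()` emits 100 Hz marker and 1000 Hz per-belt force
signals whose *processed* outcomes match a prescribed per-step
step-length sequence:

* Timing: the stride period for step pair $k$ is $(L_{fast,k} +
  L_{slow,k}) / \bar v$ with $\bar v$ the mean belt speed, symmetric step
  timing and duty factor 0.6. Cadence is not constrained by the emulated
  study, so this convention is the generator's own; it avoids a free
  parameter and yields realistic periods (~1 s).
* Ankle trajectories: stance translates rearward at belt speed; swing is
  a quintic Hermite segment whose end velocities match the belt, so the
  trajectory is $C^2$ and survives 6 Hz low-pass filtering without
  displacing the strike-time positions. A kinematic-only (zero-force)
  slow stance precedes the first fast strike so the first prescribed
  step length is well defined.
* Forces: stance vertical force is a half-sine scaled so the
  trial-average vertical force over both belts equals body weight
  exactly; the anterior–posterior force is a braking-then-propulsion
  sinusoid with zero net impulse (peak 15% of vertical). Analytic shapes
  keep the work integrals testable.

What the generator does **not** emulate: physiological joint kinematics,
handrail forces, marker occlusion, force-plate crosstalk, or
non-Gaussian step-to-step variability. Passing round-trip tests
therefore shows the *processing chain* is correct, not that it is robust
to every artefact of real laboratory data. Similarly, on synthetic
series the within-participant epoch SD mixes residual noise with the
deterministic curve trend (steep early decay inflates the initial-epoch
SD), so epoch comparisons on synthetic data reflect the generating
curves as much as the noise.

# Signal processing and mechanics

Filtering is a 4th-order Butterworth applied forward and backward (zero
phase lag; two passes of −3 dB leave ~0.5 amplitude at the cutoff), with
odd-reflection padding and steady-state initial conditions to suppress
edge transients. Kinematics are filtered at 6 Hz, forces at 20 Hz. A
foot strike is the first sample where the filtered vertical belt force
rises above 20 N after ≥ 50 ms below (both exposed as configuration);
strides span consecutive ipsilateral strikes of the fast leg.

The individual-limbs power of one leg is
$P = \mathbf{F}_{leg} \cdot \mathbf{v}_{com} + \mathbf{F}_{belt} \cdot \mathbf{v}_{belt}$.
In the treadmill frame the belt velocity is posterior ($-x$) and the
force applied to the belt is the anterior–posterior reaction
$-F_{x}$, so the belt term reduces to $F_{x} v_{belt}$ — negative
(absorption) for braking. COM acceleration is $(\mathbf{F}_{tot} - mg\hat z)/m$;
velocity is the per-stride cumulative trapezoid with the integration
constant set so the stride-mean velocity is zero in each axis (the
standard treadmill point-mass convention; it removes drift). Power is
evaluated on the 100 Hz grid after decimating the 20 Hz-filtered forces,
which is alias-safe. Work integrals split any sign-changing segment at
its linear zero crossing, making the positive/negative partition exact
for the piecewise-linear interpolant; positive plus negative work rate
equals the signed integral to machine precision by construction.

# Cohort statistics

Group classification: excluded if all reported modalities are
strength/flexibility types (default weightlifting, yoga, scuba diving);
otherwise MOVE requires ≥ 150 minutes/week sustained ≥ 13 consecutive
weeks (the questionnaire records weeks, so "the last three months" is
operationalised as 13 weeks). Welch's t-test and the Yates-corrected
chi-squared are implemented from their formulas and cross-checked
against the base-R reference implementations to $10^{-10}$; the epoch
variability follow-up uses Student's pooled-variance t-tests (the
convention of the analysis it mirrors), with the middle epoch centred at
$\lfloor (n - 100)/2 \rfloor$.

# Problem sizes and determinism

The test suite exercises the full default design (32 × 823) for single
fits and 20-replicate ladders for model selection, and smaller cohorts
(≤ 8 participants, ≤ 300 steps) for property-style checks; raw-trial
tests use 15–80 step pairs. All stochastic tests fix their seeds, and the
pipeline records a manifest of config hash and output checksums so a run
is reproducible stage by stage.

# Known limitations

* The slow-component growth rate is intrinsically noisy at this design
  size (a 13-participant group yields standard errors of 70+ steps for
  $r_s$); single-cohort estimates can deviate from the generating value
  by tens of percent without any defect in the fitting.
* The marginal model assumes a single residual variance and no residual
  autocorrelation, matching the emulated analysis; real stride series
  show mild autocorrelation that would shrink nominal standard errors.
* Work computed from belt forces ignores handrail loading, as in the
  emulated protocol; measured vertical forces under-account body weight
  whenever a walker leans on the rails.
* The work-outcome stride count uses $\lfloor n_{steps}/2 \rfloor$; an
  823-step trial yields 411 strides, so stride-indexed totals are close
  to, but not exactly, half the step-indexed totals.
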