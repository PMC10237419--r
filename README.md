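# splitbelt

Tools for analysing gait adaptation on a split-belt treadmill — a treadmill
whose two belts run at different speeds (here 2:1), forcing walkers to
adapt their stepping pattern over hundreds of strides. The package covers
the whole chain from raw laboratory signals to group-level statistics:

* **Synthetic cohort generation.** Stride- and step-indexed outcome series
  (step length asymmetry; positive/negative work rate per leg) with known
  double-exponential adaptation structure, plus raw marker/force signals
  for any prescribed step-length sequence, so every processing step can be
  checked against ground truth. The default configuration reproduces a
  published two-group design: 19 participants meeting the 150 min/week
  physical-activity guideline (MOVE) and 13 below it (notMOVE), 823 steps
  each.
* **Signal processing.** Zero-lag 4th-order Butterworth filtering (6 Hz
  kinematics, 20 Hz forces), threshold-based foot-strike detection, stride
  segmentation.
* **Gait outcomes.** Step length from the anterior–posterior ankle-marker
  separation at foot strike; step length asymmetry
  `SLA = (fast − slow)/(fast + slow)`; per-leg mechanical power by the
  individual-limbs (point-mass) method,
  `P = F_leg · v_com + F_belt · v_belt`, integrated to positive/negative
  work rates per stride (W/kg); net work rate over the last 100 strides.
* **Adaptation models.** For an outcome `y` of participant `i` in group `g`
  at step/stride `t`:

  ```
  y_it = c_g + b_i + a_f,g exp(−t/r_f,g) + a_s,g exp(−t/r_s,g) + e_it
  b_i ~ N(0, σ_id²),  e_it ~ N(0, σ_resid²)
  ```

  a two-timescale learning curve (fast component `a_f, r_f`; slow
  component `a_s, r_s`; plateau `c`) with a participant-level random
  plateau. Because the random effect is additive, the marginal likelihood
  is an exact multivariate Gaussian; models are fitted by maximum
  likelihood with the linear coefficients and residual variance profiled
  out in closed form. A four-model ladder (one/two exponents ×
  pooled/group coefficients) is compared by AIC, BIC and likelihood-ratio
  tests, with Wald tests for group differences in each coefficient.
* **Cohort statistics.** Guideline-based group classification from
  questionnaire records, Welch t-tests, Yates-corrected chi-squared,
  initial-value and net-work comparisons, and within-participant epoch
  variability (SD of the initial/middle/final 100 strides).

## Worked example

```r
library(splitbelt)

cfg <- synthetic_config(seed = 1)           # 19 MOVE / 13 notMOVE, 823 steps
d   <- truncate_to_min(generate_outcome_series(cfg, "sla"))
fit <- fit_ml(d, n_exponents = 2, group_effects = TRUE)
fit
#> 2-exponent adaptation model (group fixed effects), random plateau
#>    group        c      a_f   r_f      a_s   r_s ...
#>     MOVE -0.03405 -0.07456 13.33 -0.05790 410.5
#>  notMOVE -0.04333 -0.10212 31.67 -0.01449 208.6
#> sigma_id = 0.0417, sigma_resid = 0.0323
#> logLik = 52918.74, k = 12, AIC = -105813.48, ... n = 26336 obs / 32 participants
```

The fitted curve says: both groups start with negative SLA (the slow-belt
leg takes the longer step) and converge towards a slightly negative
plateau `c`; the MOVE group's fast component decays in ~13 steps versus
~32 for notMOVE (a quicker initial response), while its slow component
decays over ~400 steps versus ~200 (a more gradual long-term drift). The
generating values were (11.6, 32.5, 396.3, 162.1), so the fit recovers the
design within sampling error; `sigma_resid` matches the generating 0.032.

The staged workflow lives under `analysis/`:

```sh
Rscript analysis/01_simulate.R   # cohort tables + example raw trial
Rscript analysis/02_process.R    # raw signals -> steps/strides
Rscript analysis/03_fit.R        # model ladder per outcome + selection
Rscript analysis/04_stats.R      # demographics, net work, epoch variability
Rscript analysis/05_report.R     # coefficient table + figures
```

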