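# balancekf

Simulation and system-identification toolkit for human balance recovery,
modelled as a sagittal-plane **double inverted pendulum** (ankle + hip) with
**time-varying Kelvin–Voigt joints**. It is written for movement scientists
and biomechanical engineers who want to recover joint stiffness and damping
from motion-capture kinematics of *hold-and-release* trials — a leaning
subject is held static, suddenly released, and the body's own dynamics
provide the identification perturbation.

## The model and the estimators

Two rigid segments (legs; trunk + head + arms) with generalized coordinates
`q = [theta1, theta2]` obey

```
M(q) q̈ + C(q, q̇) q̇ + G(q) = tau,
tau = -[k1(t) theta1 + b1(t) theta1̇ ;  k2(t) theta2 + b2(t) theta2̇ ]
```

where the stiffness coefficients `k1(t)`, `k2(t)` may vary in time and
change sign (negative stiffness = energy injection by reflex activity).
Because the torque balance is linear in `lambda = [k1, b1, k2, b2]`, each
sample gives a regressor equation `Z_k = H_k lambda` with `H_k` built from
measured angles/velocities and `Z_k` from inverse dynamics. The package
provides:

* **dynamics** — exact non-linear equations of motion and a fixed-step RK4
  simulator (`simulate_pendulum()`, `energies()`);
* **synthetic data** — anthropometric subjects, sigmoidal stiffness
  profiles, SNR-controlled Gaussian angle noise (`subject_params()`,
  `generate_trial()`);
* **preprocessing** — marker-to-angle conversion, zero-phase Butterworth
  filtering, central differences (`angles_from_markers()`,
  `preprocess_trajectory()`);
* **estimation** — constant-parameter least squares and a Kalman filter
  over the parameter vector, with process-covariance tuning and error
  metrics (`lsm_estimate()`, `kf_run()`, `tune_process_covariance()`);
* **prototype** — a geometric model of a spring-loaded bench pendulum with
  angle-dependent moment arms and slack springs, used to validate the
  filter on a system of known dynamics (`prototype_spec()`,
  `prototype_kf_stiffness()`);
* **balance control** — a sign-switching ankle-stiffness recovery
  controller (`switching_rule()`, `simulate_recovery()`).

Everything is tidyverse-flavoured: trajectories and estimates are tibbles,
fitted objects have `tidy()` / `glance()` methods and `autoplot()` figures.

## Worked example

Estimate joint parameters from a simulated noisy hold-and-release trial
(85 kg, 1.70 m subject, 30 s at 100 Hz, angle noise at 40 dB SNR —
a realistic optical-capture regime):

```r
library(balancekf)

p       <- subject_params(85, 1.7)
trial   <- generate_trial(params = p, snr_db = 40, seed = 1, duration = 30)
prep    <- preprocess_trajectory(trial$noisy, cutoff = 30)
samples <- build_regressor(prep, p)

lsm_estimate(samples)
#> <lsm_fit> constant visco-elastic parameters
#>       k1       b1       k2       b2
#> 1182.466   -8.174  574.944   29.227
#>   residual mean = -0.256 Nm, RMSE = 212 Nm (n = 3001)
```

The constant fit lands near the time-average of the true sigmoidal
stiffness profiles (`k1` rises 1050 → 1260, `k2` 500 → 650 N m/rad) but, by
construction, cannot follow their rise. The Kalman filter can:

```r
cfg <- tune_process_covariance(samples, trial$truth)
kf  <- kf_run(samples, cfg)
glance(kf)
#> # A tibble: 1 × 7
#>   k1_final b1_final k2_final b2_final residual_mean residual_rmse n_steps
#>      <dbl>    <dbl>    <dbl>    <dbl>         <dbl>         <dbl>   <int>
#> 1    1176.     17.0     618.     31.8        -0.326          212.    3001

estimation_errors(kf, trial$truth)
#> # A tibble: 4 × 3
#>   parameter  rmse  nrmse
#>   <chr>     <dbl>  <dbl>
#> 1 k1        88.5  0.0723
#> 2 b1         9.56 0.319
#> 3 k2        51.4  0.0823
#> 4 b2        14.6  0.730
```

so the tracked stiffness stays within ~7–8% (NRMSE) of the truth while the
dampings — weakly excited once the motion decays — are harder.
`autoplot(kf, truth = trial$truth)` overlays the track on the ground truth.

Validating on the spring-loaded bench prototype (releases at 22.5 fps,
marker-scale noise, calibrated measurement covariance):

```r
prototype_kf_stiffness(seed = 1)
#> <prototype_kf> near-neutral stiffness estimates (Nm/rad):
#>  joint estimate expected
#>  ankle 8.750765 9.359588
#>    hip 1.913420 1.899446
```

where `expected` is the small-angle formula `k_r = n * k_l * r^2` for the
engaged springs. And the sign-switching recovery strategy:

```r
simulate_recovery(subject_params(85, 1.7), switching_rule())
#> <recovery_sim> 3 s; |theta1|: 0.06 -> 0.107 rad, |theta21|: 0.32 -> 0.159 rad
```

the combined posture error (norm of the two segment inclinations) drops
from 0.326 to 0.192 rad in 3 s, while the same model with all joint
torques removed falls over.

A thin command-line wrapper over these functions ships in
`inst/cli/balancekf.R` (subcommands `generate`, `simulate`, `estimate`,
`validate-prototype`, `recover`, `suite`).

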