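Package: balancekf
Title: Two-Link Balance Dynamics and Time-Varying Joint Stiffness Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and system identification toolkit for human balance
    recovery modelled as a sagittal-plane double inverted pendulum (ankle and
    hip) with time-varying Kelvin-Voigt joints. Provides the exact non-linear
    equations of motion and a fixed-step Runge-Kutta simulator, anthropometric
    subject generation with sigmoidal stiffness profiles and controlled
    measurement noise, motion-capture preprocessing (marker-to-angle
    conversion, zero-phase Butterworth filtering, central differences), an
    inverse-dynamics regressor with least-squares and Kalman-filter estimators
    of joint stiffness and damping, a geometric model of a spring-loaded
    mechanical prototype for validation, and a sign-switching ankle stiffness
    controller for balance recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
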