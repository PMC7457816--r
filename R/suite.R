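# End-to-end validation experiments tying the modules together.

#' Full estimation pipeline on one synthetic reference trial
#'
#' Generates the reference hold-and-release trial (85 kg / 1.7 m subject,
#' sigmoidal stiffness rise, noisy angles), preprocesses it (zero-phase
#' low-pass at `cutoff`, central differences), builds the inverse-dynamics
#' regressor, fits the constant-parameter least-squares estimate, tunes the
#' filter's process covariance against the known ground truth, and runs the
#' Kalman filter.
#'
#' @param seed RNG seed for the measurement noise.
#' @param eta Stiffness rise-velocity multiplier.
#' @param params Subject parameters.
#' @param snr_db Angle noise level (dB); `Inf` for a noiseless pipeline.
#' @param duration,dt Trial length and step (s).
#' @param cutoff Low-pass cutoff (Hz).
#' @param cfg Optional pre-tuned [kalman_config()]; `NULL` tunes Q on this
#'   trial.
#' @return A list of class `reference_run` with elements `trial`, `samples`,
#'   `lsm`, `cfg`, `kf`, `param_errors` (tibble from
#'   [estimation_errors()]), `residuals` (per-estimator torque residual
#'   mean/RMSE).
#' @export
run_reference_estimation <- function(seed = 1, eta = 1,
                                     params = subject_params(85, 1.7),
                                     snr_db = -0.1, duration = 30,
                                     dt = 0.01, cutoff = 30, cfg = NULL) {
  trial <- generate_trial(params = params,
                          profile = reference_profile(eta),
                          duration = duration, dt = dt,
                          snr_db = snr_db, seed = seed)
  prep <- preprocess_trajectory(trial$noisy, cutoff = cutoff)
  samples <- build_regressor(prep, params)
  lsm <- lsm_estimate(samples)
  if (is.null(cfg)) {
    cfg <- tune_process_covariance(samples, trial$truth)
  }
  kf <- kf_run(samples, cfg)
  residuals <- dplyr::bind_rows(
    dplyr::mutate(residual_metrics(lsm$residuals), estimator = "lsm",
                  .before = 1),
    dplyr::mutate(residual_metrics(kf$residuals), estimator = "kf",
                  .before = 1)
  )
  structure(
    list(trial = trial, samples = samples, lsm = lsm, cfg = cfg, kf = kf,
         param_errors = estimation_errors(kf, trial$truth),
         residuals = residuals),
    class = "reference_run"
  )
}

#' Least-squares estimates across noise seeds
#'
#' Repeats the reference trial with fresh measurement noise and returns the
#' constant-parameter least-squares estimate per seed (the stochastic
#' spread of the pipeline).
#'
#' @param seeds Integer vector of noise seeds.
#' @inheritParams run_reference_estimation
#' @return A tibble with columns `seed`, `k1`, `b1`, `k2`, `b2`.
#' @export
lsm_over_seeds <- function(seeds = 1:20, eta = 1,
                           params = subject_params(85, 1.7),
                           snr_db = -0.1, duration = 30, dt = 0.01,
                           cutoff = 30) {
  clean <- simulate_pendulum(params, reference_profile(eta),
                             joint_state(-0.10, 0.22), duration, dt)
  purrr::map_dfr(seeds, function(s) {
    noisy <- add_noise(clean, snr_db = snr_db, seed = s)
    prep <- preprocess_trajectory(noisy, cutoff = cutoff)
    fit <- lsm_estimate(build_regressor(prep, params))
    tibble::as_tibble(c(list(seed = s), as.list(fit$lambda_hat)))
  })
}

#' Sensitivity study: three subjects by three stiffness rise velocities
#'
#' Runs the Kalman-filter pipeline over the nine-condition grid of
#' [sensitivity_conditions()], using one process covariance tuned on the
#' reference subject (the tuning trial is part of the protocol, not of the
#' grid), and reports per-condition stiffness estimation errors.
#'
#' @param seed Base RNG seed; condition `i` uses `seed + i`.
#' @param conditions Tibble of `mass`, `height`, `eta` rows.
#' @param cfg Optional pre-tuned [kalman_config()]; `NULL` tunes on the
#'   reference trial with `seed`.
#' @inheritParams run_reference_estimation
#' @return A tibble with one row per condition: the condition columns plus
#'   `rmse_k1`, `nrmse_k1`, `rmse_k2`, `nrmse_k2` (NRMSE as fractions of
#'   the time-mean true parameter).
#' @export
sensitivity_study <- function(seed = 1, conditions = sensitivity_conditions(),
                              cfg = NULL, snr_db = -0.1, duration = 30,
                              dt = 0.01, cutoff = 30) {
  if (is.null(cfg)) {
    base <- run_reference_estimation(seed = seed, snr_db = snr_db,
                                     duration = duration, dt = dt,
                                     cutoff = cutoff)
    cfg <- base$cfg
  }
  purrr::pmap_dfr(
    list(conditions$mass, conditions$height, conditions$eta,
         seq_len(nrow(conditions))),
    function(mass, height, eta, i) {
      params <- subject_params(mass, height)
      trial <- generate_trial(params = params,
                              profile = reference_profile(eta),
                              duration = duration, dt = dt,
                              snr_db = snr_db, seed = seed + i)
      prep <- preprocess_trajectory(trial$noisy, cutoff = cutoff)
      samples <- build_regressor(prep, params)
      fit <- kf_run(samples, cfg)
      err <- estimation_errors(fit, trial$truth)
      tibble::tibble(
        mass = mass, height = height, eta = eta,
        rmse_k1 = err$rmse[err$parameter == "k1"],
        nrmse_k1 = err$nrmse[err$parameter == "k1"],
        rmse_k2 = err$rmse[err$parameter == "k2"],
        nrmse_k2 = err$nrmse[err$parameter == "k2"]
      )
    }
  )
}

#' Run the full validation suite
#'
#' Executes the four validation experiments end to end: (1) prototype
#' release simulations with Kalman filtering, (2) the reference synthetic
#' trial with least-squares and Kalman estimates plus error metrics, (3)
#' the nine-condition sensitivity grid, and (4) the sign-switching recovery
#' simulation. Stage failures are caught and recorded; the suite continues.
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir Optional directory: when given, trial and estimate CSVs
#'   are written there (created with a notice if missing).
#' @param lsm_seeds Number of noise seeds for the least-squares spread.
#' @param snr_db Noise level of the synthetic trials.
#' @return A list of class `balance_report` with elements `prototype`,
#'   `reference`, `lsm_spread`, `sensitivity`, `recovery`, `errors`
#'   (named list of stage error messages, empty on success) and `seed`.
#' @export
run_validation_suite <- function(seed = 1, out_dir = NULL, lsm_seeds = 20,
                                 snr_db = -0.1) {
  report <- list(seed = seed, errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  report$prototype <- run_stage("prototype", {
    prototype_kf_stiffness(seed = seed)
  })
  report$reference <- run_stage("reference", {
    run_reference_estimation(seed = seed, snr_db = snr_db)
  })
  report$lsm_spread <- run_stage("lsm_spread", {
    lsm_over_seeds(seeds = seed + seq_len(lsm_seeds), snr_db = snr_db)
  })
  report$sensitivity <- run_stage("sensitivity", {
    cfg <- if (!is.null(report$reference)) report$reference$cfg else NULL
    sensitivity_study(seed = seed, cfg = cfg, snr_db = snr_db)
  })
  report$recovery <- run_stage("recovery", {
    sim <- simulate_recovery(subject_params(85, 1.7), switching_rule())
    list(sim = sim, posture = posture_error(sim))
  })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      message("creating output directory: ", out_dir)
      dir.create(out_dir, recursive = TRUE)
    }
    if (!is.null(report$reference)) {
      write_trajectory_csv(report$reference$trial$noisy,
                           file.path(out_dir, "reference_noisy.csv"))
      write_profile_csv(report$reference$trial$truth,
                        file.path(out_dir, "reference_truth.csv"))
      utils::write.csv(report$reference$kf$estimates,
                       file.path(out_dir, "reference_kf.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$sensitivity)) {
      utils::write.csv(report$sensitivity,
                       file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
    }
  }
  structure(report, class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> seed =", x$seed, "\n")
  if (!is.null(x$prototype)) {
    cat("  prototype near-neutral stiffness (Nm/rad):\n")
    print(as.data.frame(x$prototype$near_neutral), row.names = FALSE)
  }
  if (!is.null(x$lsm_spread)) {
    m <- colMeans(x$lsm_spread[c("k1", "b1", "k2", "b2")])
    cat(sprintf("  LSM mean over %d seeds: k1 = %.1f, b1 = %.1f, k2 = %.1f, b2 = %.1f\n",
                nrow(x$lsm_spread), m[1], m[2], m[3], m[4]))
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  sensitivity worst-case NRMSE: k1 = %.1f%%, k2 = %.1f%%\n",
                100 * max(x$sensitivity$nrmse_k1),
                100 * max(x$sensitivity$nrmse_k2)))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery posture error: %.4g -> %.4g rad\n",
                x$recovery$posture$initial, x$recovery$posture$final))
  }
  if (length(x$errors) > 0) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
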