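# Regressor construction, least squares, Kalman filter, tuning, metrics.

make_traj <- function(df) as_trajectory(tibble::as_tibble(df))

test_that("the configuration matrix has the exact sparsity and entries", {
  tr <- make_traj(data.frame(
    time = c(0, 0.01), theta1 = c(0, 0.1), theta2 = c(0, 0.3),
    dtheta1 = c(0, 0.2), dtheta2 = c(0, 0.4),
    ddtheta1 = c(0, 0), ddtheta2 = c(0, 0)
  ))
  s <- build_regressor(tr, subject_params(85, 1.7))
  # sample at exact rest at the origin: H = 0 and Z = 0
  expect_equal(regressor_H(s, 1), matrix(0, 2, 4))
  expect_equal(c(s$z1[1], s$z2[1]), c(0, 0))
  # direct substitution
  H <- regressor_H(s, 2)
  expect_equal(H, matrix(c(0.1, 0.2, 0, 0, 0, 0, 0.3, 0.4), 2, 4,
                         byrow = TRUE))
  expect_equal(H[1, 3:4], c(0, 0))
  expect_equal(H[2, 1:2], c(0, 0))
})

test_that("missing derivatives are a precondition error", {
  tr <- make_traj(data.frame(time = c(0, 0.01), theta1 = c(0, 0.1),
                             theta2 = c(0, 0.2)))
  expect_error(build_regressor(tr, subject_params(85, 1.7)),
               "preprocess_trajectory")
})

test_that("the regressor identity Z = H lambda holds along clean dynamics", {
  p <- subject_params(85, 1.7)
  lam <- c(k1 = 1050, b1 = 30, k2 = 500, b2 = 20)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  # exact simulator derivatives: identity to machine precision
  tr <- simulate_pendulum(p, prof, joint_state(-0.1, 0.22), 3, dt = 0.01)
  s <- build_regressor(tr, p)
  res1 <- s$z1 - (s$theta1 * lam[1] + s$dtheta1 * lam[2])
  res2 <- s$z2 - (s$theta2 * lam[3] + s$dtheta2 * lam[4])
  expect_lt(max(abs(c(res1, res2))), 1e-9)
  # numerical derivatives: residual shrinks as dt -> 0
  res_at <- function(dt) {
    tr <- simulate_pendulum(p, prof, joint_state(-0.1, 0.22), 3, dt = dt)
    raw <- make_traj(tibble::as_tibble(tr)[c("time", "theta1", "theta2")])
    s <- build_regressor(preprocess_trajectory(raw, cutoff = NULL), p)
    inner <- 3:(nrow(s) - 2)
    sqrt(mean((s$z1 - (s$theta1 * lam[1] + s$dtheta1 * lam[2]))[inner]^2))
  }
  expect_gt(res_at(0.02) / res_at(0.01), 3)
})

test_that("least squares recovers constant parameters exactly from clean data", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 10, dt = 0.01)
  fit <- lsm_estimate(build_regressor(tr, p))
  expect_equal(unname(fit$lambda_hat), c(1050, 30, 500, 20),
               tolerance = 1e-6)
  expect_lt(glance(fit)$residual_rmse, 1e-8)
  # pseudoinverse route agrees with explicit normal equations
  sys <- balancekf:::stack_regressor(build_regressor(tr, p))
  ne <- solve(t(sys$H) %*% sys$H, t(sys$H) %*% sys$Z)
  expect_equal(unname(fit$lambda_hat), drop(ne), tolerance = 1e-10)
})

test_that("rank deficiency names the unidentifiable components", {
  tr <- make_traj(data.frame(
    time = seq(0, 0.1, by = 0.01),
    theta1 = sin(seq(0, 0.1, by = 0.01) * 20) * 0.1,
    theta2 = 0, dtheta1 = cos(seq(0, 0.1, by = 0.01) * 20) * 2,
    dtheta2 = 0, ddtheta1 = 0, ddtheta2 = 0
  ))
  expect_error(lsm_estimate(build_regressor(tr, subject_params(85, 1.7))),
               "k2, b2")
})

test_that("the Kalman filter with Q = 0 is a recursive least squares", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 10, dt = 0.01)
  s <- build_regressor(tr, p)
  lsm <- lsm_estimate(s)
  kf <- kf_run(s, kalman_config(Q = 0, P0 = 1e6, lambda0 = rep(0, 4),
                                R = 1e-6))
  fin <- unlist(kf$estimates[nrow(kf$estimates), c("k1", "b1", "k2", "b2")])
  expect_equal(unname(fin), unname(lsm$lambda_hat), tolerance = 1e-4)
})

test_that("an enormous measurement covariance freezes the estimate", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 2, dt = 0.01)
  s <- build_regressor(tr, p)
  lam0 <- c(100, 1, 50, 1)
  kf <- kf_run(s, kalman_config(Q = 0, P0 = 1, lambda0 = lam0, R = 1e12))
  fin <- unlist(kf$estimates[nrow(kf$estimates), c("k1", "b1", "k2", "b2")])
  expect_equal(unname(fin), lam0, tolerance = 1e-4)
})

test_that("the filter tracks a step change in stiffness on clean data", {
  p <- subject_params(85, 1.7)
  k1_step <- function(t) ifelse(t < 4, 1200, 800)
  prof <- viscoelastic_profile(k1 = k1_step, b1 = 30, k2 = 500, b2 = 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 8, dt = 0.01)
  s <- build_regressor(tr, p)
  kf <- kf_run(s, kalman_config(Q = c(10, 0.1, 10, 0.1), R = 1e-4,
                                lambda0 = c(1200, 30, 500, 20), P0 = 1))
  est <- kf$estimates
  # mid-segment estimates sit within 10% of the realized level
  expect_equal(est$k1[est$time > 2 & est$time < 3.5],
               rep(1200, sum(est$time > 2 & est$time < 3.5)),
               tolerance = 0.1)
  expect_equal(est$k1[est$time > 6.5],
               rep(800, sum(est$time > 6.5)), tolerance = 0.1)
  # the recursive-least-squares limit (Q = 0) averages instead of tracking:
  # its final value is the all-sample least-squares solution, not the final
  # segment level
  rls <- kf_run(s, kalman_config(Q = 0, R = 1e-4,
                                 lambda0 = c(1200, 30, 500, 20), P0 = 1e6))
  fin <- rls$estimates$k1[nrow(rls$estimates)]
  lsm_all <- lsm_estimate(s)$lambda_hat[["k1"]]
  expect_equal(fin, lsm_all, tolerance = 1e-3)
  expect_gt(abs(fin - 800), 20)
})

test_that("the estimation covariance stays symmetric positive semi-definite", {
  p <- subject_params(85, 1.7)
  trial <- generate_trial(params = p, duration = 5, seed = 2)
  s <- build_regressor(preprocess_trajectory(trial$noisy), p)
  kf <- kf_run(s, kalman_config(Q = c(1, 0.01, 1, 0.01)))
  for (P in kf$P[seq(1, length(kf$P), by = 50)]) {
    expect_equal(P, t(P), tolerance = 1e-10)
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
              -1e-6 * max(diag(P)))
  }
})

test_that("parameter error does not improve as measurement noise grows", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  clean <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 6, dt = 0.01)
  truth <- profile_eval(prof, clean$time)
  rmse_k1 <- function(snr) {
    mean(vapply(1:4, function(seed) {
      noisy <- add_noise(clean, snr_db = snr, seed = seed)
      s <- build_regressor(preprocess_trajectory(noisy), p)
      fit <- lsm_estimate(s)
      abs(fit$lambda_hat[["k1"]] - 1050)
    }, numeric(1)))
  }
  errs <- c(rmse_k1(60), rmse_k1(30), rmse_k1(10))
  expect_true(all(diff(errs) > 0))
})

test_that("process-covariance tuning is deterministic, idempotent, and shrinks on clean data", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 6, dt = 0.01)
  s <- build_regressor(tr, p)
  truth <- profile_eval(prof, tr$time)
  grid <- lapply(10^c(-6, -2, 2), function(q) q * c(1, 0.01, 1, 0.01))
  cfg <- tune_process_covariance(s, truth, candidates = grid,
                                 cfg = kalman_config(R = 1e-6))
  # constant truth, clean data: the smallest candidate wins
  expect_equal(diag(cfg$Q), 1e-6 * c(1, 0.01, 1, 0.01))
  # idempotence: re-offering the winner returns it
  cfg2 <- tune_process_covariance(s, truth,
                                  candidates = list(diag(cfg$Q)),
                                  cfg = kalman_config(R = 1e-6))
  expect_equal(cfg2$Q, cfg$Q)
  expect_error(tune_process_covariance(s, truth, candidates = list()),
               "empty")
  expect_s3_class(attr(cfg, "tuning"), "tbl_df")
})

test_that("error metrics match closed forms and a brute-force loop", {
  tt <- seq(0, 1, by = 0.1)
  truth <- tibble::tibble(time = tt, k1 = 100, b1 = 10, k2 = 50, b2 = 5)
  est <- truth
  out <- estimation_errors(est, truth)
  expect_equal(out$rmse, rep(0, 4))
  expect_equal(out$nrmse, rep(0, 4))
  # constant offset: RMSE = |e|, NRMSE = |e| / truth
  est2 <- dplyr::mutate(truth, k1 = k1 + 7)
  out2 <- estimation_errors(est2, truth)
  expect_equal(out2$rmse[out2$parameter == "k1"], 7)
  expect_equal(out2$nrmse[out2$parameter == "k1"], 0.07)
  # randomized pairs against a direct loop
  withr::with_seed(9, {
    truth3 <- tibble::tibble(time = tt, k1 = rnorm(11, 100), b1 = rnorm(11, 10),
                             k2 = rnorm(11, 50), b2 = rnorm(11, 5))
    est3 <- dplyr::mutate(truth3, dplyr::across(-time, ~ .x + rnorm(11)))
  })
  out3 <- estimation_errors(est3, truth3)
  for (pn in c("k1", "b1", "k2", "b2")) {
    acc <- 0
    for (i in seq_along(tt)) acc <- acc + (est3[[pn]][i] - truth3[[pn]][i])^2
    rmse <- sqrt(acc / length(tt))
    expect_equal(out3$rmse[out3$parameter == pn], rmse)
    expect_equal(out3$nrmse[out3$parameter == pn],
                 rmse / abs(mean(truth3[[pn]])))
  }
  # alternative normalizers
  outr <- estimation_errors(est2, truth, normalizer = "range")
  expect_true(all(is.na(outr$nrmse) | is.infinite(outr$nrmse) |
                    outr$nrmse >= 0))
  expect_error(estimation_errors(est2[1:5, ], truth), "length")
})

test_that("tidiers return the documented shapes", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.10, 0.22), 2, dt = 0.01)
  s <- build_regressor(tr, p)
  fit <- lsm_estimate(s)
  td <- tidy(fit)
  expect_equal(td$term, c("k1", "b1", "k2", "b2"))
  expect_s3_class(glance(fit), "tbl_df")
  kf <- kf_run(s, kalman_config(R = 1e-6))
  tk <- tidy(kf)
  expect_equal(nrow(tk), 4 * nrow(s))
  expect_true(all(c("time", "term", "estimate", "variance") %in% names(tk)))
  expect_equal(nrow(glance(kf)), 1L)
  expect_s3_class(autoplot(kf), "ggplot")
  expect_s3_class(autoplot(tr), "ggplot")
})
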