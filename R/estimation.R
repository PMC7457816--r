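# Inverse-dynamics regressor, least-squares and Kalman-filter estimators of
# the joint visco-elastic parameters lambda = [k1, b1, k2, b2].

#' Build the inverse-dynamics regressor from a trajectory
#'
#' For each sample the model torque balance is rewritten linearly in the
#' parameter vector `lambda = [k1, b1, k2, b2]`:
#' `Z_k = H_k lambda`, with
#' `H_k = [[theta1, dtheta1, 0, 0], [0, 0, theta2, dtheta2]]` and
#' `Z_k = -(M(q) ddq + C(q, dq) dq + G(q))` (the negated joint torque,
#' computed by inverse dynamics from measured kinematics and known inertial
#' parameters).
#'
#' @param traj A `pend_trajectory` with filled velocity and acceleration
#'   channels (see [preprocess_trajectory()]).
#' @param params A [pendulum_params()] object.
#' @return A tibble of class `regressor_set` with columns `time`, `theta1`,
#'   `dtheta1`, `theta2`, `dtheta2` (the non-zero entries of `H_k`) and
#'   `z1`, `z2`.
#' @export
build_regressor <- function(traj, params) {
  stopifnot(inherits(traj, "pend_trajectory"))
  if (!has_derivatives(traj)) {
    stop("trajectory lacks velocity/acceleration channels; run ",
         "preprocess_trajectory() first", call. = FALSE)
  }
  co <- lumped_coefficients(params)
  th1 <- traj$theta1; th2 <- traj$theta2
  dth1 <- traj$dtheta1; dth2 <- traj$dtheta2
  ddth1 <- traj$ddtheta1; ddth2 <- traj$ddtheta2
  c2 <- cos(th2); s2 <- sin(th2)
  m11 <- co$alpha + 2 * co$beta * c2
  m12 <- -(co$gamma + co$beta * c2)
  s21 <- sin(th2 - th1)
  # Z = -tau = -(M(q) ddq + C(q, dq) dq + G(q)); along the true dynamics
  # this equals H lambda with lambda = [k1, b1, k2, b2].
  z1 <- -(m11 * ddth1 + m12 * ddth2 +
            co$beta * s2 * (-2 * dth2 * dth1 + dth2^2) +
            co$epsilon * co$g * s21 - co$delta * co$g * sin(th1))
  z2 <- -(m12 * ddth1 + co$gamma * ddth2 +
            co$beta * s2 * dth1^2 - co$epsilon * co$g * s21)
  structure(
    tibble::tibble(time = traj$time, theta1 = th1, dtheta1 = dth1,
                   theta2 = th2, dtheta2 = dth2, z1 = z1, z2 = z2),
    class = c("regressor_set", class(tibble::tibble())),
    params = params
  )
}

#' Configuration matrix of a single regressor sample
#'
#' @param samples A `regressor_set`.
#' @param i Row index.
#' @return The 2x4 matrix `H_i` (zeros at positions (1,3), (1,4), (2,1),
#'   (2,2)).
#' @export
regressor_H <- function(samples, i) {
  matrix(c(samples$theta1[i], 0,
           samples$dtheta1[i], 0,
           0, samples$theta2[i],
           0, samples$dtheta2[i]), 2, 4)
}

# Stack a regressor set into the 2N x 4 design matrix and 2N response.
stack_regressor <- function(samples) {
  n <- nrow(samples)
  H <- matrix(0, 2L * n, 4L)
  odd <- seq(1L, 2L * n, by = 2L)
  H[odd, 1] <- samples$theta1
  H[odd, 2] <- samples$dtheta1
  H[odd + 1L, 3] <- samples$theta2
  H[odd + 1L, 4] <- samples$dtheta2
  Z <- numeric(2L * n)
  Z[odd] <- samples$z1
  Z[odd + 1L] <- samples$z2
  list(H = H, Z = Z)
}

lambda_names <- c("k1", "b1", "k2", "b2")

#' Least-squares estimate of constant visco-elastic parameters
#'
#' Solves the stacked linear system `Z = H lambda` in the least-squares
#' (Moore-Penrose) sense, treating the parameters as constant over the trial.
#' Reports the torque-reconstruction residual `rho = Z - H lambda_hat` and
#' its mean and RMSE.
#'
#' @param samples A `regressor_set` from [build_regressor()].
#' @return An object of class `lsm_fit` with elements `lambda_hat` (named
#'   vector), `residuals` (tibble `time`, `rho1`, `rho2`), `n`.
#' @export
lsm_estimate <- function(samples) {
  if (nrow(samples) < 2L) {
    stop("need at least two samples for an overdetermined system",
         call. = FALSE)
  }
  sys <- stack_regressor(samples)
  qrH <- qr(sys$H)
  if (qrH$rank < 4L) {
    dropped <- lambda_names[sort(qrH$pivot[-seq_len(qrH$rank)])]
    stop("regressor is rank deficient; unidentifiable component(s): ",
         paste(dropped, collapse = ", "),
         " (angles or velocities lack excitation)", call. = FALSE)
  }
  lambda <- qr.coef(qrH, sys$Z)
  names(lambda) <- lambda_names
  rho <- sys$Z - drop(sys$H %*% lambda)
  odd <- seq(1L, length(rho), by = 2L)
  structure(
    list(
      lambda_hat = lambda,
      residuals = tibble::tibble(time = samples$time,
                                 rho1 = rho[odd], rho2 = rho[odd + 1L]),
      n = nrow(samples)
    ),
    class = "lsm_fit"
  )
}

#' @export
print.lsm_fit <- function(x, ...) {
  cat("<lsm_fit> constant visco-elastic parameters\n")
  print(round(x$lambda_hat, 3))
  g <- glance.lsm_fit(x)
  cat(sprintf("  residual mean = %.3g Nm, RMSE = %.3g Nm (n = %d)\n",
              g$residual_mean, g$residual_rmse, x$n))
  invisible(x)
}

residual_metrics <- function(res) {
  rho <- c(res$rho1, res$rho2)
  tibble::tibble(residual_mean = mean(rho),
                 residual_rmse = sqrt(mean(rho^2)))
}

#' Kalman filter configuration
#'
#' State-space model for the parameter vector: `lambda_k = A lambda_{k-1}`
#' (plus optional control input `B mu`, zero by default), observed through
#' `Z_k = H_k lambda_k + v_k`, `v_k ~ N(0, R)`.
#'
#' Defaults: `A = I` (constant-parameter model), `Q = 0` (which makes the
#' filter algebraically a recursive least squares), `P0 = 1e3 * I`.
#' When `R` or `lambda0` are `NULL` they are filled at run time from the
#' data: `R` as the diagonal covariance of the least-squares torque
#' residuals, and `lambda0` as the least-squares estimate over the first
#' `init_window` seconds (falling back to zero if that window is not
#' identifiable).
#'
#' @param A 4x4 state-transition matrix.
#' @param Q 4x4 process covariance (symmetric PSD); a scalar or length-4
#'   vector is expanded to a diagonal matrix.
#' @param R 2x2 measurement covariance, or `NULL` for the data-driven
#'   default.
#' @param lambda0 Initial parameter estimate (length 4), or `NULL`.
#' @param P0 4x4 initial covariance; scalar/vector expanded as for `Q`.
#' @param B,mu Optional control-input matrix and input sequence; unused by
#'   default (accepted for completeness, `mu` defaults to zero).
#' @param init_window Length (s) of the initial window used for the
#'   `lambda0` default.
#' @return An object of class `kalman_config`.
#' @export
kalman_config <- function(A = diag(4), Q = 0, R = NULL, lambda0 = NULL,
                          P0 = 1e3, B = NULL, mu = NULL,
                          init_window = 0.5) {
  expand4 <- function(x, name) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(4, 4))) stop(name, " must be 4x4", call. = FALSE)
      return(x)
    }
    if (length(x) == 1L) return(diag(rep(x, 4)))
    if (length(x) == 4L) return(diag(as.numeric(x)))
    stop(name, " must be a 4x4 matrix, a scalar or a length-4 diagonal",
         call. = FALSE)
  }
  Q <- expand4(Q, "Q")
  P0 <- expand4(P0, "P0")
  check_psd(Q, "Q")
  check_psd(P0, "P0")
  if (!is.null(R)) {
    if (length(R) == 1L) R <- diag(rep(R, 2))
    if (length(R) == 2L && !is.matrix(R)) R <- diag(as.numeric(R))
    if (!is.matrix(R) || !all(dim(R) == c(2, 2))) {
      stop("R must be 2x2 (or a scalar / length-2 diagonal)", call. = FALSE)
    }
    check_psd(R, "R")
  }
  structure(
    list(A = A, Q = Q, R = R, lambda0 = lambda0, P0 = P0, B = B, mu = mu,
         init_window = init_window),
    class = "kalman_config"
  )
}

check_psd <- function(M, name, tol = 1e-8) {
  if (max(abs(M - t(M))) > tol * max(abs(M), 1)) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(name, " must be positive semi-definite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Estimate the measurement covariance from least-squares residuals
#'
#' The torque measurement noise entering the regressor equation is
#' characterized by the covariance of the residuals `Z - H lambda` around a
#' reference parameter vector (by default the least-squares fit of the same
#' samples). Off-diagonal terms are dropped: the two joint channels are
#' treated as uncorrelated.
#'
#' @param samples A `regressor_set`.
#' @param lambda Optional reference parameter vector; default the LSM fit.
#' @return A diagonal 2x2 covariance matrix.
#' @export
estimate_measurement_covariance <- function(samples, lambda = NULL) {
  if (is.null(lambda)) lambda <- lsm_estimate(samples)$lambda_hat
  r1 <- samples$z1 - (samples$theta1 * lambda[1] + samples$dtheta1 * lambda[2])
  r2 <- samples$z2 - (samples$theta2 * lambda[3] + samples$dtheta2 * lambda[4])
  v <- c(stats::var(r1), stats::var(r2))
  # floor keeps R invertible on (numerically) noiseless data
  diag(pmax(v, 1e-12 * max(mean(samples$z1^2), mean(samples$z2^2), 1)))
}

#' Run the Kalman filter over a regressor set
#'
#' Per-step predict/update of the parameter vector `lambda = [k1, b1, k2,
#' b2]` treated as the filter state, with the 2-vector `Z_k` as the joint
#' measurement:
#' predict `lambda- = A lambda`, `P- = A P A' + Q`; gain
#' `K = P- H' (H P- H' + R)^-1`; update `lambda = lambda- + K (Z - H
#' lambda-)`, `P = (I - K H) P-` (symmetrized, PSD asserted each step).
#'
#' @param samples A `regressor_set` from [build_regressor()].
#' @param cfg A [kalman_config()].
#' @return An object of class `kf_fit`: a list with `estimates` (tibble
#'   `time`, `k1`, `b1`, `k2`, `b2` and covariance diagonal `P_k1` ...
#'   `P_b2`), `P` (list of 4x4 covariances), `residuals` (post-update
#'   innovation tibble), `config` (the completed configuration).
#' @export
kf_run <- function(samples, cfg = kalman_config()) {
  stopifnot(inherits(cfg, "kalman_config"))
  n <- nrow(samples)
  if (n < 1L) stop("empty regressor set", call. = FALSE)

  R <- cfg$R
  if (is.null(R)) R <- estimate_measurement_covariance(samples)
  lambda <- cfg$lambda0
  if (is.null(lambda)) {
    t0 <- samples$time[1]
    head_idx <- which(samples$time <= t0 + cfg$init_window)
    lambda <- tryCatch(
      unname(lsm_estimate(samples[head_idx, ])$lambda_hat),
      error = function(e) rep(0, 4)
    )
  }
  lambda <- as.numeric(lambda)
  if (length(lambda) != 4L) stop("lambda0 must have length 4", call. = FALSE)
  lambda0_used <- lambda

  A <- cfg$A; Q <- cfg$Q; P <- cfg$P0
  B <- cfg$B
  mu <- cfg$mu
  I4 <- diag(4)
  est <- matrix(NA_real_, n, 4L)
  pdiag <- matrix(NA_real_, n, 4L)
  rho <- matrix(NA_real_, n, 2L)
  Plist <- vector("list", n)

  for (k in seq_len(n)) {
    lam_pred <- drop(A %*% lambda)
    if (!is.null(B) && !is.null(mu)) {
      mu_k <- if (is.matrix(mu)) mu[k, ] else mu
      lam_pred <- lam_pred + drop(B %*% mu_k)
    }
    Pp <- A %*% P %*% t(A) + Q
    H <- matrix(c(samples$theta1[k], 0,
                  samples$dtheta1[k], 0,
                  0, samples$theta2[k],
                  0, samples$dtheta2[k]), 2, 4)
    S <- H %*% Pp %*% t(H) + R
    dS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    if (!is.finite(dS) || abs(dS) < 1e-300) {
      stop(sprintf("innovation covariance is singular at step %d", k),
           call. = FALSE)
    }
    Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / dS
    K <- Pp %*% t(H) %*% Sinv
    z <- c(samples$z1[k], samples$z2[k])
    innov <- z - drop(H %*% lam_pred)
    lambda <- lam_pred + drop(K %*% innov)
    # Joseph-form covariance update: algebraically (I - K H) P- for the
    # optimal gain, but numerically robust to cancellation
    IKH <- I4 - K %*% H
    P <- IKH %*% Pp %*% t(IKH) + K %*% R %*% t(K)
    P <- (P + t(P)) / 2
    dP <- diag(P)
    if (any(dP < -1e-8 * max(dP, 1))) {
      stop(sprintf("covariance lost positive semi-definiteness at step %d", k),
           call. = FALSE)
    }
    est[k, ] <- lambda
    pdiag[k, ] <- dP
    rho[k, ] <- z - drop(H %*% lambda)
    Plist[[k]] <- P
  }

  estimates <- tibble::tibble(
    time = samples$time,
    k1 = est[, 1], b1 = est[, 2], k2 = est[, 3], b2 = est[, 4],
    P_k1 = pdiag[, 1], P_b1 = pdiag[, 2], P_k2 = pdiag[, 3],
    P_b2 = pdiag[, 4]
  )
  cfg$R <- R
  cfg$lambda0 <- lambda0_used
  structure(
    list(
      estimates = estimates,
      P = Plist,
      residuals = tibble::tibble(time = samples$time,
                                 rho1 = rho[, 1], rho2 = rho[, 2]),
      config = cfg
    ),
    class = "kf_fit"
  )
}

#' @export
print.kf_fit <- function(x, ...) {
  fin <- x$estimates[nrow(x$estimates), c("k1", "b1", "k2", "b2")]
  cat(sprintf("<kf_fit> %d steps; final estimate:\n", nrow(x$estimates)))
  print(round(as.data.frame(fin), 3), row.names = FALSE)
  invisible(x)
}

#' Tune the process covariance on a trial with known ground truth
#'
#' Runs the filter once per candidate diagonal process covariance and picks
#' the candidate minimizing the parameter estimation error (sum over the
#' four parameters of RMSE normalized by the time-mean of the true
#' parameter); the torque-reconstruction RMSE of every candidate is
#' reported alongside. Deterministic given the samples and the grid.
#'
#' @param samples A `regressor_set` built from the (noisy, preprocessed)
#'   trial.
#' @param truth Ground-truth parameter tibble with columns `time`, `k1`,
#'   `b1`, `k2`, `b2` aligned with `samples` (e.g. the `truth` element of a
#'   [generate_trial()] bundle).
#' @param candidates List of candidate `Q` diagonals (each a scalar or
#'   length-4 vector). The default grid spans scalar magnitudes `10^(-8)`
#'   to `10^2` scaled by `c(1, 0.01, 1, 0.01)` (stiffness vs damping
#'   scale).
#' @param cfg Base [kalman_config()] supplying `A`, `R`, `P0`, `lambda0`.
#' @return The tuned `kalman_config`; the per-candidate scores are attached
#'   as attribute `"tuning"` (a tibble).
#' @export
tune_process_covariance <- function(samples, truth,
                                    candidates = default_q_grid(),
                                    cfg = kalman_config()) {
  if (length(candidates) == 0) stop("empty candidate grid", call. = FALSE)
  truth <- align_truth(samples, truth)
  scores <- purrr::map_dfr(seq_along(candidates), function(i) {
    q <- candidates[[i]]
    cfg_i <- cfg
    cfg_i$Q <- if (length(q) == 1L) diag(rep(q, 4)) else diag(as.numeric(q))
    fit <- kf_run(samples, cfg_i)
    err <- estimation_errors(fit, truth)
    res <- residual_metrics(fit$residuals)
    tibble::tibble(candidate = i,
                   q_diag = list(diag(cfg_i$Q)),
                   score = sum(err$nrmse),
                   torque_rmse = res$residual_rmse)
  })
  best <- scores$candidate[which.min(scores$score)]
  q <- candidates[[best]]
  cfg$Q <- if (length(q) == 1L) diag(rep(q, 4)) else diag(as.numeric(q))
  attr(cfg, "tuning") <- scores
  cfg
}

#' Default process-covariance candidate grid
#'
#' Scalar magnitudes `10^-8, 10^-7, ..., 10^2` applied to the diagonal
#' pattern `c(1, 0.01, 1, 0.01)` (stiffness entries vary on a ~100x larger
#' scale than damping entries, mirroring their physical magnitudes).
#'
#' @return A list of length-4 diagonals.
#' @export
default_q_grid <- function() {
  lapply(10^seq(-8, 2), function(s) s * c(1, 0.01, 1, 0.01))
}

align_truth <- function(samples, truth) {
  need <- c("time", lambda_names)
  miss <- setdiff(need, names(truth))
  if (length(miss) > 0) {
    stop("truth is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(truth) != nrow(samples) ||
      max(abs(truth$time - samples$time)) > 1e-8) {
    stop("truth and samples time bases are not aligned", call. = FALSE)
  }
  truth
}

#' Estimation-error metrics against ground truth
#'
#' Per-parameter RMSE and normalized RMSE (RMSE divided by a scale of the
#' true parameter: its time-mean by default, optionally its range or final
#' value). For constant estimates (an `lsm_fit`) the estimate is expanded
#' to the truth's time base.
#'
#' @param estimates A `kf_fit`, an `lsm_fit`, or a tibble with columns
#'   `time`, `k1`, `b1`, `k2`, `b2`.
#' @param truth Ground-truth tibble (`time`, `k1`, `b1`, `k2`, `b2`).
#' @param normalizer `"mean"`, `"range"` or `"final"` scale of the true
#'   parameter used for NRMSE.
#' @return A tibble with columns `parameter`, `rmse`, `nrmse` (fraction;
#'   multiply by 100 for percent).
#' @export
estimation_errors <- function(estimates, truth,
                              normalizer = c("mean", "range", "final")) {
  normalizer <- match.arg(normalizer)
  est <- if (inherits(estimates, "kf_fit")) {
    estimates$estimates[c("time", lambda_names)]
  } else if (inherits(estimates, "lsm_fit")) {
    tibble::as_tibble(c(list(time = truth$time),
                        as.list(estimates$lambda_hat)))
  } else {
    tibble::as_tibble(estimates)[c("time", lambda_names)]
  }
  if (nrow(est) != nrow(truth)) {
    stop("estimates and truth have different lengths", call. = FALSE)
  }
  purrr::map_dfr(lambda_names, function(pn) {
    e <- est[[pn]] - truth[[pn]]
    rmse <- sqrt(mean(e^2))
    scale <- switch(normalizer,
                    mean = abs(mean(truth[[pn]])),
                    range = diff(range(truth[[pn]])),
                    final = abs(truth[[pn]][nrow(truth)]))
    tibble::tibble(parameter = pn, rmse = rmse,
                   nrmse = if (scale > 0) rmse / scale else NA_real_)
  })
}
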