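#' Mass matrix of the two-link model
#'
#' \deqn{M(\theta_2) = \begin{bmatrix}
#'   \alpha + 2\beta\cos\theta_2 & -(\gamma + \beta\cos\theta_2) \\
#'   -(\gamma + \beta\cos\theta_2) & \gamma \end{bmatrix}}
#' The matrix is symmetric for every configuration and depends only on the
#' generalized hip coordinate.
#'
#' @param co A [lumped_coefficients()] object.
#' @param theta2 Generalized hip coordinate (rad).
#' @return A 2x2 numeric matrix.
#' @export
mass_matrix <- function(co, theta2) {
  c2 <- cos(theta2)
  off <- -(co$gamma + co$beta * c2)
  matrix(c(co$alpha + 2 * co$beta * c2, off, off, co$gamma), 2, 2)
}

#' Coriolis/centrifugal matrix of the two-link model
#'
#' \deqn{C(q, \dot q) = \begin{bmatrix}
#'   -2\beta\dot\theta_2\sin\theta_2 & \beta\dot\theta_2\sin\theta_2 \\
#'   \beta\dot\theta_1\sin\theta_2 & 0 \end{bmatrix}}
#'
#' @param co A [lumped_coefficients()] object.
#' @param state A [joint_state()] (or list with `theta2`, `dtheta1`,
#'   `dtheta2`).
#' @return A 2x2 numeric matrix; the (2,2) entry is always zero.
#' @export
coriolis_matrix <- function(co, state) {
  s2 <- sin(state$theta2)
  matrix(c(-2 * co$beta * state$dtheta2 * s2,
           co$beta * state$dtheta1 * s2,
           co$beta * state$dtheta2 * s2,
           0), 2, 2)
}

#' Gravity vector of the two-link model
#'
#' \deqn{G(q) = \begin{bmatrix}
#'   \epsilon g \sin\theta_{21} - \delta g \sin\theta_1 \\
#'   -\epsilon g \sin\theta_{21} \end{bmatrix}}
#' with \eqn{\theta_{21} = \theta_2 - \theta_1} the trunk inclination from
#' vertical. Upright (`theta1 = theta2 = 0`) is an equilibrium: `G = 0`.
#'
#' @param co A [lumped_coefficients()] object.
#' @param state A [joint_state()].
#' @param g Gravitational acceleration; defaults to the value stored with the
#'   coefficients.
#' @return A numeric 2-vector.
#' @export
gravity_vector <- function(co, state, g = co$g) {
  s21 <- sin(state$theta2 - state$theta1)
  c(co$epsilon * g * s21 - co$delta * g * sin(state$theta1),
    -co$epsilon * g * s21)
}

#' Kelvin-Voigt joint torque
#'
#' \deqn{\tau = -\begin{bmatrix} k_1(t)\theta_1 + b_1(t)\dot\theta_1 \\
#'   k_2(t)\theta_2 + b_2(t)\dot\theta_2 \end{bmatrix}}
#' A negative stiffness yields a torque pushing the joint away from zero.
#'
#' @param profile A [viscoelastic_profile()].
#' @param state A [joint_state()].
#' @param t Time (s) at which the profile is evaluated.
#' @return A numeric 2-vector of joint torques (N m).
#' @export
joint_torque <- function(profile, state, t) {
  -c(profile$k1(t) * state$theta1 + profile$b1(t) * state$dtheta1,
     profile$k2(t) * state$theta2 + profile$b2(t) * state$dtheta2)
}

#' Forward dynamics: joint accelerations
#'
#' Solves \eqn{M(q)\ddot q + C(q,\dot q)\dot q + G(q) = \tau} for
#' \eqn{\ddot q}.
#'
#' @param params A [pendulum_params()] object.
#' @param profile A [viscoelastic_profile()].
#' @param state A [joint_state()].
#' @param t Time (s).
#' @return Numeric 2-vector of angular accelerations (rad/s^2).
#' @export
forward_dynamics <- function(params, profile, state, t = 0) {
  co <- lumped_coefficients(params)
  qdd <- fd_accel(co, profile, state$theta1, state$theta2,
                  state$dtheta1, state$dtheta2, t)
  if (is.null(qdd)) {
    stop(sprintf(
      "mass matrix is singular at theta2 = %.6g rad; cannot invert",
      state$theta2), call. = FALSE)
  }
  qdd
}

# Internal hot path: acceleration from lumped coefficients and scalars.
# Returns NULL when the mass matrix is (numerically) singular.
fd_accel <- function(co, profile, th1, th2, dth1, dth2, t) {
  c2 <- cos(th2)
  s2 <- sin(th2)
  m11 <- co$alpha + 2 * co$beta * c2
  m12 <- -(co$gamma + co$beta * c2)
  m22 <- co$gamma
  det <- m11 * m22 - m12 * m12
  if (!is.finite(det) || abs(det) < 1e-12 * max(abs(m11 * m22), 1)) {
    return(NULL)
  }
  s21 <- sin(th2 - th1)
  g1 <- co$epsilon * co$g * s21 - co$delta * co$g * sin(th1)
  g2 <- -co$epsilon * co$g * s21
  cq1 <- co$beta * s2 * (-2 * dth2 * dth1 + dth2 * dth2)
  cq2 <- co$beta * s2 * dth1 * dth1
  tau1 <- -(profile$k1(t) * th1 + profile$b1(t) * dth1)
  tau2 <- -(profile$k2(t) * th2 + profile$b2(t) * dth2)
  r1 <- tau1 - cq1 - g1
  r2 <- tau2 - cq2 - g2
  c(m22 * r1 - m12 * r2, m11 * r2 - m12 * r1) / det
}

#' Simulate the two-link model with a fixed-step classical Runge-Kutta scheme
#'
#' Integrates the non-linear equations of motion with the classical
#' fourth-order Runge-Kutta method at a fixed step (no adaptive stepping),
#' matching common fixed-rate motion-capture pipelines. Stored accelerations
#' are recomputed exactly from the forward dynamics at each stored sample.
#'
#' @param params A [pendulum_params()] object.
#' @param profile A [viscoelastic_profile()].
#' @param state0 Initial [joint_state()].
#' @param duration Trial length (s); must be at least `dt`.
#' @param dt Integration/sampling step (s), default 0.01 (100 Hz).
#' @param meta Optional provenance list merged into the trajectory metadata.
#' @return A [as_trajectory()] tibble with angles, velocities and
#'   accelerations.
#' @examples
#' p <- subject_params(85, 1.7)
#' traj <- simulate_pendulum(p, reference_profile(),
#'                           joint_state(-0.10, 0.22), duration = 2)
#' @export
simulate_pendulum <- function(params, profile, state0, duration,
                              dt = 0.01, meta = list()) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < dt) stop("duration must be at least dt", call. = FALSE)
  co <- lumped_coefficients(params)
  n <- floor(duration / dt + 1e-9) + 1L
  out <- rk4_integrate(
    y0 = c(state0$theta1, state0$theta2, state0$dtheta1, state0$dtheta2),
    n = n, dt = dt,
    deriv = function(t, y) {
      qdd <- fd_accel(co, profile, y[1], y[2], y[3], y[4], t)
      if (is.null(qdd)) {
        stop(sprintf("singular mass matrix at t = %.4f s", t), call. = FALSE)
      }
      c(y[3], y[4], qdd)
    }
  )
  qdd <- matrix(0, n, 2)
  tgrid <- out$t
  for (i in seq_len(n)) {
    y <- out$y[i, ]
    qdd[i, ] <- fd_accel(co, profile, y[1], y[2], y[3], y[4], tgrid[i])
  }
  as_trajectory(
    tibble::tibble(
      time = tgrid,
      theta1 = out$y[, 1], theta2 = out$y[, 2],
      dtheta1 = out$y[, 3], dtheta2 = out$y[, 4],
      ddtheta1 = qdd[, 1], ddtheta2 = qdd[, 2]
    ),
    meta = utils::modifyList(list(source = "simulated"), meta)
  )
}

# Acceleration with an arbitrary generalized torque (2-vector).
fd_accel_tau <- function(co, th1, th2, dth1, dth2, tau) {
  c2 <- cos(th2)
  s2 <- sin(th2)
  m11 <- co$alpha + 2 * co$beta * c2
  m12 <- -(co$gamma + co$beta * c2)
  m22 <- co$gamma
  det <- m11 * m22 - m12 * m12
  if (!is.finite(det) || abs(det) < 1e-12 * max(abs(m11 * m22), 1)) {
    return(NULL)
  }
  s21 <- sin(th2 - th1)
  g1 <- co$epsilon * co$g * s21 - co$delta * co$g * sin(th1)
  g2 <- -co$epsilon * co$g * s21
  r1 <- tau[1] - co$beta * s2 * (-2 * dth2 * dth1 + dth2 * dth2) - g1
  r2 <- tau[2] - co$beta * s2 * dth1 * dth1 - g2
  c(m22 * r1 - m12 * r2, m11 * r2 - m12 * r1) / det
}

# Simulate with a user-supplied generalized torque function
# torque_fn(state-vector c(th1, th2, dth1, dth2), t) -> 2-vector.
simulate_torque_fn <- function(params, torque_fn, state0, duration, dt,
                               meta = list()) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < dt) stop("duration must be at least dt", call. = FALSE)
  co <- lumped_coefficients(params)
  n <- floor(duration / dt + 1e-9) + 1L
  deriv <- function(t, y) {
    qdd <- fd_accel_tau(co, y[1], y[2], y[3], y[4], torque_fn(y, t))
    if (is.null(qdd)) {
      stop(sprintf("singular mass matrix at t = %.4f s", t), call. = FALSE)
    }
    c(y[3], y[4], qdd)
  }
  out <- rk4_integrate(
    y0 = c(state0$theta1, state0$theta2, state0$dtheta1, state0$dtheta2),
    n = n, dt = dt, deriv = deriv
  )
  qdd <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    y <- out$y[i, ]
    qdd[i, ] <- fd_accel_tau(co, y[1], y[2], y[3], y[4],
                             torque_fn(y, out$t[i]))
  }
  as_trajectory(
    tibble::tibble(time = out$t,
                   theta1 = out$y[, 1], theta2 = out$y[, 2],
                   dtheta1 = out$y[, 3], dtheta2 = out$y[, 4],
                   ddtheta1 = qdd[, 1], ddtheta2 = qdd[, 2]),
    meta = meta
  )
}

# Fixed-step classical RK4. Aborts with the time of failure if the state
# leaves the finite range (divergence).
rk4_integrate <- function(y0, n, dt, deriv) {
  y <- matrix(NA_real_, n, length(y0))
  y[1, ] <- y0
  tgrid <- (seq_len(n) - 1L) * dt
  yi <- y0
  d <- function(t, y) {
    if (!all(is.finite(y)) || max(abs(y)) > 1e8) {
      stop(sprintf("integration diverged at t = %.4f s (state out of range)",
                   t), call. = FALSE)
    }
    deriv(t, y)
  }
  for (i in seq_len(n - 1L)) {
    t <- tgrid[i]
    k1 <- d(t, yi)
    k2 <- d(t + dt / 2, yi + dt / 2 * k1)
    k3 <- d(t + dt / 2, yi + dt / 2 * k2)
    k4 <- d(t + dt, yi + dt * k3)
    yi <- yi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(yi)) || max(abs(yi)) > 1e8) {
      stop(sprintf("integration diverged at t = %.4f s (state out of range)",
                   t + dt), call. = FALSE)
    }
    y[i + 1L, ] <- yi
  }
  list(t = tgrid, y = y)
}

#' Mechanical energies of the two-link model
#'
#' Kinetic energy is assembled from the segment COM velocities; potential
#' energy contains the gravitational terms plus the elastic energy
#' \eqn{\tfrac12(k_1\theta_1^2 + k_2\theta_2^2)}; the dissipation rate is
#' \eqn{b_1\dot\theta_1^2 + b_2\dot\theta_2^2} (the time derivative of the
#' energy lost to the dampers, i.e. twice the Rayleigh function).
#'
#' @param params A [pendulum_params()] object.
#' @param profile A [viscoelastic_profile()].
#' @param state A [joint_state()].
#' @param t Time (s).
#' @return A tibble with columns `kinetic`, `potential`, `dissipation_rate`.
#' @export
energies <- function(params, profile, state, t = 0) {
  validate_pendulum_params(params)
  th1 <- state$theta1; th2 <- state$theta2
  dth1 <- state$dtheta1; dth2 <- state$dtheta2
  dth21 <- dth2 - dth1
  # T = 1/2 (m1 r1^2 + I1) th1'^2 + 1/2 I2 th21'^2
  #   + 1/2 m2 (l1^2 th1'^2 + r2^2 th21'^2 - 2 l1 r2 th1' th21' cos th2)
  kin <- 0.5 * ((params$m1 * params$r1^2 + params$I1) * dth1^2 +
                  params$I2 * dth21^2 +
                  params$m2 * (params$l1^2 * dth1^2 + params$r2^2 * dth21^2 -
                                 2 * params$l1 * params$r2 * dth1 * dth21 *
                                 cos(th2)))
  pot <- params$m1 * params$g * params$r1 * cos(th1) +
    params$m2 * params$g * (params$l1 * cos(th1) +
                              params$r2 * cos(th2 - th1)) +
    0.5 * (profile$k1(t) * th1^2 + profile$k2(t) * th2^2)
  diss <- profile$b1(t) * dth1^2 + profile$b2(t) * dth2^2
  tibble::tibble(kinetic = kin, potential = pot, dissipation_rate = diss)
}
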