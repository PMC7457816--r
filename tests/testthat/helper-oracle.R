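# Independent Euler-Lagrange oracle.
#
# Everything here is derived symbolically (via R's D()) from the segment COM
# *positions* and the energy functions only -- never from the closed-form
# mass/Coriolis/gravity expressions the package implements -- so agreement is
# a genuine cross-derivation check, exact to machine precision.

local({
  x1 <- quote(-r1 * sin(th1))
  y1 <- quote(r1 * cos(th1))
  x2 <- quote(-l1 * sin(th1) + r2 * sin(th2 - th1))
  y2 <- quote(l1 * cos(th1) + r2 * cos(th2 - th1))
  vel <- function(e) {
    call("+", call("*", D(e, "th1"), quote(dth1)),
         call("*", D(e, "th2"), quote(dth2)))
  }
  sq <- function(e) call("^", call("(", e), 2)
  Texpr <- bquote(
    0.5 * m1 * (.(sq(vel(x1))) + .(sq(vel(y1)))) + 0.5 * I1 * dth1^2 +
      0.5 * m2 * (.(sq(vel(x2))) + .(sq(vel(y2)))) +
      0.5 * I2 * (dth2 - dth1)^2
  )
  Vgrav <- bquote(m1 * g * .(y1) + m2 * g * .(y2))
  Vexpr <- bquote(.(Vgrav) + 0.5 * (k1 * th1^2 + k2 * th2^2))
  Fexpr <- quote(0.5 * (b1 * dth1^2 + 0.5 * 0))  # placeholder, rebuilt below
  Fexpr <- quote(0.5 * b1 * dth1^2 + 0.5 * b2 * dth2^2)

  qn <- c("th1", "th2")
  vn <- c("dth1", "dth2")
  Mij <- matrix(list(), 2, 2)
  Aij <- matrix(list(), 2, 2)  # d2T / (dvel_i dq_j)
  dTdq <- vector("list", 2)
  dVdq <- vector("list", 2)
  dVgdq <- vector("list", 2)
  dFdv <- vector("list", 2)
  for (i in 1:2) {
    dTdvi <- D(Texpr, vn[i])
    for (j in 1:2) {
      Mij[[i, j]] <- D(dTdvi, vn[j])
      Aij[[i, j]] <- D(dTdvi, qn[j])
    }
    dTdq[[i]] <- D(Texpr, qn[i])
    dVdq[[i]] <- D(Vexpr, qn[i])
    dVgdq[[i]] <- D(Vgrav, qn[i])
    dFdv[[i]] <- D(Fexpr, vn[i])
  }

  state_env <- function(params, state, lam = list(k1 = 0, b1 = 0,
                                                  k2 = 0, b2 = 0)) {
    list2env(c(unclass(params), unclass(state)[c("dtheta1", "dtheta2")],
               list(th1 = state$theta1, th2 = state$theta2,
                    dth1 = state$dtheta1, dth2 = state$dtheta2),
               lam))
  }

  # Mass matrix as the velocity Hessian of the kinetic energy.
  oracle_mass_matrix <<- function(params, theta2) {
    env <- state_env(params, balancekf::joint_state(0, theta2))
    matrix(vapply(1:4, function(k) {
      eval(Mij[[(k - 1) %/% 2 + 1, (k - 1) %% 2 + 1]], env)
    }, numeric(1)), 2, 2, byrow = TRUE)
  }

  # Velocity-product (Coriolis/centrifugal) force vector.
  oracle_coriolis_force <<- function(params, state) {
    env <- state_env(params, state)
    qd <- c(state$dtheta1, state$dtheta2)
    vapply(1:2, function(i) {
      sum(vapply(1:2, function(j) eval(Aij[[i, j]], env), numeric(1)) * qd) -
        eval(dTdq[[i]], env)
    }, numeric(1))
  }

  # Gradient of the gravitational potential.
  oracle_gravity <<- function(params, state) {
    env <- state_env(params, state)
    vapply(1:2, function(i) eval(dVgdq[[i]], env), numeric(1))
  }

  # Full Euler-Lagrange accelerations with Kelvin-Voigt joint coefficients
  # lam (numbers, evaluated at the state's instant).
  oracle_accel <<- function(params, state, lam = list(k1 = 0, b1 = 0,
                                                      k2 = 0, b2 = 0)) {
    env <- state_env(params, state, lam)
    M <- matrix(vapply(1:4, function(k) {
      eval(Mij[[(k - 1) %/% 2 + 1, (k - 1) %% 2 + 1]], env)
    }, numeric(1)), 2, 2, byrow = TRUE)
    qd <- c(state$dtheta1, state$dtheta2)
    rhs <- vapply(1:2, function(i) {
      eval(dTdq[[i]], env) -
        sum(vapply(1:2, function(j) eval(Aij[[i, j]], env),
                   numeric(1)) * qd) -
        eval(dVdq[[i]], env) - eval(dFdv[[i]], env)
    }, numeric(1))
    solve(M, rhs)
  }
})

# Random joint states with angles/velocities on physiological scales.
random_states <- function(n, seed = 42, angle = 0.6, vel = 2) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      balancekf::joint_state(
        stats::runif(1, -angle, angle), stats::runif(1, -angle, angle),
        stats::runif(1, -vel, vel), stats::runif(1, -vel, vel)
      )
    })
  })
}

table3_params <- function() {
  balancekf::pendulum_params(m1 = 0.25, m2 = 0.20, l1 = 0.53,
                             r1 = 0.27, r2 = 0.23)
}
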