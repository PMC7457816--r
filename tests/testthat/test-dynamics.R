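# Equations of motion and the fixed-step integrator.

test_that("lumped coefficients match independent arithmetic for the bench rig", {
  p <- table3_params()
  co <- lumped_coefficients(p)
  # frozen hand evaluation: I1 = 0.25*0.53^2/12, I2 = 0.20*0.46^2/12 (rod
  # defaults), then the five aggregates
  expect_equal(p$I1, 0.005852083333, tolerance = 1e-9)
  expect_equal(p$I2, 0.003526666667, tolerance = 1e-9)
  expect_equal(co$alpha, 0.09436375, tolerance = 1e-9)
  expect_equal(co$beta, 0.024380, tolerance = 1e-9)
  expect_equal(co$gamma, 0.014106666667, tolerance = 1e-9)
  expect_equal(co$delta, 0.17350, tolerance = 1e-9)
  expect_equal(co$epsilon, 0.04600, tolerance = 1e-9)
})

test_that("vanishing trunk mass degenerates the coefficients correctly", {
  p <- pendulum_params(m1 = 2, m2 = 0, l1 = 0.9, r1 = 0.5, r2 = 0.3,
                       I1 = 0.1, I2 = 0.05)
  co <- lumped_coefficients(p)
  expect_equal(co$beta, 0)
  expect_equal(co$epsilon, 0)
  expect_equal(co$gamma, p$I2)           # gamma - I2 = 0
  expect_equal(co$alpha, p$I1 + p$I2 + 2 * 0.5^2)
})

test_that("coefficients are linear in the masses", {
  c1 <- lumped_coefficients(subject_params(70, 1.7))
  c2 <- lumped_coefficients(subject_params(210, 1.7))
  for (f in c("alpha", "beta", "gamma", "delta", "epsilon")) {
    expect_equal(c2[[f]], 3 * c1[[f]], tolerance = 1e-12)
  }
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(pendulum_params(-1, 1, 1, 0.5, 0.3), "positive")
  expect_error(pendulum_params(1, 1, 0.5, 0.6, 0.3), "r1")
  expect_error(pendulum_params(1, 1, 1, 0.5, 0.3, I1 = -1), "inertia")
  expect_error(subject_params(85, 1.7, f_m1 = 1.2), "fraction")
})

test_that("mass matrix matches its closed special cases and the energy Hessian", {
  p <- subject_params(85, 1.7)
  co <- lumped_coefficients(p)
  M <- mass_matrix(co, pi / 2)
  expect_equal(M, matrix(c(co$alpha, -co$gamma, -co$gamma, co$gamma), 2, 2))
  expect_equal(mass_matrix(co, 0)[1, 1], co$alpha + 2 * co$beta)
  for (th2 in seq(-pi / 2, pi / 2, length.out = 9)) {
    M <- mass_matrix(co, th2)
    expect_equal(M, t(M))
    expect_equal(M, oracle_mass_matrix(p, th2), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  }
  # the bench rig's mass matrix is positive definite over the workspace too
  cot <- lumped_coefficients(table3_params())
  for (th2 in seq(-pi / 2, pi / 2, length.out = 9)) {
    expect_gt(min(eigen(mass_matrix(cot, th2), symmetric = TRUE)$values), 0)
  }
})

test_that("Coriolis matrix vanishes when it must and matches the oracle", {
  p <- subject_params(70, 1.75)
  co <- lumped_coefficients(p)
  expect_equal(coriolis_matrix(co, joint_state(0.3, 0.2)), matrix(0, 2, 2))
  expect_equal(coriolis_matrix(co, joint_state(0.3, 0, 1, 2)),
               matrix(0, 2, 2))
  expect_equal(coriolis_matrix(co, joint_state(0, 0.5, 1, 2))[2, 2], 0)
  for (s in random_states(25, seed = 7)) {
    qd <- c(s$dtheta1, s$dtheta2)
    expect_equal(drop(coriolis_matrix(co, s) %*% qd),
                 oracle_coriolis_force(p, s), tolerance = 1e-10)
  }
})

test_that("gravity vector is the potential gradient and vanishes upright", {
  p <- subject_params(60, 1.6)
  co <- lumped_coefficients(p)
  expect_equal(gravity_vector(co, joint_state()), c(0, 0))
  expect_equal(gravity_vector(co, joint_state(0.3, -0.2), g = 0), c(0, 0))
  for (s in random_states(25, seed = 11)) {
    expect_equal(gravity_vector(co, s), oracle_gravity(p, s),
                 tolerance = 1e-10)
  }
})

test_that("Kelvin-Voigt torque has the right values and signs", {
  prof <- viscoelastic_profile(10, 0, 0, 0)
  expect_equal(joint_torque(prof, joint_state(), 0), c(0, 0))
  expect_equal(joint_torque(prof, joint_state(0.1, 0), 0), c(-1, 0))
  neg <- viscoelastic_profile(-10, 0, 0, 0)
  expect_gt(joint_torque(neg, joint_state(0.1, 0), 0)[1], 0)
})

test_that("forward dynamics agrees with the Euler-Lagrange oracle", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(900, 25, 400, 15)
  lam <- list(k1 = 900, b1 = 25, k2 = 400, b2 = 15)
  expect_equal(
    forward_dynamics(p, viscoelastic_profile(), joint_state(), 0), c(0, 0))
  for (s in random_states(200, seed = 3)) {
    a <- forward_dynamics(p, prof, s, 0)
    b <- oracle_accel(p, s, lam)
    expect_lt(max(abs(a - b)) / max(abs(b), 1), 1e-10)
  }
})

test_that("forward dynamics reports a singular mass matrix", {
  # a (near) massless inertia-free leg makes the kinetic metric degenerate
  # when the trunk folds back onto the leg (theta2 = pi)
  p <- pendulum_params(m1 = 1e-9, m2 = 1, l1 = 1, r1 = 1e-3, r2 = 0.5,
                       I1 = 0, I2 = 0)
  expect_error(forward_dynamics(p, viscoelastic_profile(),
                                joint_state(0.1, pi)), "singular")
})

test_that("large stiffness with damping makes upright locally attracting", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(3000, 100, 2000, 80)
  tr <- simulate_pendulum(p, prof, joint_state(0.02, -0.03), 5, dt = 0.005)
  n <- nrow(tr)
  expect_lt(abs(tr$theta1[n]), 0.02 * 0.2)
  expect_lt(abs(tr$theta2[n]), 0.03 * 0.2)
})

test_that("undamped energy is conserved and damped power balances", {
  p <- subject_params(85, 1.7)
  # no damping, constant stiffness: T + V conserved
  prof <- viscoelastic_profile(1500, 0, 900, 0)
  tr <- simulate_pendulum(p, prof, joint_state(-0.1, 0.22), 3, dt = 1e-3)
  E <- vapply(seq_len(nrow(tr)), function(i) {
    e <- energies(p, prof, joint_state(tr$theta1[i], tr$theta2[i],
                                       tr$dtheta1[i], tr$dtheta2[i]),
                  tr$time[i])
    e$kinetic + e$potential
  }, numeric(1))
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-6)

  # with damping: d(T+V)/dt = -(b1 dth1^2 + b2 dth2^2)
  prof2 <- viscoelastic_profile(1500, 40, 900, 25)
  tr2 <- simulate_pendulum(p, prof2, joint_state(-0.1, 0.22), 3, dt = 1e-3)
  idx <- seq_len(nrow(tr2))
  E2 <- vapply(idx, function(i) {
    e <- energies(p, prof2, joint_state(tr2$theta1[i], tr2$theta2[i],
                                        tr2$dtheta1[i], tr2$dtheta2[i]),
                  tr2$time[i])
    e$kinetic + e$potential
  }, numeric(1))
  D2 <- vapply(idx, function(i) {
    energies(p, prof2, joint_state(tr2$theta1[i], tr2$theta2[i],
                                   tr2$dtheta1[i], tr2$dtheta2[i]),
             tr2$time[i])$dissipation_rate
  }, numeric(1))
  dEdt <- central_difference(E2, 1e-3, 1)
  inner <- 2:(length(E2) - 1L)
  imbalance <- dEdt[inner] + D2[inner]
  expect_lt(sqrt(mean(imbalance^2)) / max(D2), 1e-4)
})

test_that("free rotation without gravity conserves kinetic energy", {
  p <- pendulum_params(m1 = 1, m2 = 0.8, l1 = 0.6, r1 = 0.3, r2 = 0.25,
                       g = 0)
  prof <- viscoelastic_profile()
  tr <- simulate_pendulum(p, prof, joint_state(0, 0, 1.2, -0.7), 3,
                          dt = 1e-3)
  Tk <- vapply(seq_len(nrow(tr)), function(i) {
    energies(p, prof, joint_state(tr$theta1[i], tr$theta2[i],
                                  tr$dtheta1[i], tr$dtheta2[i]))$kinetic
  }, numeric(1))
  expect_lt(max(abs(Tk - Tk[1])) / Tk[1], 1e-6)
})

test_that("the integrator shows fourth-order step-size convergence", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1200, 30, 600, 20)
  s0 <- joint_state(-0.1, 0.22)
  ref <- simulate_pendulum(p, prof, s0, 1, dt = 1e-4)
  fin <- function(dt) {
    tr <- simulate_pendulum(p, prof, s0, 1, dt = dt)
    unlist(tr[nrow(tr), c("theta1", "theta2", "dtheta1", "dtheta2")])
  }
  refv <- unlist(ref[nrow(ref), c("theta1", "theta2", "dtheta1", "dtheta2")])
  e1 <- max(abs(fin(0.02) - refv))
  e2 <- max(abs(fin(0.01) - refv))
  expect_gt(e1 / e2, 12)   # ~16 for exact 4th order
})

test_that("the trajectory matches an independent adaptive integrator", {
  skip_if_not_installed("deSolve")
  p <- subject_params(85, 1.7)
  co <- lumped_coefficients(p)
  prof <- viscoelastic_profile(1200, 30, 600, 20)
  tr <- simulate_pendulum(p, prof, joint_state(-0.1, 0.22), 3, dt = 1e-3)
  rhs <- function(t, y, parms) {
    s <- joint_state(y[1], y[2], y[3], y[4])
    list(c(y[3], y[4], forward_dynamics(p, prof, s, t)))
  }
  sol <- deSolve::ode(c(-0.1, 0.22, 0, 0), times = seq(0, 3, by = 0.1),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  idx <- match(round(sol[, 1], 6), round(tr$time, 6))
  expect_lt(max(abs(sol[, 2] - tr$theta1[idx])), 1e-7)
  expect_lt(max(abs(sol[, 3] - tr$theta2[idx])), 1e-7)
})

test_that("reference-subject trial stays bounded and converges toward upright", {
  p <- subject_params(85, 1.7)
  tr <- simulate_pendulum(p, reference_profile(), joint_state(-0.10, 0.22),
                          30, dt = 0.01)
  expect_equal(nrow(tr), 3001L)
  expect_true(all(abs(tr$theta1) < 0.5) && all(abs(tr$theta2) < 0.5))
  n <- nrow(tr)
  expect_lt(abs(tr$theta1[n]), 0.01)
  expect_lt(abs(tr$theta2[n]), 0.01)
})

test_that("doubling masses preserves trajectories only if k and b double too", {
  s0 <- joint_state(-0.08, 0.15)
  p1 <- subject_params(70, 1.7)
  p2 <- subject_params(140, 1.7)
  prof1 <- viscoelastic_profile(1000, 30, 500, 20)
  prof2 <- viscoelastic_profile(2000, 60, 1000, 40)
  a <- simulate_pendulum(p1, prof1, s0, 3, dt = 0.01)
  b <- simulate_pendulum(p2, prof2, s0, 3, dt = 0.01)
  expect_equal(b$theta1, a$theta1, tolerance = 1e-12)
  expect_equal(b$theta2, a$theta2, tolerance = 1e-12)
  c <- simulate_pendulum(p2, prof1, s0, 3, dt = 0.01)
  expect_gt(max(abs(c$theta1 - a$theta1)), 1e-3)
})

test_that("divergence is reported with the time of failure", {
  # inverted pendulum with zero stiffness falls; past the horizontal the
  # unactuated model keeps accelerating and the state explodes
  p <- subject_params(85, 1.7)
  expect_error(
    simulate_pendulum(p, viscoelastic_profile(k1 = -5e5, b1 = -1e4),
                      joint_state(0.3, 0.1), 10, dt = 0.05),
    "diverged at t"
  )
})

test_that("energies at rest and upright take their closed-form values", {
  p <- subject_params(85, 1.7)
  prof <- viscoelastic_profile(1050, 30, 500, 20)
  e <- energies(p, prof, joint_state())
  expect_equal(e$kinetic, 0)
  expect_equal(e$dissipation_rate, 0)
  expect_equal(e$potential,
               p$m1 * p$g * p$r1 + p$m2 * p$g * (p$l1 + p$r2))
})
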