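#' Inertial and geometric parameters of the two-link balance model
#'
#' The sagittal-plane model has two rigid segments: segment 1 (the legs)
#' rotating about the ankle, and segment 2 (trunk, head and arms) rotating
#' about the hip. `pendulum_params()` collects the constants that enter the
#' equations of motion.
#'
#' Segment inertias default to the uniform-rod value about the segment's own
#' centre of mass, `I = m * L^2 / 12`, with `L1 = l1` and `L2 = 2 * r2` unless
#' overridden. All inertias are interpreted about each segment's own COM; the
#' parallel-axis contributions appear explicitly in the lumped coefficients.
#'
#' @param m1,m2 Segment masses (kg).
#' @param l1 Ankle-to-hip distance (m).
#' @param r1 Ankle-to-COM distance of segment 1 (m); must satisfy `r1 <= l1`.
#' @param r2 Hip-to-COM distance of segment 2 (m).
#' @param I1,I2 Segment moments of inertia about their own COM (kg m^2).
#'   `NULL` means the uniform-rod default.
#' @param g Gravitational acceleration (m/s^2).
#' @param L1,L2 Segment lengths used only for the rod-inertia defaults (m).
#' @return An object of class `pendulum_params` (a named list).
#' @examples
#' pendulum_params(m1 = 0.25, m2 = 0.20, l1 = 0.53, r1 = 0.27, r2 = 0.23)
#' @export
pendulum_params <- function(m1, m2, l1, r1, r2,
                            I1 = NULL, I2 = NULL, g = 9.81,
                            L1 = l1, L2 = 2 * r2) {
  if (is.null(I1)) I1 <- m1 * L1^2 / 12
  if (is.null(I2)) I2 <- m2 * L2^2 / 12
  p <- list(m1 = m1, m2 = m2, l1 = l1, r1 = r1, r2 = r2,
            I1 = I1, I2 = I2, g = g)
  validate_pendulum_params(p)
  structure(p, class = "pendulum_params")
}

validate_pendulum_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("m1", "m2", "l1", "r1", "r2", "I1", "I2", "g")) {
    if (!num1(p[[f]])) {
      stop("pendulum parameter '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$m1 <= 0 || p$l1 <= 0 || p$r1 <= 0 || p$r2 <= 0) {
    stop("masses and lengths must be strictly positive (m2 = 0 is allowed ",
         "only as a degenerate limit)", call. = FALSE)
  }
  if (p$m2 < 0) stop("m2 must be non-negative", call. = FALSE)
  if (p$r1 > p$l1 + 1e-12) {
    stop("r1 (ankle-to-COM distance) cannot exceed l1 (segment length)",
         call. = FALSE)
  }
  if (p$I1 < 0 || p$I2 < 0) stop("inertias must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.pendulum_params <- function(x, ...) {
  cat("<pendulum_params>\n")
  cat(sprintf("  m1 = %.4g kg, m2 = %.4g kg\n", x$m1, x$m2))
  cat(sprintf("  l1 = %.4g m, r1 = %.4g m, r2 = %.4g m\n", x$l1, x$r1, x$r2))
  cat(sprintf("  I1 = %.4g, I2 = %.4g kg m^2, g = %.4g m/s^2\n",
              x$I1, x$I2, x$g))
  invisible(x)
}

#' Lumped coefficients of the equations of motion
#'
#' Aggregates the inertial parameters into the five constants that appear in
#' the mass matrix, Coriolis matrix and gravity vector:
#' \deqn{\alpha = I_1 + I_2 + m_1 r_1^2 + m_2 (l_1^2 + r_2^2), \quad
#'       \beta = m_2 l_1 r_2, \quad \gamma = I_2 + m_2 r_2^2,}
#' \deqn{\delta = m_1 r_1 + m_2 l_1, \quad \epsilon = m_2 r_2.}
#'
#' @param p A [pendulum_params()] object.
#' @return An object of class `lumped_coefficients` with fields
#'   `alpha`, `beta`, `gamma`, `delta`, `epsilon` and `g`.
#' @export
lumped_coefficients <- function(p) {
  validate_pendulum_params(p)
  structure(
    list(
      alpha   = p$I1 + p$I2 + p$m1 * p$r1^2 + p$m2 * (p$l1^2 + p$r2^2),
      beta    = p$m2 * p$l1 * p$r2,
      gamma   = p$I2 + p$m2 * p$r2^2,
      delta   = p$m1 * p$r1 + p$m2 * p$l1,
      epsilon = p$m2 * p$r2,
      g       = p$g
    ),
    class = "lumped_coefficients"
  )
}

#' @export
print.lumped_coefficients <- function(x, ...) {
  cat("<lumped_coefficients>\n")
  cat(sprintf("  alpha = %.6g, beta = %.6g, gamma = %.6g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  delta = %.6g, epsilon = %.6g (g = %.4g)\n",
              x$delta, x$epsilon, x$g))
  invisible(x)
}

#' Joint state of the two-link model
#'
#' Generalized coordinates are `theta1` (leg inclination from vertical) and
#' `theta2` (the generalized hip coordinate). The trunk inclination from
#' vertical is the derived quantity `theta21 = theta2 - theta1` and is never
#' stored independently.
#'
#' @param theta1,theta2 Joint angles (rad).
#' @param dtheta1,dtheta2 Angular velocities (rad/s).
#' @return A named list of class `joint_state`.
#' @export
joint_state <- function(theta1 = 0, theta2 = 0, dtheta1 = 0, dtheta2 = 0) {
  s <- list(theta1 = theta1, theta2 = theta2,
            dtheta1 = dtheta1, dtheta2 = dtheta2)
  if (!all(vapply(s, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1)))) {
    stop("joint state components must be single finite numbers", call. = FALSE)
  }
  structure(s, class = "joint_state")
}

#' Anthropometric subject specification
#'
#' Builds a [pendulum_params()] object for a simulated standing human from
#' total body mass and height using standard anthropometric fractions:
#' `m1 = 0.322 m`, `m2 = 0.678 m`, `l1 = 0.53 H`, `r1 = 0.29 H`,
#' `r2 = 0.18 H`. Each fraction can be overridden. Segment inertias use the
#' uniform-rod default with segment lengths `l1` and `H - l1`.
#'
#' @param mass Total body mass (kg).
#' @param height Total height (m).
#' @param f_m1,f_m2 Mass fractions of the leg and trunk segments; must sum
#'   to 1 so that `m1 + m2 = mass` exactly.
#' @param f_l1,f_r1,f_r2 Length fractions of `l1`, `r1` and `r2`.
#' @param g Gravitational acceleration (m/s^2).
#' @return A `pendulum_params` object.
#' @examples
#' subject_params(mass = 85, height = 1.7)
#' @export
subject_params <- function(mass, height,
                           f_m1 = 0.322, f_m2 = 1 - f_m1,
                           f_l1 = 0.53, f_r1 = 0.29, f_r2 = 0.18,
                           g = 9.81) {
  if (mass <= 0 || height <= 0) {
    stop("mass and height must be positive", call. = FALSE)
  }
  fr <- c(f_m1 = f_m1, f_m2 = f_m2, f_l1 = f_l1, f_r1 = f_r1, f_r2 = f_r2)
  if (any(fr <= 0 | fr >= 1)) {
    stop("anthropometric fractions must lie in (0, 1)", call. = FALSE)
  }
  l1 <- f_l1 * height
  pendulum_params(
    m1 = f_m1 * mass, m2 = f_m2 * mass,
    l1 = l1, r1 = f_r1 * height, r2 = f_r2 * height,
    g = g, L1 = l1, L2 = height - l1
  )
}
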