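# Marker-to-angle conversion, zero-phase filtering, numerical derivatives.

#' Convert sagittal marker positions to model joint angles
#'
#' Markers sit on the ankle, the hip and a torso point. The leg inclination
#' `theta1` is measured from vertical with positive angles moving the leg COM
#' in the -x direction; the trunk inclination from vertical `theta21` uses
#' the opposite (+x) sign, and the generalized hip coordinate is
#' `theta2 = theta1 + theta21`. Irregular timestamps are resampled to a
#' uniform grid by linear interpolation.
#'
#' @param markers Data frame with columns `time`, `ankle_x`, `ankle_y`,
#'   `hip_x`, `hip_y`, `torso_x`, `torso_y` (seconds and metres).
#' @param interpolation Resampling method for irregular time stamps
#'   (currently only `"linear"`).
#' @return A `pend_trajectory` with angle channels only.
#' @export
angles_from_markers <- function(markers, interpolation = "linear") {
  interpolation <- match.arg(interpolation)
  need <- c("time", "ankle_x", "ankle_y", "hip_x", "hip_y",
            "torso_x", "torso_y")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0) {
    stop("marker data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(markers) < 2L) stop("need at least two marker frames",
                               call. = FALSE)
  leg_x <- markers$hip_x - markers$ankle_x
  leg_y <- markers$hip_y - markers$ankle_y
  trunk_x <- markers$torso_x - markers$hip_x
  trunk_y <- markers$torso_y - markers$hip_y
  if (any(leg_x^2 + leg_y^2 < 1e-12) || any(trunk_x^2 + trunk_y^2 < 1e-12)) {
    stop("coincident markers: segment length is numerically zero",
         call. = FALSE)
  }
  theta1 <- atan2(-leg_x, leg_y)
  theta21 <- atan2(trunk_x, trunk_y)
  theta2 <- theta1 + theta21
  t <- markers$time
  dts <- diff(t)
  if (any(dts <= 0)) stop("marker time stamps must be strictly increasing",
                          call. = FALSE)
  dt <- mean(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    grid <- seq(t[1], t[length(t)], by = dt)
    theta1 <- stats::approx(t, theta1, xout = grid)$y
    theta2 <- stats::approx(t, theta2, xout = grid)$y
    t <- grid
  }
  as_trajectory(
    tibble::tibble(time = t, theta1 = theta1, theta2 = theta2),
    meta = list(source = "markers", interpolation = interpolation)
  )
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` low-pass Butterworth filter forward and backward
#' (via [signal::filtfilt()]), cancelling the phase response; the effective
#' magnitude response is the squared one-pass response.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cut-off frequency (Hz); must be below the Nyquist frequency
#'   `fs / 2`. For low-rate data a cutoff of about `0.4 * fs` is a sensible
#'   upper bound.
#' @param order Filter order of the one-pass design (default 4).
#' @return The filtered series.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff = 30, order = 4) {
  if (!is.numeric(x) || length(x) < 3 * (order + 1)) {
    stop("series too short to filter at order ", order, call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop(sprintf(
      paste0("cutoff (%.3g Hz) must lie strictly below the Nyquist ",
             "frequency (%.3g Hz); for low-rate data use about 0.4 * fs"),
      cutoff, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  # odd-reflection padding keeps the forward-backward transients out of the
  # data window (endpoint-matched, as in standard zero-phase pipelines)
  n <- length(x)
  pad <- min(n - 1L, max(12L * order, ceiling(10 * fs / cutoff)))
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  as.numeric(y[seq(pad + 1L, pad + n)])
}

#' Central-difference derivatives on a uniform grid
#'
#' First (`order = 1`) or second (`order = 2`) derivative by symmetric
#' second-order stencils at interior points; endpoints use one-sided stencils
#' of matching accuracy (first-order fallback for very short series). The
#' symmetric stencil introduces no phase shift. The returned vector carries
#' an attribute `endpoints = "one-sided"` flagging the boundary treatment.
#'
#' @param x Numeric series (at least 3 samples).
#' @param dt Sampling interval (s).
#' @param order Derivative order, 1 or 2.
#' @return Numeric vector of the same length as `x`.
#' @export
central_difference <- function(x, dt, order = 1) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for central differences",
                   call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!order %in% c(1, 2)) stop("order must be 1 or 2", call. = FALSE)
  d <- numeric(n)
  i <- 2:(n - 1L)
  if (order == 1) {
    d[i] <- (x[i + 1L] - x[i - 1L]) / (2 * dt)
    d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
    d[n] <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / (2 * dt)
  } else {
    d[i] <- (x[i + 1L] - 2 * x[i] + x[i - 1L]) / dt^2
    if (n >= 4L) {
      d[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
      d[n] <- (2 * x[n] - 5 * x[n - 1L] + 4 * x[n - 2L] - x[n - 3L]) / dt^2
    } else {
      d[1] <- d[n] <- d[2]
    }
  }
  attr(d, "endpoints") <- "one-sided"
  d
}

#' Filter a noisy trajectory and fill velocities and accelerations
#'
#' The standard measurement pipeline: zero-phase low-pass filtering of each
#' angle channel followed by central-difference differentiation (first and
#' second derivatives), avoiding any phase shift between angles and their
#' derivatives.
#'
#' @param traj A `pend_trajectory` (angles required; any existing derivative
#'   columns are recomputed).
#' @param cutoff,order Filter settings passed to [lowpass_zero_phase()];
#'   set `cutoff = NULL` to skip filtering and only differentiate.
#' @return A `pend_trajectory` with `theta*` filtered and `dtheta*`,
#'   `ddtheta*` filled; metadata records the filter specification.
#' @export
preprocess_trajectory <- function(traj, cutoff = 30, order = 4) {
  stopifnot(inherits(traj, "pend_trajectory"))
  dt <- trajectory_dt(traj)
  fs <- 1 / dt
  th1 <- traj$theta1
  th2 <- traj$theta2
  if (!is.null(cutoff)) {
    th1 <- lowpass_zero_phase(th1, fs, cutoff, order)
    th2 <- lowpass_zero_phase(th2, fs, cutoff, order)
  }
  out <- tibble::tibble(
    time = traj$time,
    theta1 = th1, theta2 = th2,
    dtheta1 = as.numeric(central_difference(th1, dt, 1)),
    dtheta2 = as.numeric(central_difference(th2, dt, 1)),
    ddtheta1 = as.numeric(central_difference(th1, dt, 2)),
    ddtheta2 = as.numeric(central_difference(th2, dt, 2))
  )
  meta <- utils::modifyList(
    trajectory_meta(traj),
    list(filter = list(cutoff = cutoff, order = order,
                       type = "butterworth-zero-phase"),
         derivative_endpoints = "one-sided")
  )
  as_trajectory(out, meta = meta)
}
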