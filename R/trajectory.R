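#' Construct a joint-angle trajectory
#'
#' A trajectory is a tibble with a strictly increasing, uniformly spaced
#' `time` column, angle columns `theta1`, `theta2` (rad) and optionally
#' velocity (`dtheta1`, `dtheta2`) and acceleration (`ddtheta1`, `ddtheta2`)
#' columns, plus sampling and provenance metadata carried in attributes.
#' Velocities and accelerations may be absent until preprocessing fills them.
#'
#' @param data A data frame with at least `time`, `theta1`, `theta2`.
#' @param meta Named list of provenance fields (e.g. `source`, `seed`,
#'   `subject`).
#' @return A tibble of class `pend_trajectory` with attributes `dt` and
#'   `meta`.
#' @export
as_trajectory <- function(data, meta = list()) {
  data <- tibble::as_tibble(data)
  need <- c("time", "theta1", "theta2")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  t <- data$time
  if (length(t) < 2L) stop("a trajectory needs at least two samples",
                           call. = FALSE)
  dts <- diff(t)
  if (any(dts <= 0)) stop("trajectory time must be strictly increasing",
                          call. = FALSE)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * max(dt, 1e-12)) {
    stop("trajectory time grid must be uniform; resample first",
         call. = FALSE)
  }
  num_cols <- intersect(
    c("time", "theta1", "theta2", "dtheta1", "dtheta2",
      "ddtheta1", "ddtheta2"),
    names(data)
  )
  for (cn in num_cols) {
    if (!is.numeric(data[[cn]])) {
      stop("trajectory column '", cn, "' must be numeric", call. = FALSE)
    }
  }
  structure(data, dt = dt, meta = meta,
            class = c("pend_trajectory", class(data)))
}

#' Sampling interval of a trajectory
#' @param traj A `pend_trajectory`.
#' @return The sampling interval in seconds.
#' @export
trajectory_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- stats::median(diff(traj$time))
  dt
}

#' Trajectory provenance metadata
#' @param traj A `pend_trajectory`.
#' @return The metadata list (possibly empty).
#' @export
trajectory_meta <- function(traj) {
  meta <- attr(traj, "meta")
  if (is.null(meta)) list() else meta
}

has_derivatives <- function(traj, accel = TRUE) {
  need <- c("dtheta1", "dtheta2", if (accel) c("ddtheta1", "ddtheta2"))
  all(need %in% names(traj)) &&
    all(vapply(need, function(cn) !anyNA(traj[[cn]]), logical(1)))
}

#' @export
print.pend_trajectory <- function(x, ...) {
  meta <- trajectory_meta(x)
  src <- if (is.null(meta$source)) "unknown" else meta$source
  cat(sprintf("<pend_trajectory> %d samples, dt = %.4g s, source: %s\n",
              nrow(x), trajectory_dt(x), src))
  NextMethod()
}
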