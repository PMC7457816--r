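# broom-style tidiers and ggplot2 methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a least-squares parameter fit
#'
#' @param x An `lsm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @method tidy lsm_fit
#' @export
tidy.lsm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$lambda_hat),
                 estimate = unname(x$lambda_hat))
}

#' @rdname tidy.lsm_fit
#' @method glance lsm_fit
#' @export
glance.lsm_fit <- function(x, ...) {
  dplyr::bind_cols(residual_metrics(x$residuals),
                   tibble::tibble(n_samples = x$n))
}

#' Tidy a Kalman-filter run
#'
#' @param x A `kf_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `term`, `estimate`,
#'   `variance` (the corresponding diagonal entry of the estimation
#'   covariance).
#' @method tidy kf_fit
#' @export
tidy.kf_fit <- function(x, ...) {
  est <- tidyr::pivot_longer(
    x$estimates[c("time", "k1", "b1", "k2", "b2")],
    -"time", names_to = "term", values_to = "estimate"
  )
  v <- x$estimates[c("time", "P_k1", "P_b1", "P_k2", "P_b2")]
  names(v) <- c("time", "k1", "b1", "k2", "b2")
  var <- tidyr::pivot_longer(v, -"time", names_to = "term",
                             values_to = "variance")
  dplyr::left_join(est, var, by = c("time", "term"))
}

#' @rdname tidy.kf_fit
#' @method glance kf_fit
#' @export
glance.kf_fit <- function(x, ...) {
  fin <- x$estimates[nrow(x$estimates), c("k1", "b1", "k2", "b2")]
  dplyr::bind_cols(
    stats::setNames(fin, paste0(names(fin), "_final")),
    residual_metrics(x$residuals),
    tibble::tibble(n_steps = nrow(x$estimates))
  )
}

#' Plot a trajectory
#'
#' Joint angles (and, when present, angular velocities) against time.
#'
#' @param object A `pend_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pend_trajectory
#' @export
autoplot.pend_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time", "theta1", "theta2")],
    -"time", names_to = "channel", values_to = "angle"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$angle,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (rad)", colour = NULL)
}

#' Plot a Kalman-filter parameter track
#'
#' One panel per parameter; if a ground-truth tibble is supplied it is
#' overlaid as a dashed line.
#'
#' @param object A `kf_fit`.
#' @param truth Optional tibble `time`, `k1`, `b1`, `k2`, `b2`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kf_fit
#' @export
autoplot.kf_fit <- function(object, truth = NULL, ...) {
  est <- tidyr::pivot_longer(
    object$estimates[c("time", "k1", "b1", "k2", "b2")],
    -"time", names_to = "term", values_to = "value"
  )
  p <- ggplot2::ggplot(est, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "estimate")
  if (!is.null(truth)) {
    tr <- tidyr::pivot_longer(truth[c("time", "k1", "b1", "k2", "b2")],
                              -"time", names_to = "term",
                              values_to = "value")
    p <- p + ggplot2::geom_line(data = tr, linetype = "dashed",
                                colour = "grey30")
  }
  p
}

#' Plot the prototype stiffness-versus-angle validation
#'
#' Kalman-filter stiffness estimates from release trials as points against
#' joint angle, with the geometric prediction as a line.
#'
#' @param object A `prototype_kf` from [prototype_kf_stiffness()].
#' @param joint `"ankle"` or `"hip"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prototype_kf
#' @export
autoplot.prototype_kf <- function(object, joint = c("ankle", "hip"), ...) {
  joint <- match.arg(joint)
  if (joint == "ankle") {
    pts <- tibble::tibble(theta = object$track$theta1, k = object$track$k1)
  } else {
    pts <- tibble::tibble(theta = object$track$theta2, k = object$track$k2)
  }
  curve <- predicted_stiffness_curve(object$spec, joint)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$theta, y = .data$k)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = .data$theta, y = .data$stiffness),
      colour = "#2c7fb8", linewidth = 0.8
    ) +
    ggplot2::labs(x = sprintf("%s angle (rad)", joint),
                  y = "stiffness (Nm/rad)")
}

#' Plot a recovery simulation
#'
#' Segment inclinations and the realized switching ankle stiffness.
#'
#' @param object A `recovery_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_sim
#' @export
autoplot.recovery_sim <- function(object, ...) {
  tr <- object$trajectory
  long <- dplyr::bind_rows(
    tibble::tibble(time = tr$time, value = tr$theta1,
                   channel = "theta1 (rad)"),
    tibble::tibble(time = tr$time, value = tr$theta2 - tr$theta1,
                   channel = "theta21 (rad)"),
    tibble::tibble(time = object$stiffness$time,
                   value = object$stiffness$k1,
                   channel = "ankle stiffness (Nm/rad)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
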