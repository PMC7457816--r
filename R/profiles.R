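#' Time-varying visco-elastic joint profile
#'
#' A Kelvin-Voigt joint produces torque `-(k(t) * theta + b(t) * dtheta)`.
#' A profile bundles the four coefficient functions `k1(t)`, `b1(t)`,
#' `k2(t)`, `b2(t)`. Components may be given as constants or as functions of
#' time; evaluation is deterministic and no sign constraint is imposed
#' (negative stiffness is physically meaningful: it injects energy).
#'
#' @param k1,b1 Ankle stiffness (N m/rad) and damping (N m s/rad), each a
#'   number or a `function(t)`.
#' @param k2,b2 Hip stiffness and damping, same conventions.
#' @return An object of class `visco_profile`: a list of four vectorized
#'   functions of time.
#' @examples
#' viscoelastic_profile(k1 = 1050, b1 = 30, k2 = 500, b2 = 20)
#' @export
viscoelastic_profile <- function(k1 = 0, b1 = 0, k2 = 0, b2 = 0) {
  as_tfun <- function(x, name) {
    if (is.function(x)) return(x)
    if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
      force(x)
      return(function(t) rep_len(x, length(t)))
    }
    stop("profile component '", name,
         "' must be a finite number or a function of time", call. = FALSE)
  }
  structure(
    list(k1 = as_tfun(k1, "k1"), b1 = as_tfun(b1, "b1"),
         k2 = as_tfun(k2, "k2"), b2 = as_tfun(b2, "b2")),
    class = "visco_profile"
  )
}

#' Evaluate a visco-elastic profile on a time grid
#'
#' @param profile A [viscoelastic_profile()].
#' @param t Numeric vector of times (s).
#' @return A tibble with columns `time`, `k1`, `b1`, `k2`, `b2`.
#' @export
profile_eval <- function(profile, t) {
  stopifnot(inherits(profile, "visco_profile"))
  tibble::tibble(
    time = t,
    k1 = as.numeric(profile$k1(t)), b1 = as.numeric(profile$b1(t)),
    k2 = as.numeric(profile$k2(t)), b2 = as.numeric(profile$b2(t))
  )
}

#' Sigmoidal stiffness rise
#'
#' Returns the function
#' `k(t) = base * (1 + gain / (1 + exp(-rate * eta * (t - onset))))`,
#' a smooth monotone rise from `base` (as `t -> -Inf`) to `base * (1 + gain)`
#' (as `t -> +Inf`), used to emulate neural stiffness modulation without
#' discontinuities.
#'
#' @param base Resting stiffness (N m/rad).
#' @param gain Relative rise (dimensionless); the plateau is
#'   `base * (1 + gain)`.
#' @param rate Steepness of the rise (1/s).
#' @param eta Dimensionless rate multiplier (rise-velocity condition); larger
#'   `eta` means a faster transition.
#' @param onset Centre time of the transition (s).
#' @return A vectorized `function(t)`.
#' @examples
#' k1 <- sigmoid_stiffness(1050, 0.2, 0.5)
#' k1(5) # 1050 * 1.1 = 1155 at the transition centre
#' @export
sigmoid_stiffness <- function(base, gain, rate, eta = 1, onset = 5) {
  force(base); force(gain); force(rate); force(eta); force(onset)
  function(t) base * (1 + gain / (1 + exp(-rate * eta * (t - onset))))
}

#' Reference simulation profile for a balancing human
#'
#' The stiffness/damping schedule used by the in-silico experiments: ankle
#' stiffness rising sigmoidally from 1050 N m/rad by 20% (rate 0.5/s), hip
#' stiffness rising from 500 N m/rad by 30% (rate 0.8/s), both centred at
#' t = 5 s and scaled by the rise-velocity multiplier `eta`; constant
#' dampings b1 = 30 and b2 = 20 N m s/rad.
#'
#' @param eta Rise-velocity multiplier applied to both sigmoid rates.
#' @return A [viscoelastic_profile()].
#' @export
reference_profile <- function(eta = 1) {
  viscoelastic_profile(
    k1 = sigmoid_stiffness(1050, 0.2, 0.5, eta = eta, onset = 5),
    b1 = 30,
    k2 = sigmoid_stiffness(500, 0.3, 0.8, eta = eta, onset = 5),
    b2 = 20
  )
}
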