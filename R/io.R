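# Plain-text readers/writers: trajectory CSV, parameter key-value files,
# profile CSV. Radians and SI units throughout.

#' Write / read a trajectory CSV
#'
#' The on-disk format is a plain CSV with header
#' `time,theta1,theta2[,dtheta1,dtheta2,ddtheta1,ddtheta2]`, one row per
#' sample, SI units (seconds, radians).
#'
#' @param traj A `pend_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `pend_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pend_trajectory"))
  cols <- intersect(c("time", "theta1", "theta2", "dtheta1", "dtheta2",
                      "ddtheta1", "ddtheta2"), names(traj))
  utils::write.csv(tibble::as_tibble(traj)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  as_trajectory(utils::read.csv(path),
                meta = list(source = "file", path = path))
}

#' Write / read a pendulum parameter file
#'
#' Flat `key = value` text with keys `m1, m2, l1, r1, r2, I1, I2, g`
#' (SI units).
#'
#' @param params A [pendulum_params()].
#' @param path File path.
#' @return `write_params_file()` returns `path` invisibly;
#'   `read_params_file()` returns a `pendulum_params`.
#' @export
write_params_file <- function(params, path) {
  validate_pendulum_params(params)
  keys <- c("m1", "m2", "l1", "r1", "r2", "I1", "I2", "g")
  writeLines(sprintf("%s = %.17g", keys,
                     vapply(keys, function(k) params[[k]], numeric(1))),
             path)
  invisible(path)
}

#' @rdname write_params_file
#' @export
read_params_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2L, logical(1))
  if (any(bad)) {
    stop("malformed parameter line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  vals <- stats::setNames(
    as.numeric(trimws(vapply(kv, `[[`, character(1), 2L))),
    trimws(vapply(kv, `[[`, character(1), 1L))
  )
  need <- c("m1", "m2", "l1", "r1", "r2")
  miss <- setdiff(need, names(vals))
  if (length(miss) > 0) {
    stop("parameter file missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pendulum_params(
    m1 = vals[["m1"]], m2 = vals[["m2"]], l1 = vals[["l1"]],
    r1 = vals[["r1"]], r2 = vals[["r2"]],
    I1 = if ("I1" %in% names(vals)) vals[["I1"]] else NULL,
    I2 = if ("I2" %in% names(vals)) vals[["I2"]] else NULL,
    g = if ("g" %in% names(vals)) vals[["g"]] else 9.81
  )
}

#' Write / read a visco-elastic profile sampled on a time grid
#'
#' CSV with header `time,k1,b1,k2,b2` (ground-truth export format).
#'
#' @param profile_tab A tibble as returned by [profile_eval()].
#' @param path File path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` a tibble.
#' @export
write_profile_csv <- function(profile_tab, path) {
  stopifnot(all(c("time", "k1", "b1", "k2", "b2") %in% names(profile_tab)))
  utils::write.csv(profile_tab[c("time", "k1", "b1", "k2", "b2")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Read marker positions from CSV
#'
#' Header `time,ankle_x,ankle_y,hip_x,hip_y,torso_x,torso_y` (seconds,
#' metres, sagittal plane).
#'
#' @param path File path.
#' @return A tibble suitable for [angles_from_markers()].
#' @export
read_markers_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
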