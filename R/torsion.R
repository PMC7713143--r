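#' Torque-angle curve
#'
#' Validates and normalizes a torsion test recording: equal-length angle and
#' torque channels, at least 10 samples, duplicated angles collapsed so the
#' angle channel is strictly increasing.
#'
#' @param angle_deg Angular displacement, degrees, monotone non-decreasing.
#' @param torque_Nm Torque, Nm.
#' @param sampling_rate_hz Acquisition rate (metadata; default 20).
#' @param angular_rate_deg_min Actuator rate (metadata; default 5).
#' @return A `torsion_curve` data.frame with columns `angle_deg`,
#'   `torque_Nm`.
#' @export
torsion_curve <- function(angle_deg, torque_Nm, sampling_rate_hz = 20,
                          angular_rate_deg_min = 5) {
  if (length(angle_deg) != length(torque_Nm))
    stopf("angle and torque channels differ in length")
  keep <- !duplicated(angle_deg)
  angle_deg <- angle_deg[keep]; torque_Nm <- torque_Nm[keep]
  if (length(angle_deg) < 10L)
    stopf("need at least 10 samples, got %d", length(angle_deg))
  if (any(diff(angle_deg) <= 0))
    stopf("angle must be strictly increasing after deduplication")
  structure(data.frame(angle_deg = angle_deg, torque_Nm = torque_Nm),
            sampling_rate_hz = sampling_rate_hz,
            angular_rate_deg_min = angular_rate_deg_min,
            class = c("torsion_curve", "data.frame"))
}

#' Specify a synthetic torsion curve
#'
#' Piecewise torque-angle model of a torsion-to-failure test: a quadratic
#' toe region whose slope ramps to the elastic stiffness, a linear elastic
#' region up to the yield torque, a shallower post-yield branch up to the
#' failure angle, then an abrupt torque drop that triggers the machine's
#' stop criterion. Sampling follows the actuator and acquisition rates
#' (angle step = angular rate / sampling rate).
#'
#' @param stiffness Elastic slope, Nm/degree (> 0).
#' @param toe_extent Toe region length, degrees (0 = no toe).
#' @param yield_torque Yield torque, Nm.
#' @param post_yield_slope Post-yield slope, Nm/degree.
#' @param failure_angle Angle at failure, degrees.
#' @param failure_drop Torque drop at failure, Nm; the stop criterion is a
#'   3 Nm drop, so drops >= 3 trigger it.
#' @param sampling_rate_hz,angular_rate_deg_min Acquisition metadata.
#' @param noise_sd SD of additive torque noise, Nm.
#' @param seed Integer seed.
#' @return A `torsion_curve_spec` list.
#' @export
torsion_curve_spec <- function(stiffness = 5, toe_extent = 1,
                               yield_torque = 37, post_yield_slope = 0.3,
                               failure_angle = 10, failure_drop = 3,
                               sampling_rate_hz = 20,
                               angular_rate_deg_min = 5,
                               noise_sd = 0, seed = 1L) {
  if (stiffness <= 0) stopf("stiffness must be > 0")
  if (failure_drop <= 0) stopf("failure_drop must be > 0")
  if (toe_extent < 0) stopf("toe_extent must be >= 0")
  yield_angle <- yield_torque / stiffness + toe_extent / 2
  if (failure_angle <= toe_extent)
    stopf("failure_angle (%g deg) lies inside the toe region (%g deg)",
          failure_angle, toe_extent)
  if (yield_angle >= failure_angle)
    stopf("yield angle (%g deg) must precede failure_angle (%g deg)",
          yield_angle, failure_angle)
  structure(list(stiffness = stiffness, toe_extent = toe_extent,
                 yield_torque = yield_torque,
                 post_yield_slope = post_yield_slope,
                 failure_angle = failure_angle, failure_drop = failure_drop,
                 sampling_rate_hz = sampling_rate_hz,
                 angular_rate_deg_min = angular_rate_deg_min,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 yield_angle = yield_angle),
            class = "torsion_curve_spec")
}

# Noiseless piecewise torque at angle theta for a torsion_curve_spec.
piecewise_torque <- function(spec, theta) {
  k <- spec$stiffness; T <- spec$toe_extent
  ty <- spec$yield_torque; k2 <- spec$post_yield_slope
  thy <- spec$yield_angle
  tau <- ifelse(theta <= T & T > 0, k * theta^2 / (2 * max(T, 1e-12)),
                ifelse(theta <= thy, k * (theta - T / 2),
                       ty + k2 * (theta - thy)))
  if (T == 0) tau <- ifelse(theta <= thy, k * theta,
                            ty + k2 * (theta - thy))
  tau
}

#' Generate a synthetic torsion curve with known truth metrics
#'
#' @param spec A [torsion_curve_spec()].
#' @return List with `curve` (a [torsion_curve()], including a few samples
#'   after the failure drop, as recorded before the machine stops) and
#'   `truth` (a `torsion_metrics` with the closed-form stiffness, yield,
#'   ultimate torque, rotation and energy to failure).
#' @export
generate_torsion_curve <- function(spec) {
  stopifnot(inherits(spec, "torsion_curve_spec"))
  dtheta <- spec$angular_rate_deg_min / 60 / spec$sampling_rate_hz
  theta <- seq(0, spec$failure_angle, by = dtheta)
  tau <- piecewise_torque(spec, theta)
  ultimate <- piecewise_torque(spec, spec$failure_angle)
  # post-failure: the drop is recorded over the next samples, then stop
  theta_post <- spec$failure_angle + dtheta * (1:3)
  tau_post <- rep(ultimate - spec$failure_drop, 3)
  theta <- c(theta, theta_post); tau <- c(tau, tau_post)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    tau <- tau + stats::rnorm(length(tau), sd = spec$noise_sd)
  }
  curve <- torsion_curve(theta, tau, spec$sampling_rate_hz,
                         spec$angular_rate_deg_min)
  # closed-form energy up to the failure angle
  k <- spec$stiffness; T <- spec$toe_extent
  e_toe <- if (T > 0) k * T^2 / 6 else 0
  tau_T <- if (T > 0) k * T / 2 else 0
  e_lin <- (tau_T + spec$yield_torque) / 2 * (spec$yield_angle - T)
  e_post <- (spec$yield_torque + ultimate) / 2 *
    (spec$failure_angle - spec$yield_angle)
  truth <- torsion_metrics(stiffness = k,
                           yield_torque = spec$yield_torque,
                           ultimate_torque = ultimate,
                           rotation_to_failure = spec$failure_angle,
                           energy_to_failure = e_toe + e_lin + e_post)
  list(curve = curve, truth = truth)
}

#' Torsion outcome metrics
#'
#' @param stiffness Nm/degree. @param yield_torque Nm.
#' @param ultimate_torque Nm. @param rotation_to_failure degrees.
#' @param energy_to_failure Nm*degree.
#' @param normalized Optional named vector of percent-of-contralateral
#'   values.
#' @param flags Character vector of estimator flags.
#' @return A `torsion_metrics` list.
#' @export
torsion_metrics <- function(stiffness, yield_torque, ultimate_torque,
                            rotation_to_failure, energy_to_failure,
                            normalized = NULL, flags = character()) {
  if (ultimate_torque < yield_torque - 1e-9)
    stopf("ultimate torque (%g) below yield torque (%g)", ultimate_torque,
          yield_torque)
  if (energy_to_failure < 0) stopf("energy must be >= 0")
  if (rotation_to_failure <= 0) stopf("rotation to failure must be > 0")
  structure(list(stiffness = stiffness, yield_torque = yield_torque,
                 ultimate_torque = ultimate_torque,
                 rotation_to_failure = rotation_to_failure,
                 energy_to_failure = energy_to_failure,
                 normalized = normalized, flags = flags),
            class = "torsion_metrics")
}

#' @export
print.torsion_metrics <- function(x, ...) {
  cat(sprintf(paste0("torsion_metrics: stiffness %.3g Nm/deg, yield %.3g Nm, ",
                     "ultimate %.3g Nm,\n  rotation %.3g deg, energy %.4g Nm*deg\n"),
              x$stiffness, x$yield_torque, x$ultimate_torque,
              x$rotation_to_failure, x$energy_to_failure))
  if (!is.null(x$normalized)) {
    cat("  normalized to contralateral [%]:\n")
    print(round(x$normalized, 1))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Detect the torque-drop failure stop
#'
#' First sample at which the running maximum torque exceeds the current
#' torque by at least `drop` (3 Nm by default, the machine's stop
#' criterion).
#'
#' @param curve A [torsion_curve()].
#' @param drop Torque drop threshold, Nm (> 0).
#' @return List: `index` (first sample meeting the criterion, or the last
#'   sample), `detected` (logical).
#' @export
detect_failure <- function(curve, drop = 3) {
  if (drop <= 0) stopf("drop must be > 0")
  deficit <- cummax(curve$torque_Nm) - curve$torque_Nm
  hit <- which(deficit >= drop)
  if (length(hit)) list(index = hit[1], detected = TRUE)
  else list(index = nrow(curve), detected = FALSE)
}

#' Apparent stiffness of the linear loading region
#'
#' Maximum least-squares slope over a window sliding across the pre-ultimate
#' part of the curve; the window covers `window_fraction` of the angle range
#' up to the ultimate torque. Deterministic surrogate for a manually chosen
#' "linear region".
#'
#' @param curve A [torsion_curve()].
#' @param window_fraction Fraction of the pre-ultimate angle range (default
#'   0.2).
#' @return Stiffness in Nm/degree, with attributes `window` (angle bounds of
#'   the best window) and `intercept`.
#' @export
apparent_stiffness <- function(curve, window_fraction = 0.2) {
  th <- curve$angle_deg; tq <- curve$torque_Nm
  i_ult <- which.max(tq)
  wspan <- window_fraction * (th[i_ult] - th[1])
  n <- i_ult
  if (n < 5L) stopf("fewer than 5 pre-ultimate samples")
  # fixed-count sliding window: the number of samples spanning the nominal
  # angular width (floor of 5 so coarse recordings remain analyzable); a
  # fixed count avoids degenerate short windows at the end of the range
  # that would fit noise rather than stiffness
  m <- max(5L, sum(th[1:n] <= th[1] + wspan))
  cx <- cumsum(th[1:n]); cy <- cumsum(tq[1:n])
  cxx <- cumsum(th[1:n]^2); cxy <- cumsum(th[1:n] * tq[1:n])
  best <- -Inf; best_rng <- c(1L, n); best_b <- 0
  for (i in seq_len(n - m + 1L)) {
    j <- i + m - 1L
    sx <- cx[j] - cx[i] + th[i]; sy <- cy[j] - cy[i] + tq[i]
    sxx <- cxx[j] - cxx[i] + th[i]^2
    sxy <- cxy[j] - cxy[i] + th[i] * tq[i]
    denom <- m * sxx - sx^2
    if (denom <= 0) next
    slope <- (m * sxy - sx * sy) / denom
    if (slope > best) {
      best <- slope; best_rng <- c(i, j); best_b <- (sy - slope * sx) / m
    }
  }
  if (!is.finite(best)) stopf("could not fit a linear region")
  structure(best, window = th[best_rng], intercept = best_b)
}

#' Yield point by the offset method
#'
#' The linear fit of the stiffest window is shifted along the angle axis by
#' `offset_angle`; the yield torque is the torque at the first sample beyond
#' the fit window where the measured curve falls below the shifted line. If
#' the curve never deviates the ultimate torque is returned with flag
#' `"no_yield"`. The offset criterion is this package's declared surrogate:
#' torsion protocols rarely publish an exact yield definition.
#'
#' @param curve A [torsion_curve()].
#' @param offset_angle Offset, degrees (default 0.5).
#' @param stiffness Optional precomputed [apparent_stiffness()] result.
#' @return Yield torque (Nm) with attribute `flag` (`"ok"` or
#'   `"no_yield"`).
#' @export
yield_point <- function(curve, offset_angle = 0.5, stiffness = NULL) {
  k <- stiffness %||% apparent_stiffness(curve)
  b <- attr(k, "intercept") %||% 0
  wnd <- attr(k, "window") %||% range(curve$angle_deg)
  th <- curve$angle_deg; tq <- curve$torque_Nm
  i_ult <- which.max(tq)
  line <- as.numeric(k) * (th - offset_angle) + b
  cand <- which(th > wnd[2] & tq < line & seq_along(th) <= i_ult)
  if (!length(cand))
    return(structure(tq[i_ult], flag = "no_yield"))
  structure(tq[cand[1]], flag = "ok")
}

#' Energy to failure
#'
#' Trapezoidal integral of torque over angle up to the failure index (or
#' the end of the curve).
#'
#' @param curve A [torsion_curve()].
#' @param failure_index Sample index of failure; default from
#'   [detect_failure()].
#' @return Energy, Nm*degree.
#' @export
energy_to_failure <- function(curve, failure_index = NULL) {
  i <- failure_index %||% detect_failure(curve)$index
  trapz(curve$angle_deg[1:i], curve$torque_Nm[1:i])
}

#' Extract all torsion metrics from a curve
#'
#' @param curve A [torsion_curve()].
#' @param drop Failure stop criterion, Nm.
#' @param window_fraction Linear-region window fraction.
#' @param offset_angle Yield offset, degrees.
#' @return A [torsion_metrics()] object. Rotation to failure is the angle at
#'   the ultimate (pre-drop peak) torque.
#' @export
analyze_torsion_curve <- function(curve, drop = 3, window_fraction = 0.2,
                                  offset_angle = 0.5) {
  fail <- detect_failure(curve, drop)
  pre <- curve[1:fail$index, , drop = FALSE]
  i_ult <- which.max(pre$torque_Nm)
  k <- apparent_stiffness(curve, window_fraction)
  y <- yield_point(curve, offset_angle, k)
  flags <- character()
  if (!fail$detected) flags <- c(flags, "no_failure_detected")
  if (attr(y, "flag") == "no_yield") flags <- c(flags, "no_yield")
  torsion_metrics(stiffness = as.numeric(k),
                  yield_torque = min(as.numeric(y), pre$torque_Nm[i_ult]),
                  ultimate_torque = pre$torque_Nm[i_ult],
                  rotation_to_failure = pre$angle_deg[i_ult],
                  energy_to_failure = energy_to_failure(curve, fail$index),
                  flags = flags)
}

#' Normalize operated-limb metrics to the contralateral limb
#'
#' Each variable is expressed as 100 x operated / contralateral (percent).
#'
#' @param operated,contralateral [torsion_metrics()] objects; all
#'   contralateral values must be > 0.
#' @return The operated metrics with the `normalized` field filled.
#' @export
normalize_to_contralateral <- function(operated, contralateral) {
  stopifnot(inherits(operated, "torsion_metrics"),
            inherits(contralateral, "torsion_metrics"))
  vars <- c("stiffness", "yield_torque", "ultimate_torque",
            "rotation_to_failure", "energy_to_failure")
  contra <- unlist(contralateral[vars])
  if (any(contra <= 0))
    stopf("non-positive contralateral value for %s",
          paste(vars[contra <= 0], collapse = ", "))
  operated$normalized <- 100 * unlist(operated[vars]) / contra
  operated
}

#' Read / write torsion curves as two-column CSV
#'
#' CSV with columns `angle_deg`, `torque_Nm` (header optional on read).
#'
#' @param path File path.
#' @param curve A [torsion_curve()] (for writing).
#' @return [read_torsion_csv()] returns a [torsion_curve()].
#' @export
read_torsion_csv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = header)
  torsion_curve(df[[1]], df[[2]])
}

#' @rdname read_torsion_csv
#' @export
write_torsion_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("angle_deg", "torque_Nm")], path,
                   row.names = FALSE)
  invisible(path)
}
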