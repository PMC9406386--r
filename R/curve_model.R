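#' Gamma-variate indicator-dilution curve specification
#'
#' Constructs the analytic curve family used throughout the package to model
#' the inflow phase of an ICG bolus. The curve is flat at `baseline` until
#' `t_onset`, then follows a normalised gamma-variate
#' \deqn{f(t) = baseline + amplitude \cdot x^{\alpha} e^{\alpha (1 - x)},
#'   \quad x = (t - t_{onset}) / t_{peak\_offset},}
#' which attains its unique maximum `baseline + amplitude` at
#' `t_onset + t_peak_offset`. The three quantities a perfusion analyst reads
#' off a recording map directly onto the family: `amplitude` is the analytic
#' Fmax, `t_peak_offset` the analytic Tmax, and the shape `alpha` alone
#' controls the rise-shape ratio T1/2 / Tmax.
#'
#' @param baseline Pre-injection luminance, arbitrary units (AU).
#' @param amplitude Peak minus baseline, AU; must be > 0. Equals analytic Fmax.
#' @param t_onset Time of fluorescence onset in seconds, >= 0.
#' @param t_peak_offset Time from onset to the maximum in seconds, > 0.
#'   Equals analytic Tmax.
#' @param shape Dimensionless gamma-variate shape `alpha` > 0.
#'
#' @return An object of class `gamma_spec` (a named list).
#' @examples
#' spec <- gamma_spec(baseline = 0, amplitude = 100, t_onset = 10,
#'                    t_peak_offset = 50, shape = 2)
#' eval_gamma(spec, c(10, 60))
#' @export
gamma_spec <- function(baseline = 5, amplitude, t_onset = 10,
                       t_peak_offset, shape) {
  vals <- c(baseline = baseline, amplitude = amplitude, t_onset = t_onset,
            t_peak_offset = t_peak_offset, shape = shape)
  if (!all(is.finite(vals))) {
    stop_icg("all gamma_spec fields must be finite numbers",
             class = "icg_validation_error")
  }
  if (amplitude <= 0) {
    stop_icg("`amplitude` must be > 0", class = "icg_validation_error")
  }
  if (t_onset < 0) {
    stop_icg("`t_onset` must be >= 0", class = "icg_validation_error")
  }
  if (t_peak_offset <= 0) {
    stop_icg("`t_peak_offset` must be > 0", class = "icg_validation_error")
  }
  if (shape <= 0) {
    stop_icg("`shape` must be > 0", class = "icg_validation_error")
  }
  structure(
    list(baseline = baseline, amplitude = amplitude, t_onset = t_onset,
         t_peak_offset = t_peak_offset, shape = shape),
    class = "gamma_spec"
  )
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat("<gamma_spec>\n")
  cat(sprintf("  baseline      %.4g AU\n", x$baseline))
  cat(sprintf("  amplitude     %.4g AU (analytic Fmax)\n", x$amplitude))
  cat(sprintf("  t_onset       %.4g s\n", x$t_onset))
  cat(sprintf("  t_peak_offset %.4g s (analytic Tmax)\n", x$t_peak_offset))
  cat(sprintf("  shape         %.4g\n", x$shape))
  invisible(x)
}

#' @export
as.data.frame.gamma_spec <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Evaluate a gamma-variate curve
#'
#' @param spec A [gamma_spec()].
#' @param t Numeric vector of times in seconds, all >= 0 and finite.
#' @return Numeric vector of intensities (AU), `baseline` for `t <= t_onset`.
#' @export
eval_gamma <- function(spec, t) {
  check_gamma_spec(spec)
  if (!is.numeric(t) || !all(is.finite(t))) {
    stop_icg("`t` must be finite numeric", class = "icg_validation_error")
  }
  if (any(t < 0)) {
    stop_icg("`t` must be >= 0", class = "icg_validation_error")
  }
  x <- (t - spec$t_onset) / spec$t_peak_offset
  out <- rep(spec$baseline, length(t))
  up <- x > 0
  # x^alpha e^{alpha(1-x)} computed on the log scale for numerical stability
  # at large alpha / large x
  lx <- spec$shape * (log(x[up]) + 1 - x[up])
  out[up] <- spec$baseline + spec$amplitude * exp(lx)
  out
}

#' Time from onset to half-maximum on the rising limb
#'
#' Solves for the delay `D` in seconds such that the curve reaches
#' `baseline + amplitude/2` at `t_onset + D`. The rising limb of the
#' gamma-variate is strictly increasing, so the crossing is unique in
#' `(0, t_peak_offset)`; it is found by bisection to an absolute tolerance of
#' `tol` seconds. The ratio `D / t_peak_offset` is the analytic TR and is a
#' strictly increasing function of the shape parameter.
#'
#' @inheritParams eval_gamma
#' @param tol Absolute tolerance in seconds (default 1e-6).
#' @return Delay from onset to half-maximum, seconds.
#' @export
gamma_half_time <- function(spec, tol = 1e-6) {
  check_gamma_spec(spec)
  spec$t_peak_offset * half_ratio(spec$shape, tol = tol / spec$t_peak_offset)
}

# root of x^a e^{a(1-x)} = 1/2 on (0, 1), i.e. a*(log x + 1 - x) = -log 2,
# by bisection on the strictly increasing rising limb. Bisection runs in
# u = log(x) so small-alpha roots (which can underflow any absolute x
# tolerance) retain full relative precision.
half_ratio <- function(alpha, tol = 1e-9) {
  g <- function(u) alpha * (u + 1 - exp(u)) + log(2)
  lo <- -700
  hi <- 0
  # since x = exp(u) <= 1, |dx| <= |du|: a log-interval below tol bounds the
  # x error by tol while keeping relative precision for underflow-small roots
  while (hi - lo > max(tol, 1e-13)) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break   # interval at floating-point spacing
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# shape bracket within which calibration is attempted
.alpha_bracket <- c(1e-3, 1e3)

#' Attainable T1/2 / Tmax interval of the curve family
#'
#' The rise-shape ratio TR = T1/2 / Tmax is a strictly increasing function of
#' the shape parameter; this returns the interval it spans over the shape
#' bracket used by [calibrate_gamma()].
#'
#' @return Length-2 numeric vector (min, max) of attainable TR.
#' @export
attainable_tr_range <- function() {
  vapply(.alpha_bracket, half_ratio, numeric(1))
}

#' Calibrate a gamma-variate curve to target perfusion parameters
#'
#' Inverse problem: given target Fmax, Tmax and T1/2, returns the curve
#' specification whose analytic parameters reproduce them. Amplitude and peak
#' offset are identified directly (`amplitude = fmax`,
#' `t_peak_offset = tmax`); the shape is solved by 1-D root finding on the
#' ratio `t_half / tmax` so that [gamma_half_time()] matches `t_half` to
#' within `tol` seconds.
#'
#' @param fmax Target Fmax in AU, > 0.
#' @param tmax Target Tmax in seconds, > 0.
#' @param t_half Target T1/2 in seconds, with `0 < t_half < tmax`.
#' @param baseline,t_onset Passed to [gamma_spec()].
#' @param tol Absolute tolerance on the reproduced T1/2, seconds.
#' @return A [gamma_spec()].
#' @examples
#' spec <- calibrate_gamma(fmax = 176, tmax = 192, t_half = 8.8)
#' gamma_half_time(spec) # ~8.8
#' @export
calibrate_gamma <- function(fmax, tmax, t_half, baseline = 5, t_onset = 10,
                            tol = 1e-3) {
  if (!all(is.finite(c(fmax, tmax, t_half))) ||
      fmax <= 0 || tmax <= 0 || t_half <= 0) {
    stop_icg("targets (fmax, tmax, t_half) must be finite and > 0",
             class = "icg_validation_error")
  }
  if (t_half >= tmax) {
    stop_icg("`t_half` must be < `tmax`", class = "icg_validation_error")
  }
  rho <- t_half / tmax
  rng <- attainable_tr_range()
  if (rho <= rng[1] || rho >= rng[2]) {
    stop_icg(sprintf(
      "t_half/tmax = %.4g is outside the attainable interval (%.3g, %.3g) of the curve family",
      rho, rng[1], rng[2]), class = "icg_calibration_error")
  }
  f <- function(a) half_ratio(a, tol = 1e-13) - rho
  alpha <- stats::uniroot(f, interval = .alpha_bracket,
                          tol = 1e-10)$root
  spec <- gamma_spec(baseline = baseline, amplitude = fmax,
                     t_onset = t_onset, t_peak_offset = tmax, shape = alpha)
  # guard: round trip must hold
  err <- abs(gamma_half_time(spec) - t_half)
  if (err > tol) {
    stop_icg(sprintf("calibration failed to converge (residual %.3g s)", err),
             class = "icg_calibration_error")
  }
  spec
}

#' Sample a gamma-variate curve on a regular time grid
#'
#' @inheritParams eval_gamma
#' @param dt Sampling interval, seconds.
#' @param record_length Total record duration, seconds.
#' @return A curve tibble with columns `time_s`, `intensity_au`.
#' @export
gamma_curve <- function(spec, dt = 1, record_length = 400) {
  check_gamma_spec(spec)
  if (dt <= 0 || record_length <= 0) {
    stop_icg("`dt` and `record_length` must be > 0",
             class = "icg_validation_error")
  }
  t <- seq(0, record_length, by = dt)
  tibble::tibble(time_s = t, intensity_au = eval_gamma(spec, t))
}

#' Serialize / deserialize a curve specification as JSON
#'
#' @param spec A [gamma_spec()].
#' @param path File path; for `read_gamma_spec()` an existing JSON file.
#' @return `write_gamma_spec()` returns `path` invisibly; `read_gamma_spec()`
#'   returns a [gamma_spec()].
#' @export
write_gamma_spec <- function(spec, path) {
  check_gamma_spec(spec)
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gamma_spec
#' @export
read_gamma_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma_spec(baseline = x$baseline, amplitude = x$amplitude,
             t_onset = x$t_onset, t_peak_offset = x$t_peak_offset,
             shape = x$shape)
}

check_gamma_spec <- function(spec) {
  if (!inherits(spec, "gamma_spec")) {
    stop_icg("`spec` must be a gamma_spec object",
             class = "icg_validation_error")
  }
  invisible(spec)
}
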