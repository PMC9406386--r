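#' Validate a time-intensity curve table
#'
#' A curve is any data frame with numeric columns `time_s` (strictly
#' increasing) and `intensity_au` (finite), at least 10 samples long.
#'
#' @param curve Data frame with columns `time_s`, `intensity_au`.
#' @return The curve as a tibble, invisibly usable downstream.
#' @export
validate_curve <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("time_s", "intensity_au") %in% names(curve))) {
    stop_icg("a curve needs columns `time_s` and `intensity_au`",
             class = "icg_validation_error")
  }
  tt <- curve$time_s
  yy <- curve$intensity_au
  if (!is.numeric(tt) || !is.numeric(yy) || length(tt) != length(yy)) {
    stop_icg("`time_s` and `intensity_au` must be numeric and equal length",
             class = "icg_validation_error")
  }
  if (length(tt) < 10) {
    stop_icg("a curve needs at least 10 samples",
             class = "icg_validation_error")
  }
  if (!all(is.finite(tt)) || !all(is.finite(yy))) {
    stop_icg("curve values must be finite (no NA/NaN/Inf)",
             class = "icg_validation_error")
  }
  if (any(diff(tt) <= 0)) {
    stop_icg("`time_s` must be strictly increasing",
             class = "icg_validation_error")
  }
  tibble::as_tibble(curve[c("time_s", "intensity_au")])
}

#' Extraction configuration
#'
#' Tunable constants of baseline/onset detection and smoothing. All thresholds
#' are expressed in units derived from the data itself (baseline standard
#' deviations), so extraction is equivariant under intensity rescaling and
#' time shifts.
#'
#' @param smooth_window Centered moving-average window in samples; odd,
#'   default 5. `1` disables smoothing.
#' @param onset_k Onset threshold in baseline-SD multiples (default 3).
#' @param onset_run Consecutive supra-threshold smoothed samples required to
#'   call an onset (default 5).
#' @param baseline_span Seconds from the start of the record used for the
#'   provisional baseline; `NULL` (default) uses the first 5 samples. The
#'   final baseline is always recomputed over all samples strictly before the
#'   detected onset (minimum 5 samples).
#' @param onset_refine_k Baseline-SD multiple of the lower level used by the
#'   two-level onset back-extrapolation (default 2; the upper level is twice
#'   that).
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(smooth_window = 5, onset_k = 3, onset_run = 5,
                              baseline_span = NULL, onset_refine_k = 2) {
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop_icg("`smooth_window` must be a positive odd integer",
             class = "icg_validation_error")
  }
  if (onset_k <= 0 || onset_run < 1) {
    stop_icg("`onset_k` and `onset_run` must be positive",
             class = "icg_validation_error")
  }
  if (!is.null(baseline_span) && baseline_span <= 0) {
    stop_icg("`baseline_span` must be positive seconds or NULL",
             class = "icg_validation_error")
  }
  if (onset_refine_k <= 0) {
    stop_icg("`onset_refine_k` must be positive",
             class = "icg_validation_error")
  }
  structure(list(smooth_window = as.integer(smooth_window),
                 onset_k = onset_k, onset_run = as.integer(onset_run),
                 baseline_span = baseline_span,
                 onset_refine_k = onset_refine_k),
            class = "extraction_config")
}

#' Centered moving-average smoothing
#'
#' @param curve A curve table (see [validate_curve()]).
#' @param window Odd window length in samples; edges use truncated windows,
#'   `window = 1` is the identity.
#' @return The smoothed curve tibble.
#' @export
smooth_curve <- function(curve, window = 5) {
  curve <- validate_curve(curve)
  n <- nrow(curve)
  if (window %% 2 == 0) {
    stop_icg("`window` must be odd", class = "icg_validation_error")
  }
  if (window > n) {
    stop_icg("`window` exceeds curve length", class = "icg_validation_error")
  }
  curve$intensity_au <- moving_average(curve$intensity_au, window)
  curve
}

# truncated-edge centered moving average via cumulative sums
moving_average <- function(y, window) {
  if (window == 1) return(y)
  n <- length(y)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect pre-injection baseline and fluorescence onset
#'
#' Two-pass procedure. A provisional baseline mean/SD is taken from the start
#' of the record (`baseline_span`, default the first 5 samples). The onset is
#' the start of the first run of `onset_run` consecutive smoothed samples
#' exceeding `baseline + onset_k * SD`; the final baseline is then recomputed
#' over all samples strictly before the provisional onset, and the onset time
#' is refined. On a noise-free record the refinement interpolates the exact
#' baseline departure of the raw samples. With baseline noise it
#' back-extrapolates the early rise linearly through two interpolated
#' threshold crossings of the smoothed signal (at `onset_refine_k` and twice
#' `onset_refine_k` baseline SDs): `t_onset = 2 t_lo - t_hi`. Because the
#' early rise is convex this is a tight upper bound on the true arrival time,
#' and it stays low-bias both for sharp bolus arrivals and for the slow
#' convex rises of severely ischemic tissue, where a plain threshold
#' crossing can lag arrival by many seconds.
#'
#' @param curve A curve table.
#' @param cfg An [extraction_config()].
#' @return A list with `baseline` (AU), `baseline_sd` (AU), `t_onset` (s) and
#'   the internal index of the sustained run start.
#' @export
detect_onset <- function(curve, cfg = extraction_config()) {
  curve <- validate_curve(curve)
  tt <- curve$time_s
  y <- curve$intensity_au
  n <- length(y)
  ys <- moving_average(y, min(cfg$smooth_window, if (n %% 2L == 0L) n - 1L else n))

  n0 <- if (is.null(cfg$baseline_span)) 5L else {
    max(5L, sum(tt <= tt[1] + cfg$baseline_span))
  }
  n0 <- min(n0, n)
  base <- mean(y[seq_len(n0)])
  bsd <- stats::sd(y[seq_len(n0)])

  run <- find_onset_run(ys, base, bsd, cfg)
  if (is.na(run)) {
    stop_icg(
      sprintf("no fluorescence onset found: signal never exceeds baseline %.4g + %g SD (%.4g) for %d consecutive samples",
              base, cfg$onset_k, base + cfg$onset_k * bsd, cfg$onset_run),
      class = "icg_no_signal",
      data = list(threshold = base + cfg$onset_k * bsd))
  }

  # pass 2: provisional refinement, then recompute the baseline over all
  # samples strictly before the provisional onset and refine once more
  # against the improved baseline
  noiseless <- function(b, s) s <= 1e-9 * max(abs(y - b), 1e-300)
  t1 <- if (noiseless(base, bsd)) {
    refine_onset(tt, y, base, run)
  } else {
    refine_onset(tt, ys, base, run)
  }
  pre <- which(tt < t1)
  if (length(pre) < 5L) pre <- seq_len(min(5L, n))
  base <- mean(y[pre])
  bsd <- stats::sd(y[pre])

  t_onset <- if (noiseless(base, bsd)) {
    # exact baseline departure of the raw record
    refine_onset(tt, y, base, run)
  } else {
    # two-level linear back-extrapolation of the early rise
    t_lo <- first_crossing_time(tt, ys, base + cfg$onset_refine_k * bsd)
    t_hi <- first_crossing_time(tt, ys, base + 2 * cfg$onset_refine_k * bsd)
    if (is.finite(t_lo) && is.finite(t_hi) && t_hi > t_lo) {
      2 * t_lo - t_hi
    } else {
      refine_onset(tt, ys, base, run)   # weak signal: fall back to walk-back
    }
  }
  t_onset <- max(t_onset, tt[1])

  list(baseline = base, baseline_sd = bsd, t_onset = t_onset, run_start = run)
}

# earliest interpolated time at which y rises to `level`; NA if never reached
first_crossing_time <- function(tt, y, level) {
  i <- which(y >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L || y[i] == level) return(tt[i])
  tt[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (tt[i] - tt[i - 1L])
}

# first index of a run of `onset_run` smoothed samples strictly above
# baseline + k*SD (with an epsilon floor so SD = 0 means "above baseline")
find_onset_run <- function(ys, base, bsd, cfg) {
  eps <- 1e-12 * max(abs(ys), 1)
  thr <- base + max(cfg$onset_k * bsd, eps)
  above <- ys > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= cfg$onset_run
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1]]
}

# locate the upward crossing of the baseline level closest to the sustained
# run: scan forward from the run start to the first sample strictly above the
# level, walk back to the last sample at/below it, and linearly interpolate
refine_onset <- function(tt, y, level, run) {
  n <- length(y)
  i1 <- run
  while (i1 <= n && y[i1] <= level) i1 <- i1 + 1L
  if (i1 > n) return(tt[run])        # degenerate: no rise above the level
  j <- i1 - 1L
  while (j >= 1L && y[j] > level) j <- j - 1L
  if (j < 1L) return(tt[1])          # signal above baseline from record start
  y1 <- y[j]; y2 <- y[j + 1L]
  if (y1 >= level) return(tt[j])     # sample sits exactly on the level
  tt[j] + (level - y1) / (y2 - y1) * (tt[j + 1L] - tt[j])
}

#' Extract the five perfusion parameters from a time-intensity curve
#'
#' Implements the standard quantitative read-out of an ICG inflow recording:
#' after baseline/onset detection on the smoothed curve,
#' * `fmax` — maximum minus baseline (AU),
#' * `tmax` — time from onset to the (earliest) global maximum (s),
#' * `t_half` — time from onset to the first crossing of half-maximum on the
#'   rising limb, linearly interpolated between bracketing samples (s),
#' * `slope` — `fmax / tmax` (AU/s), the mean inflow rate,
#' * `tr` — `t_half / tmax`, a dimensionless rise-shape ratio.
#'
#' Quality flags are set when the maximum falls on the final sample
#' (`flag_max_at_end`: the record may have ended before the true peak) or when
#' `fmax < 5 * baseline_sd` (`flag_weak_signal`).
#'
#' @param curve A curve table (columns `time_s`, `intensity_au`).
#' @param cfg An [extraction_config()].
#' @param baseline,t_onset Optional known values overriding automatic
#'   detection (both must be given together with at least one of them to skip
#'   detection of that quantity; supplying both skips detection entirely).
#' @return A one-row tibble with columns `baseline`, `baseline_sd`, `t_onset`,
#'   `fmax`, `tmax`, `t_half`, `slope`, `tr`, `flag_max_at_end`,
#'   `flag_weak_signal`.
#' @examples
#' spec <- calibrate_gamma(fmax = 176, tmax = 192, t_half = 8.8)
#' extract_parameters(gamma_curve(spec, dt = 0.5))
#' @export
extract_parameters <- function(curve, cfg = extraction_config(),
                               baseline = NULL, t_onset = NULL) {
  curve <- validate_curve(curve)
  tt <- curve$time_s
  y <- curve$intensity_au
  n <- length(y)
  ys <- moving_average(y, min(cfg$smooth_window, if (n %% 2L == 0L) n - 1L else n))

  if (is.null(baseline) || is.null(t_onset)) {
    det <- detect_onset(curve, cfg)
    if (is.null(baseline)) {
      base <- det$baseline
      bsd <- det$baseline_sd
    } else {
      base <- baseline
      bsd <- 0
    }
    if (is.null(t_onset)) t_onset <- det$t_onset
  } else {
    base <- baseline
    bsd <- 0
  }

  after <- which(tt >= t_onset)
  if (length(after) < 2) {
    stop_icg("onset falls at the end of the record",
             class = "icg_no_signal")
  }
  i_peak <- after[which.max(ys[after])]   # which.max: earliest index on ties
  fmax <- ys[i_peak] - base
  if (fmax <= 0) {
    stop_icg("no signal rise above baseline after onset",
             class = "icg_no_signal")
  }
  tmax <- tt[i_peak] - t_onset

  half <- base + fmax / 2
  t_cross <- first_crossing(tt, ys, half, from = after[1], to = i_peak)
  t_half <- t_cross - t_onset

  tibble::tibble(
    baseline = base,
    baseline_sd = bsd,
    t_onset = t_onset,
    fmax = fmax,
    tmax = tmax,
    t_half = t_half,
    slope = fmax / tmax,
    tr = t_half / tmax,
    flag_max_at_end = i_peak == n,
    flag_weak_signal = fmax < 5 * bsd
  )
}

# earliest time in [from, to] where y rises through `level`, linearly
# interpolated; if the first considered sample is already at/above the level,
# interpolate from the preceding sample when possible
first_crossing <- function(tt, y, level, from, to) {
  idx <- from:to
  k <- idx[which(y[idx] >= level)[1]]
  if (is.na(k)) return(tt[to])       # level never reached (cannot happen for
                                     # half-maximum by construction)
  if (k == 1L || y[k] == level) return(tt[k])
  y1 <- y[k - 1L]; y2 <- y[k]
  if (y1 >= level) return(tt[k - 1L])
  tt[k - 1L] + (level - y1) / (y2 - y1) * (tt[k] - tt[k - 1L])
}

#' Round extracted parameters to reporting precision
#'
#' Reports use the precision conventional for these quantities: Fmax to the
#' AU, times to 0.1 s, Slope to 0.01 AU/s, TR to 0.001. Internal values keep
#' full precision; this applies rounding for human-readable output only.
#'
#' @param params Tibble from [extract_parameters()] (any number of rows).
#' @return The tibble with rounded `fmax`, `tmax`, `t_half`, `slope`, `tr`.
#' @export
format_parameters <- function(params) {
  dplyr::mutate(
    params,
    fmax = round(.data$fmax),
    tmax = round(.data$tmax, 1),
    t_half = round(.data$t_half, 1),
    slope = round(.data$slope, 2),
    tr = round(.data$tr, 3)
  )
}

#' Extract parameters for every animal in a simulated cohort
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (needs `animal_id`
#'   and the `curve` list-column).
#' @param cfg An [extraction_config()].
#' @return Tibble with one parameter row per animal, prefixed by `animal_id`
#'   and `group`.
#' @export
extract_cohort_parameters <- function(cohort, cfg = extraction_config()) {
  stopifnot(all(c("animal_id", "curve") %in% names(cohort)))
  params <- purrr::map(cohort$curve, extract_parameters, cfg = cfg)
  dplyr::bind_cols(
    cohort[intersect(c("animal_id", "group"), names(cohort))],
    dplyr::bind_rows(params)
  )
}
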