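#' The four ischemia groups of the rat anastomotic-leak study design
#'
#' Returns the group-level calibration table the simulator is built around:
#' a non-ischemic Control and three groups with progressively longer (1, 2,
#' 3 cm) devascularised colonic segments. Curve targets are the group-mean
#' perfusion parameters (Fmax, Tmax, T1/2); leak probabilities are the
#' observed anastomotic-leak rates among evaluable animals (0/10, 2/9, 2/8,
#' 4/8) and bursting pressures the group means in mmHg. `reported_slope`
#' carries the group-mean Slope as reported per animal; note that a mean of
#' per-animal ratios need not equal the ratio of means, so it is retained as
#' study data rather than derived from `target_fmax / target_tmax`.
#'
#' @param cv Between-animal coefficient of variation applied log-normally to
#'   all three curve targets (default 0.15).
#' @param bp_sd Within-group bursting-pressure SD in mmHg (default 20).
#' @return A tibble with one row per group: `group`, `n`, `target_fmax`,
#'   `target_tmax`, `target_t_half`, `reported_slope`, `cv`, `leak_prob`,
#'   `bp_mean`, `bp_sd`.
#' @export
study_groups <- function(cv = 0.15, bp_sd = 20) {
  tibble::tibble(
    group = factor(c("Control", "Group1", "Group2", "Group3"),
                   levels = c("Control", "Group1", "Group2", "Group3")),
    n = c(10L, 9L, 8L, 8L),
    target_fmax = c(176, 101, 91, 64),
    target_tmax = c(192, 172, 208, 230),
    target_t_half = c(8.8, 18.7, 35.1, 76.9),
    reported_slope = c(0.7, 0.6, 0.45, 0.3),
    cv = cv,
    leak_prob = c(0 / 10, 2 / 9, 2 / 8, 4 / 8),
    bp_mean = c(167.5, 100, 82.5, 77),
    bp_sd = bp_sd
  )
}

#' Acquisition noise and sampling specification
#'
#' @param additive_sd_frac SD of additive Gaussian sensor noise as a fraction
#'   of the curve amplitude (default 0.02).
#' @param sampling_dt Frame interval in seconds (default 1).
#' @param record_length Record duration in seconds (default 400, i.e. more
#'   than 5 minutes of acquisition).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(additive_sd_frac = 0.02, sampling_dt = 1,
                       record_length = 400) {
  if (additive_sd_frac < 0 || sampling_dt <= 0 || record_length <= 0) {
    stop_icg("noise_spec fields must be non-negative (dt, length positive)",
             class = "icg_validation_error")
  }
  structure(list(additive_sd_frac = additive_sd_frac,
                 sampling_dt = sampling_dt, record_length = record_length),
            class = "noise_spec")
}

#' Simulate a seeded synthetic cohort of perfusion recordings and outcomes
#'
#' For each animal, draws (Fmax, Tmax, T1/2) log-normally around its group's
#' targets with coefficient of variation `cv` (the log-normal is parameterised
#' so that the arithmetic mean equals the target; T1/2 is redrawn, up to 100
#' times, until `t_half < tmax` and the ratio lies in the attainable range of
#' the curve family), calibrates a gamma-variate curve, samples it on a
#' regular grid with additive Gaussian noise, and draws a leak outcome
#' (Bernoulli at the group rate) and a bursting pressure (Normal truncated at
#' zero). Fully reproducible for a given seed.
#'
#' @param groups Group table as from [study_groups()]; any subset of rows or
#'   modified `n`/`cv` works.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; required, every random draw derives from it.
#' @param baseline,t_onset Curve baseline (AU) and onset time (s) common to
#'   all animals; extraction is invariant to both.
#' @return A cohort tibble with one row per animal: `animal_id`, `group`,
#'   `fmax_true`, `tmax_true`, `t_half_true`, `shape`, `baseline`, `t_onset`,
#'   `leak`, `bursting_pressure`, `excluded`, `exclusion_reason`, and a
#'   `curve` list-column of sampled curve tibbles.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' nrow(coh) # 35 evaluable animals
#' @export
simulate_cohort <- function(groups = study_groups(), noise = noise_spec(),
                            seed, baseline = 5, t_onset = 10) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop_icg("`seed` (a single integer) is required",
             class = "icg_validation_error")
  }
  if (!inherits(noise, "noise_spec")) {
    stop_icg("`noise` must be a noise_spec()", class = "icg_validation_error")
  }
  need <- c("group", "n", "target_fmax", "target_tmax", "target_t_half",
            "cv", "leak_prob", "bp_mean", "bp_sd")
  if (!all(need %in% names(groups))) {
    stop_icg(paste("`groups` must have columns:", paste(need, collapse = ", ")),
             class = "icg_validation_error")
  }
  if (noise$record_length < max(groups$target_tmax) + t_onset) {
    stop_icg("`record_length` must cover t_onset + the largest target Tmax",
             class = "icg_validation_error")
  }

  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  rng <- attainable_tr_range()
  rows <- purrr::pmap(groups, function(group, n, target_fmax, target_tmax,
                                       target_t_half, cv, leak_prob, bp_mean,
                                       bp_sd, ...) {
    purrr::map(seq_len(n), function(i) {
      fmax <- rlnorm_mean(1, target_fmax, cv)
      tmax <- rlnorm_mean(1, target_tmax, cv)
      t_half <- rlnorm_mean(1, target_t_half, cv)
      tries <- 0L
      while (!(t_half < tmax && t_half / tmax > rng[1] &&
               t_half / tmax < rng[2])) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop_icg(sprintf(
            "could not draw t_half < tmax for group %s after 100 rejections",
            group), class = "icg_generation_error")
        }
        t_half <- rlnorm_mean(1, target_t_half, cv)
      }
      spec <- calibrate_gamma(fmax, tmax, t_half,
                              baseline = baseline, t_onset = t_onset)
      curve <- gamma_curve(spec, dt = noise$sampling_dt,
                           record_length = noise$record_length)
      if (noise$additive_sd_frac > 0) {
        curve$intensity_au <- curve$intensity_au +
          stats::rnorm(nrow(curve), 0, noise$additive_sd_frac * fmax)
      }
      bp <- stats::rnorm(1, bp_mean, bp_sd)
      while (bp <= 0) bp <- stats::rnorm(1, bp_mean, bp_sd)
      tibble::tibble(
        animal_id = sprintf("%s_%02d", group, i),
        group = group,
        fmax_true = fmax, tmax_true = tmax, t_half_true = t_half,
        shape = spec$shape, baseline = baseline, t_onset = t_onset,
        leak = stats::runif(1) < leak_prob,
        bursting_pressure = bp,
        excluded = FALSE,
        exclusion_reason = NA_character_,
        curve = list(curve)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (is.factor(groups$group)) {
    out$group <- factor(out$group, levels = levels(groups$group))
  }
  out
}

# log-normal with arithmetic mean `m` and coefficient of variation `cv`
rlnorm_mean <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Write / read a simulated cohort as plain-text files
#'
#' `write_cohort()` writes one curve CSV per animal (`<animal_id>.csv`,
#' columns `time_s`, `intensity_au`) plus a manifest
#' CSV (`manifest.csv`: `animal_id`, `group`, `leak`,
#' `bursting_pressure_mmhg`, `excluded`, `exclusion_reason`, `seed`).
#' `read_curve()` reads one curve CSV back; `read_manifest()` the manifest.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @param seed Seed echoed into the manifest for provenance.
#' @return `write_cohort()` returns the manifest path invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk2(cohort$curve, cohort$animal_id, function(cv, id) {
    readr::write_csv(cv, file.path(dir, paste0(id, ".csv")))
  })
  manifest <- tibble::tibble(
    animal_id = cohort$animal_id,
    group = as.character(cohort$group),
    leak = cohort$leak,
    bursting_pressure_mmhg = cohort$bursting_pressure,
    excluded = cohort$excluded,
    exclusion_reason = cohort$exclusion_reason,
    seed = as.integer(seed)
  )
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_cohort
#' @param path Path to a curve CSV (`time_s`, `intensity_au`).
#' @export
read_curve <- function(path) {
  # parse problems surface as NA values, which validate_curve() rejects with
  # a structured error; readr's own warning would only duplicate that signal
  cv <- tryCatch(
    suppressWarnings(
      readr::read_csv(path, show_col_types = FALSE,
                      col_types = readr::cols(
                        time_s = readr::col_double(),
                        intensity_au = readr::col_double()))),
    error = function(e) {
      stop_icg(sprintf("cannot parse curve CSV '%s': %s", path,
                       conditionMessage(e)), class = "icg_io_error")
    })
  if (!all(c("time_s", "intensity_au") %in% names(cv))) {
    stop_icg(sprintf("curve CSV '%s' must have columns time_s, intensity_au",
                     path), class = "icg_io_error")
  }
  validate_curve(cv)
}

#' @rdname write_cohort
#' @export
read_manifest <- function(path) {
  m <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE),
    error = function(e) {
      stop_icg(sprintf("cannot parse manifest '%s': %s", path,
                       conditionMessage(e)), class = "icg_io_error")
    })
  need <- c("animal_id", "group", "leak", "bursting_pressure_mmhg", "excluded")
  if (!all(need %in% names(m))) {
    stop_icg(paste("manifest must have columns:", paste(need, collapse = ", ")),
             class = "icg_io_error")
  }
  m
}
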