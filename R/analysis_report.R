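#' Full statistical analysis of an extracted cohort
#'
#' Reproduces the study's statistical battery on a parameter table joined to
#' an outcome manifest: per-group parameter summaries, pairwise Mann-Whitney
#' comparisons of each perfusion parameter and of bursting pressure,
#' leak-vs-no-leak comparisons, Fisher's exact test of the cutoff
#' classification, Pearson correlations of each parameter with bursting
#' pressure, ROC analysis of Slope, and the confusion summary at the Slope
#' cutoff. Excluded animals are dropped before any statistic and listed with
#' their reasons. All tests are two-sided at alpha = 0.05; no
#' multiple-testing correction is applied (noted in the report).
#'
#' @param params Parameter tibble (one row per animal, needs `animal_id` and
#'   the five parameter columns).
#' @param manifest Outcome table with `animal_id`, `group`, `leak`,
#'   `bursting_pressure_mmhg` (or `bursting_pressure`), optionally `excluded`
#'   and `exclusion_reason`.
#' @param cutoff Slope cutoff in AU/s for leak prediction (default 0.4).
#' @return An object of class `icg_report` (a named list of tibbles plus
#'   settings); see [tidy.icg_report()] and [glance.icg_report()].
#' @export
analyze_cohort <- function(params, manifest, cutoff = 0.4) {
  if (!"animal_id" %in% names(params) || !"animal_id" %in% names(manifest)) {
    stop_icg("both tables need an `animal_id` column",
             class = "icg_validation_error")
  }
  if ("bursting_pressure" %in% names(manifest) &&
      !"bursting_pressure_mmhg" %in% names(manifest)) {
    manifest <- dplyr::rename(manifest,
                              bursting_pressure_mmhg = "bursting_pressure")
  }
  excluded <- tibble::tibble(animal_id = character(),
                             exclusion_reason = character())
  if ("excluded" %in% names(manifest)) {
    excluded <- manifest |>
      dplyr::filter(.data$excluded) |>
      dplyr::select("animal_id",
                    dplyr::any_of("exclusion_reason"))
    manifest <- dplyr::filter(manifest, !.data$excluded)
  }
  missing_outcomes <- setdiff(params$animal_id, manifest$animal_id)
  df <- dplyr::inner_join(params, manifest, by = "animal_id",
                          suffix = c("", ".manifest"))
  if (nrow(df) == 0) {
    stop_icg("no animals left after joining parameters to outcomes",
             class = "icg_validation_error")
  }

  pars <- c("fmax", "tmax", "t_half", "slope", "tr")
  group_summary <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(c(pars,
                                                   "bursting_pressure_mmhg")),
                                   \(x) mean(x, na.rm = TRUE)),
                     leaks = sum(.data$leak), .groups = "drop")

  multi_group <- length(unique(df$group)) > 1
  pairwise <- if (multi_group) {
    purrr::map_dfr(c(pars, "bursting_pressure_mmhg"), function(p) {
      compare_groups(df, !!rlang::sym(p), .data$group) |>
        dplyr::mutate(parameter = p, .before = 1)
    })
  } else {
    NULL
  }

  both_classes <- any(df$leak) && any(!df$leak)
  leak_compare <- roc <- confusion <- fisher <- NULL
  if (both_classes) {
    leak_compare <- purrr::map_dfr(pars, function(p) {
      res <- mann_whitney(df[[p]][df$leak], df[[p]][!df$leak])
      tibble::tibble(parameter = p,
                     mean_leak = mean(df[[p]][df$leak]),
                     mean_no_leak = mean(df[[p]][!df$leak]),
                     u = res$u, p_value = res$p_value)
    })
    roc <- roc_analysis(df, .data$slope, .data$leak)
    confusion <- confusion_at_cutoff(df, .data$slope, .data$leak,
                                     cutoff = cutoff)
    fisher <- fisher_exact(confusion$tp, confusion$fp,
                           confusion$fn, confusion$tn)
  }

  correlations <- purrr::map_dfr(pars, function(p) {
    pearson_correlation(df, !!rlang::sym(p),
                        .data$bursting_pressure_mmhg) |>
      dplyr::mutate(parameter = p, .before = 1)
  })

  structure(list(
    data = df,
    group_summary = group_summary,
    pairwise_mann_whitney = pairwise,
    leak_comparison = leak_compare,
    correlations_with_bp = correlations,
    roc = roc,
    confusion = confusion,
    fisher_cutoff = fisher,
    leak_rates = leak_rates(manifest),
    excluded = excluded,
    missing_outcomes = missing_outcomes,
    settings = list(cutoff = cutoff, alpha = 0.05, two_sided = TRUE,
                    multiple_testing_correction = "none"),
    notes = c(
      if (!multi_group) "single group supplied: group comparisons skipped",
      if (!both_classes) "single outcome class: ROC/cutoff analysis skipped",
      "all tests two-sided at alpha = 0.05; no multiple-testing correction")
  ), class = "icg_report")
}

#' @export
print.icg_report <- function(x, ...) {
  cat("<icg_report>\n")
  cat(sprintf("  %d animals, %d groups; %d excluded, %d missing outcomes\n",
              nrow(x$data), length(unique(x$data$group)), nrow(x$excluded),
              length(x$missing_outcomes)))
  if (!is.null(x$roc)) {
    cat(sprintf("  Slope ROC AUC = %.3f; at cutoff %.2g AU/s: sens %.1f%%, spec %.1f%%\n",
                x$roc$auc, x$settings$cutoff,
                x$confusion$sensitivity_pct, x$confusion$specificity_pct))
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Tidy and one-line summaries of an analysis report
#'
#' `tidy()` returns the per-group summary table; `glance()` a one-row tibble
#' with the headline numbers (AUC, sensitivity/specificity at the cutoff,
#' Fisher p, cohort size).
#'
#' @param x An `icg_report`.
#' @param ... Unused.
#' @method tidy icg_report
#' @export
tidy.icg_report <- function(x, ...) x$group_summary

#' @rdname tidy.icg_report
#' @method glance icg_report
#' @export
glance.icg_report <- function(x, ...) {
  tibble::tibble(
    n_animals = nrow(x$data),
    n_groups = length(unique(x$data$group)),
    n_excluded = nrow(x$excluded),
    auc_slope = if (is.null(x$roc)) NA_real_ else x$roc$auc,
    cutoff = x$settings$cutoff,
    sensitivity_pct = if (is.null(x$confusion)) NA_real_
                      else x$confusion$sensitivity_pct,
    specificity_pct = if (is.null(x$confusion)) NA_real_
                      else x$confusion$specificity_pct,
    fisher_p = if (is.null(x$fisher_cutoff)) NA_real_
               else x$fisher_cutoff$p_value
  )
}

#' Serialize an analysis report to JSON or TSV
#'
#' JSON output nests every component table; TSV output writes the per-group
#' summary and appends headline statistics as comment lines.
#'
#' @param report An `icg_report`.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- list(
      group_summary = report$group_summary,
      pairwise_mann_whitney = report$pairwise_mann_whitney,
      leak_comparison = report$leak_comparison,
      correlations_with_bp = report$correlations_with_bp,
      roc_points = if (is.null(report$roc)) NULL else report$roc$points,
      auc_slope = if (is.null(report$roc)) NULL else report$roc$auc,
      confusion = report$confusion,
      fisher_cutoff = report$fisher_cutoff,
      leak_rates = report$leak_rates,
      excluded = report$excluded,
      missing_outcomes = report$missing_outcomes,
      settings = report$settings,
      notes = report$notes
    )
    jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    hdr <- glance.icg_report(report)
    lines <- c(
      paste0("# ", names(hdr), " = ", unlist(lapply(hdr, as.character))),
      paste0("# note: ", report$notes))
    writeLines(lines, path)
    suppressWarnings(
      utils::write.table(report$group_summary, path, sep = "\t",
                         row.names = FALSE, quote = FALSE, append = TRUE))
  }
  invisible(path)
}
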