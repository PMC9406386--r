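#' Mann-Whitney U test (two-sided, midranks for ties)
#'
#' The U statistic is oriented on `x`: `U = R_x - n_x (n_x + 1) / 2`, the
#' number of (x, y) pairs with `x > y` counting ties one half. For combined
#' sample sizes up to `exact_limit` the two-sided p-value is exact, obtained
#' by enumerating every assignment of the pooled midranks to the two groups
#' and summing the probability of assignments at least as far from the null
#' mean `n_x n_y / 2` as observed. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param mode `"auto"` (exact when `length(x) + length(y) <= exact_limit`),
#'   `"exact"` or `"approximate"`.
#' @param exact_limit Combined-size limit for exact enumeration (default 20).
#' @return A one-row tibble: `u`, `p_value`, `n_x`, `n_y`, `method`,
#'   `degenerate` (TRUE when all pooled values are identical, in which case
#'   `p_value` is 1).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approximate"),
                         exact_limit = 20) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop_icg("both samples must be non-empty", class = "icg_validation_error")
  }
  if (!all(is.finite(c(x, y)))) {
    stop_icg("samples must be finite", class = "icg_validation_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (length(unique(c(x, y))) == 1) {
    return(tibble::tibble(u = u, p_value = 1, n_x = nx, n_y = ny,
                          method = "degenerate", degenerate = TRUE))
  }

  exact <- switch(mode,
                  auto = n <= exact_limit,
                  exact = TRUE,
                  approximate = FALSE)
  if (exact && n > 25) {
    stop_icg("exact enumeration limited to combined n <= 25",
             class = "icg_validation_error")
  }

  if (exact) {
    combs <- utils::combn(n, nx)
    us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * (n + 1 - tie_term))
    z <- (abs(u - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  tibble::tibble(u = u, p_value = p, n_x = nx, n_y = ny,
                 method = method, degenerate = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided via hypergeometric enumeration: the p-value sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. Rows are test
#' positive/negative, columns are leak/no-leak.
#'
#' @param a,b,c,d Non-negative integer counts (row-wise: `a` = positive+leak,
#'   `b` = positive+no-leak, `c` = negative+leak, `d` = negative+no-leak).
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return A one-row tibble: `p_value`, `odds_ratio` (conditional MLE),
#'   `a`, `b`, `c`, `d`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
    if (!all(dim(m) == c(2, 2))) {
      stop_icg("matrix input must be 2x2", class = "icg_validation_error")
    }
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(m < 0) || any(m != round(m)) || sum(m) == 0) {
    stop_icg("counts must be non-negative integers with positive total",
             class = "icg_validation_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    # a zero margin fixes the table; no evidence either way
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_,
                          a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2]))
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  tibble::tibble(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2])
}

#' Pearson correlation with t-distribution p-value
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the two numeric variables.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    stop_icg("Pearson correlation needs n >= 3 finite pairs",
             class = "icg_validation_error")
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop_icg("correlation undefined: a variable has zero variance",
             class = "icg_validation_error")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(xv))
}

#' ROC analysis with a low-score-positive decision rule
#'
#' Poor perfusion predicts anastomotic leak, so the classifier is "positive
#' if score <= threshold". The threshold sweep visits every unique score; the
#' AUC is computed through the rank identity `AUC = U / (n1 n2)` with midrank
#' tie handling (the probability that a randomly chosen positive scores below
#' a randomly chosen negative, ties counted one half), equivalent to the
#' trapezoidal area under the stepped ROC curve.
#'
#' @param data A data frame.
#' @param score Column (tidy-eval) holding the continuous score, e.g. Slope.
#' @param truth Column (tidy-eval) holding the positive-class indicator
#'   (logical, or coercible to logical), e.g. leak.
#' @return An object of class `icg_roc`: list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`,
#'   `direction`.
#' @export
roc_analysis <- function(data, score, truth) {
  s <- rlang::eval_tidy(rlang::enquo(score), data)
  lab <- as.logical(rlang::eval_tidy(rlang::enquo(truth), data))
  ok <- is.finite(s) & !is.na(lab)
  s <- s[ok]; lab <- lab[ok]
  n1 <- sum(lab); n2 <- sum(!lab)
  if (n1 == 0 || n2 == 0) {
    stop_icg("ROC analysis needs both classes present",
             class = "icg_validation_error")
  }
  r <- rank(s)
  # pairs where a positive scores below a negative, ties one half
  u_pos_above <- sum(r[lab]) - n1 * (n1 + 1) / 2   # pos > neg pairs
  auc <- 1 - u_pos_above / (n1 * n2)
  thr <- sort(unique(s))
  pts <- purrr::map_dfr(thr, function(ct) {
    pos <- s <= ct
    tibble::tibble(threshold = ct,
                   sensitivity = sum(pos & lab) / n1,
                   specificity = sum(!pos & !lab) / n2)
  })
  structure(list(points = pts, auc = auc, n_pos = n1, n_neg = n2,
                 direction = "low-score-positive"),
            class = "icg_roc")
}

#' @export
print.icg_roc <- function(x, ...) {
  cat(sprintf("<icg_roc> %d positives, %d negatives (%s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUC = %.3f over %d thresholds\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy icg_roc
#' @export
tidy.icg_roc <- function(x, ...) x$points

#' @method glance icg_roc
#' @export
glance.icg_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 direction = x$direction)
}

#' Confusion summary at a fixed score cutoff
#'
#' Classifies `score <= cutoff` as test-positive (the rule used for the
#' 0.4 AU/s Slope cutoff) and cross-tabulates against the true class.
#' Percentages are truncated, not rounded, to one decimal: 22/27 correctly
#' classified negatives reports specificity 81.4.
#'
#' @inheritParams roc_analysis
#' @param cutoff Score cutoff (default 0.4 AU/s).
#' @return One-row tibble: `cutoff`, `tp`, `fn`, `fp`, `tn`, `sensitivity`,
#'   `specificity` (proportions), `sensitivity_pct`, `specificity_pct`
#'   (percentages truncated to one decimal).
#' @export
confusion_at_cutoff <- function(data, score, truth, cutoff = 0.4) {
  s <- rlang::eval_tidy(rlang::enquo(score), data)
  lab <- as.logical(rlang::eval_tidy(rlang::enquo(truth), data))
  ok <- is.finite(s) & !is.na(lab)
  s <- s[ok]; lab <- lab[ok]
  if (!any(lab) || all(lab)) {
    stop_icg("confusion summary needs both classes present",
             class = "icg_validation_error")
  }
  pos <- s <= cutoff
  tp <- sum(pos & lab); fn <- sum(!pos & lab)
  fp <- sum(pos & !lab); tn <- sum(!pos & !lab)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(cutoff = cutoff, tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = trunc1(100 * sens),
                 specificity_pct = trunc1(100 * spec))
}

# truncate (not round) to one decimal, as in 22/27 -> 81.4
trunc1 <- function(x) trunc(x * 10 + 1e-9) / 10

#' Relative Slope attenuation of the ischemia groups
#'
#' Expresses each group's mean Slope as a percentage of the Control group's,
#' rounded to one decimal: with the study's group means 0.7/0.6/0.45/0.3
#' AU/s this gives 100, 85.7, 64.3 and 42.9 percent.
#'
#' @param groups Group table with columns `group` and a slope column.
#' @param slope_col Name of the slope column (default `"reported_slope"`).
#' @param control Label of the reference group (default `"Control"`).
#' @return Tibble `group`, `slope`, `attenuation_pct`.
#' @export
slope_attenuation <- function(groups = study_groups(),
                              slope_col = "reported_slope",
                              control = "Control") {
  sl <- groups[[slope_col]]
  ref <- sl[as.character(groups$group) == control]
  if (length(ref) != 1) {
    stop_icg("exactly one control group row required",
             class = "icg_validation_error")
  }
  tibble::tibble(group = groups$group, slope = sl,
                 attenuation_pct = round(100 * sl / ref, 1))
}

#' Anastomotic-leak rates per group
#'
#' @param manifest Data frame with columns `group`, `leak` and optionally
#'   `excluded` (excluded animals are dropped first).
#' @return Tibble `group`, `n`, `leaks`, `leak_rate_pct` (rounded to one
#'   decimal).
#' @export
leak_rates <- function(manifest) {
  if ("excluded" %in% names(manifest)) {
    manifest <- dplyr::filter(manifest, !.data$excluded)
  }
  manifest |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), leaks = sum(.data$leak),
                     .groups = "drop") |>
    dplyr::mutate(leak_rate_pct = round(100 * .data$leaks / .data$n, 1))
}

#' Pairwise Mann-Whitney comparisons of a parameter across groups
#'
#' @param data Data frame with a grouping column and a numeric value column.
#' @param value Column (tidy-eval) of the continuous variable.
#' @param group Column (tidy-eval) of the group labels.
#' @param ... Passed to [mann_whitney()].
#' @return Tibble with one row per unordered group pair: `group1`, `group2`,
#'   `u`, `p_value`, `method`.
#' @export
compare_groups <- function(data, value, group, ...) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  levs <- unique(g)
  if (length(levs) < 2) {
    stop_icg("at least two groups required for comparison",
             class = "icg_single_group_error")
  }
  pairs <- utils::combn(levs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    res <- mann_whitney(v[g == g1], v[g == g2], ...)
    tibble::tibble(group1 = g1, group2 = g2, u = res$u,
                   p_value = res$p_value, method = res$method)
  })
}
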