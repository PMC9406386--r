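test_that("Mann-Whitney on fully separated triples gives U = 0 and exact p = 0.1", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)                # oriented on x: no x > y pair
  expect_equal(res$p_value, 0.1)        # 2 of the 20 assignments as extreme
  expect_equal(res$method, "exact")
})

test_that("Mann-Whitney is symmetric and degenerates gracefully", {
  x <- c(2, 5, 5, 9)
  expect_equal(mann_whitney(x, x)$p_value, 1)
  res <- mann_whitney(c(3, 3), c(3, 3, 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), class = "icg_validation_error")
})

test_that("exact Mann-Whitney p-values match brute-force pair-count enumeration", {
  set.seed(701)
  for (i in 1:12) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:8, nx, replace = TRUE)   # ties likely
    y <- sample(1:8, ny, replace = TRUE)
    res <- mann_whitney(x, y, mode = "exact")
    oracle <- brute_mw(x, y)
    expect_equal(res$u, oracle$u)
    expect_equal(res$p_value, oracle$p)
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(702)
  for (i in 1:8) {
    x <- rnorm(sample(3:7, 1)); y <- rnorm(sample(3:7, 1))
    res <- mann_whitney(x, y, mode = "exact")
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(res$u, unname(wt$statistic))
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact Mann-Whitney p-value", {
  set.seed(703)
  diffs <- replicate(50, {
    x <- rnorm(sample(6:10, 1)); y <- rnorm(sample(6:10, 1), 0.5)
    abs(mann_whitney(x, y, mode = "exact")$p_value -
          mann_whitney(x, y, mode = "approximate")$p_value)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("Fisher's exact test matches hypergeometric enumeration on the study table", {
  res <- fisher_exact(6, 5, 2, 22)   # slope<=cutoff leak/no-leak split
  expect_equal(res$p_value, brute_fisher(6, 5, 2, 22), tolerance = 1e-12)
  set.seed(704)
  for (i in 1:10) {
    m <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact(m)$p_value,
                 brute_fisher(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher's test handles zero margins and is transpose-invariant", {
  expect_equal(fisher_exact(0, 10, 0, 10)$p_value, 1)
  m <- matrix(c(6, 2, 5, 22), 2, byrow = TRUE)
  expect_equal(fisher_exact(m)$p_value, fisher_exact(t(m))$p_value,
               tolerance = 1e-12)
  expect_error(fisher_exact(-1, 2, 3, 4), class = "icg_validation_error")
})

test_that("Pearson correlation is exact on linear data and guards degenerate input", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  res <- pearson_correlation(d, x, y)
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 1e-10)
  expect_error(pearson_correlation(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               class = "icg_validation_error")
  expect_error(pearson_correlation(tibble::tibble(x = 1:2, y = 1:2), x, y),
               class = "icg_validation_error")
})

test_that("null correlations are small and p-values roughly uniform", {
  set.seed(705)
  ps <- replicate(60, {
    d <- tibble::tibble(x = rnorm(100), y = rnorm(100))
    pearson_correlation(d, x, y)$p_value
  })
  expect_gt(min(ps), 0)
  expect_lt(abs(mean(ps) - 0.5), 0.15)     # uniform mean 0.5
  expect_gt(mean(ps > 0.05), 0.8)          # ~95% expected
})

test_that("perfusion parameters correlate with bursting pressure in the expected direction", {
  coh <- simulate_cohort(study_groups(cv = 0.1), noise_spec(0.02), seed = 706)
  params <- extract_cohort_parameters(coh)
  d <- dplyr::left_join(params,
                        dplyr::select(coh, "animal_id", "bursting_pressure"),
                        by = "animal_id")
  expect_gt(pearson_correlation(d, slope, bursting_pressure)$r, 0)
  expect_lt(pearson_correlation(d, t_half, bursting_pressure)$r, 0)
})

test_that("ROC analysis is exact under separation and near chance under the null", {
  sep <- tibble::tibble(score = c(1:8 / 10, 2 + 1:27 / 10),
                        leak = rep(c(TRUE, FALSE), c(8, 27)))
  expect_equal(roc_analysis(sep, score, leak)$auc, 1)

  set.seed(707)
  null <- tibble::tibble(score = rnorm(2000), leak = rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(roc_analysis(null, score, leak)$auc - 0.5), 0.05)
  expect_error(roc_analysis(tibble::tibble(score = 1:5, leak = rep(TRUE, 5)),
                            score, leak),
               class = "icg_validation_error")
})

test_that("rank-identity AUC equals pair-counting on random instances", {
  set.seed(708)
  for (i in 1:50) {
    n1 <- sample(3:10, 1); n2 <- sample(3:15, 1)
    s <- c(sample(1:12, n1, TRUE), sample(1:12, n2, TRUE)) # ties likely
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    d <- tibble::tibble(score = s, leak = lab)
    expect_equal(roc_analysis(d, score, leak)$auc, pair_auc(s, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney U identity on the same data", {
  set.seed(709)
  s <- c(rnorm(8, 0.35, 0.15), rnorm(27, 0.7, 0.2))
  lab <- rep(c(TRUE, FALSE), c(8, 27))
  d <- tibble::tibble(score = s, leak = lab)
  auc <- roc_analysis(d, score, leak)$auc
  u <- mann_whitney(s[lab], s[!lab])$u   # pairs with positive above negative
  expect_equal(auc, 1 - u / (8 * 27), tolerance = 1e-12)
})

test_that("ROC sensitivity/specificity are monotone in the threshold", {
  set.seed(710)
  d <- tibble::tibble(score = rnorm(60), leak = runif(60) < 0.3)
  roc <- roc_analysis(d, score, leak)
  expect_true(all(diff(roc$points$sensitivity) >= 0))
  expect_true(all(diff(roc$points$specificity) <= 0))
  expect_s3_class(tidy(roc), "tbl_df")
  expect_equal(glance(roc)$auc, roc$auc)
})

test_that("confusion at the cutoff truncates percentages and honours boundaries", {
  sens_spec <- confusion_at_cutoff(
    tibble::tibble(score = c(0.2, 0.25, 0.3, 0.35, 0.38, 0.4, 0.55, 0.6,
                             0.1, 0.2, 0.3, 0.35, 0.4, 2 + 1:22 / 10),
                   leak = rep(c(TRUE, FALSE), c(8, 27))),
    score, leak, cutoff = 0.4)
  expect_equal(sens_spec$sensitivity_pct, 75.0)
  expect_equal(sens_spec$specificity_pct, 81.4)   # 22/27 truncated

  d <- tibble::tibble(score = 1:10, leak = rep(c(TRUE, FALSE), 5))
  lo <- confusion_at_cutoff(d, score, leak, cutoff = 0)
  expect_equal(c(lo$sensitivity_pct, lo$specificity_pct), c(0, 100))
  hi <- confusion_at_cutoff(d, score, leak, cutoff = 10)
  expect_equal(c(hi$sensitivity_pct, hi$specificity_pct), c(100, 0))
})

test_that("slope attenuation and leak rates reproduce the group-level study figures", {
  att <- slope_attenuation()
  expect_equal(att$attenuation_pct, c(100, 85.7, 64.3, 42.9))

  manifest <- tibble::tibble(
    group = rep(c("Control", "Group1", "Group2", "Group3"), c(10, 9, 8, 8)),
    leak = c(rep(FALSE, 10), rep(c(TRUE, FALSE), c(2, 7)),
             rep(c(TRUE, FALSE), c(2, 6)), rep(c(TRUE, FALSE), c(4, 4))))
  lr <- leak_rates(manifest)
  expect_equal(lr$leak_rate_pct, c(0, 22.2, 25, 50))
})

test_that("pairwise group comparisons cover all pairs and reject single groups", {
  d <- tibble::tibble(v = rnorm(30), g = rep(c("a", "b", "c"), 10))
  pw <- compare_groups(d, v, g)
  expect_equal(nrow(pw), 3)
  expect_error(compare_groups(dplyr::filter(d, g == "a"), v, g),
               class = "icg_single_group_error")
})
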