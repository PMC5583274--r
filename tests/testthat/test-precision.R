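# Build an area matrix by hand from a per-cell value function.
manual_precision_matrix <- function(value_fun, n_days = 3, n_reps = 2,
                                    analyte = "a1") {
  rows <- expand.grid(day = seq_len(n_days), replicate = seq_len(n_reps))
  df <- tibble::tibble(
    sample_id = sprintf("p_d%d_r%d", rows$day, rows$replicate),
    group = "pool", day = rows$day, replicate = rows$replicate
  )
  df[[analyte]] <- mapply(value_fun, rows$day, rows$replicate)
  area_matrix(df)
}

test_that("pure between-day variation gives cv_intra 0 and cv_total = cv_inter", {
  m <- manual_precision_matrix(function(d, r) c(100, 120, 90)[d])
  res <- variance_components(m, "pool")
  per <- res$per_analyte
  expect_equal(per$cv_intra, 0)
  expect_gt(per$cv_inter, 0)
  expect_equal(per$cv_total, per$cv_inter)
})

test_that("the quadrature identity holds exactly for every analyte", {
  lib <- tiny_library(n = 40)
  st <- generate_study(lib, study_design("precision"), noise_spec(seed = 6))
  per <- variance_components(st, "control_pool")$per_analyte
  expect_equal(per$cv_total^2, per$cv_intra^2 + per$cv_inter^2,
               tolerance = 1e-12)
  expect_true(all(per$cv_inter >= 0))
})

test_that("mean squares agree with stats::aov", {
  m <- manual_precision_matrix(function(d, r) 100 + 7 * d + 3 * r + d * r,
                               n_days = 4, n_reps = 3)
  long <- area_long(m)
  fit <- summary(stats::aov(area ~ factor(day), data = long))[[1]]
  ms_between <- fit["factor(day)", "Mean Sq"]
  ms_within <- fit["Residuals", "Mean Sq"]
  per <- variance_components(m, "pool")$per_analyte
  grand <- mean(long$area)
  expect_equal(per$cv_intra, 100 * sqrt(ms_within) / grand, tolerance = 1e-10)
  expect_equal(per$cv_inter,
               100 * sqrt(max(0, (ms_between - ms_within) / 3)) / grand,
               tolerance = 1e-10)
})

test_that("the estimator matches direct empirical SDs on a large design", {
  # two-level model with many days and replicates: the ANOVA estimates
  # converge to the plain empirical variance components
  n_days <- 150
  n_reps <- 40
  sd_day <- 9
  sd_rep <- 5
  base <- 1000
  vals <- withr::with_seed(10, {
    day_fx <- rnorm(n_days, 0, sd_day)
    lapply(seq_len(n_days), function(d) base + day_fx[d] +
             rnorm(n_reps, 0, sd_rep))
  })
  df <- tibble::tibble(
    sample_id = sprintf("s%05d", seq_len(n_days * n_reps)),
    group = "pool",
    day = rep(seq_len(n_days), each = n_reps),
    replicate = rep(seq_len(n_reps), n_days),
    a1 = unlist(vals)
  )
  res <- variance_components(area_matrix(df), "pool")$per_analyte
  expect_equal(res$cv_intra, 100 * sd_rep / base, tolerance = 0.03)
  expect_equal(res$cv_inter, 100 * sd_day / base, tolerance = 0.05)
})

test_that("synthetic 5x5 studies recover their generating CVs", {
  lib <- tiny_library(n = 300, seed = 21)
  vals <- sapply(1:6, function(s) {
    st <- generate_study(lib, study_design("precision"),
                         noise_spec(0.074, 0.095, seed = s))
    g <- glance(variance_components(st, "control_pool"))
    c(g$mean_cv_intra, g$mean_cv_inter, g$mean_cv_total)
  })
  expect_equal(mean(vals[1, ]), 7.4, tolerance = 1 / 7.4)
  expect_equal(mean(vals[3, ]), 12, tolerance = 1.5 / 12)
})

test_that("unbalanced designs are refused", {
  m <- manual_precision_matrix(function(d, r) 100, n_days = 3, n_reps = 2)
  m2 <- area_matrix(as.data.frame(m)[-1, ])
  expect_error(variance_components(m2, "pool"), class = "mrmqc_design_error")
})

test_that("CVs are invariant under global rescaling of areas", {
  lib <- tiny_library(n = 10)
  st <- generate_study(lib, study_design("precision"), noise_spec(seed = 3))
  r1 <- variance_components(st, "control_pool")$per_analyte
  st2 <- st
  for (a in analytes(st2)) st2[[a]] <- st2[[a]] * 1e4
  r2 <- variance_components(st2, "control_pool")$per_analyte
  expect_equal(r1$cv_intra, r2$cv_intra, tolerance = 1e-10)
  expect_equal(r1$cv_total, r2$cv_total, tolerance = 1e-10)
})

test_that("constant retention times give zero CVs", {
  rt <- tidyr::expand_grid(analyte_id = c("x", "y"), day = 1:3,
                           replicate = 1:2)
  rt$rt_min <- 12
  res <- rt_reproducibility(rt)
  expect_true(all(res$per_analyte$cv_intra == 0))
  expect_true(all(res$per_analyte$cv_total == 0))
})

test_that("RT CVs do not depend on the time unit", {
  lib <- tiny_library(n = 10)
  rt <- generate_rt_study(lib, seed = 5)
  r_min <- rt_reproducibility(rt)$per_analyte
  rt_s <- rt
  rt_s$rt_min <- rt_s$rt_min * 60
  r_sec <- rt_reproducibility(rt_s)$per_analyte
  expect_equal(r_min$cv_intra, r_sec$cv_intra, tolerance = 1e-10)
  expect_equal(r_min$cv_inter, r_sec$cv_inter, tolerance = 1e-10)
})

test_that("generated RT jitter at 0.11%/0.14% is recovered", {
  lib <- tiny_library(n = 200, seed = 31)
  vals <- sapply(1:5, function(s) {
    res <- rt_reproducibility(generate_rt_study(lib, seed = s))
    glance(res)[c("mean_cv_intra", "mean_cv_inter")]
  })
  expect_equal(mean(unlist(vals["mean_cv_intra", ])), 0.11,
               tolerance = 0.03 / 0.11)
})

test_that("zero-mean analytes are flagged and kept out of the panel mean", {
  m <- manual_precision_matrix(function(d, r) 100 + d + r)
  m$a2 <- 0
  attr(m, "analytes") <- c("a1", "a2")
  res <- variance_components(m, "pool")
  expect_identical(res$per_analyte$flag[res$per_analyte$analyte_id == "a2"],
                   "zero mean")
  expect_false(any(is.na(res$panel$mean)))
})

test_that("quadrature of the printed pool CVs gives the printed totals", {
  expect_equal(round(cv_total(7.4, 9.5)), 12)
  expect_equal(round(cv_total(7.5, 9.7)), 12)
})
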