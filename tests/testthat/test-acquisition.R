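test_that("concurrency histogram matches a naive per-bin recount", {
  for (seed in 1:3) {
    lib <- tiny_library(n = 20, seed = seed)
    prof <- concurrency_profile(lib, bin_width_min = 2)
    naive <- vapply(seq_len(nrow(prof)), function(i) {
      sum(lib$rt_min >= prof$bin_start[i] & lib$rt_min < prof$bin_end[i])
    }, integer(1))
    expect_identical(prof$n, naive)
    expect_identical(max_concurrency(prof), max(naive))
  }
})

test_that("co-eluting transitions land in a single bin", {
  lib <- concurrent_library(10, rt = 12)
  prof <- concurrency_profile(lib, 2)
  expect_identical(max_concurrency(prof), 10L)
  expect_identical(sum(prof$n), 10L)
})

test_that("dwell budget at 150 concurrent dual-polarity transitions is 11.2 ms", {
  lib <- concurrent_library(150, both_polarities = TRUE)
  sch <- build_schedule(lib, target_cycle_s = 1.78, min_dwell_s = 0.002,
                        polarity_switch_s = 0.05)
  seg <- sch$segments[sch$segments$n_active == 150, ]
  expect_true(nrow(seg) >= 1)
  expect_equal(unique(seg$dwell_s), (1.78 - 2 * 0.05) / 150)
  expect_equal(unique(seg$dwell_s) * 1000, 11.2, tolerance = 1e-9)
  expect_gt(unique(seg$dwell_s), 0.002)
})

test_that("a lone transition receives the whole cycle, no switch overhead", {
  lib <- fixed_library(rts = 10, pol = "positive")
  sch <- build_schedule(lib, target_cycle_s = 1.78)
  seg <- sch$segments[sch$segments$n_active == 1, ]
  expect_equal(unique(seg$dwell_s), 1.78)
  expect_identical(unique(seg$n_switches), 0L)
})

test_that("single-polarity libraries pay no switch overhead anywhere", {
  lib <- concurrent_library(40, both_polarities = FALSE)
  sch <- build_schedule(lib)
  expect_true(all(sch$segments$n_switches == 0L))
})

test_that("the dwell budget inequality holds in every segment", {
  for (seed in 1:3) {
    lib <- tiny_library(n = 60, seed = seed)
    sch <- build_schedule(lib, target_cycle_s = 1, min_dwell_s = 0.02)
    seg <- sch$segments[sch$segments$n_active > 0, ]
    used <- seg$n_active * seg$dwell_s + seg$n_switches * 0.05
    expect_true(all(used <= seg$cycle_time_s + 1e-12))
  }
})

test_that("adding a transition never shrinks any segment's cycle time", {
  lib_small <- concurrent_library(100, both_polarities = FALSE)
  lib_big <- concurrent_library(101, both_polarities = FALSE)
  # a 1 s target with a 20 ms floor binds at 50 concurrent transitions
  s_small <- build_schedule(lib_small, target_cycle_s = 1, min_dwell_s = 0.02)
  s_big <- build_schedule(lib_big, target_cycle_s = 1, min_dwell_s = 0.02)
  ct_small <- max(s_small$segments$cycle_time_s, na.rm = TRUE)
  ct_big <- max(s_big$segments$cycle_time_s, na.rm = TRUE)
  expect_gte(ct_big, ct_small)
  expect_true(any(s_big$segments$inflated))
})

test_that("impossible dwell budgets raise a scheduling error", {
  lib <- concurrent_library(200, both_polarities = FALSE)
  expect_error(build_schedule(lib, target_cycle_s = 0.5, min_dwell_s = 0.1),
               class = "mrmqc_scheduling_error")
})

test_that("points across peak is the width to cycle-time ratio", {
  lib <- fixed_library(rts = 10, pol = "positive")
  sch <- build_schedule(lib, target_cycle_s = 1.78)
  expect_equal(points_per_peak(sch, "a1", 35.6)$n_points, 20)
  sch2 <- build_schedule(lib, target_cycle_s = 3.56)
  expect_equal(points_per_peak(sch2, "a1", 35.6)$n_points, 10)
  expect_error(points_per_peak(sch, "missing", 35.6),
               class = "mrmqc_validation_error")
})

test_that("predicted points agree with counted sample times in the window", {
  lib <- tiny_library(n = 15, seed = 4)
  sch <- build_schedule(lib, target_cycle_s = 1.78)
  traces <- simulate_acquisition(lib, sch, seed = 1)
  pred <- points_per_peak(sch, lib$analyte_id, 35.6)
  for (i in seq_len(5)) {
    a <- lib$analyte_id[i]
    tr <- traces[traces$analyte_id == a, ]
    counted <- sum(abs(tr$time_min - lib$rt_min[i]) * 60 <= 35.6 / 2)
    expect_lte(abs(counted - pred$n_points[pred$analyte_id == a]), 1)
  }
})

test_that("scheduled acquisition recovers analytic areas at >= 15 points", {
  lib <- tiny_library(n = 10, seed = 2)
  sch <- build_schedule(lib, target_cycle_s = 1.78)
  peaks <- tibble::tibble(analyte_id = lib$analyte_id, height = 2e5,
                          peak_width_base_s = 40, noise_sd = 0)
  traces <- simulate_acquisition(lib, sch, peaks, seed = 1)
  # integrate over a wide base so truncation does not confound the check
  mets <- measure_peaks(traces, base_frac = 0.005)
  expect_equal(mets$area, rep(gaussian_peak_area(2e5, 40), 10),
               tolerance = 0.02)
})

test_that("a peak eluting outside its window is missed", {
  lib <- fixed_library(rts = 10, pol = "positive")
  sch <- build_schedule(lib, window_half_width_min = 1)
  peaks <- tibble::tibble(analyte_id = "a1", peak_rt_min = 14, height = 1e5,
                          peak_width_base_s = 30, noise_sd = 0)
  traces <- simulate_acquisition(lib, sch, peaks, seed = 1)
  m <- measure_peak(traces[, c("time_min", "intensity")])
  expect_lt(m$area, gaussian_peak_area(1e5, 30) * 0.01)
})

test_that("doubling the target cycle halves the points per peak", {
  lib <- tiny_library(n = 8, seed = 3)
  p1 <- points_per_peak(build_schedule(lib, target_cycle_s = 1),
                        lib$analyte_id, 35.6)
  p2 <- points_per_peak(build_schedule(lib, target_cycle_s = 2),
                        lib$analyte_id, 35.6)
  expect_equal(mean(p2$n_points) * 2, mean(p1$n_points))
})
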