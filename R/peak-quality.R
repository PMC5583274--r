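#' Measure peak-quality metrics from a sampled trace
#'
#' Operational definitions: the apex is the maximum sampled point; the peak
#' base is the contiguous region about the apex where intensity is at least
#' `base_frac` of the apex (5% by default, about 4.4 sigma for a Gaussian);
#' FWHM is the contiguous span at 50% of the apex; the area is the
#' trapezoidal integral over the base region in intensity-seconds;
#' `n_points` counts samples inside the base; S/N is the apex height over
#' the standard deviation of the noise-window intensities.
#'
#' @param trace A data frame with columns `time_min`, `intensity` (at least
#'   3 points).
#' @param noise_window Optional `(start_min, end_min)` range used for the
#'   noise SD; must be disjoint from the peak base. When `NULL`, all points
#'   outside the peak base serve as the noise window.
#' @param base_frac Fraction of apex height defining the peak base.
#' @return A one-row tibble: `rt_obs_min`, `area`, `width_base_s`, `fwhm_s`,
#'   `n_points`, `snr`, `flag` (`"ok"`, `"no peak"` or `"zero noise"`).
#' @export
measure_peak <- function(trace, noise_window = NULL, base_frac = 0.05) {
  trace <- as_tibble(trace)
  stopifnot(all(c("time_min", "intensity") %in% names(trace)))
  if (nrow(trace) < 3) {
    stop_mrmqc("A trace needs at least 3 points.", "mrmqc_validation_error")
  }
  trace <- trace[order(trace$time_min), ]
  y <- trace$intensity
  t_s <- trace$time_min * 60
  apex_i <- which.max(y)
  apex <- y[apex_i]
  if (!is.finite(apex) || apex <= 0) {
    return(tibble(rt_obs_min = NA_real_, area = 0, width_base_s = 0,
                  fwhm_s = 0, n_points = 0L, snr = 0, flag = "no peak"))
  }
  span_about_apex <- function(frac) {
    thr <- frac * apex
    lo <- apex_i
    while (lo > 1 && y[lo - 1] >= thr) lo <- lo - 1
    hi <- apex_i
    while (hi < length(y) && y[hi + 1] >= thr) hi <- hi + 1
    c(lo, hi)
  }
  # crossing-point width: linear interpolation at the threshold on each flank
  interp_width <- function(idx, frac) {
    thr <- frac * apex
    lo <- idx[1]; hi <- idx[2]
    t_left <- if (lo > 1 && y[lo] > y[lo - 1]) {
      t_s[lo - 1] + (thr - y[lo - 1]) / (y[lo] - y[lo - 1]) *
        (t_s[lo] - t_s[lo - 1])
    } else t_s[lo]
    t_right <- if (hi < length(y) && y[hi] > y[hi + 1]) {
      t_s[hi] + (y[hi] - thr) / (y[hi] - y[hi + 1]) *
        (t_s[hi + 1] - t_s[hi])
    } else t_s[hi]
    t_right - t_left
  }
  base_idx <- span_about_apex(base_frac)
  half_idx <- span_about_apex(0.5)
  in_base <- seq(base_idx[1], base_idx[2])
  area <- if (length(in_base) >= 2) {
    sum(diff(t_s[in_base]) * (head(y[in_base], -1) + tail(y[in_base], -1)) / 2)
  } else 0
  noise_sd <- if (is.null(noise_window)) {
    outside <- setdiff(seq_along(y), in_base)
    if (length(outside) >= 2) sd(y[outside]) else 0
  } else {
    in_win <- trace$time_min >= noise_window[1] & trace$time_min <= noise_window[2]
    if (any(in_win & seq_along(y) %in% in_base)) {
      stop_mrmqc("noise_window overlaps the peak base.", "mrmqc_validation_error")
    }
    if (sum(in_win) >= 2) sd(y[in_win]) else 0
  }
  flag <- "ok"
  snr <- if (noise_sd > 0) apex / noise_sd else { flag <- "zero noise"; Inf }
  tibble(
    rt_obs_min = trace$time_min[apex_i],
    area = area,
    width_base_s = interp_width(base_idx, base_frac),
    fwhm_s = interp_width(half_idx, 0.5),
    n_points = length(in_base),
    snr = snr,
    flag = flag
  )
}

#' Measure peaks for every analyte in a trace table
#'
#' @param traces Long trace tibble (`analyte_id`, `time_min`, `intensity`),
#'   as produced by [simulate_acquisition()].
#' @param ... Passed to [measure_peak()].
#' @return A tibble with one metrics row per analyte.
#' @export
measure_peaks <- function(traces, ...) {
  traces <- as_tibble(traces)
  stopifnot("analyte_id" %in% names(traces))
  traces |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::group_modify(function(d, key) measure_peak(d, ...)) |>
    dplyr::ungroup()
}

#' Summarize a positive-valued metric as a lognormal fit
#'
#' Chromatographic quality metrics (peak width, FWHM, points per peak, S/N)
#' are well described by lognormal distributions, so the summary fits
#' `mu`/`sigma` as the mean and SD of the log values and reports the
#' linear-space mean `exp(mu + sigma^2/2)` together with a 95% population
#' dispersion interval `exp(mu +/- 1.96 sigma)` — an interval describing the
#' spread of the metric across analytes, not a standard error of the mean.
#'
#' @param values Positive numeric vector (`n >= 3`).
#' @return A one-row tibble of class `lognormal_summary`: `mean_linear`,
#'   `ci95_lo`, `ci95_hi`, `mu_log`, `sigma_log`, `n`.
#' @export
summarize_lognormal <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop_mrmqc("Need at least 3 non-missing values.", "mrmqc_validation_error")
  }
  bad <- which(values <= 0 | !is.finite(values))
  if (length(bad) > 0) {
    stop_mrmqc(
      paste0("Non-positive or non-finite value(s) at position(s): ",
             paste(head(bad, 5), collapse = ", ")),
      "mrmqc_validation_error"
    )
  }
  lx <- log(values)
  mu <- mean(lx)
  sigma <- sd(lx)
  out <- tibble(
    mean_linear = exp(mu + sigma^2 / 2),
    ci95_lo = exp(mu - 1.96 * sigma),
    ci95_hi = exp(mu + 1.96 * sigma),
    mu_log = mu,
    sigma_log = sigma,
    n = length(values)
  )
  class(out) <- c("lognormal_summary", class(out))
  out
}
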