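#' Retention-time concurrency profile
#'
#' Bins the library's retention times into fixed-width bins tiling
#' `[0, run_length]` and counts transitions per bin — the histogram view of
#' scheduled-MRM load. Note this counts point retention times; the
#' scheduling load that actually constrains dwell time depends on detection-
#' window overlap and is computed by [build_schedule()].
#'
#' @param library A [transition_library()].
#' @param bin_width_min Bin width in minutes (2 min is the conventional
#'   resolution for gradient-load histograms).
#' @return A tibble of class `concurrency_profile` with columns `bin_start`,
#'   `bin_end`, `n`, carrying `max_concurrency` as an attribute (also
#'   available via [max_concurrency()]).
#' @export
concurrency_profile <- function(library, bin_width_min = 2) {
  stopifnot(inherits(library, "transition_library"))
  check_number(bin_width_min, "bin_width_min", lower = 1e-9)
  if (nrow(library) == 0) {
    stop_mrmqc("Cannot profile an empty library.", "mrmqc_validation_error")
  }
  run_len <- run_length_min(library)
  breaks <- seq(0, run_len + bin_width_min, by = bin_width_min)
  idx <- findInterval(library$rt_min, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  out <- tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    n = counts
  )
  attr(out, "max_concurrency") <- max(counts)
  class(out) <- c("concurrency_profile", class(out))
  out
}

#' @rdname concurrency_profile
#' @export
max_concurrency <- function(x) attr(x, "max_concurrency")

#' Build a scheduled-MRM acquisition schedule
#'
#' Assigns each transition a detection window (`rt` plus/minus the half
#' width, clipped to the run bounds) and budgets instrument time over the
#' run: within each segment of constant window overlap, the cycle budget
#' remaining after polarity-switching overhead is divided equally among the
#' concurrent transitions, floored at the minimum dwell. Polarity switching
#' costs at most two switches per cycle (one contiguous block per polarity);
#' segments with only one polarity pay no overhead. If the dwell floor
#' forces the cycle beyond the target, the actual cycle time is inflated
#' and the segment flagged.
#'
#' @param library A [transition_library()].
#' @param window_half_width_min Detection-window half width in minutes.
#' @param target_cycle_s Target cycle time in seconds.
#' @param min_dwell_s Minimum dwell time per transition in seconds (modern
#'   triple quadrupoles go as low as 2 ms).
#' @param polarity_switch_s Time cost of one polarity switch in seconds.
#' @return An object of class `acquisition_schedule`: a list with `windows`
#'   (per-transition tibble), `segments` (piecewise-constant budget tibble
#'   with `start_min`, `end_min`, `n_active`, `n_switches`, `dwell_s`,
#'   `cycle_time_s`, `inflated`) and the scheduling parameters.
#' @export
build_schedule <- function(library, window_half_width_min = 1,
                           target_cycle_s = 1.78, min_dwell_s = 0.002,
                           polarity_switch_s = 0.05) {
  stopifnot(inherits(library, "transition_library"))
  check_number(window_half_width_min, "window_half_width_min", lower = 1e-9)
  check_number(min_dwell_s, "min_dwell_s", lower = 1e-9)
  check_number(polarity_switch_s, "polarity_switch_s", lower = 0)
  if (target_cycle_s <= polarity_switch_s) {
    stop_mrmqc("target_cycle_s must exceed polarity_switch_s.",
               "mrmqc_validation_error")
  }
  run_len <- run_length_min(library)
  windows <- tibble(
    analyte_id = library$analyte_id,
    polarity = library$polarity,
    rt_min = library$rt_min,
    start_min = pmax(0, library$rt_min - window_half_width_min),
    end_min = pmin(run_len, library$rt_min + window_half_width_min)
  )
  edges <- sort(unique(c(0, windows$start_min, windows$end_min, run_len)))
  starts <- edges[-length(edges)]
  ends <- edges[-1]
  mids <- (starts + ends) / 2
  n_active <- integer(length(mids))
  n_switches <- integer(length(mids))
  dwell <- numeric(length(mids))
  cycle <- numeric(length(mids))
  for (i in seq_along(mids)) {
    act <- windows$start_min <= mids[i] & windows$end_min > mids[i]
    n <- sum(act)
    n_active[i] <- n
    if (n == 0) { dwell[i] <- NA_real_; cycle[i] <- NA_real_; next }
    both <- length(unique(windows$polarity[act])) == 2
    sw <- if (both) 2L else 0L
    n_switches[i] <- sw
    overhead <- sw * polarity_switch_s
    d <- max(min_dwell_s, (target_cycle_s - overhead) / n)
    if (min_dwell_s * n > 10 * target_cycle_s) {
      stop_mrmqc(sprintf(
        "Impossible dwell budget in segment [%.2f, %.2f] min: %d concurrent transitions at the %.3g s floor exceed 10x the %.3g s target cycle.",
        starts[i], ends[i], n, min_dwell_s, target_cycle_s
      ), "mrmqc_scheduling_error")
    }
    dwell[i] <- d
    cycle[i] <- max(target_cycle_s, overhead + n * d)
  }
  segments <- tibble(
    start_min = starts, end_min = ends, n_active = n_active,
    n_switches = n_switches, dwell_s = dwell, cycle_time_s = cycle,
    inflated = !is.na(cycle) & cycle > target_cycle_s + 1e-12
  )
  structure(list(
    windows = windows, segments = segments,
    params = list(window_half_width_min = window_half_width_min,
                  target_cycle_s = target_cycle_s,
                  min_dwell_s = min_dwell_s,
                  polarity_switch_s = polarity_switch_s,
                  run_length_min = run_len)
  ), class = "acquisition_schedule")
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  seg <- x$segments[x$segments$n_active > 0, ]
  cat(sprintf(
    "<acquisition_schedule> %d transitions, max concurrency %d, cycle %.3g-%.3g s%s\n",
    nrow(x$windows), max(seg$n_active), min(seg$cycle_time_s),
    max(seg$cycle_time_s),
    if (any(seg$inflated)) " (some segments inflated above target)" else ""
  ))
  invisible(x)
}

# Cycle time of the segment containing a time point; internal.
cycle_time_at <- function(schedule, time_min) {
  seg <- schedule$segments
  i <- findInterval(time_min, seg$start_min, rightmost.closed = FALSE)
  i <- pmax(1L, pmin(i, nrow(seg)))
  seg$cycle_time_s[i]
}

#' Expected points across a peak
#'
#' The sampling cadence of a scheduled transition is its segment's cycle
#' time, so a peak of base width `w` seconds collects about
#' `w / cycle_time` points.
#'
#' @param schedule An [build_schedule()] result.
#' @param analyte_id One or more analyte identifiers present in the
#'   schedule.
#' @param peak_width_base_s Peak base width(s) in seconds.
#' @return A tibble with columns `analyte_id`, `cycle_time_s`, `n_points`.
#' @export
points_per_peak <- function(schedule, analyte_id, peak_width_base_s = 35.6) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  w <- schedule$windows
  hit <- match(analyte_id, w$analyte_id)
  if (anyNA(hit)) {
    stop_mrmqc(paste0("Analyte(s) not in schedule: ",
                      paste(analyte_id[is.na(hit)], collapse = ", ")),
               "mrmqc_validation_error")
  }
  if (any(peak_width_base_s <= 0)) {
    stop_mrmqc("peak_width_base_s must be positive.", "mrmqc_validation_error")
  }
  ct <- cycle_time_at(schedule, w$rt_min[hit])
  tibble(analyte_id = analyte_id, cycle_time_s = ct,
         n_points = peak_width_base_s / ct)
}

#' Simulate scheduled acquisition of Gaussian peaks
#'
#' Samples each analyte's chromatogram only inside its detection window at
#' its segment's cycle cadence, producing the traces a scheduled-MRM run
#' would record. Peaks whose apex lies outside the window are still sampled
#' (and will integrate to roughly nothing downstream).
#'
#' @param library A [transition_library()].
#' @param schedule A matching [build_schedule()] result.
#' @param peaks Per-analyte peak specification: a data frame with
#'   `analyte_id`, `height`, `peak_width_base_s`, `noise_sd`. Missing
#'   analytes get the defaults `height = 1e5`,
#'   `peak_width_base_s = 35.6`, `noise_sd = 0`.
#' @param seed Integer seed.
#' @return A long tibble of traces: `analyte_id`, `time_min`, `intensity`.
#' @export
simulate_acquisition <- function(library, schedule, peaks = NULL, seed = 1) {
  stopifnot(inherits(library, "transition_library"),
            inherits(schedule, "acquisition_schedule"))
  w <- schedule$windows
  missing_ids <- setdiff(library$analyte_id, w$analyte_id)
  if (length(missing_ids) > 0) {
    stop_mrmqc("Schedule does not cover the library.", "mrmqc_validation_error")
  }
  spec <- tibble(analyte_id = library$analyte_id, rt_min = library$rt_min)
  spec$height <- 1e5; spec$peak_width_base_s <- 35.6; spec$noise_sd <- 0
  if (!is.null(peaks)) {
    peaks <- as_tibble(peaks)
    hit <- match(peaks$analyte_id, spec$analyte_id)
    for (col in intersect(c("height", "peak_width_base_s", "noise_sd"),
                          names(peaks))) {
      spec[[col]][hit] <- peaks[[col]]
    }
    if ("peak_rt_min" %in% names(peaks)) {
      spec$rt_min[hit] <- peaks$peak_rt_min
    }
  }
  traces <- with_seed(seed, {
    purrr::map(seq_len(nrow(spec)), function(i) {
      win <- w[w$analyte_id == spec$analyte_id[i], ]
      cadence_s <- cycle_time_at(schedule, win$rt_min)
      times <- seq(win$start_min, win$end_min, by = cadence_s / 60)
      tr <- generate_chromatogram(
        peak_rt_min = spec$rt_min[i],
        peak_width_base_s = spec$peak_width_base_s[i],
        height = spec$height[i],
        noise_sd = spec$noise_sd[i],
        sampling_times_min = times,
        seed = NULL
      )
      tr$analyte_id <- spec$analyte_id[i]
      tr
    })
  })
  dplyr::bind_rows(traces)[, c("analyte_id", "time_min", "intensity")]
}
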