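#' Generate a synthetic transition library
#'
#' Emulates the composition of a single-injection, dual-polarity plasma
#' method: endogenous metabolites plus stable-isotope internal standards,
#' retention times drawn from a unimodal distribution that concentrates
#' mid-gradient (a symmetric Beta over `rt_range`), pathway annotations over
#' a fixed number of pathways, and a small set of chemical classes. With the
#' defaults (610 + 95 transitions, 63 pathways) the 2-min concurrency
#' histogram peaks at about 150 concurrent transitions.
#'
#' @param n_analytes Number of endogenous transitions.
#' @param n_internal_standards Number of internal-standard transitions.
#' @param rt_range Elution range `(min, max)` in minutes.
#' @param polarity_fraction_negative Expected fraction of negative-mode
#'   transitions.
#' @param n_pathways Number of distinct pathway annotations among endogenous
#'   analytes (each is guaranteed at least one member when
#'   `n_analytes >= n_pathways`).
#' @param rt_shape Shape of the symmetric Beta retention-time distribution;
#'   larger values concentrate elution mid-gradient.
#' @param run_length_min Run length in minutes.
#' @param seed Integer seed; identical inputs and seed give identical
#'   libraries.
#' @return A [transition_library()].
#' @export
generate_transition_library <- function(n_analytes = 610,
                                        n_internal_standards = 95,
                                        rt_range = c(4, 30),
                                        polarity_fraction_negative = 0.5,
                                        n_pathways = 63,
                                        rt_shape = 6.3,
                                        run_length_min = 45,
                                        seed = 1) {
  check_number(n_analytes, "n_analytes", lower = 1)
  check_number(n_internal_standards, "n_internal_standards", lower = 0)
  check_number(polarity_fraction_negative, "polarity_fraction_negative", 0, 1)
  if (length(rt_range) != 2 || rt_range[1] >= rt_range[2]) {
    stop_mrmqc("rt_range must be an increasing (min, max) pair.",
               "mrmqc_validation_error")
  }
  if (rt_range[2] > run_length_min) {
    stop_mrmqc("rt_range must lie within the run length.",
               "mrmqc_validation_error")
  }
  classes <- c("amino acid", "organic acid", "nucleoside", "nucleotide",
               "phospholipid", "sphingolipid", "acylcarnitine", "fatty acid",
               "sterol", "sugar", "bile acid", "vitamin")
  with_seed(seed, {
    n <- n_analytes + n_internal_standards
    rt <- rt_range[1] + diff(rt_range) * rbeta(n, rt_shape, rt_shape)
    q1 <- runif(n, 70, 1000)
    q3 <- pmax(30, q1 - runif(n, 10, 120))
    pol <- ifelse(runif(n) < polarity_fraction_negative, "negative", "positive")
    n_pw <- min(n_pathways, n_analytes)
    pw <- character(n_analytes)
    pw_labels <- sprintf("pathway_%02d", seq_len(n_pw))
    pw[seq_len(n_pw)] <- pw_labels            # every pathway gets one member
    if (n_analytes > n_pw) {
      pw[(n_pw + 1):n_analytes] <- sample(pw_labels, n_analytes - n_pw,
                                          replace = TRUE)
    }
    lib <- tibble(
      analyte_id = c(sprintf("met_%04d", seq_len(n_analytes)),
                     if (n_internal_standards > 0)
                       sprintf("istd_%03d", seq_len(n_internal_standards))),
      q1_mz = q1,
      q3_mz = q3,
      polarity = pol,
      rt_min = rt,
      declustering_potential = round(runif(n, 20, 120), 1),
      collision_energy = round(runif(n, 10, 60), 1),
      chem_class = c(sample(classes, n_analytes, replace = TRUE),
                     rep("internal standard", n_internal_standards)),
      pathway = c(pw, rep(NA_character_, n_internal_standards)),
      is_internal_standard = rep(c(FALSE, TRUE),
                                 c(n_analytes, n_internal_standards))
    )
    transition_library(lib, run_length_min = run_length_min)
  })
}

#' Simulate a single chromatographic peak
#'
#' A Gaussian peak of the given height and base width (the base is treated
#' as four standard deviations) plus white baseline noise, evaluated at the
#' supplied sampling times. The analytic area is
#' `height * sigma * sqrt(2*pi)` with `sigma = peak_width_base_s / 4`.
#'
#' @param peak_rt_min Apex position in minutes.
#' @param peak_width_base_s Base width in seconds (4 sigma).
#' @param height Apex intensity.
#' @param noise_sd Standard deviation of the additive baseline noise.
#' @param sampling_times_min Sampling times in minutes.
#' @param seed Integer seed for the noise draw.
#' @return A tibble with columns `time_min` and `intensity`.
#' @export
generate_chromatogram <- function(peak_rt_min, peak_width_base_s = 35.6,
                                  height = 1e5, noise_sd = 0,
                                  sampling_times_min, seed = 1) {
  check_number(peak_width_base_s, "peak_width_base_s", lower = 1e-9)
  check_number(height, "height", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (missing(sampling_times_min) || length(sampling_times_min) == 0) {
    stop_mrmqc("sampling_times_min must be a non-empty vector.",
               "mrmqc_validation_error")
  }
  sigma_s <- peak_width_base_s / 4
  t_s <- sampling_times_min * 60
  signal <- height * exp(-((t_s - peak_rt_min * 60)^2) / (2 * sigma_s^2))
  noise <- if (noise_sd > 0) {
    with_seed(seed, rnorm(length(t_s), 0, noise_sd))
  } else rep(0, length(t_s))
  tibble(time_min = sampling_times_min, intensity = signal + noise)
}

#' Analytic area of a simulated Gaussian peak
#'
#' @param height Apex intensity.
#' @param peak_width_base_s Base width in seconds (4 sigma).
#' @return Area in intensity-seconds.
#' @export
gaussian_peak_area <- function(height, peak_width_base_s) {
  height * (peak_width_base_s / 4) * sqrt(2 * pi)
}

#' The eight-metabolite chronic fatigue syndrome biomarker panel
#'
#' The named biomarker panel used for scoring pre-chosen panels without
#' re-selection: phosphatidylcholine PC(16:0/16:0), glucosylceramide
#' GC(18:1/16:0), 1-pyrroline-5-carboxylic acid, FAD, pyroglutamic acid,
#' hydroxyisocaproic acid, L-serine and lathosterol.
#'
#' @return A character vector of eight analyte names.
#' @export
cfs_biomarker_panel <- function() {
  c("PC(16:0/16:0)", "GC(18:1/16:0)", "1-pyrroline-5-carboxylic acid",
    "FAD", "pyroglutamic acid", "hydroxyisocaproic acid", "L-serine",
    "lathosterol")
}
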