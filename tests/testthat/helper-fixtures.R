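# Small fixtures built in code, shared across test files.

tiny_library <- function(n = 20, n_is = 0, seed = 7, rt_range = c(4, 30)) {
  generate_transition_library(
    n_analytes = n, n_internal_standards = n_is,
    rt_range = rt_range, seed = seed
  )
}

# A hand-built 3-transition library with fixed RTs, for exact assertions.
fixed_library <- function(rts = c(10, 12, 12), pol = c("positive", "negative",
                                                       "positive")) {
  transition_library(tibble::tibble(
    analyte_id = paste0("a", seq_along(rts)),
    q1_mz = 100 + seq_along(rts),
    q3_mz = 50 + seq_along(rts),
    polarity = pol,
    rt_min = rts
  ), run_length_min = 45)
}

# n transitions all eluting at the same RT, mixed or single polarity.
concurrent_library <- function(n, rt = 17, both_polarities = TRUE) {
  transition_library(tibble::tibble(
    analyte_id = sprintf("c%03d", seq_len(n)),
    q1_mz = 100 + seq_len(n),
    q3_mz = 50 + seq_len(n),
    polarity = if (both_polarities) rep(c("positive", "negative"),
                                        length.out = n)
               else rep("positive", n),
    rt_min = rep(rt, n)
  ), run_length_min = 45)
}

# Planted case/control cohort: 8 informative analytes among noise.
planted_cohort <- function(n_noise = 600, n_per_group = 20, log2fc = 1,
                           seed = 1) {
  lib <- generate_transition_library(
    n_analytes = n_noise + 8, n_internal_standards = 0, seed = 11
  )
  planted <- setNames(rep(c(log2fc, -log2fc), 4), lib$analyte_id[1:8])
  des <- study_design("case_control",
                      groups = c(control = n_per_group, case = n_per_group),
                      planted_effects = planted)
  st <- generate_study(lib, des, noise_spec(seed = seed))
  xy <- log2_cohort(st, c("control", "case"))
  list(X = xy$X, y = xy$y, planted = names(planted), library = lib)
}

# Pure-noise cohort for null-calibration checks.
null_cohort <- function(n_analytes = 30, n_per_group = 10, seed = 1) {
  lib <- generate_transition_library(n_analytes = n_analytes,
                                     n_internal_standards = 0, seed = 3)
  des <- study_design("case_control",
                      groups = c(control = n_per_group, case = n_per_group))
  st <- generate_study(lib, des, noise_spec(seed = seed))
  log2_cohort(st, c("control", "case"))
}
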