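#' Noise specification for synthetic studies
#'
#' Within-day (`cv_intra`) and between-day (`cv_inter`) coefficients of
#' variation of peak area, as fractions. Defaults are the control-pool values
#' of a validated plasma method: 7.4% within-day and 9.5% between-day,
#' combining in quadrature to 12% total.
#'
#' @param cv_intra Within-day CV as a fraction.
#' @param cv_inter Between-day CV as a fraction.
#' @param seed Default integer seed used by [generate_study()].
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cv_intra = 0.074, cv_inter = 0.095, seed = 1) {
  check_number(cv_intra, "cv_intra", lower = 0)
  check_number(cv_inter, "cv_inter", lower = 0)
  structure(list(cv_intra = cv_intra, cv_inter = cv_inter, seed = seed),
            class = "noise_spec")
}

#' Study design for synthetic peak-area matrices
#'
#' Describes one of the validation study layouts: `"precision"` (balanced
#' replicates-by-days per pool), `"linearity"` (admixtures of two pools at
#' known mixing fractions), `"carryover"` (alternating upper-limit-of-
#' quantification injections and blanks), `"tube"` (parallel collection-tube
#' groups), `"case_control"` (two clinical groups) and `"concordance"`
#' (the same case/control cohort measured in two runs with instrument-
#' specific gains).
#'
#' @param kind Design kind.
#' @param n_days Number of days/batches (precision).
#' @param n_reps_per_day Replicates per day (precision), duplicates per
#'   admixture point (linearity), ULOQ/blank pairs (carryover), or samples
#'   per tube (tube).
#' @param mix_fractions Case-pool fractions of the admixture series.
#' @param groups Named integer vector of group sizes (case_control,
#'   concordance) or character vector of pool labels (precision). The first
#'   group is the reference.
#' @param planted_effects Named numeric vector of log2 fold changes applied
#'   to non-reference groups (and defining the case pool of linearity
#'   designs).
#' @param tube_effects Data frame with columns `tube`, `chem_class`,
#'   `factor`: multiplicative detection factors relative to the reference
#'   tube (the first level of `tubes`).
#' @param tubes Tube types of a `"tube"` design; the first is the reference.
#' @param carryover_fraction_mean Mean proportional carryover of blanks after
#'   a ULOQ injection (default 0.75%).
#' @param carryover_sdlog Log-space SD of the per-analyte carryover fraction;
#'   fractions are truncated at 4%.
#' @param uloq_factor ULOQ concentration as a multiple of baseline.
#' @param gain_sdlog Log-space SD of the per-analyte, per-run gain of a
#'   concordance design (instrument-to-instrument response spread).
#' @param rerun_cv Extra per-sample measurement CV of each run in a
#'   concordance design, emulating the repeatability loss of re-analyzing
#'   long-stored aliquots on a different instrument; calibrated to the
#'   cross-run z-score concordance regime of a real method transfer.
#' @param baseline_sdlog Log-space SD of the between-analyte baseline
#'   abundance distribution.
#' @return A list of class `study_design`.
#' @export
study_design <- function(kind = c("precision", "linearity", "carryover",
                                  "tube", "case_control", "concordance"),
                         n_days = 5, n_reps_per_day = 5,
                         mix_fractions = c(1, 0.75, 0.5, 0.25, 0),
                         groups = NULL,
                         planted_effects = NULL,
                         tube_effects = NULL,
                         tubes = c("Li-heparin", "Na-heparin", "K2-EDTA", "SST"),
                         carryover_fraction_mean = 0.0075,
                         carryover_sdlog = 0.9,
                         uloq_factor = 10,
                         gain_sdlog = 0.28,
                         rerun_cv = 0.35,
                         baseline_sdlog = 1.2) {
  kind <- match.arg(kind)
  check_number(n_days, "n_days", lower = 1)
  check_number(n_reps_per_day, "n_reps_per_day", lower = 1)
  if (any(mix_fractions < 0 | mix_fractions > 1)) {
    stop_mrmqc("mix_fractions must lie in [0, 1].", "mrmqc_validation_error")
  }
  if (!is.null(planted_effects)) {
    if (is.null(names(planted_effects)) || !all(is.finite(planted_effects))) {
      stop_mrmqc("planted_effects must be a named vector of finite log2 fold changes.",
                 "mrmqc_validation_error")
    }
  }
  if (is.null(groups)) {
    groups <- switch(kind,
      precision = c("control_pool", "cfs_pool"),
      case_control = , concordance = c(control = 18, case = 21),
      NULL
    )
  }
  structure(list(
    kind = kind, n_days = n_days, n_reps_per_day = n_reps_per_day,
    mix_fractions = mix_fractions, groups = groups,
    planted_effects = planted_effects, tube_effects = tube_effects,
    tubes = tubes, carryover_fraction_mean = carryover_fraction_mean,
    carryover_sdlog = carryover_sdlog, uloq_factor = uloq_factor,
    gain_sdlog = gain_sdlog, rerun_cv = rerun_cv,
    baseline_sdlog = baseline_sdlog
  ), class = "study_design")
}

# Lognormal multiplicative factor with unit mean and linear-space CV `cv`.
.ln_sdlog <- function(cv) sqrt(log(1 + cv^2))
.rln_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sl <- .ln_sdlog(cv)
  rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

# Day effect for one group: per (analyte, day) factor whose log is the sum of
# a day-shared component and a per-analyte jitter, each carrying half the
# between-day log-variance. Returns an n_analytes x n_days matrix.
.day_effects <- function(n_analytes, n_days, cv_inter) {
  if (cv_inter <= 0) return(matrix(1, n_analytes, n_days))
  sl2 <- .ln_sdlog(cv_inter)^2
  shared <- rnorm(n_days, 0, sqrt(sl2 / 2))
  jitter <- matrix(rnorm(n_analytes * n_days, 0, sqrt(sl2 / 2)),
                   n_analytes, n_days)
  exp(sweep(jitter, 2, shared, `+`) - sl2 / 2)
}

#' Generate a synthetic study as a peak-area matrix
#'
#' Draws per-analyte baseline abundances from a lognormal distribution and
#' composes observed areas multiplicatively:
#' `area = baseline x day effect x replicate effect x design effects`,
#' where the day effect has between-day CV `cv_inter` (half of its
#' log-variance shared across the analytes of a sample) and the replicate
#' effect has within-day CV `cv_intra`. Design effects depend on the kind:
#' group log2 fold changes, admixture interpolation
#' `baseline*(1-f) + case_level*f`, tube-by-class detection factors,
#' per-run instrument gains, or proportional carryover of the immediately
#' preceding ULOQ injection into a blank.
#'
#' @param library A [transition_library()].
#' @param design A [study_design()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed; defaults to `noise$seed`.
#' @return An [area_matrix()] whose `sample_meta` columns reflect the design.
#' @export
generate_study <- function(library, design, noise = noise_spec(),
                           seed = noise$seed) {
  stopifnot(inherits(library, "transition_library"),
            inherits(design, "study_design"),
            inherits(noise, "noise_spec"))
  ids <- library$analyte_id
  if (!is.null(design$planted_effects)) {
    unknown <- setdiff(names(design$planted_effects), ids)
    if (length(unknown) > 0) {
      stop_mrmqc(paste0("planted_effects name unknown analyte(s): ",
                        paste(head(unknown, 5), collapse = ", ")),
                 "mrmqc_validation_error")
    }
  }
  with_seed(seed, {
    n <- length(ids)
    baseline <- rlnorm(n, meanlog = log(1e6), sdlog = design$baseline_sdlog)
    names(baseline) <- ids
    fc <- setNames(rep(0, n), ids)
    if (!is.null(design$planted_effects)) {
      fc[names(design$planted_effects)] <- design$planted_effects
    }
    case_level <- baseline * 2^fc

    out <- switch(design$kind,
      precision = .gen_precision(ids, baseline, case_level, design, noise),
      linearity = .gen_linearity(ids, baseline, case_level, design, noise),
      carryover = .gen_carryover(ids, baseline, design, noise),
      tube = .gen_tube(library, baseline, design, noise),
      case_control = .gen_case_control(ids, baseline, case_level, design, noise),
      concordance = .gen_concordance(ids, baseline, case_level, design, noise)
    )
    area_matrix(out, analytes = ids)
  })
}

.new_rows <- function(ids, meta, expected, noise_cv) {
  areas <- expected * .rln_factor(length(expected), noise_cv)
  vals <- as.list(setNames(areas, ids))
  dplyr::bind_cols(as_tibble(meta), as_tibble(vals))
}

.gen_precision <- function(ids, baseline, case_level, design, noise) {
  pools <- design$groups
  ref <- pools[1]
  rows <- list()
  for (pool in pools) {
    level <- if (pool == ref) baseline else case_level
    day_fx <- .day_effects(length(ids), design$n_days, noise$cv_inter)
    for (d in seq_len(design$n_days)) {
      for (r in seq_len(design$n_reps_per_day)) {
        rows[[length(rows) + 1]] <- .new_rows(
          ids,
          list(sample_id = sprintf("%s_d%02d_r%02d", pool, d, r),
               group = pool, day = d, replicate = r),
          level * day_fx[, d], noise$cv_intra
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

.gen_linearity <- function(ids, baseline, case_level, design, noise) {
  if (length(unique(design$mix_fractions)) < 3) {
    stop_mrmqc("A linearity design needs at least 3 distinct mix fractions.",
               "mrmqc_validation_error")
  }
  rows <- list()
  i <- 0
  for (f in design$mix_fractions) {
    expected <- baseline * (1 - f) + case_level * f
    for (r in seq_len(design$n_reps_per_day)) {
      i <- i + 1
      # admixture points are injected within a single batch, so only the
      # within-day CV applies
      rows[[i]] <- .new_rows(
        ids,
        list(sample_id = sprintf("mix%03d_r%02d", round(100 * f), r),
             group = "admixture", replicate = r, mix_fraction = f),
        expected, noise$cv_intra
      )
    }
  }
  dplyr::bind_rows(rows)
}

.gen_carryover <- function(ids, baseline, design, noise) {
  n <- length(ids)
  sl <- design$carryover_sdlog
  cap <- 0.04
  # location chosen so the mean AFTER truncation at the 4% ceiling equals
  # carryover_fraction_mean: E[X | X <= cap] for lognormal(mu, sl) is
  # exp(mu + sl^2/2) * pnorm((log(cap) - mu - sl^2)/sl) / pnorm((log(cap) - mu)/sl)
  trunc_mean <- function(mu) {
    exp(mu + sl^2 / 2) * pnorm((log(cap) - mu - sl^2) / sl) /
      pnorm((log(cap) - mu) / sl)
  }
  target <- design$carryover_fraction_mean
  mu <- stats::uniroot(function(m) trunc_mean(m) - target,
                       lower = log(target) - 3, upper = log(cap))$root
  frac <- rlnorm(n, mu, sl)
  # proportional carryover never exceeds 4% of the ULOQ signal
  while (any(frac > cap)) {
    hi <- frac > cap
    frac[hi] <- rlnorm(sum(hi), mu, sl)
  }
  rows <- list()
  for (r in seq_len(design$n_reps_per_day)) {
    uloq_area <- baseline * design$uloq_factor *
      .rln_factor(n, noise$cv_intra)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(sample_id = sprintf("uloq_%02d", r), group = "uloq",
             replicate = r, role = "uloq"),
      as_tibble(as.list(setNames(uloq_area, ids)))
    )
    blank_area <- frac * uloq_area   # memory of the preceding injection only
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(sample_id = sprintf("blank_%02d", r), group = "blank",
             replicate = r, role = "blank"),
      as_tibble(as.list(setNames(blank_area, ids)))
    )
  }
  dplyr::bind_rows(rows)
}

.gen_tube <- function(library, baseline, design, noise) {
  ids <- library$analyte_id
  rows <- list()
  for (tb in design$tubes) {
    fac <- rep(1, length(ids))
    if (!is.null(design$tube_effects)) {
      te <- design$tube_effects[design$tube_effects$tube == tb, , drop = FALSE]
      if (nrow(te) > 0) {
        for (k in seq_len(nrow(te))) {
          hit <- library$chem_class == te$chem_class[k]
          fac[hit] <- fac[hit] * te$factor[k]
        }
      }
    }
    for (r in seq_len(design$n_reps_per_day)) {
      rows[[length(rows) + 1]] <- .new_rows(
        ids,
        list(sample_id = sprintf("%s_r%02d", gsub("[^A-Za-z0-9]", "", tb), r),
             group = tb, tube = tb, replicate = r),
        baseline * fac, sqrt(noise$cv_intra^2 + noise$cv_inter^2)
      )
    }
  }
  dplyr::bind_rows(rows)
}

.gen_case_control <- function(ids, baseline, case_level, design, noise,
                              run_id = NA_character_, gain = 1,
                              subject_fx = NULL) {
  sizes <- design$groups
  if (is.null(names(sizes))) {
    stop_mrmqc("case_control designs need named group sizes.",
               "mrmqc_validation_error")
  }
  ref <- names(sizes)[1]
  cv_meas <- sqrt(noise$cv_intra^2 + noise$cv_inter^2)
  rows <- list()
  for (g in names(sizes)) {
    level <- if (g == ref) baseline else case_level
    for (s in seq_len(sizes[[g]])) {
      subj <- if (is.null(subject_fx)) {
        .rln_factor(length(ids), 0.5)   # biological between-subject spread
      } else subject_fx[[g]][[s]]
      rows[[length(rows) + 1]] <- .new_rows(
        ids,
        list(sample_id = paste0(g, "_", sprintf("%02d", s),
                                ifelse(is.na(run_id), "", paste0("_", run_id))),
             group = g, run_id = run_id),
        level * subj * gain, cv_meas
      )
    }
  }
  dplyr::bind_rows(rows)
}

.gen_concordance <- function(ids, baseline, case_level, design, noise) {
  sizes <- design$groups
  # subject effects shared between runs: the same aliquots are re-measured
  subject_fx <- lapply(setNames(names(sizes), names(sizes)), function(g) {
    lapply(seq_len(sizes[[g]]), function(s) .rln_factor(length(ids), 0.5))
  })
  # each run carries its own per-sample measurement error: the analytical
  # noise plus the repeatability loss of re-analyzing stored aliquots
  noise_run <- noise_spec(
    cv_intra = sqrt(noise$cv_intra^2 + design$rerun_cv^2),
    cv_inter = noise$cv_inter, seed = noise$seed
  )
  runs <- lapply(c("run_a", "run_b"), function(rid) {
    gain <- .rln_factor(length(ids), sqrt(exp(design$gain_sdlog^2) - 1))
    .gen_case_control(ids, baseline, case_level, design, noise_run,
                      run_id = rid, gain = gain, subject_fx = subject_fx)
  })
  dplyr::bind_rows(runs)
}

#' Generate per-injection retention times for a precision design
#'
#' Applies small multiplicative jitter to the library's nominal retention
#' times with the given within- and between-day CVs (defaults 0.11% and
#' 0.14%, typical of a stable HILIC gradient).
#'
#' @param library A [transition_library()].
#' @param n_days,n_reps_per_day Balanced design dimensions.
#' @param cv_intra,cv_inter RT CVs as fractions.
#' @param seed Integer seed.
#' @return A long tibble with columns `analyte_id`, `day`, `replicate`,
#'   `rt_min`.
#' @export
generate_rt_study <- function(library, n_days = 5, n_reps_per_day = 5,
                              cv_intra = 0.0011, cv_inter = 0.0014, seed = 1) {
  stopifnot(inherits(library, "transition_library"))
  ids <- library$analyte_id
  nominal <- library$rt_min
  with_seed(seed, {
    day_fx <- .day_effects(length(ids), n_days, cv_inter)
    rows <- list()
    for (d in seq_len(n_days)) {
      for (r in seq_len(n_reps_per_day)) {
        rows[[length(rows) + 1]] <- tibble(
          analyte_id = ids, day = d, replicate = r,
          rt_min = nominal * day_fx[, d] * .rln_factor(length(ids), cv_intra)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
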