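# Balanced one-way random-effects decomposition, value ~ day, one analyte.
# Returns NULL when the design is unbalanced or the analyte has missing data.
.anova_components <- function(value, day) {
  ok <- is.finite(value)
  if (!all(ok)) return(NULL)
  tab <- table(day)
  n_days <- length(tab)
  n_rep <- unique(as.integer(tab))
  if (length(n_rep) != 1) return(NULL)
  grand <- mean(value)
  day_means <- tapply(value, day, mean)
  ms_within <- if (n_rep > 1) {
    sum((value - day_means[as.character(day)])^2) / (n_days * (n_rep - 1))
  } else 0
  ms_between <- n_rep * sum((day_means - grand)^2) / (n_days - 1)
  var_inter <- max(0, (ms_between - ms_within) / n_rep)
  list(grand_mean = grand, ms_within = ms_within, ms_between = ms_between,
       var_intra = ms_within, var_inter = var_inter,
       n_days = n_days, n_reps = n_rep)
}

.precision_from_long <- function(long, value_col) {
  per <- long |>
    dplyr::group_by(.data$analyte_id) |>
    dplyr::group_modify(function(d, key) {
      comp <- .anova_components(d[[value_col]], d$day)
      if (is.null(comp)) {
        stop_mrmqc(
          "Unbalanced design or missing values; the precision estimator requires equal replicates per day.",
          "mrmqc_design_error"
        )
      }
      if (!is.finite(comp$grand_mean) || comp$grand_mean == 0) {
        return(tibble(grand_mean = comp$grand_mean, cv_intra = NA_real_,
                      cv_inter = NA_real_, cv_total = NA_real_,
                      flag = "zero mean"))
      }
      cv_i <- 100 * sqrt(comp$var_intra) / comp$grand_mean
      cv_b <- 100 * sqrt(comp$var_inter) / comp$grand_mean
      tibble(grand_mean = comp$grand_mean, cv_intra = cv_i, cv_inter = cv_b,
             cv_total = sqrt(cv_i^2 + cv_b^2), flag = "ok")
    }) |>
    dplyr::ungroup()

  usable <- per[per$flag == "ok", ]
  panel <- tibble(
    metric = c("cv_intra", "cv_inter", "cv_total"),
    mean = vapply(c("cv_intra", "cv_inter", "cv_total"),
                  function(m) mean(usable[[m]]), numeric(1)),
    ci95_lo = vapply(c("cv_intra", "cv_inter", "cv_total"),
                     function(m) unname(quantile(usable[[m]], 0.025)), numeric(1)),
    ci95_hi = vapply(c("cv_intra", "cv_inter", "cv_total"),
                     function(m) unname(quantile(usable[[m]], 0.975)), numeric(1))
  )
  days <- sort(unique(long$day))
  n_reps <- nrow(long[long$analyte_id == long$analyte_id[1] &
                        long$day == days[1], ])
  structure(list(per_analyte = per, panel = panel,
                 design = c(n_days = length(days), n_reps = n_reps)),
            class = "precision_result")
}

#' Variance-component precision analysis
#'
#' The balanced-precision estimator for a replicates-within-days design:
#' per analyte, a one-way random-effects ANOVA with day as the grouping
#' factor gives the within-day variance (`MS_within`) and the between-day
#' variance component `max(0, (MS_between - MS_within) / n_reps)`.
#' Coefficients of variation on the linear area scale are
#' `CV_intra = sqrt(MS_within)/mean`, `CV_inter = sqrt(component)/mean`, and
#' the quadrature total `CV_total = sqrt(CV_intra^2 + CV_inter^2)` — so the
#' identity `CV_total^2 = CV_intra^2 + CV_inter^2` holds exactly for every
#' analyte. Panel summaries average over analytes; the panel 95% interval is
#' the 2.5-97.5 percentile spread across analytes.
#'
#' @param x An [area_matrix()] from a precision design.
#' @param pool Group label of the pool to analyze.
#' @param analyte_subset Optional character vector restricting the panel
#'   summary (e.g. a representative-metabolite subset); default all.
#' @return A `precision_result`: list with `per_analyte` tibble (CVs in
#'   percent), `panel` tibble and the `design` dimensions. Analytes with a
#'   zero grand mean are flagged and excluded from panel means.
#' @export
variance_components <- function(x, pool, analyte_subset = NULL) {
  stopifnot(inherits(x, "area_matrix"))
  sel <- x[x$group == pool & !is.na(x$group), ]
  if (nrow(sel) == 0) {
    stop_mrmqc(paste0("No samples in pool: ", pool), "mrmqc_validation_error")
  }
  if (length(unique(sel$day)) < 2) {
    stop_mrmqc("Need at least 2 days.", "mrmqc_design_error")
  }
  long <- area_long(sel)[, c("analyte_id", "day", "area")]
  if (!is.null(analyte_subset)) {
    long <- long[long$analyte_id %in% analyte_subset, ]
  }
  res <- .precision_from_long(long, "area")
  res$pool <- pool
  res
}

#' Retention-time reproducibility
#'
#' Applies the balanced variance-component estimator of
#' [variance_components()] to per-injection retention times. CVs are scale
#' invariant, so minutes or seconds give identical results.
#'
#' @param rt_table Long tibble with columns `analyte_id`, `day`,
#'   `replicate`, `rt_min`.
#' @return A `precision_result` of RT CVs in percent.
#' @export
rt_reproducibility <- function(rt_table) {
  rt_table <- as_tibble(rt_table)
  need <- c("analyte_id", "day", "rt_min")
  missing_cols <- setdiff(need, names(rt_table))
  if (length(missing_cols) > 0) {
    stop_mrmqc(paste0("rt_table needs column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "mrmqc_schema_error")
  }
  if (length(unique(rt_table$day)) < 2) {
    stop_mrmqc("Need at least 2 days.", "mrmqc_design_error")
  }
  .precision_from_long(rt_table, "rt_min")
}

#' @export
print.precision_result <- function(x, ...) {
  p <- x$panel
  cat(sprintf(
    "<precision_result> %d analytes, %d days x %d reps\n  panel mean CV_intra %.2f%%, CV_inter %.2f%%, CV_total %.2f%%\n",
    nrow(x$per_analyte), x$design["n_days"], x$design["n_reps"],
    p$mean[p$metric == "cv_intra"], p$mean[p$metric == "cv_inter"],
    p$mean[p$metric == "cv_total"]
  ))
  invisible(x)
}

#' Combine within- and between-batch CVs in quadrature
#'
#' `CV_total = sqrt(CV_intra^2 + CV_inter^2)` — the arithmetic identity by
#' which a 7.4% within-day and 9.5% between-day CV combine to a 12% total.
#'
#' @param cv_intra,cv_inter CVs, in any common unit (percent or fraction).
#' @return Total CV in the same unit.
#' @export
cv_total <- function(cv_intra, cv_inter) sqrt(cv_intra^2 + cv_inter^2)
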