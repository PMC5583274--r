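# broom-style tidiers for the package's result objects.

#' @export
tidy.precision_result <- function(x, ...) x$per_analyte

#' @export
glance.precision_result <- function(x, ...) {
  p <- x$panel
  tibble(
    n_analytes = sum(x$per_analyte$flag == "ok"),
    n_days = unname(x$design["n_days"]),
    n_reps = unname(x$design["n_reps"]),
    mean_cv_intra = p$mean[p$metric == "cv_intra"],
    mean_cv_inter = p$mean[p$metric == "cv_inter"],
    mean_cv_total = p$mean[p$metric == "cv_total"]
  )
}

#' @export
tidy.linearity_summary <- function(x, ...) x$per_analyte

#' @export
glance.linearity_summary <- function(x, ...) {
  f <- x$fraction_r_above
  tibble(
    n_analytes = sum(!is.na(x$per_analyte$r)),
    n_excluded = length(x$excluded),
    median_r = median(x$per_analyte$r, na.rm = TRUE),
    fraction_r_gt_0.9 = f$fraction[f$threshold == 0.9][1]
  )
}

#' @export
tidy.carryover_summary <- function(x, ...) x$per_analyte

#' @export
glance.carryover_summary <- function(x, ...) {
  f <- x$fraction_below
  tibble(
    n_analytes = sum(x$per_analyte$flag == "ok"),
    mean_pct = x$mean_pct,
    max_pct = x$max_pct,
    fraction_below_2pct = f$fraction[f$threshold_pct == 2][1],
    fraction_below_4pct = f$fraction[f$threshold_pct == 4][1]
  )
}

#' @export
tidy.tube_comparison <- function(x, ...) x$per_analyte

#' @export
glance.tube_comparison <- function(x, ...) {
  tibble(
    reference_tube = x$reference_tube,
    n_contrasts = length(unique(x$per_analyte$tube)),
    n_significant = sum(x$per_analyte$p_adj < 0.05, na.rm = TRUE)
  )
}

#' @export
tidy.concordance_report <- function(x, ...) x$r2_by_group

#' @export
glance.concordance_report <- function(x, ...) {
  tibble(
    z_r2 = x$z_r2, pathway_r2 = x$pathway_r2, z_filter = x$z_filter,
    n_analytes_compared = x$n_analytes_compared,
    n_z_compared = x$n_z_compared
  )
}

#' @export
tidy.plsda <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_components), function(k) {
    tibble(component = k, analyte_id = x$feature_names,
           loading = x$loadings[, k])
  })
}

#' @export
glance.plsda <- function(x, ...) {
  tibble(n_components = x$n_components,
         explained_variance_total = sum(x$explained_variance))
}

#' @export
augment.plsda <- function(x, data = NULL, ...) {
  out <- as_tibble(x$scores, .name_repair = ~ paste0(".comp", seq_along(.x)))
  if (!is.null(data)) out <- dplyr::bind_cols(as_tibble(data), out)
  out
}

#' @export
tidy.rdcv_result <- function(x, ...) {
  tibble(fold = seq_along(x$aurocs), auroc = x$aurocs)
}

#' @export
glance.rdcv_result <- function(x, ...) {
  tibble(
    median_auroc = median(x$aurocs),
    iqr_lo = unname(quantile(x$aurocs, 0.25)),
    iqr_hi = unname(quantile(x$aurocs, 0.75)),
    outer_folds = x$outer_folds, repeats = x$repeats,
    target_size = x$target_size
  )
}

#' @export
tidy.classifier_report <- function(x, ...) {
  tibble(analyte_id = x$selected_panel)
}

#' @export
glance.classifier_report <- function(x, ...) {
  tibble(
    panel_size = length(x$selected_panel),
    auroc = x$auroc,
    auroc_ci95_lo = x$auroc_ci95[1],
    auroc_ci95_hi = x$auroc_ci95[2],
    rdcv_median_auroc = median(x$rdcv_aurocs),
    permutation_p = x$permutation_p,
    n_cases = x$n_cases, n_controls = x$n_controls
  )
}
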