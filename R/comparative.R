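#' Control-referenced z-scores of log2 areas
#'
#' Standardizes each sample's log2 peak area against the reference
#' (control) group: `z = (log2 area - mean_ref) / sd_ref`, per analyte. At
#' `level = "group"` the z-score of each group's mean log2 area is returned
#' instead (the group-level z used for cross-run comparisons). z-scores are
#' invariant to any per-analyte multiplicative gain applied to all samples
#' of a run, which is what makes them comparable across instruments.
#'
#' @param x An [area_matrix()].
#' @param reference_group Label of the reference group (needs >= 3
#'   samples).
#' @param level `"sample"` or `"group"`.
#' @return A long tibble: `analyte_id`, `z`, plus `sample_id`/`group`
#'   (sample level) or `group` (group level). Analytes with zero reference
#'   SD are excluded.
#' @export
zscores <- function(x, reference_group, level = c("sample", "group")) {
  stopifnot(inherits(x, "area_matrix"))
  level <- match.arg(level)
  ref <- x[x$group == reference_group & !is.na(x$group), ]
  if (nrow(ref) < 3) {
    stop_mrmqc("Reference group needs at least 3 samples.",
               "mrmqc_validation_error")
  }
  vals <- log2_area(area_values(x))
  rvals <- vals[x$sample_id %in% ref$sample_id, , drop = FALSE]
  mu <- colMeans(rvals, na.rm = TRUE)
  sg <- apply(rvals, 2, sd, na.rm = TRUE)
  keep <- is.finite(mu) & is.finite(sg) & sg > 0
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep]), 2, sg[keep], `/`)
  if (level == "sample") {
    out <- as_tibble(z)
    out$sample_id <- x$sample_id
    out$group <- x$group
    tidyr::pivot_longer(out, cols = -c("sample_id", "group"),
                        names_to = "analyte_id", values_to = "z")
  } else {
    groups <- split(seq_len(nrow(x)), x$group)
    purrr::map_dfr(names(groups), function(g) {
      gm <- colMeans(vals[groups[[g]], keep, drop = FALSE], na.rm = TRUE)
      tibble(group = g, analyte_id = names(gm),
             z = (gm - mu[keep]) / sg[keep])
    })
  }
}

# Pearson r^2 with pairwise-complete values; internal.
.r2 <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Inter-run concordance of a case/control experiment
#'
#' Quantifies how reproducibly two runs (different instrument, tester or
#' time) measure the same cohort: per group, the squared Pearson
#' correlation of per-analyte mean log2 areas across runs; the squared
#' correlation of group-level z-scores restricted to analytes responding in
#' the reference run (`|z| >` the filter); and, when a pathway membership
#' is supplied, the squared correlation of pathway impact scores. Analytes
#' missing in either run are dropped and counted.
#'
#' @param run_a,run_b [area_matrix()] objects sharing analytes and group
#'   labels.
#' @param reference_group Control-group label used for z-scores.
#' @param z_filter Absolute z-score threshold for the z concordance
#'   (default 0.8).
#' @param case_group Non-reference group whose z-scores are compared;
#'   default the first non-reference group.
#' @param membership Optional pathway membership (see [pathway_impact()]).
#' @return A `concordance_report`: list with `r2_by_group` tibble, `z_r2`,
#'   `pathway_r2` (NA without membership), `n_analytes_compared`,
#'   `n_z_compared`.
#' @export
run_concordance <- function(run_a, run_b, reference_group, z_filter = 0.8,
                            case_group = NULL, membership = NULL) {
  stopifnot(inherits(run_a, "area_matrix"), inherits(run_b, "area_matrix"))
  shared <- intersect(analytes(run_a), analytes(run_b))
  if (length(shared) < 10) {
    stop_mrmqc("Runs must share at least 10 analytes.", "mrmqc_validation_error")
  }
  groups <- intersect(unique(run_a$group), unique(run_b$group))
  if (length(groups) == 0) {
    stop_mrmqc("Runs share no group labels.", "mrmqc_validation_error")
  }
  mean_log2 <- function(run, g) {
    vals <- log2_area(area_values(run))[run$group == g, shared, drop = FALSE]
    colMeans(vals, na.rm = TRUE)
  }
  r2_by_group <- purrr::map_dfr(groups, function(g) {
    a <- mean_log2(run_a, g); b <- mean_log2(run_b, g)
    tibble(group = g, r2 = .r2(a, b),
           n = sum(is.finite(a) & is.finite(b)))
  })

  za <- zscores(run_a, reference_group, level = "group")
  zb <- zscores(run_b, reference_group, level = "group")
  if (is.null(case_group)) {
    case_group <- setdiff(groups, reference_group)[1]
  }
  za <- za[za$group == case_group & za$analyte_id %in% shared, ]
  zb <- zb[zb$group == case_group & zb$analyte_id %in% shared, ]
  m <- dplyr::inner_join(za, zb, by = c("group", "analyte_id"),
                         suffix = c("_a", "_b"))
  responders <- m[abs(m$z_a) > z_filter & is.finite(m$z_a), ]
  z_r2 <- .r2(responders$z_a, responders$z_b)

  pathway_r2 <- NA_real_
  if (!is.null(membership)) {
    pa <- pathway_impact(za[, c("analyte_id", "z")], membership)
    pb <- pathway_impact(zb[, c("analyte_id", "z")], membership)
    pm <- dplyr::inner_join(pa, pb, by = "pathway", suffix = c("_a", "_b"))
    pathway_r2 <- .r2(pm$impact_a, pm$impact_b)
  }
  structure(list(
    r2_by_group = r2_by_group, z_r2 = z_r2, pathway_r2 = pathway_r2,
    z_filter = z_filter, case_group = case_group,
    n_analytes_compared = length(shared), n_z_compared = nrow(responders)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d shared analytes; log2 AUC r2: %s; z r2 (|z|>%g, n=%d): %.3f\n",
    x$n_analytes_compared,
    paste(sprintf("%s %.3f", x$r2_by_group$group, x$r2_by_group$r2),
          collapse = ", "),
    x$z_filter, x$n_z_compared, x$z_r2
  ))
  invisible(x)
}

#' Coverage-weighted pathway impact scores
#'
#' For each pathway, the mean absolute z-score over its measured members,
#' weighted by coverage:
#' `impact = mean(|z| of measured members) * (measured / total members)`.
#' A simple, reproducible roll-up that is monotone in each member's |z| and
#' comparable across runs.
#'
#' @param z A tibble with columns `analyte_id`, `z` (one row per analyte,
#'   e.g. group-level z-scores).
#' @param membership Tibble with columns `pathway`, `analyte_id`.
#' @param min_members Pathways with fewer total members are dropped.
#' @return A tibble: `pathway`, `impact`, `n_measured`, `n_total`.
#' @export
pathway_impact <- function(z, membership, min_members = 1) {
  z <- as_tibble(z)
  membership <- as_tibble(membership)
  stopifnot(all(c("analyte_id", "z") %in% names(z)),
            all(c("pathway", "analyte_id") %in% names(membership)))
  membership |>
    dplyr::group_by(.data$pathway) |>
    dplyr::group_modify(function(d, key) {
      n_total <- nrow(d)
      zm <- z$z[match(d$analyte_id, z$analyte_id)]
      zm <- zm[is.finite(zm)]
      tibble(impact = if (length(zm) == 0) NA_real_ else
               mean(abs(zm)) * length(zm) / n_total,
             n_measured = length(zm), n_total = n_total)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_total >= min_members, !is.na(.data$impact))
}

#' Blood-collection-tube comparison
#'
#' Per analyte, the log2 fold change of each tube type against the
#' reference tube and a Welch two-sample t-test on log2 areas, with
#' Benjamini-Hochberg adjustment across analytes within each tube contrast.
#' Chemical-class roll-ups (median log2 FC per class) flag systematic
#' artifacts such as nucleoside depletion in EDTA plasma.
#'
#' @param x An [area_matrix()] with `tube` metadata (>= 2 tube types, >= 3
#'   samples each).
#' @param reference_tube Reference tube label (conventionally Li-heparin).
#' @param chem_class Optional tibble `analyte_id`, `chem_class` enabling
#'   class-level summaries.
#' @return A `tube_comparison`: list with `per_analyte` tibble (`tube`,
#'   `analyte_id`, `log2_fc`, `p`, `p_adj`, `censored`) and `by_class`
#'   tibble (or NULL).
#' @export
tube_comparison <- function(x, reference_tube = "Li-heparin",
                            chem_class = NULL) {
  stopifnot(inherits(x, "area_matrix"))
  tubes <- unique(x$tube[!is.na(x$tube)])
  if (length(tubes) < 2) {
    stop_mrmqc("Need at least 2 tube types.", "mrmqc_validation_error")
  }
  if (!reference_tube %in% tubes) {
    stop_mrmqc(paste0("Reference tube not present: ", reference_tube),
               "mrmqc_validation_error")
  }
  sizes <- table(x$tube)
  if (any(sizes < 3)) {
    stop_mrmqc("Every tube type needs at least 3 samples.",
               "mrmqc_validation_error")
  }
  vals <- log2_area(area_values(x))
  ref_rows <- which(x$tube == reference_tube)
  per <- purrr::map_dfr(setdiff(tubes, reference_tube), function(tb) {
    rows <- which(x$tube == tb)
    res <- purrr::map_dfr(colnames(vals), function(a) {
      va <- vals[rows, a]; vr <- vals[ref_rows, a]
      va <- va[is.finite(va)]; vr <- vr[is.finite(vr)]
      if (length(va) < 2 || length(vr) < 2) {
        return(tibble(analyte_id = a, log2_fc = NA_real_, p = NA_real_,
                      censored = TRUE))
      }
      p <- if (sd(va) == 0 && sd(vr) == 0) {
        if (mean(va) == mean(vr)) 1 else 0
      } else t.test(va, vr)$p.value
      tibble(analyte_id = a, log2_fc = mean(va) - mean(vr), p = p,
             censored = FALSE)
    })
    res$p_adj <- p.adjust(res$p, method = "BH")
    res$tube <- tb
    res
  })
  by_class <- NULL
  if (!is.null(chem_class)) {
    by_class <- per |>
      dplyr::left_join(as_tibble(chem_class), by = "analyte_id") |>
      dplyr::filter(!is.na(.data$chem_class), !.data$censored) |>
      dplyr::group_by(.data$tube, .data$chem_class) |>
      dplyr::summarise(
        median_log2_fc = median(.data$log2_fc),
        n = dplyr::n(),
        n_significant = sum(.data$p_adj < 0.05),
        .groups = "drop"
      )
  }
  structure(list(per_analyte = per[, c("tube", "analyte_id", "log2_fc",
                                       "p", "p_adj", "censored")],
                 by_class = by_class, reference_tube = reference_tube),
            class = "tube_comparison")
}

#' @export
print.tube_comparison <- function(x, ...) {
  cat(sprintf(
    "<tube_comparison> %d contrasts vs %s; %d analyte tests, %d with FDR < 0.05\n",
    length(unique(x$per_analyte$tube)), x$reference_tube,
    nrow(x$per_analyte), sum(x$per_analyte$p_adj < 0.05, na.rm = TRUE)
  ))
  invisible(x)
}
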