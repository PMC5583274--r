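#' Admixture linearity analysis
#'
#' For each analyte, ordinary least squares of linear-scale peak area on the
#' admixture mixing fraction, plus the Pearson correlation coefficient. The
#' admixture design mixes two pools at known ratios, so an analyte with a
#' proportional response is affine in the mixing fraction; `r` above 0.9 is
#' the conventional pass threshold.
#'
#' @param x An [area_matrix()] with `mix_fraction` metadata (at least 3
#'   distinct fractions).
#' @param r_thresholds Thresholds at which to report the fraction of
#'   analytes with `r` above the threshold.
#' @return A `linearity_summary`: list with `per_analyte` tibble (`slope`,
#'   `intercept`, `r`), `fraction_r_above` tibble, `design_fractions`, and
#'   `excluded` (analytes with no usable data).
#' @export
linearity_fit <- function(x, r_thresholds = c(0.9, 0.95, 0.99)) {
  stopifnot(inherits(x, "area_matrix"))
  keep <- !is.na(x$mix_fraction)
  sel <- x[keep, ]
  fracs <- sort(unique(sel$mix_fraction))
  if (length(fracs) < 3) {
    stop_mrmqc("Need at least 3 distinct mix fractions.", "mrmqc_design_error")
  }
  f <- sel$mix_fraction
  per <- purrr::map_dfr(analytes(sel), function(a) {
    y <- sel[[a]]
    ok <- is.finite(y)
    if (sum(ok) < 3 || length(unique(f[ok])) < 3) {
      return(tibble(analyte_id = a, slope = NA_real_, intercept = NA_real_,
                    r = NA_real_))
    }
    fit <- lm(y[ok] ~ f[ok])
    r <- if (sd(y[ok]) == 0) 0 else cor(f[ok], y[ok])
    tibble(analyte_id = a, slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]), r = r)
  })
  excluded <- per$analyte_id[is.na(per$r)]
  usable <- per$r[!is.na(per$r)]
  frac_above <- tibble(
    threshold = sort(r_thresholds),
    fraction = vapply(sort(r_thresholds),
                      function(th) mean(usable > th), numeric(1))
  )
  structure(list(per_analyte = per, fraction_r_above = frac_above,
                 design_fractions = fracs, excluded = excluded),
            class = "linearity_summary")
}

#' @export
print.linearity_summary <- function(x, ...) {
  f90 <- x$fraction_r_above$fraction[x$fraction_r_above$threshold == 0.9]
  cat(sprintf(
    "<linearity_summary> %d analytes over fractions {%s}; %.0f%% with r > 0.90\n",
    nrow(x$per_analyte), paste(x$design_fractions, collapse = ", "),
    100 * if (length(f90)) f90 else NA
  ))
  invisible(x)
}

#' Carryover assessment from a ULOQ/blank injection sequence
#'
#' Carryover is the signal of the first blank injected immediately after a
#' sample at the upper limit of quantification (ULOQ), expressed as a
#' percentage of the ULOQ signal:
#' `carryover % = 100 * blank area / ULOQ area`, averaged over pairs.
#'
#' @param x An [area_matrix()] whose row order is the injection order and
#'   whose `role` metadata column marks each injection `"uloq"` or
#'   `"blank"`. Every blank must directly follow a ULOQ injection.
#' @param pct_thresholds Carryover percentages at which to report the
#'   fraction of analytes below the threshold.
#' @return A `carryover_summary`: list with `per_analyte` tibble
#'   (`carryover_pct`, `flag`), `mean_pct`, `max_pct` and `fraction_below`
#'   tibble. Analytes with a zero ULOQ area are flagged and excluded from
#'   the panel mean.
#' @export
carryover_assess <- function(x, pct_thresholds = c(2, 4)) {
  stopifnot(inherits(x, "area_matrix"))
  if (!"role" %in% names(x) || all(is.na(x$role))) {
    stop_mrmqc("Carryover assessment needs a `role` metadata column.",
               "mrmqc_schema_error")
  }
  roles <- x$role
  blanks <- which(roles == "blank")
  if (length(blanks) == 0) {
    stop_mrmqc("No blank injections in the sequence.", "mrmqc_design_error")
  }
  bad <- blanks[blanks == 1 | roles[pmax(1, blanks - 1)] != "uloq"]
  if (length(bad) > 0) {
    stop_mrmqc(
      paste0("Blank injection(s) not immediately preceded by a ULOQ injection at position(s): ",
             paste(bad, collapse = ", ")),
      "mrmqc_sequence_error"
    )
  }
  vals <- area_values(x)
  per <- purrr::map_dfr(colnames(vals), function(a) {
    uloq <- vals[blanks - 1, a]
    blank <- vals[blanks, a]
    ok <- is.finite(uloq) & uloq > 0 & is.finite(blank)
    if (!any(ok)) {
      return(tibble(analyte_id = a, carryover_pct = NA_real_,
                    flag = "zero ULOQ"))
    }
    tibble(analyte_id = a,
           carryover_pct = mean(100 * blank[ok] / uloq[ok]),
           flag = "ok")
  })
  usable <- per$carryover_pct[per$flag == "ok"]
  structure(list(
    per_analyte = per,
    mean_pct = mean(usable),
    max_pct = max(usable),
    fraction_below = tibble(
      threshold_pct = sort(pct_thresholds),
      fraction = vapply(sort(pct_thresholds),
                        function(th) mean(usable < th), numeric(1))
    ),
    n_pairs = length(blanks)
  ), class = "carryover_summary")
}

#' @export
print.carryover_summary <- function(x, ...) {
  cat(sprintf(
    "<carryover_summary> %d analytes, %d ULOQ/blank pairs: mean %.2f%%, max %.2f%%\n",
    nrow(x$per_analyte), x$n_pairs, x$mean_pct, x$max_pct
  ))
  invisible(x)
}
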