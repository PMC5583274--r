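# Rank-based AUROC: Mann-Whitney U / (n_case * n_control), ties at 0.5.
.auroc <- function(scores, y01) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC with stratified bootstrap confidence interval
#'
#' The area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic (ties count one half): the probability that a random case
#' outranks a random control. The 95% CI is a stratified percentile
#' bootstrap, resampling cases and controls separately.
#'
#' @param scores Per-sample risk scores (higher = more case-like).
#' @param y Binary labels; the second level is the case class.
#' @param n_boot Bootstrap replicates (0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `auroc`, `ci95_lo`, `ci95_hi`, `n_cases`,
#'   `n_controls`.
#' @export
roc_auc <- function(scores, y, n_boot = 2000, seed = 1) {
  cls <- .binary_labels(y)
  y01 <- cls$y01
  if (length(scores) != length(y01)) {
    stop_mrmqc("scores and y lengths disagree.", "mrmqc_validation_error")
  }
  if (sum(y01 == 1) == 0 || sum(y01 == 0) == 0) {
    stop_mrmqc("Both classes must be present.", "mrmqc_validation_error")
  }
  est <- .auroc(scores, y01)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    cases <- which(y01 == 1)
    controls <- which(y01 == 0)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i1 <- sample(cases, length(cases), replace = TRUE)
      i0 <- sample(controls, length(controls), replace = TRUE)
      idx <- c(i1, i0)
      .auroc(scores[idx], y01[idx])
    }, numeric(1)))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  tibble(auroc = est, ci95_lo = ci[1], ci95_hi = ci[2],
         n_cases = sum(y01 == 1), n_controls = sum(y01 == 0))
}

# Stratified k-fold assignment; returns an integer fold id per sample.
.stratified_folds <- function(y01, k) {
  folds <- integer(length(y01))
  for (cl in c(0, 1)) {
    idx <- sample(which(y01 == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Cross-validated AUROC of a PLS-DA discriminant on a feature subset,
# averaged over `repeats` random fold splits to stabilize small differences.
.cv_auroc <- function(X, y01, features, k = 5, repeats = 5) {
  one <- function() {
    folds <- .stratified_folds(y01, k)
    scores <- numeric(length(y01))
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y01[tr])) < 2) return(NA_real_)
      fit <- try(plsda_fit(X[tr, features, drop = FALSE], y01[tr],
                           n_components = 1), silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      scores[!tr] <- predict(fit, X[!tr, features, drop = FALSE])
    }
    .auroc(scores, y01)
  }
  mean(vapply(seq_len(repeats), function(i) one(), numeric(1)))
}

#' Select a biomarker panel
#'
#' Three-stage selection mirroring a random-forest-plus-wrapper workflow:
#' (1) analytes ranked by permutation importance from a random-forest
#' ensemble; (2) greedy forward selection among the top candidates,
#' adding at each step the analyte that maximizes stratified
#' cross-validated AUROC of a one-component PLS-DA discriminant, until
#' `target_size` analytes are included; (3) backward elimination, dropping
#' any analyte whose removal does not reduce the CV AUROC by more than
#' `tolerance`. Deterministic under `seed`.
#'
#' @param X Samples x analytes matrix (log2 areas recommended).
#' @param y Binary labels (each class needs >= 5 samples).
#' @param target_size Panel size reached by forward selection; if
#'   `target_size >= ncol(X)` all analytes are returned.
#' @param seed Integer seed.
#' @param n_candidates Number of top-ranked analytes entering the wrapper.
#' @param cv_folds Folds of the selection CV (each CV AUROC is averaged
#'   over `cv_repeats` random fold splits).
#' @param cv_repeats Fold-split repeats of the selection CV.
#' @param tolerance Maximum CV-AUROC loss tolerated when eliminating an
#'   analyte (an analyte is removed while `auroc_without >= auroc_with -
#'   tolerance`). The default -0.005 is deliberately conservative: removal
#'   must improve the averaged CV AUROC, so elimination targets analytes
#'   that actively hurt generalization rather than members that are merely
#'   redundant with the rest of the panel.
#' @param num_trees Trees of the ranking forest.
#' @return Character vector of selected analyte names.
#' @export
select_panel <- function(X, y, target_size = 8, seed = 1, n_candidates = 25,
                         cv_folds = 5, cv_repeats = 5, tolerance = -0.005,
                         num_trees = 500) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cls <- .binary_labels(y)
  y01 <- cls$y01
  if (min(table(y01)) < 5) {
    stop_mrmqc("Each class needs at least 5 samples.", "mrmqc_validation_error")
  }
  if (any(!is.finite(X))) {
    stop_mrmqc("X must be finite (impute or drop missing analytes first).",
               "mrmqc_validation_error")
  }
  if (target_size >= ncol(X)) return(colnames(X))

  with_seed(seed, {
    rf <- ranger::ranger(
      x = as.data.frame(X), y = factor(y01),
      importance = "permutation", num.trees = num_trees,
      seed = sample.int(.Machine$integer.max, 1)
    )
    ranking <- names(sort(rf$variable.importance, decreasing = TRUE))
    candidates <- head(ranking, n_candidates)

    panel <- character(0)
    pool <- candidates
    while (length(panel) < target_size && length(pool) > 0) {
      gains <- vapply(pool, function(a) {
        .cv_auroc(X, y01, c(panel, a), k = cv_folds, repeats = cv_repeats)
      }, numeric(1))
      if (all(is.na(gains))) break
      # candidates within CV noise of the best gain are tied; break the
      # tie by the forest importance ranking
      tied <- which(gains >= max(gains, na.rm = TRUE) - 0.005)
      best <- pool[tied[which.min(match(pool[tied], ranking))]]
      panel <- c(panel, best)
      pool <- setdiff(pool, best)
    }

    # backward elimination: drop analytes whose removal costs nothing
    repeat {
      if (length(panel) <= 1) break
      full_auc <- .cv_auroc(X, y01, panel, k = cv_folds,
                            repeats = cv_repeats)
      drop_auc <- vapply(panel, function(a) {
        .cv_auroc(X, y01, setdiff(panel, a), k = cv_folds,
                  repeats = cv_repeats)
      }, numeric(1))
      removable <- which(drop_auc >= full_auc - tolerance)
      if (length(removable) == 0) break
      panel <- setdiff(panel, panel[removable[which.max(drop_auc[removable])]])
    }
    panel
  })
}

#' Repeated double cross-validation
#'
#' Nested cross-validation repeated over random fold splits: the outer loop
#' holds out test folds never seen by selection; within each outer training
#' set the inner step selects a panel (by default the top `target_size`
#' analytes by random-forest permutation importance) and fits a
#' one-component PLS-DA discriminant, which is then scored on the held-out
#' fold. The distribution of outer-fold AUROCs estimates how the selected
#' classifier generalizes; per-analyte selection frequencies expose
#' selection stability.
#'
#' @param X Samples x analytes matrix.
#' @param y Binary labels.
#' @param outer_folds,inner_folds Fold counts (>= 2); every outer training
#'   fold must keep >= 2 samples per class.
#' @param repeats Number of random re-splits.
#' @param target_size Panel size selected inside the loop.
#' @param seed Integer seed.
#' @param num_trees Trees of the inner ranking forest.
#' @return An `rdcv_result`: list with `aurocs` (one per outer fold x
#'   repeat), `selection_frequency` tibble and the design parameters.
#' @export
rdcv <- function(X, y, outer_folds = 5, inner_folds = 4, repeats = 5,
                 target_size = 8, seed = 1, num_trees = 300) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cls <- .binary_labels(y)
  y01 <- cls$y01
  if (outer_folds < 2 || inner_folds < 2 || repeats < 1) {
    stop_mrmqc("Need outer_folds, inner_folds >= 2 and repeats >= 1.",
               "mrmqc_validation_error")
  }
  if (min(table(y01)) < 2 * outer_folds) {
    stop_mrmqc("Classes too small for the requested outer folds.",
               "mrmqc_validation_error")
  }
  aurocs <- numeric(0)
  picks <- character(0)
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      folds <- .stratified_folds(y01, outer_folds)
      for (f in seq_len(outer_folds)) {
        tr <- folds != f
        rf <- ranger::ranger(
          x = as.data.frame(X[tr, , drop = FALSE]), y = factor(y01[tr]),
          importance = "permutation", num.trees = num_trees,
          seed = sample.int(.Machine$integer.max, 1)
        )
        panel <- names(sort(rf$variable.importance,
                            decreasing = TRUE))[seq_len(target_size)]
        fit <- plsda_fit(X[tr, panel, drop = FALSE], y01[tr],
                         n_components = 1)
        sc <- predict(fit, X[!tr, panel, drop = FALSE])
        aurocs <- c(aurocs, .auroc(sc, y01[!tr]))
        picks <- c(picks, panel)
      }
    }
  })
  freq <- sort(table(picks), decreasing = TRUE)
  structure(list(
    aurocs = aurocs,
    selection_frequency = tibble(
      analyte_id = names(freq),
      frequency = as.numeric(freq) / (outer_folds * repeats)
    ),
    outer_folds = outer_folds, inner_folds = inner_folds,
    repeats = repeats, target_size = target_size, seed = seed
  ), class = "rdcv_result")
}

#' @export
print.rdcv_result <- function(x, ...) {
  cat(sprintf(
    "<rdcv_result> %d x %d outer folds: median held-out AUROC %.3f (IQR %.3f-%.3f)\n",
    x$repeats, x$outer_folds, median(x$aurocs),
    quantile(x$aurocs, 0.25), quantile(x$aurocs, 0.75)
  ))
  invisible(x)
}

#' Permutation test of class separation
#'
#' Refits the full discriminant pipeline under label permutation and
#' reports the add-one permutation p-value
#' `p = (1 + #(permuted >= observed)) / (1 + n_perm)`, which is never zero.
#' The statistic is either the AUROC of the one-component PLS-DA
#' discriminant score or the explained label variance of component 1
#' (`plsda_separation`).
#'
#' @param X Samples x analytes matrix.
#' @param y Binary labels.
#' @param n_perm Number of permutations (>= 100 conventionally; smaller
#'   values are allowed for calibration studies).
#' @param statistic `"auroc"` or `"plsda_separation"`.
#' @param seed Integer seed.
#' @return A one-row tibble: `statistic`, `observed`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(X, y, n_perm = 1000,
                             statistic = c("auroc", "plsda_separation"),
                             seed = 1) {
  statistic <- match.arg(statistic)
  X <- as.matrix(X)
  cls <- .binary_labels(y)
  y01 <- cls$y01
  check_number(n_perm, "n_perm", lower = 1)
  stat_fun <- function(yy) {
    fit <- plsda_fit(X, yy, n_components = 1)
    if (statistic == "auroc") {
      .auroc(predict(fit, X), yy)
    } else {
      tt <- fit$scores[, 1]
      summary(lm(tt ~ factor(yy)))$r.squared
    }
  }
  observed <- stat_fun(y01)
  perms <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    stat_fun(sample(y01))
  }, numeric(1)))
  tibble(statistic = statistic, observed = observed,
         p_value = (1 + sum(perms >= observed)) / (1 + n_perm),
         n_perm = n_perm)
}

#' Assemble a full classifier report
#'
#' Runs the case/control discrimination workflow end to end on a cohort:
#' panel selection (or scoring of a pre-chosen panel), PLS-DA risk scoring,
#' AUROC with stratified bootstrap CI, repeated double cross-validation on
#' the full feature set, and a permutation test.
#'
#' @param X Samples x analytes log2 matrix.
#' @param y Binary labels (reference level first).
#' @param panel Optional pre-chosen analyte panel; when `NULL` a panel of
#'   `target_size` analytes is selected with [select_panel()].
#' @param target_size Panel size for selection.
#' @param n_boot Bootstrap replicates for the AUROC CI.
#' @param n_perm Permutations for the permutation test.
#' @param outer_folds,repeats rdCV design.
#' @param seed Integer seed governing every stochastic step.
#' @return A `classifier_report`: list with `selected_panel`, `auroc`,
#'   `auroc_ci95`, `rdcv_aurocs`, `permutation_p`, `n_cases`, `n_controls`,
#'   `seed`.
#' @export
classifier_report <- function(X, y, panel = NULL, target_size = 8,
                              n_boot = 2000, n_perm = 1000, outer_folds = 5,
                              repeats = 5, seed = 1) {
  X <- as.matrix(X)
  cls <- .binary_labels(y)
  if (is.null(panel)) {
    panel <- select_panel(X, y, target_size = target_size, seed = seed)
  } else {
    miss <- setdiff(panel, colnames(X))
    if (length(miss) > 0) {
      stop_mrmqc(paste0("Panel analyte(s) not in X: ",
                        paste(head(miss, 5), collapse = ", ")),
                 "mrmqc_validation_error")
    }
  }
  fit <- plsda_fit(X[, panel, drop = FALSE], y,
                   n_components = min(2, length(panel), nrow(X) - 1))
  risk <- predict(fit, X[, panel, drop = FALSE])
  auc <- roc_auc(risk, y, n_boot = n_boot, seed = seed)
  cv <- rdcv(X, y, outer_folds = outer_folds, repeats = repeats,
             target_size = min(target_size, ncol(X)), seed = seed)
  perm <- permutation_test(X[, panel, drop = FALSE], y, n_perm = n_perm,
                           seed = seed)
  structure(list(
    selected_panel = panel,
    model = fit,
    auroc = auc$auroc,
    auroc_ci95 = c(auc$ci95_lo, auc$ci95_hi),
    rdcv_aurocs = cv$aurocs,
    selection_frequency = cv$selection_frequency,
    permutation_p = perm$p_value,
    n_cases = auc$n_cases, n_controls = auc$n_controls,
    seed = seed
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> panel of %d analytes: AUROC %.3f (95%% CI %.3f-%.3f), rdCV median %.3f, permutation p = %.4g\n",
    length(x$selected_panel), x$auroc, x$auroc_ci95[1], x$auroc_ci95[2],
    median(x$rdcv_aurocs), x$permutation_p
  ))
  invisible(x)
}
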