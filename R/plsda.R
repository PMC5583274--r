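#' Fit a PLS-DA model (NIPALS)
#'
#' Partial least squares discriminant analysis against a binary label:
#' columns of `X` are centered and unit-variance scaled internally, the
#' label is coded -1/+1 and centered, and latent components are extracted
#' iteratively (NIPALS): weight `w = X'y / |X'y|`, score `t = X w`,
#' X-loading `p = X't / t't`, y-loading `q = y't / t't`, followed by
#' deflation `X <- X - t p'`, `y <- y - t q`. Scores are mutually
#' orthogonal; weights (reported as loadings) are unit-norm per component.
#'
#' @param X Numeric matrix or data frame, samples x analytes (log2 areas
#'   recommended).
#' @param y Binary labels (factor, character or 0/1); the second level is
#'   the positive (case) class.
#' @param n_components Number of latent components (`< n_samples`).
#' @return An object of class `plsda`: scores, loadings (unit-norm
#'   weights), x_loadings, y_loadings, explained_variance (fraction of the
#'   scaled X variance per component), coefficients for prediction, and the
#'   centering/scaling used.
#' @export
plsda_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  cls <- .binary_labels(y)
  if (nrow(X) != length(cls$y01)) {
    stop_mrmqc("X and y dimensions disagree.", "mrmqc_validation_error")
  }
  if (n_components < 1 || n_components >= nrow(X)) {
    stop_mrmqc("Need 1 <= n_components < n_samples.", "mrmqc_validation_error")
  }
  sds <- apply(X, 2, sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < ncol(X)) {
    warn(sprintf("Dropping %d constant column(s).", ncol(X) - length(keep)))
  }
  if (length(keep) == 0) {
    stop_mrmqc("All columns are constant.", "mrmqc_validation_error")
  }
  X <- X[, keep, drop = FALSE]
  mu <- colMeans(X)
  sds <- sds[keep]
  Xs <- sweep(sweep(X, 2, mu), 2, sds, `/`)
  yv <- ifelse(cls$y01 == 1, 1, -1)
  yv <- yv - mean(yv)

  n_comp <- min(n_components, ncol(Xs))
  ssx_total <- sum(Xs^2)
  W <- matrix(0, ncol(Xs), n_comp)
  P <- matrix(0, ncol(Xs), n_comp)
  Tm <- matrix(0, nrow(Xs), n_comp)
  qv <- numeric(n_comp)
  expl <- numeric(n_comp)
  Xd <- Xs
  yd <- yv
  for (k in seq_len(n_comp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_comp <- k - 1L; break }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    p <- drop(crossprod(Xd, tt)) / tt2
    q <- sum(yd * tt) / tt2
    W[, k] <- w; P[, k] <- p; Tm[, k] <- tt; qv[k] <- q
    expl[k] <- tt2 * sum(p^2) / ssx_total
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - tt * q
  }
  if (n_comp == 0) {
    stop_mrmqc("No informative component could be extracted.",
               "mrmqc_validation_error")
  }
  W <- W[, seq_len(n_comp), drop = FALSE]
  P <- P[, seq_len(n_comp), drop = FALSE]
  Tm <- Tm[, seq_len(n_comp), drop = FALSE]
  qv <- qv[seq_len(n_comp)]
  # regression coefficients on the scaled X: B = W (P'W)^-1 q
  B <- W %*% solve(crossprod(P, W), qv)
  structure(list(
    n_components = n_comp,
    scores = Tm,
    loadings = W,
    x_loadings = P,
    y_loadings = qv,
    explained_variance = expl[seq_len(n_comp)],
    coefficients = drop(B),
    center = mu, scale = sds,
    feature_names = colnames(Xs),
    levels = cls$levels
  ), class = "plsda")
}

.binary_labels <- function(y) {
  u <- if (is.factor(y)) {
    lv <- levels(droplevels(y))
    y <- as.character(y)
    lv
  } else {
    sort(unique(y))
  }
  if (length(u) != 2) {
    stop_mrmqc("y must be binary (exactly two classes).",
               "mrmqc_validation_error")
  }
  list(y01 = as.integer(y == u[2]), levels = u)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf(
    "<plsda> %d components over %d features; explained X variance: %s\n",
    x$n_components, length(x$feature_names),
    paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")
  ))
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object A [plsda_fit()] model.
#' @param newdata Samples x analytes matrix or data frame containing the
#'   model's features.
#' @param type `"response"` for the continuous discriminant score (the
#'   default risk score: larger means more case-like) or `"scores"` for the
#'   latent-component scores.
#' @param ... Unused.
#' @return Numeric vector (`response`) or matrix (`scores`).
#' @export
predict.plsda <- function(object, newdata, type = c("response", "scores"),
                          ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss) > 0) {
      stop_mrmqc(paste0("newdata lacks feature(s): ",
                        paste(head(miss, 5), collapse = ", ")),
                 "mrmqc_validation_error")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  if (type == "response") {
    drop(Xs %*% object$coefficients)
  } else {
    # successive projection with deflation by the x-loadings
    out <- matrix(0, nrow(Xs), object$n_components)
    Xd <- Xs
    for (k in seq_len(object$n_components)) {
      out[, k] <- Xd %*% object$loadings[, k]
      Xd <- Xd - tcrossprod(out[, k], object$x_loadings[, k])
    }
    out
  }
}

#' Extract a cohort design matrix from an area matrix
#'
#' Convenience bridge from an [area_matrix()] to the classifier functions:
#' log2-transforms the areas of the requested groups and returns the label
#' vector alongside.
#'
#' @param x An [area_matrix()].
#' @param groups Two group labels, reference first.
#' @param analyte_subset Optional analyte restriction (e.g. a biomarker
#'   panel).
#' @return A list with `X` (samples x analytes log2 matrix) and `y`
#'   (character labels).
#' @export
log2_cohort <- function(x, groups, analyte_subset = NULL) {
  stopifnot(inherits(x, "area_matrix"), length(groups) == 2)
  sel <- x[x$group %in% groups, ]
  if (nrow(sel) == 0) {
    stop_mrmqc("No samples in the requested groups.", "mrmqc_validation_error")
  }
  vals <- log2_area(area_values(sel))
  if (!is.null(analyte_subset)) {
    vals <- vals[, intersect(colnames(vals), analyte_subset), drop = FALSE]
  }
  list(X = vals, y = factor(sel$group, levels = groups))
}
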