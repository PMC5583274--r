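#' Peak-area matrices
#'
#' The universal input of every validation stage: a wide tibble with one row
#' per injection, the sample-metadata columns `sample_id`, `group`, `day`,
#' `replicate`, `tube`, `run_id`, `mix_fraction`, and one numeric column per
#' analyte. Missing areas are `NA` — "not detected" is never coerced to zero,
#' since zeros would corrupt CV and log2 computations.
#'
#' @param x A data frame containing `sample_id` and at least one analyte
#'   column.
#' @param analytes Character vector naming the analyte columns. Defaults to
#'   every non-metadata column.
#' @return A tibble of class `area_matrix` with an `analytes` attribute.
#' @export
area_matrix <- function(x, analytes = NULL) {
  x <- as_tibble(x)
  meta_cols <- c("sample_id", "group", "day", "replicate", "tube", "run_id",
                 "mix_fraction", "role")
  if (!"sample_id" %in% names(x)) {
    stop_mrmqc("An area matrix needs a `sample_id` column.", "mrmqc_schema_error")
  }
  if (is.null(analytes)) analytes <- setdiff(names(x), meta_cols)
  if (length(analytes) == 0) {
    stop_mrmqc("An area matrix needs at least one analyte column.",
               "mrmqc_validation_error")
  }
  if (anyDuplicated(x$sample_id)) {
    stop_mrmqc("sample_id values must be unique (one metadata record per sample).",
               "mrmqc_validation_error")
  }
  for (col in setdiff(meta_cols, names(x))) {
    x[[col]] <- switch(col,
      day = NA_integer_, replicate = NA_integer_, mix_fraction = NA_real_,
      NA_character_
    )
  }
  for (a in analytes) {
    v <- x[[a]]
    if (!is.numeric(v)) {
      stop_mrmqc(paste0("Analyte column is not numeric: ", a), "mrmqc_parse_error")
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop_mrmqc(paste0("Negative peak area in analyte: ", a),
                 "mrmqc_validation_error")
    }
  }
  known_tubes <- c("Li-heparin", "Na-heparin", "K2-EDTA", "SST")
  bad_tube <- setdiff(unique(x$tube[!is.na(x$tube)]), known_tubes)
  if (length(bad_tube) > 0) {
    stop_mrmqc(paste0("Unknown tube type(s): ", paste(bad_tube, collapse = ", ")),
               "mrmqc_validation_error")
  }
  mf <- x$mix_fraction
  if (any(mf < 0 | mf > 1, na.rm = TRUE)) {
    stop_mrmqc("mix_fraction must lie in [0, 1].", "mrmqc_validation_error")
  }
  x <- x[, c(intersect(meta_cols, names(x)), analytes)]
  attr(x, "analytes") <- analytes
  class(x) <- c("area_matrix", class(x))
  x
}

#' @rdname area_matrix
#' @export
analytes <- function(x) attr(x, "analytes")

#' @export
print.area_matrix <- function(x, ...) {
  cat(sprintf("<area_matrix> %d samples x %d analytes\n",
              nrow(x), length(analytes(x))))
  NextMethod()
}

#' Pivot an area matrix to long form
#'
#' @param x An [area_matrix()].
#' @return A tibble with one row per (sample, analyte) and columns
#'   `sample_id`, metadata, `analyte_id`, `area`.
#' @export
area_long <- function(x) {
  stopifnot(inherits(x, "area_matrix"))
  tidyr::pivot_longer(as_tibble(as.data.frame(x)),
                      cols = dplyr::all_of(analytes(x)),
                      names_to = "analyte_id", values_to = "area")
}

# Bare numeric matrix (samples x analytes) with dimnames; internal.
area_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, analytes(x), drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' Read a peak-area matrix
#'
#' Wide layout: one row per sample, metadata columns plus analyte columns.
#' Long layout: columns `sample_id`, `analyte_id`, `area` plus optional
#' metadata. Empty cells are missing areas, never zero.
#'
#' @param path CSV path.
#' @param layout `"wide"` or `"long"`.
#' @param metadata Optional sidecar data frame of per-sample metadata joined
#'   on `sample_id`; samples present in the areas but absent here raise an
#'   error.
#' @return An [area_matrix()].
#' @export
read_area_matrix <- function(path, layout = c("wide", "long"), metadata = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop_mrmqc(paste0("File not found: ", path), "mrmqc_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "long") {
    need <- c("sample_id", "analyte_id", "area")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0) {
      stop_mrmqc(paste0("Long layout needs column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "mrmqc_schema_error")
    }
    raw <- tidyr::pivot_wider(raw, names_from = "analyte_id",
                              values_from = "area")
  }
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    orphans <- setdiff(raw$sample_id, metadata$sample_id)
    if (length(orphans) > 0) {
      stop_mrmqc(paste0("Sample(s) missing from metadata: ",
                        paste(head(orphans, 10), collapse = ", ")),
                 "mrmqc_join_error")
    }
    raw <- dplyr::left_join(
      raw[, setdiff(names(raw), setdiff(names(metadata), "sample_id"))],
      metadata, by = "sample_id"
    )
  }
  area_matrix(raw)
}

#' Write a peak-area matrix
#'
#' Emits a wide CSV with metadata columns first, then analyte columns in
#' library order. Missing areas become empty fields.
#'
#' @param x An [area_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_matrix <- function(x, path) {
  stopifnot(inherits(x, "area_matrix"))
  if (length(analytes(x)) == 0) {
    stop_mrmqc("Refusing to write an area matrix with no analytes.",
               "mrmqc_validation_error")
  }
  readr::write_csv(as_tibble(as.data.frame(x)), path, na = "", progress = FALSE)
  invisible(path)
}
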