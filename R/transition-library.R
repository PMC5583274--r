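#' Transition libraries
#'
#' A transition library is a tibble with one row per MRM transition
#' (precursor/fragment pair) and the columns `analyte_id`, `q1_mz`, `q3_mz`,
#' `polarity` (`"positive"` or `"negative"`), `rt_min`, `chem_class`,
#' `pathway`, `is_internal_standard`, plus any number of compound-dependent
#' parameter columns (declustering potential, collision energy, ...). The
#' chromatographic run length in minutes is carried as the
#' `run_length_min` attribute.
#'
#' @param x A data frame with at least `analyte_id`, `q1_mz`, `q3_mz`,
#'   `polarity`, `rt_min`.
#' @param run_length_min Run length in minutes; retention times must fall in
#'   `[0, run_length_min]`.
#' @return A tibble of class `transition_library`.
#' @export
transition_library <- function(x, run_length_min = 45) {
  x <- as_tibble(x)
  required <- c("analyte_id", "q1_mz", "q3_mz", "polarity", "rt_min")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_mrmqc(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "mrmqc_schema_error"
    )
  }
  if (nrow(x) == 0) {
    stop_mrmqc("A transition library must contain at least one transition.",
               "mrmqc_validation_error")
  }
  check_number(run_length_min, "run_length_min", lower = 0)
  if (!"chem_class" %in% names(x)) x$chem_class <- NA_character_
  if (!"pathway" %in% names(x)) x$pathway <- NA_character_
  if (!"is_internal_standard" %in% names(x)) x$is_internal_standard <- FALSE
  x$analyte_id <- as.character(x$analyte_id)
  x$is_internal_standard <- as.logical(x$is_internal_standard)

  dup <- unique(x$analyte_id[duplicated(x$analyte_id)])
  if (length(dup) > 0) {
    stop_mrmqc(
      paste0("Duplicate analyte_id(s): ", paste(head(dup, 10), collapse = ", ")),
      "mrmqc_validation_error"
    )
  }
  bad_num <- !is.finite(x$q1_mz) | !is.finite(x$q3_mz) | !is.finite(x$rt_min)
  if (any(bad_num)) {
    stop_mrmqc(
      paste0("Non-numeric or missing Q1/Q3/RT in row(s): ",
             paste(head(which(bad_num), 10), collapse = ", ")),
      "mrmqc_parse_error"
    )
  }
  if (any(x$q1_mz <= 0 | x$q3_mz <= 0)) {
    stop_mrmqc("q1_mz and q3_mz must be positive.", "mrmqc_validation_error")
  }
  if (any(x$rt_min < 0 | x$rt_min > run_length_min)) {
    stop_mrmqc(
      sprintf("rt_min must lie within [0, %g] minutes.", run_length_min),
      "mrmqc_validation_error"
    )
  }
  if (!all(x$polarity %in% c("positive", "negative"))) {
    stop_mrmqc('polarity must be "positive" or "negative".',
               "mrmqc_validation_error")
  }
  attr(x, "run_length_min") <- run_length_min
  class(x) <- c("transition_library", class(x))
  x
}

#' @export
print.transition_library <- function(x, ...) {
  cnt <- library_counts(x)
  cat(sprintf(
    "<transition_library> %d transitions (%d endogenous + %d internal standards), run %g min\n",
    cnt$total, cnt$endogenous, cnt$internal_standard, run_length_min(x)
  ))
  NextMethod()
}

#' @rdname transition_library
#' @export
run_length_min <- function(x) attr(x, "run_length_min")

#' Count transitions by role
#'
#' Tallies endogenous versus internal-standard transitions and the number of
#' distinct pathway annotations among endogenous analytes. The invariant
#' `endogenous + internal_standard == total` holds by construction.
#'
#' @param library A [transition_library()].
#' @return A one-row tibble with columns `total`, `endogenous`,
#'   `internal_standard`, `n_pathways`.
#' @export
library_counts <- function(library) {
  stopifnot(inherits(library, "transition_library"))
  endo <- !library$is_internal_standard
  tibble(
    total = nrow(library),
    endogenous = sum(endo),
    internal_standard = sum(!endo),
    n_pathways = dplyr::n_distinct(library$pathway[endo & !is.na(library$pathway)])
  )
}

# Header aliases: canonical snake_case plus Analyst/method-table style names.
.transition_aliases <- c(
  "analyte_id" = "analyte_id", "analyte" = "analyte_id", "compound" = "analyte_id",
  "compound_name" = "analyte_id", "name" = "analyte_id", "compound_id" = "analyte_id",
  "q1_mz" = "q1_mz", "q1" = "q1_mz", "q1_mass" = "q1_mz", "precursor_mz" = "q1_mz",
  "q3_mz" = "q3_mz", "q3" = "q3_mz", "q3_mass" = "q3_mz", "fragment_mz" = "q3_mz",
  "polarity" = "polarity", "ion_mode" = "polarity", "mode" = "polarity",
  "rt_min" = "rt_min", "rt" = "rt_min", "retention_time" = "rt_min",
  "retention_time_min" = "rt_min", "time_min" = "rt_min",
  "chem_class" = "chem_class", "class" = "chem_class", "chemical_class" = "chem_class",
  "pathway" = "pathway", "metabolic_pathway" = "pathway",
  "is_internal_standard" = "is_internal_standard", "is" = "is_internal_standard",
  "internal_standard" = "is_internal_standard", "is_flag" = "is_internal_standard"
)

.normalise_header <- function(h) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(h)))
  key <- gsub("^_|_$", "", key)
  mapped <- .transition_aliases[key]
  ifelse(is.na(mapped), key, mapped)
}

.normalise_polarity <- function(p) {
  p <- tolower(trimws(as.character(p)))
  out <- rep(NA_character_, length(p))
  out[p %in% c("positive", "pos", "+", "1")] <- "positive"
  out[p %in% c("negative", "neg", "-", "-1")] <- "negative"
  out
}

#' Read a transition method table
#'
#' Reads a transition table in either the package's canonical snake_case
#' dialect or an Analyst-style export (aliased headers such as `Q1 Mass`,
#' `Retention Time`, `Ion Mode`). Unknown columns are preserved as
#' annotation columns.
#'
#' @param path Path to a CSV or XLSX file.
#' @param dialect `"csv"` or `"xlsx"` (XLSX requires the readxl package).
#' @param run_length_min Run length in minutes.
#' @return A [transition_library()].
#' @export
read_transition_table <- function(path, dialect = c("csv", "xlsx"),
                                  run_length_min = 45) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_mrmqc(paste0("File not found: ", path), "mrmqc_io_error")
  }
  raw <- if (dialect == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_mrmqc("Reading XLSX requires the readxl package.", "mrmqc_io_error")
    }
    as_tibble(readxl::read_excel(path))
  }
  if (nrow(raw) == 0) {
    stop_mrmqc("Transition table has a header but no data rows.",
               "mrmqc_validation_error")
  }
  names(raw) <- .normalise_header(names(raw))
  required <- c("analyte_id", "q1_mz", "q3_mz", "polarity", "rt_min")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_mrmqc(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "mrmqc_schema_error"
    )
  }
  for (col in c("q1_mz", "q3_mz", "rt_min")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop_mrmqc(
        sprintf("Non-numeric %s in row(s): %s", col,
                paste(head(bad, 10), collapse = ", ")),
        "mrmqc_parse_error"
      )
    }
    raw[[col]] <- v
  }
  raw$polarity <- .normalise_polarity(raw$polarity)
  if ("is_internal_standard" %in% names(raw)) {
    v <- raw$is_internal_standard
    if (!is.logical(v)) {
      v <- tolower(trimws(as.character(v))) %in% c("true", "t", "yes", "y", "1", "is")
    }
    raw$is_internal_standard <- v
  }
  transition_library(raw, run_length_min = run_length_min)
}

#' Write a transition method table
#'
#' @param library A [transition_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(library, path) {
  stopifnot(inherits(library, "transition_library"))
  readr::write_csv(as_tibble(as.data.frame(library)), path, progress = FALSE)
  invisible(path)
}
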