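test_that("transition tables round-trip field for field", {
  lib <- tiny_library(n = 10, n_is = 2, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(lib, path)
  back <- read_transition_table(path)
  expect_equal(back$analyte_id, lib$analyte_id)
  expect_equal(back$q1_mz, lib$q1_mz)
  expect_equal(back$q3_mz, lib$q3_mz)
  expect_equal(back$polarity, lib$polarity)
  expect_equal(back$rt_min, lib$rt_min)
  expect_equal(back$pathway, lib$pathway)
  expect_equal(back$is_internal_standard, lib$is_internal_standard)
})

test_that("Analyst-style header aliases are accepted and annotations kept", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Compound Name,Q1 Mass,Q3 Mass,Ion Mode,Retention Time,CE,Custom Note",
    "alanine,90.1,44.1,pos,5.2,20,keep-me",
    "lactate,89.0,43.0,neg,6.0,18,also"
  ), path)
  lib <- read_transition_table(path)
  expect_equal(lib$analyte_id, c("alanine", "lactate"))
  expect_equal(lib$polarity, c("positive", "negative"))
  expect_true("ce" %in% names(lib))
  expect_true("custom_note" %in% names(lib))
})

test_that("schema, duplicate and parse errors name the offender", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte_id,q1_mz,polarity,rt_min", "x,100,positive,5"), path)
  expect_error(read_transition_table(path), class = "mrmqc_schema_error")
  expect_error(read_transition_table(path), "q3_mz")

  writeLines(c("analyte_id,q1_mz,q3_mz,polarity,rt_min",
               "dup,100,50,positive,5", "dup,101,51,negative,6"), path)
  expect_error(read_transition_table(path), class = "mrmqc_validation_error")
  expect_error(read_transition_table(path), "dup")

  writeLines(c("analyte_id,q1_mz,q3_mz,polarity,rt_min",
               "ok,100,50,positive,5", "bad,oops,51,negative,6"), path)
  expect_error(read_transition_table(path), class = "mrmqc_parse_error")
  expect_error(read_transition_table(path), "2")
})

test_that("header-only tables are rejected, never an empty library", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("analyte_id,q1_mz,q3_mz,polarity,rt_min", path)
  expect_error(read_transition_table(path), class = "mrmqc_validation_error")
})

test_that("endogenous + internal-standard counts equal the total on load", {
  lib <- tiny_library(n = 50, n_is = 10)
  cnt <- library_counts(lib)
  expect_identical(cnt$endogenous + cnt$internal_standard, cnt$total)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(lib, path)
  cnt2 <- library_counts(read_transition_table(path))
  expect_identical(cnt2$endogenous + cnt2$internal_standard, cnt2$total)
})

test_that("wide and long area layouts load to the identical matrix", {
  lib <- tiny_library(n = 3)
  st <- generate_study(lib, study_design("precision", n_days = 2,
                                         n_reps_per_day = 2),
                       noise_spec(seed = 5))
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_area_matrix(st, wide)
  readr::write_csv(area_long(st)[, c("sample_id", "group", "day", "replicate",
                                     "analyte_id", "area")], long)
  m_wide <- read_area_matrix(wide, layout = "wide")
  m_long <- read_area_matrix(long, layout = "long")
  expect_equal(area_values(m_wide), area_values(m_long))
  expect_equal(area_values(m_wide), area_values(st), tolerance = 1e-12)
})

test_that("missing areas survive a round trip as NA, never zero", {
  lib <- tiny_library(n = 3)
  st <- generate_study(lib, study_design("precision", n_days = 2,
                                         n_reps_per_day = 2),
                       noise_spec(seed = 5))
  st[[analytes(st)[1]]][2] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_matrix(st, path)
  raw <- readLines(path)
  expect_false(any(grepl(",0,", raw[3], fixed = TRUE)))
  back <- read_area_matrix(path)
  expect_true(is.na(back[[analytes(back)[1]]][2]))
})

test_that("area matrices reject bad input", {
  df <- tibble::tibble(sample_id = c("s1", "s2"), a1 = c(1, -5))
  expect_error(area_matrix(df), class = "mrmqc_validation_error")
  df2 <- tibble::tibble(sample_id = c("s1", "s1"), a1 = c(1, 2))
  expect_error(area_matrix(df2), class = "mrmqc_validation_error")
  ok <- area_matrix(tibble::tibble(sample_id = "s1", a1 = 1))
  expect_error(write_area_matrix(structure(ok, analytes = character(0)),
                                 withr::local_tempfile()),
               class = "mrmqc_validation_error")
})

test_that("samples lacking sidecar metadata raise a join error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,a1", "s1,10", "s2,20"), path)
  meta <- tibble::tibble(sample_id = "s1", group = "g")
  expect_error(read_area_matrix(path, metadata = meta),
               class = "mrmqc_join_error")
  full <- tibble::tibble(sample_id = c("s1", "s2"), group = "g")
  m <- read_area_matrix(path, metadata = full)
  expect_equal(m$group, c("g", "g"))
})

test_that("shipped synthetic example files load cleanly", {
  lib <- read_transition_table(
    system.file("extdata", "synthetic_transitions.csv", package = "mrmqc")
  )
  expect_identical(library_counts(lib)$total, 12L)
  m <- read_area_matrix(
    system.file("extdata", "synthetic_precision_areas.csv", package = "mrmqc")
  )
  expect_identical(length(analytes(m)), 12L)
})
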