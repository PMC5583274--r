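make_two_group_matrix <- function(n_ref = 5, n_case = 5, n_analytes = 6,
                                  case_shift_log2 = 0, seed = 1) {
  withr::with_seed(seed, {
    base <- rlnorm(n_analytes, log(1e6), 1)
    rows <- lapply(seq_len(n_ref + n_case), function(i) {
      is_case <- i > n_ref
      shift <- if (is_case) 2^case_shift_log2 else 1
      vals <- base * shift * rlnorm(n_analytes, 0, 0.2)
      out <- tibble::as_tibble(as.list(setNames(vals,
                                                paste0("m", seq_len(n_analytes)))))
      out$sample_id <- sprintf("s%02d", i)
      out$group <- if (is_case) "case" else "control"
      out
    })
    area_matrix(dplyr::bind_rows(rows))
  })
}

test_that("a reference sample at the reference mean has z = 0", {
  m <- area_matrix(tibble::tibble(
    sample_id = c("r1", "r2", "r3"), group = "control",
    a = c(4, 8, 16)   # log2 values 2, 3, 4; mean 3
  ))
  z <- zscores(m, "control")
  expect_equal(z$z[z$sample_id == "r2"], 0)
})

test_that("a unit log2 shift against unit reference SD gives z near 1", {
  m <- make_two_group_matrix(n_ref = 60, n_case = 60, case_shift_log2 = 1,
                             seed = 3)
  zg <- zscores(m, "control", level = "group")
  ref_sd_log2 <- 0.2 / log(2)
  expect_equal(mean(zg$z[zg$group == "case"]) * ref_sd_log2, 1,
               tolerance = 0.15)
})

test_that("z-scores are invariant to per-analyte multiplicative gain", {
  m <- make_two_group_matrix(seed = 4)
  z1 <- zscores(m, "control")
  m2 <- m
  gains <- seq(0.5, 3, length.out = length(analytes(m)))
  for (i in seq_along(analytes(m2))) {
    m2[[analytes(m2)[i]]] <- m2[[analytes(m2)[i]]] * gains[i]
  }
  z2 <- zscores(m2, "control")
  expect_equal(z1$z, z2$z, tolerance = 1e-10)
})

test_that("a run compared against itself is perfectly concordant", {
  m <- make_two_group_matrix(n_analytes = 15, case_shift_log2 = 0.8, seed = 5)
  rc <- run_concordance(m, m, reference_group = "control")
  expect_true(all(abs(rc$r2_by_group$r2 - 1) < 1e-12))
  expect_equal(rc$z_r2, 1, tolerance = 1e-12)
})

test_that("per-analyte gains break AUC concordance but not z concordance", {
  m <- make_two_group_matrix(n_analytes = 15, case_shift_log2 = 1, seed = 6)
  m2 <- m
  gains <- withr::with_seed(7, rlnorm(length(analytes(m)), 0, 0.5))
  for (i in seq_along(analytes(m2))) {
    m2[[analytes(m2)[i]]] <- m2[[analytes(m2)[i]]] * gains[i]
  }
  rc <- run_concordance(m, m2, reference_group = "control")
  expect_lt(max(rc$r2_by_group$r2), 1 - 1e-6)
  expect_equal(rc$z_r2, 1, tolerance = 1e-10)
})

test_that("Pearson r-squared equals the covariance-formula oracle", {
  withr::with_seed(8, {
    a <- rnorm(20)
    b <- 0.6 * a + rnorm(20)
  })
  naive_r2 <- (mean(a * b) - mean(a) * mean(b))^2 /
    ((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
  expect_equal(mrmqc:::.r2(a, b), naive_r2, tolerance = 1e-12)
})

test_that("concordant synthetic runs land in the expected r2 band", {
  lib <- tiny_library(n = 150, seed = 9)
  pe <- setNames(rep(c(1.2, -1.2), 10), lib$analyte_id[1:20])
  r2s <- sapply(1:5, function(s) {
    st <- generate_study(lib, study_design("concordance",
                                           planted_effects = pe),
                         noise_spec(seed = s))
    ra <- area_matrix(as.data.frame(st[st$run_id == "run_a", ]))
    rb <- area_matrix(as.data.frame(st[st$run_id == "run_b", ]))
    rc <- run_concordance(ra, rb, reference_group = "control")
    c(mean(rc$r2_by_group$r2), rc$z_r2)
  })
  expect_gte(mean(r2s[1, ]), 0.8)
  expect_lte(mean(r2s[1, ]), 0.97)
  expect_gt(mean(r2s[2, ]), 0.85)
})

test_that("pathway impact follows its defining arithmetic", {
  membership <- tibble::tibble(
    pathway = c("p1", "p1", "p1", "p2", "p2"),
    analyte_id = c("a", "b", "c", "d", "e")
  )
  z0 <- tibble::tibble(analyte_id = letters[1:5], z = 0)
  expect_true(all(pathway_impact(z0, membership)$impact == 0))

  z2 <- tibble::tibble(analyte_id = letters[1:5], z = c(2, -2, 2, 2, -2))
  pi2 <- pathway_impact(z2, membership)
  expect_equal(pi2$impact, c(2, 2))

  # half-measured pathway: impact scales by coverage
  z_half <- tibble::tibble(analyte_id = c("a", "d"), z = c(2, 2))
  pi_half <- pathway_impact(z_half, membership)
  expect_equal(pi_half$impact[pi_half$pathway == "p1"], 2 * 1 / 3)
})

test_that("pathway impact is monotone in member |z|", {
  membership <- tibble::tibble(pathway = "p", analyte_id = c("a", "b", "c"))
  z_lo <- tibble::tibble(analyte_id = c("a", "b", "c"), z = c(1, 1, 1))
  z_hi <- tibble::tibble(analyte_id = c("a", "b", "c"), z = c(1, 2.5, 1))
  expect_gt(pathway_impact(z_hi, membership)$impact,
            pathway_impact(z_lo, membership)$impact)
})

test_that("pathway aggregation is more concordant than analyte z-scores", {
  # two cohorts of fresh subjects measured for the same planted biology:
  # averaging member z-scores within pathways cancels per-analyte noise,
  # so pathway impact correlates across studies better than raw z does
  lib <- generate_transition_library(n_analytes = 120,
                                     n_internal_standards = 0,
                                     n_pathways = 20, seed = 10)
  # perturb five whole pathways so each carries several informative members
  hit <- lib$analyte_id[lib$pathway %in% sprintf("pathway_%02d", 1:5)]
  pe <- setNames(rep(c(1.5, -1.5), length.out = length(hit)), hit)
  membership <- tibble::tibble(pathway = lib$pathway,
                               analyte_id = lib$analyte_id)
  des <- study_design("case_control", groups = c(control = 10, case = 10),
                      planted_effects = pe)
  study_z <- function(seed) {
    st <- generate_study(lib, des, noise_spec(seed = seed))
    z <- zscores(st, "control", level = "group")
    z[z$group == "case", c("analyte_id", "z")]
  }
  diffs <- sapply(1:5, function(s) {
    za <- study_z(40 + 2 * s)
    zb <- study_z(41 + 2 * s)
    m <- dplyr::inner_join(za, zb, by = "analyte_id",
                           suffix = c("_a", "_b"))
    z_r2 <- mrmqc:::.r2(m$z_a, m$z_b)
    pa <- pathway_impact(za, membership)
    pb <- pathway_impact(zb, membership)
    pm <- dplyr::inner_join(pa, pb, by = "pathway", suffix = c("_a", "_b"))
    mrmqc:::.r2(pm$impact_a, pm$impact_b) - z_r2
  })
  expect_gt(mean(diffs), 0)
})

test_that("identical tubes rarely produce any FDR discovery", {
  lib <- tiny_library(n = 50, seed = 13)
  n_with_hit <- sum(vapply(1:20, function(s) {
    st <- generate_study(lib, study_design("tube", n_reps_per_day = 4,
                                           tubes = c("Li-heparin", "K2-EDTA")),
                         noise_spec(seed = s))
    tc <- tube_comparison(st)
    any(tc$per_analyte$p_adj < 0.05, na.rm = TRUE)
  }, logical(1)))
  expect_lte(n_with_hit / 20, 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("a planted 16-fold nucleoside depletion is flagged at minus four log2", {
  lib <- tiny_library(n = 120, seed = 14)
  te <- data.frame(tube = "K2-EDTA", chem_class = "nucleoside",
                   factor = 1 / 16)
  st <- generate_study(lib, study_design("tube", n_reps_per_day = 5,
                                         tube_effects = te),
                       noise_spec(seed = 3))
  tc <- tube_comparison(st, chem_class = lib[, c("analyte_id", "chem_class")])
  cls <- tc$by_class[tc$by_class$tube == "K2-EDTA" &
                       tc$by_class$chem_class == "nucleoside", ]
  expect_equal(cls$median_log2_fc, -4, tolerance = 0.15)
  expect_gt(cls$n_significant / cls$n, 0.8)
})

test_that("a single tube type cannot be compared", {
  lib <- tiny_library(n = 5)
  st <- generate_study(lib, study_design("tube", tubes = "Li-heparin"),
                       noise_spec(seed = 1))
  expect_error(tube_comparison(st), class = "mrmqc_validation_error")
})
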