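test_that("exclusion rules drop short series and all-missing signs, counted once", {
  cohort <- exclusion_fixture()
  res <- apply_exclusions(cohort)
  expect_equal(res$report$n_input, 10L)
  expect_equal(res$report$n_excluded_short, 3L)
  expect_equal(res$report$n_excluded_all_missing, 2L)
  expect_equal(res$report$n_retained, 5L)
  expect_setequal(
    unique(res$cohort$patient_id),
    c("ok36", "ok40", "ok48", "ok50", "ok60")
  )

  # a patient failing both rules counts once, under the short rule
  both <- {
    m <- const_mat(20)
    m[, 3] <- NA_real_
    labeled_patient("both", m, 0)
  }
  res2 <- apply_exclusions(dplyr::bind_rows(cohort, both))
  expect_equal(res2$report$n_excluded_short, 4L)
  expect_equal(res2$report$n_excluded_all_missing, 2L)

  empty <- apply_exclusions(cohort[0, ])
  expect_equal(nrow(empty$cohort), 0L)
  expect_equal(empty$report$n_input, 0L)
})

test_that("36 registers is the retention boundary, 35 is excluded", {
  cohort <- dplyr::bind_rows(
    labeled_patient("p35", const_mat(35), 0),
    labeled_patient("p36", const_mat(36), 0)
  )
  res <- apply_exclusions(cohort)
  expect_equal(unique(res$cohort$patient_id), "p36")
})

test_that("limit clipping uses a closed interval and leaves in-range values", {
  lims <- vital_limits()
  m <- const_mat(4)
  m[1, 1] <- 900 # HR far above the 300 upper bound
  m[2, 3] <- 37.0 # within bounds
  m[3, 1] <- lims$upper[lims$sign == "HR"] # exactly at the bound
  m[4, 2] <- lims$lower[lims$sign == "O2Sat"]
  out <- clip_to_limits(labeled_patient("a", m, 0))
  expect_true(is.na(out$HR[1]))
  expect_equal(out$Temp[2], 37.0)
  expect_equal(out$HR[3], lims$upper[lims$sign == "HR"])
  expect_equal(out$O2Sat[4], lims$lower[lims$sign == "O2Sat"])

  # brute-force closed-interval rule on a boundary grid
  for (j in seq_len(nrow(lims))) {
    vals <- c(
      lims$lower[j] - 1e-6, lims$lower[j], (lims$lower[j] + lims$upper[j]) / 2,
      lims$upper[j], lims$upper[j] + 1e-6
    )
    mm <- const_mat(5)
    mm[, j] <- vals
    clipped <- clip_to_limits(labeled_patient("g", mm, 0))[[lims$sign[j]]]
    expect_equal(is.na(clipped), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  }
})

test_that("windowing keeps the last 48 rows or pads the front with missing", {
  long <- labeled_patient("long", matrix(seq_len(60 * 6), 60, 6), 0)
  out <- window_last_48(long)
  expect_equal(nrow(out), 48L)
  expect_equal(out$hour, 0:47)
  expect_equal(out$HR, 13:60) # rows 12..59 of the original 0-indexed series

  short <- labeled_patient("short", matrix(seq_len(40 * 6), 40, 6), 1)
  out2 <- window_last_48(short)
  expect_equal(nrow(out2), 48L)
  expect_true(all(is.na(out2$HR[1:8])))
  expect_equal(out2$HR[9:48], 1:40)
  expect_equal(unique(out2$label), 1L)

  exact <- labeled_patient("exact", const_mat(48), 0)
  expect_equal(window_last_48(exact)$HR, rep(80, 48))
})

test_that("hourly-mean imputation averages present patients and keeps observed cells", {
  m1 <- const_mat(48)
  m2 <- const_mat(48)
  m3 <- const_mat(48)
  m1[6, 1] <- 80
  m2[6, 1] <- NA_real_
  m3[6, 1] <- 90
  cohort <- dplyr::bind_rows(
    labeled_patient("a", m1, 0),
    labeled_patient("b", m2, 0),
    labeled_patient("c", m3, 1)
  )
  out <- impute_hourly_means(cohort)
  expect_equal(out$HR[out$patient_id == "b" & out$hour == 5], 85)
  # observed values bit-identical
  obs <- !is.na(cohort$HR)
  expect_identical(out$HR[obs], cohort$HR[obs])

  # no missing cells: identity
  full <- dplyr::bind_rows(
    labeled_patient("a", m1, 0), labeled_patient("c", m3, 1)
  )
  expect_identical(impute_hourly_means(full), full)

  # an hour where every patient is missing stays missing
  m1[1, 2] <- NA_real_
  m3[1, 2] <- NA_real_
  all_na <- dplyr::bind_rows(
    labeled_patient("a", m1, 0), labeled_patient("c", m3, 1)
  )
  expect_true(all(is.na(impute_hourly_means(all_na)$O2Sat[
    all_na$hour == 0
  ])))
})

test_that("interpolation fills interior gaps linearly and edges by nearest value", {
  m <- const_mat(5)
  m[, 1] <- c(1, NA, 3, NA, NA)
  m[, 2] <- c(NA, NA, 5, 6, 7)
  out <- interpolate_remaining(labeled_patient("a", m, 0))
  expect_equal(out$HR, c(1, 2, 3, 3, 3))
  expect_equal(out$O2Sat, c(5, 5, 5, 6, 7))
  expect_false(anyNA(out[vital_signs()]))

  # identity when nothing is missing
  clean <- labeled_patient("b", const_mat(5), 0)
  expect_identical(interpolate_remaining(clean), clean)

  # a sign with no observed values is an invariant violation
  m2 <- const_mat(5)
  m2[, 4] <- NA_real_
  expect_error(
    interpolate_remaining(labeled_patient("c", m2, 0)),
    "no observed values"
  )
})

test_that("trailing moving average shrinks at the window start", {
  m <- const_mat(3)
  m[, 1] <- c(1, 2, 3)
  out <- smooth_ma3(labeled_patient("a", m, 0))
  expect_equal(out$HR, c(1, 1.5, 2))

  step <- const_mat(6)
  step[, 1] <- c(0, 0, 0, 3, 3, 3)
  expect_equal(
    smooth_ma3(labeled_patient("b", step, 0))$HR,
    c(0, 0, 0, 1, 2, 3)
  )

  const <- labeled_patient("c", const_mat(10), 0)
  expect_equal(smooth_ma3(const)$HR, rep(80, 10))

  # smoothing stays inside the observed hull
  for (seed in 1:3) {
    set.seed(seed)
    mm <- const_mat(20) + matrix(rnorm(120), 20, 6)
    sm <- smooth_ma3(labeled_patient("h", mm, 0))
    for (s in vital_signs()) {
      orig <- mm[, match(s, vital_signs())]
      expect_true(all(sm[[s]] >= min(orig) - 1e-12))
      expect_true(all(sm[[s]] <= max(orig) + 1e-12))
    }
  }
})

test_that("max-normalisation scales into [0,1] with the maximum mapped to 1", {
  m <- const_mat(4)
  m[, 1] <- c(100, 150, 200, 50)
  res <- normalize_by_max(labeled_patient("a", m, 0))
  expect_equal(res$cohort$HR, c(0.5, 0.75, 1, 0.25))
  expect_equal(res$maxima$max[res$maxima$sign == "HR"], 200)
  for (s in vital_signs()) {
    expect_true(all(res$cohort[[s]] >= 0 & res$cohort[[s]] <= 1))
  }

  # reusing recorded maxima reproduces the same scale
  res2 <- normalize_by_max(labeled_patient("a", m, 0), maxima = res$maxima)
  expect_equal(res2$cohort, res$cohort)

  bad <- const_mat(2)
  bad[, 1] <- c(-5, -1)
  expect_error(normalize_by_max(labeled_patient("b", bad, 0)), "degenerate")
})

test_that("balancing keeps all positives and a seeded negative subsample", {
  cohort <- purrr::map(1:110, function(i) {
    labeled_patient(sprintf("p%03d", i), const_mat(3), as.integer(i <= 10))
  }) |> purrr::list_rbind()
  b1 <- balance_cohort(cohort, 30, seed = 11)
  ids <- unique(b1$patient_id)
  expect_equal(length(ids), 40L)
  expect_true(all(sprintf("p%03d", 1:10) %in% ids))
  expect_identical(balance_cohort(cohort, 30, seed = 11), b1)

  b2 <- balance_cohort(cohort, 30, seed = 12)
  expect_false(setequal(unique(b2$patient_id), ids))
  expect_equal(length(unique(b2$patient_id)), 40L)

  all_neg <- balance_cohort(cohort, 100, seed = 1)
  expect_equal(length(unique(all_neg$patient_id)), 110L)
  expect_error(balance_cohort(cohort, 101, seed = 1), "exceeds")
})

test_that("the full cascade yields 48 complete rows per patient in [0,1], deterministically", {
  cohort <- random_truncated_cohort(16, seed = 5)
  pp <- preprocess_cohort(cohort)
  counts <- dplyr::count(pp$cohort, .data$patient_id)
  expect_true(all(counts$n == 48L))
  expect_false(anyNA(pp$cohort[vital_signs()]))
  for (s in vital_signs()) {
    expect_true(all(pp$cohort[[s]] >= 0 & pp$cohort[[s]] <= 1))
  }
  expect_equal(
    pp$report$n_retained,
    pp$report$n_input - pp$report$n_excluded_short -
      pp$report$n_excluded_all_missing
  )
  pp2 <- preprocess_cohort(cohort)
  expect_identical(pp$cohort, pp2$cohort)
  expect_identical(pp$maxima, pp2$maxima)
})

test_that("every cascade stage matches the straight-line oracle", {
  for (seed in 1:5) {
    cohort <- random_truncated_cohort(12, seed = seed)
    patients <- oracle_cohort_from_tibble(cohort)

    o1 <- oracle_exclusions(patients)
    p1 <- apply_exclusions(cohort)$cohort
    expect_setequal(
      unique(p1$patient_id), vapply(o1, function(p) p$id, character(1))
    )

    o2 <- oracle_clip(o1, vital_limits())
    p2 <- clip_to_limits(p1)
    o3 <- oracle_window(o2)
    p3 <- window_last_48(p2)
    o4 <- oracle_hourly_means(o3)
    p4 <- impute_hourly_means(p3)
    o5 <- oracle_interpolate(o4)
    p5 <- interpolate_remaining(p4)
    o6 <- oracle_smooth(o5)
    p6 <- smooth_ma3(p5)
    o7 <- oracle_normalize(o6)
    p7 <- normalize_by_max(p6)

    for (stage in list(
      list(o3, p3), list(o4, p4), list(o5, p5),
      list(o6, p6), list(o7$patients, p7$cohort)
    )) {
      oracle_tbl <- oracle_to_tibble(stage[[1]]) |>
        dplyr::arrange(.data$patient_id, .data$hour)
      pkg_tbl <- stage[[2]] |>
        dplyr::arrange(.data$patient_id, .data$hour)
      expect_equal(
        as.matrix(pkg_tbl[vs_names]),
        as.matrix(oracle_tbl[vs_names]),
        tolerance = 1e-12
      )
    }
    expect_equal(p7$maxima$max, o7$maxima, tolerance = 1e-12)
  }
})
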