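test_that("sepsis position is the component-wise median of onset rows", {
  mk <- function(id, onset_vals, label = 1L) {
    m <- const_mat(48, values = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
    m[48, ] <- onset_vals
    labeled_patient(id, m, label)
  }
  cohort <- dplyr::bind_rows(
    mk("a", c(0.2, 0.1, 0.3, 0.4, 0.5, 0.6)),
    mk("b", c(0.5, 0.2, 0.3, 0.4, 0.5, 0.6)),
    mk("c", c(0.9, 0.3, 0.3, 0.4, 0.5, 0.6)),
    mk("neg", rep(0.9, 6), label = 0L) # negatives must not contribute
  )
  pos <- estimate_sepsis_position(cohort)
  expect_s3_class(pos, "sepsis_position")
  expect_equal(unname(pos$components["HR"]), 0.5) # odd count
  expect_equal(unname(pos$components["O2Sat"]), 0.2)
  expect_equal(pos$n_positives_used, 3L)
  expect_equal(pos$estimator, "median_at_onset")

  # even count: midpoint of the central order statistics
  even <- dplyr::bind_rows(
    mk("a", c(0.2, rep(0.5, 5))), mk("b", c(0.4, rep(0.5, 5)))
  )
  expect_equal(
    unname(estimate_sepsis_position(even)$components["HR"]), 0.3
  )

  # invariant under permutation of the positive patients
  shuffled <- dplyr::arrange(cohort, dplyr::desc(.data$patient_id), .data$hour)
  expect_equal(
    estimate_sepsis_position(shuffled)$components, pos$components
  )

  expect_error(
    estimate_sepsis_position(dplyr::filter(cohort, .data$label == 0L)),
    "no positive"
  )
})

test_that("sepsis position JSON round-trips", {
  pos <- new_position_for_test(c(0.5, 0.9, 0.8, 0.5, 0.4, 0.3))
  path <- withr::local_tempfile(fileext = ".json")
  write_sepsis_position(pos, path)
  back <- read_sepsis_position(path)
  expect_equal(back$components, pos$components)
  expect_equal(back$n_positives_used, pos$n_positives_used)
  expect_equal(back$estimator, pos$estimator)
})

test_that("unit vectors have unit norm, with the zero-distance convention", {
  expect_equal(unit_vector(c(3, 4, 0, 0, 0, 0)), c(0.6, 0.8, 0, 0, 0, 0))
  expect_equal(unit_vector(rep(0, 6)), rep(0, 6))
  expect_equal(unit_vector(rep(1e-13, 6)), rep(0, 6))
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(6)
    expect_equal(sum(unit_vector(v)^2), 1, tolerance = 1e-12)
  }
})

test_that("printed sample unit-vector row has unit norm at printed precision", {
  row1 <- c(0.7251, 0.1787, 0.0129, 0.5146, 0.3997, 0.1326)
  expect_lt(abs(sum(row1^2) - 1), 2e-3)
})

test_that("scalar projection follows dot-product semantics", {
  e <- c(0.6, 0.8, 0, 0, 0, 0)
  expect_equal(project_onto_unit(c(1, 1, 0, 0, 0, 0), e), 1.4)
  expect_equal(project_onto_unit(3 * e, e), 3) # parallel: +magnitude
  expect_equal(project_onto_unit(-2 * e, e), -2) # antiparallel
  expect_equal(project_onto_unit(c(0, 0, 1, 0, 0, 0), e), 0) # orthogonal
  expect_equal(project_onto_unit(c(5, 5, 5, 5, 5, 5), rep(0, 6)), 0)
})

test_that("relative kinematics are finite differences with zeroed boundaries", {
  pos <- new_position_for_test(rep(0, 6))

  # stationary patient: zero velocity and acceleration, constant distance
  stat <- labeled_patient("s", const_mat(10, values = c(3, 4, 0, 0, 0, 0)), 0)
  rk <- relative_kinematics(stat, pos)
  expect_equal(rk$dist, rep(5, 10)) # 3-4-5 triangle
  expect_true(all(as.matrix(rk[paste0("v.", vs_names)]) == 0))
  expect_true(all(as.matrix(rk[paste0("a.", vs_names)]) == 0))

  # straight-line motion: constant velocity, zero acceleration
  d <- c(0.1, -0.2, 0.3, 0, 0.05, -0.1)
  m <- t(vapply(0:9, function(t) c(1, 2, 3, 4, 5, 6) + t * d, numeric(6)))
  rk2 <- relative_kinematics(labeled_patient("l", m, 1), pos)
  vel <- as.matrix(rk2[paste0("v.", vs_names)])
  acc <- as.matrix(rk2[paste0("a.", vs_names)])
  expect_equal(vel[1, ], setNames(rep(0, 6), paste0("v.", vs_names)))
  for (t in 2:10) expect_equal(unname(vel[t, ]), d)
  expect_true(all(acc[1:2, ] == 0))
  expect_true(all(abs(acc[3:10, ]) < 1e-12))
})

test_that("velocity and acceleration do not depend on the sepsis position", {
  set.seed(42)
  m <- matrix(runif(48 * 6), 48, 6)
  patient <- labeled_patient("x", m, 1)
  rk_a <- relative_kinematics(patient, new_position_for_test(rep(0.2, 6)))
  rk_b <- relative_kinematics(patient, new_position_for_test(runif(6)))
  vcols <- c(paste0("v.", vs_names), paste0("a.", vs_names))
  expect_equal(rk_a[vcols], rk_b[vcols])
  expect_false(isTRUE(all.equal(rk_a$dist, rk_b$dist)))
})

test_that("kinematics features have 48 rows, 8 columns and unit e-rows", {
  cohort <- random_truncated_cohort(10, seed = 3)
  pp <- preprocess_cohort(cohort)
  position <- estimate_sepsis_position(pp$cohort)
  kf <- kinematics_features(pp$cohort, position)
  expect_named(kf, c("patient_id", "hour", kf_columns(), "label"))
  counts <- dplyr::count(kf, .data$patient_id)
  expect_true(all(counts$n == 48L))

  e_mat <- as.matrix(kf[paste0("e.", vs_names)])
  norms <- rowSums(e_mat^2)
  nonzero <- norms > 0
  expect_true(all(abs(norms[nonzero] - 1) < 1e-9))

  # Cauchy-Schwarz: |ProjV| bounded by the velocity norm
  rk <- relative_kinematics(pp$cohort, position)
  vnorm <- sqrt(rowSums(as.matrix(rk[paste0("v.", vs_names)])^2))
  expect_true(all(abs(kf$ProjV) <= vnorm + 1e-9))
})

test_that("a stationary patient at nonzero distance has constant e and zero projections", {
  pos <- new_position_for_test(rep(0, 6))
  kf <- kinematics_features(
    labeled_patient("s", const_mat(48, values = c(3, 4, 0, 0, 0, 0)), 0), pos
  )
  expect_equal(kf$e.HR, rep(0.6, 48))
  expect_equal(kf$e.O2Sat, rep(0.8, 48))
  expect_equal(kf$ProjV, rep(0, 48))
  expect_equal(kf$ProjA, rep(0, 48))
})

test_that("rectilinear approach along e gives ProjV = signed distance change", {
  pos_vec <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  e0 <- unit_vector(c(1, 2, -1, 0.5, 0, 1))
  s <- 0.03
  m <- t(vapply(
    0:47,
    function(t) pos_vec + (2 - s * t) * e0,
    numeric(6)
  ))
  kf <- kinematics_features(
    labeled_patient("r", m, 1), new_position_for_test(pos_vec)
  )
  rk <- relative_kinematics(
    labeled_patient("r", m, 1), new_position_for_test(pos_vec)
  )
  ddist <- diff(rk$dist)
  expect_equal(kf$ProjV[2:48], ddist, tolerance = 1e-9)
  expect_true(all(abs(kf$ProjV[2:48] + s) < 1e-9)) # approaching at speed s
})

test_that("assembled features match the direct formula transcription", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(runif(48 * 6), 48, 6)
    pos_vec <- runif(6)
    kf <- kinematics_features(
      labeled_patient("o", m, 1), new_position_for_test(pos_vec)
    )
    oracle <- oracle_kf(m, pos_vec)
    expect_equal(
      unname(as.matrix(kf[paste0("e.", vs_names)])), oracle$e,
      tolerance = 1e-12
    )
    expect_equal(kf$ProjV, oracle$projv, tolerance = 1e-12)
    expect_equal(kf$ProjA, oracle$proja, tolerance = 1e-12)
  }
})

test_that("assemble_kf is an alias for kinematics_features", {
  m <- matrix(runif(48 * 6), 48, 6)
  p <- labeled_patient("a", m, 1)
  pos <- new_position_for_test(runif(6))
  expect_identical(assemble_kf(p, pos), kinematics_features(p, pos))
})
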