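# Builders for small in-code cohorts used across the tests.

vs_names <- sepkin::vital_signs()

# one patient's tibble in the raw schema from a T x 6 matrix
raw_patient <- function(id, mat, sepsis_label = NULL) {
  mat <- as.matrix(mat)
  colnames(mat) <- vs_names
  if (is.null(sepsis_label)) sepsis_label <- rep(0, nrow(mat))
  dplyr::bind_cols(
    tibble::tibble(patient_id = id, hour = seq_len(nrow(mat)) - 1L),
    tibble::as_tibble(mat),
    tibble::tibble(SepsisLabel = sepsis_label)
  )
}

# one patient's tibble in the truncated schema (per-patient label column)
labeled_patient <- function(id, mat, label) {
  mat <- as.matrix(mat)
  colnames(mat) <- vs_names
  dplyr::bind_cols(
    tibble::tibble(patient_id = id, hour = seq_len(nrow(mat)) - 1L),
    tibble::as_tibble(mat),
    tibble::tibble(label = as.integer(label))
  )
}

# constant-valued series matrix with optional per-sign overrides
const_mat <- function(n_rows, values = c(80, 97, 37, 120, 60, 18)) {
  if (n_rows == 0L) {
    return(matrix(numeric(0), 0L, 6L))
  }
  matrix(values, n_rows, 6L, byrow = TRUE)
}

# the 10-patient exclusion/windowing fixture: 3 too short, 2 with one
# all-missing sign, 5 valid (one with 40 rows needing 8 padding rows)
exclusion_fixture <- function() {
  mats <- list(
    short1 = const_mat(10),
    short2 = const_mat(30),
    short3 = const_mat(35),
    miss1 = {
      m <- const_mat(50)
      m[, 2] <- NA_real_
      m
    },
    miss2 = {
      m <- const_mat(48)
      m[, 5] <- NA_real_
      m
    },
    ok40 = const_mat(40),
    ok48 = const_mat(48),
    ok50 = const_mat(50),
    ok60 = const_mat(60),
    ok36 = {
      m <- const_mat(36)
      m[3, 1] <- NA_real_ # partially missing is fine
      m
    }
  )
  purrr::imap(
    mats,
    function(m, id) labeled_patient(id, m, label = as.integer(id == "ok48"))
  ) |>
    purrr::list_rbind()
}

# a sepsis_position at arbitrary components, bypassing estimation
new_position_for_test <- function(components) {
  sepkin:::new_sepsis_position(components, n_positives_used = 1L)
}

# small random truncated cohort with missingness, for oracle comparisons
random_truncated_cohort <- function(n_patients = 20L, seed = 1L) {
  cfg <- sepkin::sim_config(
    n_positive = ceiling(n_patients / 2),
    n_negative = floor(n_patients / 2),
    seed = seed
  )
  sepkin::simulate_cohort(cfg)$cohort |>
    sepkin::extract_vitals() |>
    sepkin::truncate_at_onset()
}
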