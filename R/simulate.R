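#' Configuration for the synthetic-cohort simulator
#'
#' The simulator emulates the statistical structure the kinematics method
#' assumes: negative patients fluctuate around baseline vital signs with
#' autocorrelated (AR(1)) hourly noise; positive patients follow the same
#' process but over their final `drift_hours` the mean trajectory moves
#' linearly from baseline to a planted sepsis point, with the sepsis label
#' raised on the final row. Realistic corruption is added on top:
#' per-cell missingness and occasional out-of-limits sensor spikes.
#'
#' Default baselines and noise scales are typical adult ICU values in each
#' sign's units; the default planted point has the lowered systolic
#' pressure and raised heart, respiration rate and temperature that
#' characterise septic deterioration.
#'
#' @param n_positive,n_negative Cohort sizes.
#' @param length_range Integer bounds on the per-patient series length in
#'   hours (uniform draw).
#' @param baseline Named numeric (6): mean vital signs, [vital_signs()]
#'   order.
#' @param sepsis_point Named numeric (6): planted sepsis position in
#'   unnormalised units.
#' @param noise_sd Named numeric (6): stationary SD of the AR(1) noise per
#'   sign.
#' @param ar Autocorrelation of the hourly noise (default 0.8).
#' @param drift_hours Hours over which a positive's mean drifts to the
#'   planted point (default 12).
#' @param missing_rate Probability a vital-sign cell is missing.
#' @param error_rate Probability a cell is replaced by an out-of-limits
#'   spike.
#' @param seed Master seed; per-patient substreams are derived from it so
#'   a patient's series does not depend on cohort composition.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_positive = 50L,
                       n_negative = 50L,
                       length_range = c(30L, 120L),
                       baseline = c(
                         HR = 85, O2Sat = 97.5, Temp = 37.0,
                         SBP = 120, DBP = 62, Resp = 18
                       ),
                       sepsis_point = c(
                         HR = 100, O2Sat = 96, Temp = 37.8,
                         SBP = 91, DBP = 58, Resp = 21.7
                       ),
                       noise_sd = c(
                         HR = 6, O2Sat = 1.5, Temp = 0.3,
                         SBP = 8, DBP = 5, Resp = 2
                       ),
                       ar = 0.8,
                       drift_hours = 12L,
                       missing_rate = 0.1,
                       error_rate = 0.005,
                       seed = 1L) {
  vs <- vital_signs()
  stopifnot(
    n_positive >= 0L, n_negative >= 0L,
    length(length_range) == 2L, length_range[1] >= 1L,
    length_range[1] <= length_range[2],
    setequal(names(baseline), vs),
    setequal(names(sepsis_point), vs),
    setequal(names(noise_sd), vs),
    ar >= 0, ar < 1,
    drift_hours >= 1L,
    missing_rate >= 0, missing_rate <= 1,
    error_rate >= 0, error_rate <= 1
  )
  structure(
    list(
      n_positive = as.integer(n_positive),
      n_negative = as.integer(n_negative),
      length_range = as.integer(length_range),
      baseline = baseline[vs],
      sepsis_point = sepsis_point[vs],
      noise_sd = noise_sd[vs],
      ar = ar,
      drift_hours = as.integer(drift_hours),
      missing_rate = missing_rate,
      error_rate = error_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# deterministic per-patient substream seed, independent of cohort makeup
patient_seed <- function(master, index, label) {
  as.integer(
    (as.double(master) * 48271 + index * 2 + label) %% 2147483647
  )
}

#' Simulate one patient's hourly record
#'
#' @param config A [sim_config()].
#' @param label 0 (negative) or 1 (positive).
#' @param index Patient index within its label group (drives the RNG
#'   substream).
#' @param patient_id Identifier; default `p<label><index>`.
#' @return List with `record` (tibble in the raw cohort schema:
#'   `patient_id`, `hour`, vital signs, `SepsisLabel`) and `truth`
#'   (one-row tibble: `patient_id`, `label`, `length`, `onset_index`).
#' @export
simulate_patient <- function(config, label, index = 1L,
                             patient_id = sprintf("p%d%04d", label, index)) {
  vs <- vital_signs()
  with_local_seed(patient_seed(config$seed, index, label), {
    t_len <- sample(config$length_range[1]:config$length_range[2], 1L)
    mean_path <- matrix(config$baseline, t_len, 6L, byrow = TRUE)
    if (label == 1L) {
      d <- min(config$drift_hours, t_len - 1L)
      frac <- seq(0, 1, length.out = d + 1L)
      shift <- config$sepsis_point - config$baseline
      rows <- (t_len - d):t_len
      mean_path[rows, ] <- mean_path[rows, , drop = FALSE] +
        outer(frac, shift)
    }
    noise <- vapply(seq_along(vs), function(j) {
      sd_j <- config$noise_sd[j]
      if (sd_j == 0) {
        return(numeric(t_len))
      }
      e <- numeric(t_len)
      innov_sd <- sd_j * sqrt(1 - config$ar^2)
      e[1] <- stats::rnorm(1L, 0, sd_j)
      for (t in seq_len(t_len)[-1]) {
        e[t] <- config$ar * e[t - 1] + stats::rnorm(1L, 0, innov_sd)
      }
      e
    }, numeric(t_len))
    values <- mean_path + noise
    # out-of-limits sensor spikes, then missingness
    if (config$error_rate > 0) {
      lim <- vital_limits()
      spikes <- matrix(
        stats::runif(t_len * 6L) < config$error_rate, t_len, 6L
      )
      for (j in seq_len(6L)) {
        hit <- which(spikes[, j])
        if (length(hit) > 0L) {
          high <- stats::runif(length(hit)) < 0.5
          values[hit[high], j] <- lim$upper[j] *
            stats::runif(sum(high), 1.5, 3)
          values[hit[!high], j] <- lim$lower[j] *
            stats::runif(sum(!high), 0, 0.5)
        }
      }
    }
    if (config$missing_rate > 0) {
      values[matrix(
        stats::runif(t_len * 6L) < config$missing_rate, t_len, 6L
      )] <- NA_real_
    }
    record <- tibble::as_tibble(values, .name_repair = "minimal")
    names(record) <- vs
    record <- record |>
      dplyr::mutate(
        patient_id = patient_id,
        hour = dplyr::row_number() - 1L,
        SepsisLabel = c(
          rep(0, t_len - 1L),
          if (label == 1L) 1 else 0
        ),
        .before = 1L
      ) |>
      dplyr::relocate("SepsisLabel", .after = dplyr::last_col())
    truth <- tibble::tibble(
      patient_id = patient_id,
      label = as.integer(label),
      length = t_len,
      onset_index = if (label == 1L) t_len - 1L else NA_integer_
    )
    list(record = record, truth = truth)
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_positive + n_negative` patients from independent seeded
#' substreams. Optionally writes one `.psv` file per patient plus the
#' planted ground truth as JSON.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for `.psv` files and
#'   `truth.json`.
#' @return List with `cohort` (stacked raw records), `truth` (per-patient
#'   tibble), `sepsis_point` (the planted point) and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  sims <- c(
    purrr::map(
      seq_len(config$n_positive),
      function(i) simulate_patient(config, 1L, i)
    ),
    purrr::map(
      seq_len(config$n_negative),
      function(i) simulate_patient(config, 0L, i)
    )
  )
  cohort <- purrr::map(sims, "record") |> purrr::list_rbind()
  truth <- purrr::map(sims, "truth") |> purrr::list_rbind()
  if (!is.null(dir)) {
    write_psv(cohort, dir)
    jsonlite::write_json(
      list(
        sepsis_point = as.list(config$sepsis_point),
        patients = truth
      ),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(
    cohort = cohort, truth = truth,
    sepsis_point = config$sepsis_point, config = config
  )
}
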