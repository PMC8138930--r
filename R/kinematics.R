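#' Estimate the sepsis position in vital-sign space
#'
#' The sepsis position is the single static target point toward which
#' positive patients converge: component j is the median, over the positive
#' patients, of vital sign j at each patient's sepsis onset. After
#' onset truncation and windowing, onset is the last row of every
#' positive's series, so the estimator takes the final register of each
#' positive patient and computes a component-wise median (even counts use
#' the midpoint of the two central order statistics; missing onset cells
#' are ignored).
#'
#' @param cohort Cohort tibble (`patient_id`, `hour`, vital signs,
#'   `label`); only patients with `label == 1` contribute.
#' @return Object of class `sepsis_position`: list with `components`
#'   (named numeric of length 6 in [vital_signs()] order),
#'   `n_positives_used` and `estimator` (`"median_at_onset"`).
#' @export
estimate_sepsis_position <- function(cohort) {
  vs <- vital_signs()
  pos <- dplyr::filter(cohort, .data$label == 1L)
  if (nrow(pos) == 0L) {
    stop("cannot estimate a sepsis position: no positive patients", call. = FALSE)
  }
  onset_rows <- pos |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup()
  components <- vapply(
    vs,
    function(s) stats::median(onset_rows[[s]], na.rm = TRUE),
    numeric(1)
  )
  new_sepsis_position(components, n_positives_used = nrow(onset_rows))
}

new_sepsis_position <- function(components,
                                n_positives_used,
                                estimator = "median_at_onset") {
  stopifnot(length(components) == 6L)
  names(components) <- vital_signs()
  structure(
    list(
      components = components,
      n_positives_used = as.integer(n_positives_used),
      estimator = estimator
    ),
    class = "sepsis_position"
  )
}

#' @export
print.sepsis_position <- function(x, ...) {
  cat("<sepsis_position> estimator:", x$estimator,
      "| positives used:", x$n_positives_used, "\n")
  print(round(x$components, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sepsis position into one row per vital sign
#'
#' @param x A `sepsis_position`.
#' @param ... Unused.
#' @return Tibble with columns `sign` and `component`.
#' @export
tidy.sepsis_position <- function(x, ...) {
  tibble::tibble(sign = names(x$components), component = unname(x$components))
}

#' Serialise / restore a sepsis position as JSON
#'
#' @param x A `sepsis_position`.
#' @param path File path to write to / read from.
#' @return `write_sepsis_position()` invisibly returns `path`;
#'   `read_sepsis_position()` returns the restored `sepsis_position`.
#' @export
write_sepsis_position <- function(x, path) {
  jsonlite::write_json(
    list(
      components = as.list(x$components),
      n_positives_used = x$n_positives_used,
      estimator = x$estimator
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_sepsis_position
#' @export
read_sepsis_position <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sepsis_position(
    unlist(obj$components),
    n_positives_used = obj$n_positives_used,
    estimator = obj$estimator
  )
}

#' Unit vector of a relative position
#'
#' Divides the relative position by its Euclidean norm. When the distance
#' is at or below `eps` the patient coincides with the sepsis position and
#' the direction is undefined; the zero vector is returned by convention.
#'
#' @param relative_position Numeric vector (patient position minus sepsis
#'   position).
#' @param distance Optional pre-computed Euclidean norm.
#' @param eps Degeneracy tolerance on the distance (default 1e-12).
#' @return Numeric vector of the same length with unit norm, or all zeros.
#' @export
#' @examples
#' unit_vector(c(3, 4, 0, 0, 0, 0))
unit_vector <- function(relative_position, distance = NULL, eps = 1e-12) {
  if (is.null(distance)) {
    distance <- sqrt(sum(relative_position^2))
  }
  if (distance <= eps) {
    return(rep(0, length(relative_position)))
  }
  relative_position / distance
}

#' Scalar projection onto a unit direction
#'
#' The dot product of a (velocity or acceleration) vector with the unit
#' relative-position vector. Positive values mean the patient is moving
#' away from the sepsis position, negative values that it is approaching;
#' a zero unit vector yields 0.
#'
#' @param vector Numeric vector to project.
#' @param unit Unit vector (or the zero vector in the degenerate case).
#' @return Scalar projection.
#' @export
project_onto_unit <- function(vector, unit) {
  sum(vector * unit)
}

# finite-difference kinematics for one patient's T x 6 matrix
patient_kinematics <- function(mat, position, eps = 1e-12) {
  rel <- sweep(mat, 2L, position, "-")
  n <- nrow(rel)
  dist <- sqrt(rowSums(rel^2))
  vel <- rbind(matrix(0, 1L, ncol(rel)), diff(rel))
  acc <- rbind(matrix(0, 1L, ncol(rel)), diff(vel))
  acc[seq_len(min(2L, n)), ] <- 0
  e <- rel / ifelse(dist > eps, dist, Inf)
  list(
    rel = rel, dist = dist, vel = vel, acc = acc, e = e,
    proj_v = rowSums(vel * e), proj_a = rowSums(acc * e)
  )
}

#' Relative kinematics of each patient with respect to the sepsis position
#'
#' For every patient and hour: the relative position (patient minus sepsis
#' position), its Euclidean distance, the relative velocity (first
#' difference over the 1-hour grid) and the relative acceleration (first
#' difference of the velocity). Because the sepsis position is static, the
#' relative velocity and acceleration equal the patient's own. Boundary
#' conventions keep the full window length: v(0) = 0 and a(0) = a(1) = 0.
#'
#' @param cohort Preprocessed cohort tibble (fixed-width, missing-free).
#' @param position A `sepsis_position` (or bare numeric of length 6).
#' @return Tibble with `patient_id`, `hour`, `r.<sign>` columns, `dist`,
#'   `v.<sign>`, `a.<sign>` and `label`.
#' @export
relative_kinematics <- function(cohort, position) {
  comp <- position_components(position)
  vs <- vital_signs()
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      k <- patient_kinematics(as.matrix(df[vs]), comp)
      out <- tibble::as_tibble(
        cbind(k$rel, k$vel, k$acc),
        .name_repair = "minimal"
      )
      names(out) <- c(
        paste0("r.", vs), paste0("v.", vs), paste0("a.", vs)
      )
      out$dist <- k$dist
      out$hour <- df$hour
      out$label <- df$label
      dplyr::relocate(
        out, "hour",
        dplyr::starts_with("r."), "dist",
        dplyr::starts_with("v."), dplyr::starts_with("a."),
        "label"
      )
    }) |>
    dplyr::ungroup()
}

position_components <- function(position) {
  if (inherits(position, "sepsis_position")) {
    position$components
  } else {
    stopifnot(is.numeric(position), length(position) == 6L)
    stats::setNames(as.numeric(position), vital_signs())
  }
}

#' Assemble the eight kinematics features per patient and hour
#'
#' The kinematics-feature (KF) representation of a patient: the six
#' components of the unit relative-position vector (`e.HR` ... `e.Resp`)
#' followed by the scalar projections of the relative velocity (`ProjV`)
#' and the relative acceleration (`ProjA`) onto that direction. Rows at a
#' degenerate (zero) distance get a zero unit vector and zero projections;
#' the first one/two rows use the zero-velocity/zero-acceleration boundary
#' conventions so each patient keeps the full window length.
#'
#' @inheritParams relative_kinematics
#' @param eps Degeneracy tolerance on the distance (default 1e-12).
#' @return Tibble with `patient_id`, `hour`, `e.HR`, `e.O2Sat`, `e.Temp`,
#'   `e.SBP`, `e.DBP`, `e.Resp`, `ProjV`, `ProjA`, `label`.
#' @export
kinematics_features <- function(cohort, position, eps = 1e-12) {
  comp <- position_components(position)
  vs <- vital_signs()
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      k <- patient_kinematics(as.matrix(df[vs]), comp, eps = eps)
      out <- tibble::as_tibble(k$e, .name_repair = "minimal")
      names(out) <- paste0("e.", vs)
      out$ProjV <- k$proj_v
      out$ProjA <- k$proj_a
      out$hour <- df$hour
      out$label <- df$label
      dplyr::relocate(out, "hour")
    }) |>
    dplyr::ungroup()
}

#' @rdname kinematics_features
#' @export
assemble_kf <- kinematics_features

#' Names of the eight kinematics-feature columns
#'
#' @return Character vector `e.HR` ... `e.Resp`, `ProjV`, `ProjA`.
#' @export
kf_columns <- function() {
  c(paste0("e.", vital_signs()), "ProjV", "ProjA")
}
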