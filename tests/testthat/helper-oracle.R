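# Independent straight-line re-implementation of the preprocessing
# cascade and the kinematics formulas, written with plain loops and no
# package internals. Used as the reference the vectorised pipeline must
# match exactly.

# cohort here is a list of list(id, mat (T x 6), label)
oracle_cohort_from_tibble <- function(cohort) {
  ids <- unique(cohort$patient_id)
  lapply(ids, function(id) {
    df <- cohort[cohort$patient_id == id, ]
    df <- df[order(df$hour), ]
    list(id = id, mat = as.matrix(df[vs_names]), label = df$label[1])
  })
}

oracle_to_tibble <- function(patients) {
  purrr::map(patients, function(p) {
    labeled_patient(p$id, p$mat, p$label)
  }) |> purrr::list_rbind()
}

oracle_exclusions <- function(patients, min_rows = 36L) {
  keep <- list()
  for (p in patients) {
    if (nrow(p$mat) < min_rows) next
    all_missing <- FALSE
    for (j in 1:6) {
      if (all(is.na(p$mat[, j]))) all_missing <- TRUE
    }
    if (all_missing) next
    keep[[length(keep) + 1]] <- p
  }
  keep
}

oracle_clip <- function(patients, limits) {
  for (i in seq_along(patients)) {
    for (j in 1:6) {
      lo <- limits$lower[limits$sign == vs_names[j]]
      hi <- limits$upper[limits$sign == vs_names[j]]
      for (t in seq_len(nrow(patients[[i]]$mat))) {
        v <- patients[[i]]$mat[t, j]
        if (!is.na(v) && (v < lo || v > hi)) {
          patients[[i]]$mat[t, j] <- NA_real_
        }
      }
    }
  }
  patients
}

oracle_window <- function(patients, width = 48L) {
  for (i in seq_along(patients)) {
    m <- patients[[i]]$mat
    n <- nrow(m)
    if (n >= width) {
      out <- m[(n - width + 1):n, , drop = FALSE]
    } else {
      out <- rbind(matrix(NA_real_, width - n, 6L), m)
    }
    patients[[i]]$mat <- out
  }
  patients
}

oracle_hourly_means <- function(patients, width = 48L) {
  for (t in seq_len(width)) {
    for (j in 1:6) {
      vals <- vapply(patients, function(p) p$mat[t, j], numeric(1))
      if (any(!is.na(vals)) && any(is.na(vals))) {
        m <- mean(vals[!is.na(vals)])
        for (i in seq_along(patients)) {
          if (is.na(patients[[i]]$mat[t, j])) {
            patients[[i]]$mat[t, j] <- m
          }
        }
      }
    }
  }
  patients
}

oracle_interpolate <- function(patients) {
  for (i in seq_along(patients)) {
    for (j in 1:6) {
      x <- patients[[i]]$mat[, j]
      obs <- which(!is.na(x))
      stopifnot(length(obs) > 0)
      for (t in which(is.na(x))) {
        left <- obs[obs < t]
        right <- obs[obs > t]
        if (length(left) == 0) {
          x[t] <- x[min(right)]
        } else if (length(right) == 0) {
          x[t] <- x[max(left)]
        } else {
          l <- max(left)
          r <- min(right)
          x[t] <- x[l] + (x[r] - x[l]) * (t - l) / (r - l)
        }
      }
      patients[[i]]$mat[, j] <- x
    }
  }
  patients
}

oracle_smooth <- function(patients, width = 3L) {
  for (i in seq_along(patients)) {
    m <- patients[[i]]$mat
    out <- m
    for (t in seq_len(nrow(m))) {
      lo <- max(1, t - width + 1)
      for (j in 1:6) {
        out[t, j] <- mean(m[lo:t, j])
      }
    }
    patients[[i]]$mat <- out
  }
  patients
}

oracle_normalize <- function(patients) {
  maxima <- numeric(6)
  for (j in 1:6) {
    maxima[j] <- max(vapply(patients, function(p) max(p$mat[, j]), numeric(1)))
  }
  for (i in seq_along(patients)) {
    for (j in 1:6) {
      patients[[i]]$mat[, j] <- patients[[i]]$mat[, j] / maxima[j]
    }
  }
  list(patients = patients, maxima = maxima)
}

oracle_preprocess <- function(patients, limits = sepkin::vital_limits(),
                              min_rows = 36L, width = 48L,
                              smooth_width = 3L) {
  patients |>
    oracle_exclusions(min_rows) |>
    oracle_clip(limits) |>
    oracle_window(width) |>
    oracle_hourly_means(width) |>
    oracle_interpolate() |>
    oracle_smooth(smooth_width) |>
    oracle_normalize()
}

# direct transcription of the kinematics formulas for one patient
oracle_kf <- function(mat, position, eps = 1e-12) {
  n <- nrow(mat)
  e <- matrix(0, n, 6)
  projv <- numeric(n)
  proja <- numeric(n)
  rel <- matrix(0, n, 6)
  vel <- matrix(0, n, 6)
  acc <- matrix(0, n, 6)
  for (t in seq_len(n)) {
    rel[t, ] <- mat[t, ] - position
  }
  for (t in seq_len(n)) {
    if (t >= 2) vel[t, ] <- rel[t, ] - rel[t - 1, ]
    if (t >= 3) acc[t, ] <- vel[t, ] - vel[t - 1, ]
  }
  for (t in seq_len(n)) {
    dist <- sqrt(sum(rel[t, ]^2))
    if (dist > eps) e[t, ] <- rel[t, ] / dist
    projv[t] <- sum(vel[t, ] * e[t, ])
    proja[t] <- sum(acc[t, ] * e[t, ])
  }
  list(e = e, projv = projv, proja = proja, vel = vel, acc = acc)
}
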