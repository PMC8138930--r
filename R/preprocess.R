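#' Default operating limits for the six vital signs
#'
#' Values observed outside these closed intervals are treated as sensor or
#' transcription errors and replaced by missing values. The defaults are
#' deliberately wide physiological plausibility bounds; substitute your own
#' table to match a specific monitoring guideline.
#'
#' @return Tibble with columns `sign`, `lower`, `upper`.
#' @export
#' @examples
#' vital_limits()
vital_limits <- function() {
  tibble::tribble(
    ~sign,    ~lower, ~upper,
    "HR",        20,    300,
    "O2Sat",     50,    100,
    "Temp",      30,     45,
    "SBP",       40,    300,
    "DBP",       20,    200,
    "Resp",       4,     60
  )
}

#' Replace out-of-range vital-sign values by missing
#'
#' Values strictly outside the closed interval `[lower, upper]` for their
#' sign become `NA`; values at or within the bounds are untouched.
#'
#' @param cohort Cohort tibble with the six vital-sign columns.
#' @param limits Limits table as [vital_limits()]; must have `lower < upper`
#'   for every sign.
#' @return The cohort with out-of-range values replaced by `NA`.
#' @export
clip_to_limits <- function(cohort, limits = vital_limits()) {
  stopifnot(all(limits$lower < limits$upper))
  for (j in seq_len(nrow(limits))) {
    s <- limits$sign[j]
    if (!s %in% names(cohort)) next
    x <- cohort[[s]]
    bad <- !is.na(x) & (x < limits$lower[j] | x > limits$upper[j])
    x[bad] <- NA_real_
    cohort[[s]] <- x
  }
  cohort
}

#' Apply the cohort exclusion rules
#'
#' Two sequential rules: (1) drop patients with fewer than `min_rows`
#' hourly registers; (2) of the remainder, drop patients for whom at least
#' one vital sign is entirely missing. A patient failing both rules is
#' counted once, under the first.
#'
#' @param cohort Onset-truncated cohort tibble (`patient_id`, `hour`,
#'   vital signs, `label`).
#' @param min_rows Minimum number of registers (default 36, three 12-h
#'   medical shifts).
#' @return List with `cohort` (retained patients) and `report`, a one-row
#'   tibble of counts: `n_input`, `n_excluded_short`,
#'   `n_excluded_all_missing`, `n_retained`, `n_positive`, `n_negative`.
#' @export
apply_exclusions <- function(cohort, min_rows = 36L) {
  vs <- vital_signs()
  per_patient <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_rows = dplyr::n(),
      any_sign_all_missing = any(colSums(!is.na(
        as.matrix(dplyr::pick(dplyr::all_of(vs)))
      )) == 0L),
      label = .data$label[1L],
      .groups = "drop"
    )
  short <- per_patient$n_rows < min_rows
  all_missing <- !short & per_patient$any_sign_all_missing
  keep_ids <- per_patient$patient_id[!short & !all_missing]
  kept <- dplyr::filter(cohort, .data$patient_id %in% keep_ids)
  kept_labels <- per_patient$label[!short & !all_missing]
  report <- tibble::tibble(
    n_input = nrow(per_patient),
    n_excluded_short = sum(short),
    n_excluded_all_missing = sum(all_missing),
    n_retained = length(keep_ids),
    n_positive = sum(kept_labels == 1L),
    n_negative = sum(kept_labels == 0L)
  )
  list(cohort = kept, report = report)
}

#' Window every series to a fixed number of trailing hours
#'
#' Keeps the last `width` registers of each patient. Series shorter than
#' `width` are padded at the front with all-missing rows, so that every
#' patient ends at the same relative hour (window hour `width - 1` is the
#' last observed register, the sepsis onset for positives). Hours are
#' re-indexed 0..`width`-1.
#'
#' @param cohort Cohort tibble (`patient_id`, `hour`, vital signs, `label`).
#' @param width Window length in hours (default 48, four medical shifts).
#' @return Cohort tibble in which every patient has exactly `width` rows.
#' @export
window_last_48 <- function(cohort, width = 48L) {
  vs <- intersect(vital_signs(), names(cohort))
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n >= width) {
        out <- df[(n - width + 1L):n, , drop = FALSE]
      } else {
        pad <- df[rep(1L, width - n), , drop = FALSE]
        pad[vs] <- NA_real_
        out <- dplyr::bind_rows(pad, df)
      }
      out$hour <- seq_len(width) - 1L
      out
    }) |>
    dplyr::ungroup()
}

#' Impute missing cells by the cohort mean at each window hour
#'
#' For every vital sign and window hour, missing cells are replaced by the
#' mean of that sign at that hour over all patients with a value there.
#' Hours where no patient has a value stay missing (they are handled by
#' [interpolate_remaining()]). Originally present values are untouched.
#'
#' @param cohort Windowed cohort tibble (all patients aligned on `hour`).
#' @return Cohort tibble with hour-mean-imputed vital signs.
#' @export
impute_hourly_means <- function(cohort) {
  vs <- vital_signs()
  cohort |>
    dplyr::group_by(.data$hour) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vs), function(x) {
      if (anyNA(x) && any(!is.na(x))) {
        x[is.na(x)] <- mean(x, na.rm = TRUE)
      }
      x
    })) |>
    dplyr::ungroup()
}

interp_fill <- function(x) {
  present <- which(!is.na(x))
  if (length(present) == 0L) {
    stop("cannot interpolate a series with no observed values", call. = FALSE)
  }
  if (length(present) == length(x)) {
    return(x)
  }
  if (length(present) == 1L) {
    return(rep(x[present], length(x)))
  }
  # linear between neighbours, nearest-value extension at the edges
  stats::approx(
    x = present, y = x[present], xout = seq_along(x),
    method = "linear", rule = 2L
  )$y
}

#' Fill residual missing values by linear interpolation
#'
#' Each remaining missing run is interpolated linearly against the hour
#' index between its nearest observed neighbours; runs at the start or end
#' of the window are filled by extending the nearest observed value. After
#' this step no missing cells remain.
#'
#' @param cohort Cohort tibble, typically after [impute_hourly_means()].
#' @return Cohort tibble with no missing vital-sign cells.
#' @export
interpolate_remaining <- function(cohort) {
  vs <- vital_signs()
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vs), interp_fill)) |>
    dplyr::ungroup()
}

trailing_ma <- function(x, width = 3L) {
  n <- length(x)
  cs <- cumsum(x)
  full <- seq_len(n) >= width
  out <- numeric(n)
  out[!full] <- cs[!full] / seq_len(n)[!full]
  if (any(full)) {
    idx <- which(full)
    out[idx] <- (cs[idx] - c(0, cs)[idx - width + 1L]) / width
  }
  out
}

#' Smooth each vital sign with a trailing moving average
#'
#' The value at hour t becomes the mean of the observations from hour
#' t-`width`+1 to t. At the start of the window the average runs over the
#' hours available (so the series keeps its full length).
#'
#' @param cohort Missing-free cohort tibble.
#' @param width Moving-average width in hours (default 3).
#' @return Smoothed cohort tibble.
#' @export
smooth_ma3 <- function(cohort, width = 3L) {
  vs <- vital_signs()
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vs), ~ trailing_ma(.x, width))) |>
    dplyr::ungroup()
}

#' Normalise each vital sign by its cohort-wide maximum
#'
#' The minimum is fixed at zero and every value is divided by the maximum
#' of its sign over the whole cohort, so normalised values lie in [0, 1].
#' Pass a previously recorded `maxima` table to reuse a scale (e.g. one fit
#' on training patients only).
#'
#' @param cohort Smoothed, missing-free cohort tibble.
#' @param maxima Optional tibble (`sign`, `max`) of maxima to apply instead
#'   of recomputing them.
#' @return List with `cohort` (normalised) and `maxima` (the per-sign
#'   maxima used).
#' @export
normalize_by_max <- function(cohort, maxima = NULL) {
  vs <- vital_signs()
  if (is.null(maxima)) {
    maxima <- tibble::tibble(
      sign = vs,
      max = unname(vapply(vs, function(s) max(cohort[[s]]), numeric(1)))
    )
  }
  if (any(maxima$max <= 0)) {
    stop(
      "degenerate scale: non-positive maximum for ",
      paste(maxima$sign[maxima$max <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  for (j in seq_len(nrow(maxima))) {
    s <- maxima$sign[j]
    cohort[[s]] <- cohort[[s]] / maxima$max[j]
  }
  list(cohort = cohort, maxima = maxima)
}

#' Balance the cohort by subsampling negatives
#'
#' Keeps every positive patient and a uniform random sample (without
#' replacement) of `target_negative_count` negatives, reproducible under
#' `seed`.
#'
#' @param cohort Cohort tibble with a per-patient `label` column.
#' @param target_negative_count Number of negative patients to retain.
#' @param seed Integer seed for the subsample.
#' @return Balanced cohort tibble.
#' @export
balance_cohort <- function(cohort, target_negative_count, seed = 1L) {
  per_patient <- dplyr::distinct(cohort, .data$patient_id, .data$label)
  neg_ids <- per_patient$patient_id[per_patient$label == 0L]
  if (target_negative_count > length(neg_ids)) {
    stop(
      "target_negative_count (", target_negative_count,
      ") exceeds the number of negative patients (", length(neg_ids), ")",
      call. = FALSE
    )
  }
  keep_neg <- with_local_seed(seed, sample(neg_ids, target_negative_count))
  dplyr::filter(
    cohort,
    .data$label == 1L | .data$patient_id %in% keep_neg
  )
}

#' Run the full preprocessing cascade
#'
#' Sequences the stages in their canonical order: exclusion rules, limit
#' clipping, trailing-window alignment, cohort hourly-mean imputation,
#' linear interpolation, trailing moving-average smoothing,
#' max-normalisation and (optionally) negative subsampling.
#'
#' @param cohort Onset-truncated cohort tibble (`patient_id`, `hour`,
#'   vital signs, `label`), e.g. from [truncate_at_onset()].
#' @param limits Operating-limits table, default [vital_limits()].
#' @param min_rows Minimum registers per patient (default 36).
#' @param width Window length in hours (default 48).
#' @param smooth_width Moving-average width (default 3).
#' @param balance_negatives Optional number of negatives to retain; `NULL`
#'   (default) keeps all.
#' @param seed Seed for the balancing subsample.
#' @param maxima Optional fixed normalisation maxima (see
#'   [normalize_by_max()]).
#' @return Object of class `sepkin_preprocessed`: list with `cohort` (48
#'   rows per patient, no missing cells, values in [0, 1]), `report`
#'   (exclusion and cohort counts), and `maxima`.
#' @export
preprocess_cohort <- function(cohort,
                              limits = vital_limits(),
                              min_rows = 36L,
                              width = 48L,
                              smooth_width = 3L,
                              balance_negatives = NULL,
                              seed = 1L,
                              maxima = NULL) {
  excl <- apply_exclusions(cohort, min_rows = min_rows)
  out <- excl$cohort |>
    clip_to_limits(limits) |>
    window_last_48(width = width) |>
    impute_hourly_means() |>
    interpolate_remaining() |>
    smooth_ma3(width = smooth_width)
  norm <- normalize_by_max(out, maxima = maxima)
  result <- norm$cohort
  report <- excl$report
  if (!is.null(balance_negatives)) {
    result <- balance_cohort(result, balance_negatives, seed = seed)
    report$n_negative_retained <- balance_negatives
  } else {
    report$n_negative_retained <- report$n_negative
  }
  structure(
    list(cohort = result, report = report, maxima = norm$maxima),
    class = "sepkin_preprocessed"
  )
}

#' @export
print.sepkin_preprocessed <- function(x, ...) {
  r <- x$report
  cat("<sepkin_preprocessed>\n")
  cat(
    "  patients:", r$n_input, "in ->", r$n_retained, "retained",
    sprintf(
      "(%d short, %d all-missing sign excluded)\n",
      r$n_excluded_short, r$n_excluded_all_missing
    )
  )
  cat(
    "  labels:", r$n_positive, "positive /",
    r$n_negative_retained, "negative retained\n"
  )
  cat(
    "  maxima:",
    paste(sprintf("%s=%.4g", x$maxima$sign, x$maxima$max), collapse = ", "),
    "\n"
  )
  invisible(x)
}

# run code under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
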