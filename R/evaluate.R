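#' Withhold the final hours before onset from a feature table
#'
#' HBS ("hours before sepsis") is the earliness of the prediction: with a
#' 48-row window and `hbs = 6`, only the first 42 rows of each patient are
#' shown to the classifier, so a correct classification predicts sepsis
#' six hours before onset.
#'
#' @param features Per-patient hourly feature tibble (`patient_id`,
#'   `hour`, feature columns, `label`) with `width` rows per patient.
#' @param hbs Number of trailing hours to withhold; `0 <= hbs < width`.
#' @param width Window length (default 48).
#' @return The tibble restricted to `hour < width - hbs`.
#' @export
truncate_to_hbs <- function(features, hbs, width = 48L) {
  if (!is.numeric(hbs) || length(hbs) != 1L || hbs < 0L || hbs >= width) {
    stop("hbs must be a single integer in [0, ", width, ")", call. = FALSE)
  }
  dplyr::filter(features, .data$hour < width - hbs)
}

#' Stack an hourly feature tibble into a classifier input array
#'
#' Converts a per-patient hourly tibble into the `n_patients x rows x
#' columns` array consumed by [fit.sepkin_classifier()], together with the
#' aligned labels. Feature columns are auto-detected: the eight
#' kinematics-feature columns if present, otherwise the six vital signs.
#'
#' @param features Feature tibble (`patient_id`, `hour`, features,
#'   `label`), every patient with the same number of rows.
#' @param columns Optional explicit feature column names.
#' @return List with `x` (array), `y` (0/1 vector), `patient_id`
#'   (character vector aligned with `x`) and `columns`.
#' @export
as_model_input <- function(features, columns = NULL) {
  if (is.null(columns)) {
    columns <- if (all(kf_columns() %in% names(features))) {
      kf_columns()
    } else {
      vital_signs()
    }
  }
  stopifnot(all(columns %in% names(features)))
  features <- dplyr::arrange(features, .data$patient_id, .data$hour)
  ids <- unique(features$patient_id)
  t_len <- nrow(features) / length(ids)
  if (t_len != round(t_len)) {
    stop("patients have unequal numbers of rows", call. = FALSE)
  }
  mat <- as.matrix(features[columns])
  x <- array(0, dim = c(length(ids), t_len, length(columns)))
  for (j in seq_along(columns)) {
    x[, , j] <- t(matrix(mat[, j], nrow = t_len))
  }
  y <- features |>
    dplyr::distinct(.data$patient_id, .data$label) |>
    dplyr::arrange(.data$patient_id)
  list(
    x = x, y = as.integer(y$label), patient_id = y$patient_id,
    columns = columns
  )
}

#' Assign stratified cross-validation folds
#'
#' Patients are partitioned into `k` folds preserving the class ratio,
#' reproducibly under `split_seed`. Reusing one assignment across every
#' model and representation keeps the comparison paired: each fold holds
#' the same patients everywhere.
#'
#' @param y Binary label vector.
#' @param k Number of folds (`k >= 2`).
#' @param split_seed Integer seed for the partition.
#' @return Integer vector of fold ids (1..k) aligned with `y`.
#' @export
kfold_assign <- function(y, k = 5L, split_seed = 1L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (length(y) < k) {
    stop("fewer patients (", length(y), ") than folds (", k, ")",
      call. = FALSE
    )
  }
  folds <- integer(length(y))
  with_local_seed(split_seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' k-fold cross-validation of one classifier on one representation
#'
#' For each fold, trains on the remaining folds and scores accuracy (the
#' fraction of held-out patients whose 0.5-thresholded predicted
#' probability matches the label).
#'
#' @param input Model input list from [as_model_input()].
#' @param spec A [model_spec()].
#' @param k Number of folds (ignored when `folds` is given).
#' @param split_seed Seed for the fold partition (ignored when `folds` is
#'   given).
#' @param folds Optional precomputed fold assignment from
#'   [kfold_assign()].
#' @return List with `folds` (tibble: `fold`, `accuracy`, `n_test`) and
#'   `predictions` (tibble: `patient_id`, `fold`, `prob`, `label`).
#' @export
kfold_cross_validate <- function(input, spec, k = 5L, split_seed = 1L,
                                 folds = NULL) {
  if (is.null(folds)) {
    folds <- kfold_assign(input$y, k = k, split_seed = split_seed)
  }
  k <- max(folds)
  shape <- dim(input$x)[2:3]
  fold_rows <- vector("list", k)
  pred_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    clf <- build_classifier(spec, shape)
    clf <- fit(clf, input$x[!test, , , drop = FALSE], input$y[!test])
    prob <- predict_proba(clf, input$x[test, , , drop = FALSE])
    correct <- as.integer(prob >= 0.5) == input$y[test]
    fold_rows[[f]] <- tibble::tibble(
      fold = f, accuracy = mean(correct), n_test = sum(test)
    )
    pred_rows[[f]] <- tibble::tibble(
      patient_id = input$patient_id[test], fold = f,
      prob = prob, label = input$y[test]
    )
  }
  list(
    folds = purrr::list_rbind(fold_rows),
    predictions = purrr::list_rbind(pred_rows)
  )
}

#' Calibration curve (reliability diagram) points
#'
#' Predictions are grouped into `n_bins` equal-width probability bins;
#' each non-empty bin contributes one point: the mean predicted
#' probability against the observed positive fraction. A well-calibrated
#' classifier tracks the diagonal.
#'
#' @param probabilities Predicted probabilities in [0, 1].
#' @param labels Binary outcome labels aligned with `probabilities`.
#' @param n_bins Number of equal-width bins (default 5).
#' @return Tibble with `bin`, `mean_pred`, `frac_pos`, `n`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 5L) {
  stopifnot(
    length(probabilities) == length(labels),
    all(probabilities >= 0 & probabilities <= 1)
  )
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(probabilities, edges, rightmost.closed = TRUE),
    n_bins
  )
  tibble::tibble(bin = bin, prob = probabilities, label = as.numeric(labels)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_pred = mean(.data$prob),
      frac_pos = mean(.data$label),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Compare classifiers on kinematics-feature versus vital-sign inputs
#'
#' Runs every model spec on both representations with one shared
#' stratified fold assignment, so accuracies are paired patient-for-
#' patient, then summarises mean fold accuracy, its standard deviation,
#' the KF-minus-VS mean difference, and pooled calibration points per
#' model and representation.
#'
#' @param kf_features Kinematics-feature tibble ([kinematics_features()]),
#'   already HBS-truncated.
#' @param vs_features Vital-sign tibble over the same patients, equally
#'   truncated.
#' @param specs List of [model_spec()] objects (default: all five kinds).
#' @param k Number of folds (default 5).
#' @param split_seed Seed for the shared fold partition.
#' @param n_bins Calibration bins (default 5).
#' @return Object of class `cv_report`; see [tidy.cv_report()] /
#'   [glance.cv_report()].
#' @export
compare_models <- function(kf_features, vs_features,
                           specs = default_model_specs(),
                           k = 5L, split_seed = 1L, n_bins = 5L) {
  kf_input <- as_model_input(kf_features, columns = kf_columns())
  vs_input <- as_model_input(vs_features, columns = vital_signs())
  if (!identical(kf_input$patient_id, vs_input$patient_id)) {
    stop("KF and VS inputs must cover the same patients", call. = FALSE)
  }
  if (!identical(kf_input$y, vs_input$y)) {
    stop("KF and VS labels disagree", call. = FALSE)
  }
  folds <- kfold_assign(kf_input$y, k = k, split_seed = split_seed)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$kind, character(1))
  }
  runs <- purrr::imap(specs, function(spec, name) {
    purrr::map(
      list(KF = kf_input, VS = vs_input),
      function(input) kfold_cross_validate(input, spec, folds = folds)
    )
  })
  fold_tbl <- purrr::imap(runs, function(reps, model) {
    purrr::imap(reps, function(res, rep_name) {
      dplyr::mutate(res$folds,
        model = model, representation = rep_name,
        .before = 1L
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  calib_tbl <- purrr::imap(runs, function(reps, model) {
    purrr::imap(reps, function(res, rep_name) {
      calibration_curve(
        res$predictions$prob, res$predictions$label,
        n_bins = n_bins
      ) |>
        dplyr::mutate(model = model, representation = rep_name, .before = 1L)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(
    list(
      folds = fold_tbl, calibration = calib_tbl,
      k = max(folds), split_seed = split_seed
    ),
    class = "cv_report"
  )
}

#' The five default model specifications
#'
#' @param seed Training seed shared by all specs.
#' @param ... Hyperparameter overrides applied to every neural spec (e.g.
#'   `epochs = 15` to shorten training).
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function(seed = 1L, ...) {
  nn_overrides <- list(...)
  make <- function(kind, nn = TRUE) {
    args <- c(list(kind = kind, seed = seed), if (nn) nn_overrides)
    do.call(model_spec, args)
  }
  list(
    lstm = make("lstm"),
    cnn = make("cnn"),
    linear_nn = make("linear_nn"),
    logistic_regression = make("logistic_regression", nn = FALSE),
    decision_tree = make("decision_tree", nn = FALSE)
  )
}

#' Per-fold accuracies of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `model`, `representation`, `fold`, `accuracy`,
#'   `n_test`.
#' @export
tidy.cv_report <- function(x, ...) {
  x$folds
}

#' Comparative summary of a cross-validation report
#'
#' One row per model, ordered by KF mean accuracy (descending): mean
#' accuracy under each representation, their difference, and the fold
#' standard deviations.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `model`, `mean_acc_kf`, `mean_acc_vs`,
#'   `mean_diff`, `std_kf`, `std_vs`.
#' @export
glance.cv_report <- function(x, ...) {
  x$folds |>
    dplyr::group_by(.data$model, .data$representation) |>
    dplyr::summarise(
      mean_acc = mean(.data$accuracy),
      std = stats::sd(.data$accuracy),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "representation",
      values_from = c("mean_acc", "std"),
      names_glue = "{.value}_{tolower(representation)}"
    ) |>
    dplyr::mutate(mean_diff = .data$mean_acc_kf - .data$mean_acc_vs) |>
    dplyr::select(
      "model", "mean_acc_kf", "mean_acc_vs", "mean_diff",
      "std_kf", "std_vs"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_acc_kf))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(
    "<cv_report>", x$k, "folds, split seed", x$split_seed, "\n"
  )
  print(glance(x))
  invisible(x)
}
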