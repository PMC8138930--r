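#' Specify one of the five benchmark classifiers
#'
#' The harness compares five binary classifiers of fixed-length
#' multivariate hourly series. The two sequence models consume the time
#' dimension; the three reference models see the flattened time-by-feature
#' vector.
#'
#' Defaults follow the harness's stated configurations:
#' * `lstm` — 128 hidden units, 20% dropout on the final hidden state,
#'   batch size 64, sigmoid output, binary cross-entropy loss, Adagrad.
#' * `cnn` — one 1-D convolution over time with 64 filters and kernel
#'   size 3, ReLU, global max pooling, dense sigmoid head; same loss and
#'   optimizer.
#' * `linear_nn` — a single dense layer to a sigmoid output on the
#'   flattened input, trained with the same loss and optimizer.
#' * `logistic_regression` — ridge-penalised logistic regression
#'   ([glmnet::glmnet()], `alpha = 0`, penalty `1/n`) on the flattened
#'   input.
#' * `decision_tree` — CART via [rpart::rpart()] with default controls
#'   (no internal cross-validation, so fitting is deterministic).
#'
#' Epoch budget and Adagrad learning rate are not part of the stated
#' configurations; the defaults (50 epochs, early stopping with patience
#' 5 on a training-loss plateau, learning rate 0.1) bound the runtime
#' while letting training converge on cohorts of a few hundred patients.
#'
#' @param kind One of `"lstm"`, `"cnn"`, `"linear_nn"`,
#'   `"logistic_regression"`, `"decision_tree"`.
#' @param ... Named hyperparameter overrides (see Details).
#' @param seed Integer training seed (weight initialisation, minibatch
#'   shuffling, dropout).
#' @return Object of class `model_spec`.
#' @export
#' @examples
#' model_spec("lstm", epochs = 10)
model_spec <- function(kind = c(
                         "lstm", "cnn", "linear_nn",
                         "logistic_regression", "decision_tree"
                       ),
                       ...,
                       seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    lstm = list(
      hidden = 128L, dropout = 0.2, batch_size = 64L,
      epochs = 50L, patience = 5L, learning_rate = 0.1
    ),
    cnn = list(
      filters = 64L, kernel = 3L, batch_size = 64L,
      epochs = 50L, patience = 5L, learning_rate = 0.1
    ),
    linear_nn = list(
      batch_size = 64L, epochs = 50L, patience = 5L,
      learning_rate = 0.1
    ),
    logistic_regression = list(alpha = 0, lambda = NULL),
    decision_tree = list()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop(
      "unknown hyperparameter(s) for ", kind, ": ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  hp <- utils::modifyList(defaults, overrides)
  structure(
    list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, "(seed", paste0(x$seed, ")"), "\n")
  if (length(x$hyperparameters) > 0L) {
    hp <- x$hyperparameters
    cat(" ", paste(names(hp), unlist(lapply(hp, format)),
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' Build a trainable classifier from a spec
#'
#' @param spec A [model_spec()].
#' @param input_shape Integer vector `c(rows, columns)` of one patient's
#'   feature matrix (e.g. `c(42, 8)` for the kinematics representation at
#'   6 hours before onset).
#' @return Object of class `sepkin_classifier` exposing [fit()] and
#'   [predict_proba()].
#' @export
build_classifier <- function(spec, input_shape) {
  stopifnot(inherits(spec, "model_spec"), length(input_shape) == 2L)
  structure(
    list(spec = spec, input_shape = as.integer(input_shape), fit = NULL),
    class = "sepkin_classifier"
  )
}

#' @importFrom generics fit
#' @export
generics::fit

#' Train a classifier
#'
#' @param object A `sepkin_classifier` from [build_classifier()].
#' @param x Numeric array `n_patients x rows x columns` matching the
#'   classifier's `input_shape`.
#' @param y Binary labels (0/1), length `n_patients`.
#' @param ... Unused.
#' @return The classifier with its fitted state attached.
#' @export
fit.sepkin_classifier <- function(object, x, y, ...) {
  stopifnot(
    length(dim(x)) == 3L,
    all(dim(x)[2:3] == object$input_shape),
    dim(x)[1] == length(y)
  )
  y <- as.numeric(y)
  spec <- object$spec
  hp <- spec$hyperparameters
  object$fit <- with_local_seed(spec$seed, switch(spec$kind,
    lstm = fit_lstm(x, y, hp),
    cnn = fit_cnn(x, y, hp),
    linear_nn = fit_linear_nn(x, y, hp),
    logistic_regression = fit_logreg(x, y, hp),
    decision_tree = fit_tree(x, y, hp)
  ))
  object
}

#' Predicted positive-class probabilities
#'
#' @param object A fitted `sepkin_classifier`.
#' @param x Numeric array `n_patients x rows x columns`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(object, x, ...) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.sepkin_classifier <- function(object, x, ...) {
  if (is.null(object$fit)) {
    stop("classifier has not been fitted; call fit() first", call. = FALSE)
  }
  spec <- object$spec
  hp <- spec$hyperparameters
  switch(spec$kind,
    lstm = predict_lstm(object$fit$params, x, hp),
    cnn = predict_cnn(object$fit$params, x, hp),
    linear_nn = predict_linear_nn(object$fit$params, x, hp),
    logistic_regression = predict_logreg(object$fit, x),
    decision_tree = predict_tree(object$fit, x)
  )
}

fit_logreg <- function(x, y, hp) {
  xf <- flatten_input(x)
  lambda <- if (is.null(hp$lambda)) 1 / nrow(xf) else hp$lambda
  fitted <- suppressWarnings(glmnet::glmnet(
    xf, y,
    family = "binomial", alpha = hp$alpha,
    lambda = lambda, standardize = FALSE
  ))
  list(model = fitted, lambda = lambda)
}

predict_logreg <- function(fit, x) {
  xf <- flatten_input(x)
  as.numeric(stats::predict(
    fit$model, newx = xf,
    s = fit$lambda, type = "response"
  ))
}

fit_tree <- function(x, y, hp) {
  df <- as.data.frame(flatten_input(x))
  df$.label <- factor(y, levels = c(0, 1))
  rpart::rpart(
    .label ~ .,
    data = df, method = "class",
    control = rpart::rpart.control(xval = 0L)
  )
}

predict_tree <- function(fit, x) {
  df <- as.data.frame(flatten_input(x))
  as.numeric(stats::predict(fit, newdata = df, type = "prob")[, "1"])
}
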