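#' Configuration for learned histogram grade classifiers
#'
#' @param model `"mlp"` (single-hidden-layer perceptron with softmax
#'   output) or `"logistic"` (multinomial logistic regression).
#' @param hidden_units Hidden units for the MLP.
#' @param decay L2 weight decay; the regulariser controlling MLP capacity.
#' @param max_epochs Maximum optimiser iterations.
#' @param class_weighting `"inverse_frequency"` (per-observation weights
#'   proportional to inverse class frequency, normalised to mean 1) or
#'   `"none"`.
#' @param seed Integer seed; training is reproducible.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(model = c("mlp", "logistic"),
                              hidden_units = 64L,
                              decay = 5e-4,
                              max_epochs = 300L,
                              class_weighting = c("inverse_frequency", "none"),
                              seed = 1L) {
  model <- match.arg(model)
  class_weighting <- match.arg(class_weighting)
  stopifnot(hidden_units >= 1, decay >= 0, max_epochs >= 1)
  structure(list(model = model, hidden_units = as.integer(hidden_units),
                 decay = decay, max_epochs = as.integer(max_epochs),
                 class_weighting = class_weighting, seed = as.integer(seed)),
            class = "classifier_config")
}

feature_matrix <- function(data, grade_col = "grade") {
  drop <- c(grade_col, "patient_id", "slide_id")
  cols <- setdiff(names(data), drop)
  num <- cols[vapply(data[cols], is.numeric, logical(1))]
  if (length(num) == 0) abort("no numeric feature columns found")
  as.matrix(data[num])
}

#' Train a grade classifier on slide histogram features
#'
#' Fits a three-class classifier (MLP via `nnet::nnet` or multinomial
#' logistic regression via `nnet::multinom`) on histogram feature columns,
#' minimising class-weighted cross-entropy so each grade carries equal
#' importance despite cohort imbalance.
#'
#' @param data Data frame with numeric feature columns (e.g. the
#'   `mito_*`/`ki67_*` columns from [gen_cohort()] or [concat_features()])
#'   and a grade column; `patient_id`/`slide_id` columns are ignored.
#' @param config A [classifier_config()].
#' @param grade_col Name of the grade column.
#' @return An object of class `histogram_classifier` with `predict()`,
#'   [tidy()] and [glance()] methods.
#' @export
train_histogram_classifier <- function(data, config = classifier_config(),
                                       grade_col = "grade") {
  stopifnot(inherits(config, "classifier_config"),
            grade_col %in% names(data))
  y <- as_grade(data[[grade_col]])
  if (!all(1:3 %in% y))
    abort("every grade in {1, 2, 3} must be present in the training data")
  x <- feature_matrix(data, grade_col)
  n <- length(y)
  w <- if (config$class_weighting == "inverse_frequency") {
    cls_n <- tabulate(y, 3)
    wv <- n / (3 * cls_n)
    wv[y]
  } else rep(1, n)

  fit <- with_seed_(config$seed, {
    if (config$model == "mlp") {
      nnet::nnet(x = x, y = nnet::class.ind(factor(y, levels = 1:3)),
                 size = config$hidden_units, softmax = TRUE, weights = w,
                 decay = config$decay, maxit = config$max_epochs,
                 trace = FALSE, MaxNWts = 100000)
    } else {
      df <- data.frame(.grade = factor(y, levels = 1:3), x)
      nnet::multinom(.grade ~ ., data = df, weights = w,
                     decay = config$decay, maxit = config$max_epochs,
                     trace = FALSE, MaxNWts = 100000)
    }
  })
  structure(list(fit = fit, config = config,
                 feature_names = colnames(x), n_train = n),
            class = "histogram_classifier")
}

#' @export
print.histogram_classifier <- function(x, ...) {
  cat(sprintf("<histogram_classifier %s, %d features, n_train=%d>\n",
              x$config$model, length(x$feature_names), x$n_train))
  invisible(x)
}

#' Predict grades from a trained histogram classifier
#'
#' @param object A `histogram_classifier`.
#' @param new_data Data frame containing the training feature columns.
#' @param ... Unused.
#' @return Integer vector of predicted grades.
#' @export
predict.histogram_classifier <- function(object, new_data, ...) {
  x <- as.matrix(new_data[object$feature_names])
  if (object$config$model == "mlp") {
    p <- predict(object$fit, x)
    max.col(p, ties.method = "first")
  } else {
    as.integer(as.character(predict(object$fit,
                                    newdata = data.frame(x),
                                    type = "class")))
  }
}

#' @describeIn train_histogram_classifier One row per model coefficient
#'   (logistic) or per connection-weight summary statistic per layer (MLP).
#' @param x A `histogram_classifier`.
#' @param ... Unused.
#' @export
tidy.histogram_classifier <- function(x, ...) {
  if (x$config$model == "logistic") {
    co <- stats::coef(x$fit)
    tibble::tibble(class = rep(rownames(co), ncol(co)),
                   term = rep(colnames(co), each = nrow(co)),
                   estimate = as.vector(co))
  } else {
    w <- x$fit$wts
    tibble::tibble(term = sprintf("w%05d", seq_along(w)), estimate = w)
  }
}

#' @describeIn train_histogram_classifier One-row model summary.
#' @export
glance.histogram_classifier <- function(x, ...) {
  tibble::tibble(model = x$config$model,
                 n_features = length(x$feature_names),
                 n_train = x$n_train,
                 hidden_units = if (x$config$model == "mlp")
                   x$config$hidden_units else NA_integer_,
                 final_value = x$fit$value %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grade-stratified k-fold cross-validation of a histogram classifier
#'
#' For each of `k` permutations, trains on the other folds and evaluates
#' balanced accuracy on the held-out fold's test half (the validation half
#' is reported alongside). The headline number is the k-fold average of the
#' test-half balanced accuracy; per-fold values are retained.
#'
#' @param data Data frame with `patient_id`, a grade column and numeric
#'   feature columns (one row per patient).
#' @param config A [classifier_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold split (training uses `config$seed` offset
#'   by the fold index).
#' @param grade_col Name of the grade column.
#' @return An object of class `grade_cv`; [tidy()] gives per-fold rows and
#'   [glance()] the fold-averaged balanced accuracy.
#' @export
run_cv <- function(data, config = classifier_config(), k = 3L, seed = 1L,
                   grade_col = "grade") {
  stopifnot("patient_id" %in% names(data))
  split <- stratified_folds(
    tibble::tibble(patient_id = data$patient_id,
                   grade = data[[grade_col]]), k = k, seed = seed)
  data <- dplyr::left_join(data, split[c("patient_id", "fold", "heldout_role")],
                           by = "patient_id")
  folds <- purrr::map_dfr(0:(k - 1L), function(f) {
    train <- data[data$fold != f, , drop = FALSE]
    test <- data[data$fold == f & data$heldout_role == "test", , drop = FALSE]
    val  <- data[data$fold == f & data$heldout_role == "val", , drop = FALSE]
    cfg <- config
    cfg$seed <- as.integer(derive_seed(config$seed, f) %% .Machine$integer.max)
    model <- train_histogram_classifier(train, cfg, grade_col)
    ba <- function(d) if (nrow(d)) balanced_accuracy(d[[grade_col]],
                                                     predict(model, d)) else NA_real_
    tibble::tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
                   n_val = nrow(val), ba_test = ba(test), ba_val = ba(val))
  })
  structure(list(folds = folds, config = config, k = k, seed = seed),
            class = "grade_cv")
}

#' @export
print.grade_cv <- function(x, ...) {
  cat(sprintf("<grade_cv %d-fold %s: mean test balanced accuracy %.3f>\n",
              x$k, x$config$model, mean(x$folds$ba_test, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn run_cv Per-fold metrics.
#' @param x A `grade_cv`.
#' @param ... Unused.
#' @export
tidy.grade_cv <- function(x, ...) x$folds

#' @describeIn run_cv Fold-averaged metrics.
#' @export
glance.grade_cv <- function(x, ...) {
  tibble::tibble(model = x$config$model, k = x$k,
                 mean_ba_test = mean(x$folds$ba_test, na.rm = TRUE),
                 mean_ba_val = mean(x$folds$ba_val, na.rm = TRUE))
}
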