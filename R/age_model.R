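#' Split a cohort into training and validation halves
#'
#' @param cohort A `brainage_cohort`.
#' @param fraction Proportion of participants assigned to the training half.
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(cohort, fraction = 0.5) {
  stopifnot(inherits(cohort, "brainage_cohort"), fraction > 0, fraction < 1)
  n <- length(cohort$ages)
  train <- sort(sample.int(n, size = round(fraction * n)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit the radial-kernel support-vector age model
#'
#' Wraps [e1071::svm()] with an RBF kernel and library-default
#' hyperparameters (cost 1, epsilon 0.1, kernel coefficient 1/n_features);
#' features and response are standardized internally on training-set
#' statistics (the library default). The fit is deterministic given the
#' input data.
#'
#' @param features Training feature matrix (participants x features),
#'   all finite.
#' @param ages Training chronological ages.
#' @param cost,epsilon,gamma SVR hyperparameters; `NULL` `gamma` uses
#'   `1/ncol(features)`.
#' @return A fitted model of class `brainage_svr` (wrapping the `svm` fit).
#' @export
fit_age_model <- function(features, ages, cost = 1, epsilon = 0.1,
                          gamma = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(ages), nrow(features) >= 10,
            all(is.finite(features)), all(is.finite(ages)))
  constant <- apply(features, 2, function(x) diff(range(x)) == 0)
  if (all(constant))
    stop("all features are constant; the age model cannot be fit")
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  fit <- e1071::svm(x = features, y = ages, type = "eps-regression",
                    kernel = "radial", cost = cost, epsilon = epsilon,
                    gamma = gamma)
  structure(list(fit = fit, n_features = ncol(features)),
            class = "brainage_svr")
}

#' @export
print.brainage_svr <- function(x, ...) {
  cat(sprintf("Radial-kernel SVR age model (%d features, %d support vectors)\n",
              x$n_features, x$fit$tot.nSV))
  invisible(x)
}

#' Predict age and compute BrainAGE / BrainAGER on a validation set
#'
#' BrainAGE is predicted minus chronological age (positive values suggest an
#' older-looking brain); BrainAGER is the residual of an OLS regression of
#' BrainAGE on age, which by construction has zero mean and zero linear
#' correlation with age.
#'
#' @param model A [fit_age_model()] fit.
#' @param features Validation feature matrix; column count must match the
#'   training matrix.
#' @param ages Validation chronological ages.
#' @return Object of class `age_prediction`: `predicted_age`, `brainage`,
#'   `brainager`, `ages`, and summary scalars `mae` (years), `r_squared`
#'   (1 - SS_res/SS_tot), `r_squared_corr` (squared Pearson correlation,
#'   reported alongside since conventions differ), `age_brainage_corr`, and
#'   `pred_age_slope` (OLS slope of predicted on chronological age).
#' @export
predict_brainage <- function(model, features, ages) {
  stopifnot(inherits(model, "brainage_svr"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 model$n_features, ncol(features)))
  pred <- unname(stats::predict(model$fit, features))
  age_prediction(pred, ages)
}

#' Build an age-prediction result from predicted and chronological ages
#'
#' Computes BrainAGE, BrainAGER and the accuracy summaries from a vector of
#' predicted ages, whatever model produced them. [predict_brainage()] is
#' this applied to the package's SVR; it also serves externally supplied
#' predictions (see [run_screen()]).
#'
#' @param predicted_age,ages Aligned numeric vectors.
#' @return An `age_prediction` object; see [predict_brainage()].
#' @export
age_prediction <- function(predicted_age, ages) {
  stopifnot(length(predicted_age) == length(ages), all(is.finite(ages)))
  brainage <- predicted_age - ages
  degenerate <- all(brainage == 0)
  res <- list(
    predicted_age = predicted_age,
    brainage = brainage,
    brainager = if (degenerate) brainage else residualize(brainage, ages),
    ages = ages,
    mae = mean(abs(brainage)),
    r_squared = 1 - sum(brainage^2) / sum((ages - mean(ages))^2),
    r_squared_corr = stats::cor(predicted_age, ages)^2,
    age_brainage_corr = if (degenerate) 0 else stats::cor(ages, brainage),
    pred_age_slope = unname(stats::coef(stats::lm(predicted_age ~ ages))[2])
  )
  class(res) <- "age_prediction"
  res
}

#' @export
print.age_prediction <- function(x, ...) {
  cat("Age prediction on validation set\n")
  cat(sprintf("  n = %d, MAE = %.2f y, R^2 = %.3f (corr^2 = %.3f)\n",
              length(x$ages), x$mae, x$r_squared, x$r_squared_corr))
  cat(sprintf("  corr(age, BrainAGE) = %.3f, slope(pred ~ age) = %.3f\n",
              x$age_brainage_corr, x$pred_age_slope))
  invisible(x)
}

#' Residualize BrainAGE on chronological age
#'
#' Ordinary-least-squares residuals of `brainage` on an intercept and age.
#' The result (BrainAGER) has exactly zero mean and zero sample correlation
#' with age — an algebraic property of OLS, so it holds to machine
#' precision.
#'
#' @param brainage Numeric vector.
#' @param ages Chronological ages, same length, non-constant, `n >= 3`.
#' @return The residual vector.
#' @export
residualize <- function(brainage, ages) {
  stopifnot(length(brainage) == length(ages), length(ages) >= 3)
  if (stats::sd(ages) == 0)
    stop("ages are constant; the age slope is undefined")
  unname(stats::residuals(stats::lm(brainage ~ ages)))
}

#' Run the split / fit / predict pipeline on a cohort
#'
#' Convenience wrapper: random 50/50 (by default) split, SVR fit on the
#' training half, prediction and BrainAGE/BrainAGER on the validation half.
#'
#' @param cohort A `brainage_cohort`.
#' @param split_fraction Training proportion; defaults to the cohort
#'   config's value.
#' @return A list: `prediction` (an `age_prediction`), `split` (the index
#'   lists), `model`.
#' @export
run_age_pipeline <- function(cohort, split_fraction = NULL) {
  stopifnot(inherits(cohort, "brainage_cohort"))
  cfg <- cohort$config$model
  if (is.null(split_fraction)) split_fraction <- cfg$split_fraction
  split <- split_cohort(cohort, split_fraction)
  model <- fit_age_model(cohort$V[split$train, , drop = FALSE],
                         cohort$ages[split$train],
                         cost = cfg$svr_cost, epsilon = cfg$svr_epsilon,
                         gamma = cfg$svr_gamma)
  pred <- predict_brainage(model, cohort$V[split$test, , drop = FALSE],
                           cohort$ages[split$test])
  list(prediction = pred, split = split, model = model)
}

#' Export prediction results as delimited text
#'
#' Writes a per-participant table (`participant_id, age, predicted_age,
#' brainage, brainager`) and a one-row summary table (`mae, r_squared,
#' r_squared_corr, age_brainage_corr, pred_age_slope`).
#'
#' @param prediction An `age_prediction`.
#' @param path Path of the per-participant CSV; the summary is written next
#'   to it with suffix `_summary.csv`.
#' @param ids Optional participant ids (defaults to 1..n).
#' @return `path`, invisibly.
#' @export
write_prediction <- function(prediction, path, ids = NULL) {
  stopifnot(inherits(prediction, "age_prediction"))
  n <- length(prediction$ages)
  if (is.null(ids)) ids <- seq_len(n)
  utils::write.csv(data.frame(
    participant_id = ids, age = prediction$ages,
    predicted_age = prediction$predicted_age,
    brainage = prediction$brainage, brainager = prediction$brainager
  ), path, row.names = FALSE)
  smry <- data.frame(mae = prediction$mae, r_squared = prediction$r_squared,
                     r_squared_corr = prediction$r_squared_corr,
                     age_brainage_corr = prediction$age_brainage_corr,
                     pred_age_slope = prediction$pred_age_slope)
  utils::write.csv(smry, sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  invisible(path)
}
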