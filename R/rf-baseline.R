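#' Random-forest baseline configuration
#'
#' Protocol parameters for the bagged-tree baseline: `ntree = 1000` trees per
#' forest, `n_repeats = 100` independently seeded forests whose predictions
#' are averaged (to suppress bagging variability), and `mtry = floor(p/3) = 2`
#' candidate features per split for the six-feature regression.
#'
#' @param ntree trees per forest.
#' @param mtry candidate features per split, in `[1, 6]`.
#' @param n_repeats number of forests averaged.
#' @param seed integer RNG root seed; per-forest seeds are derived from it.
#' @return an object of class `rf_config`.
#' @export
rf_config <- function(ntree = 1000, mtry = 2, n_repeats = 100, seed = 1L) {
  if (ntree < 1 || n_repeats < 1 || mtry < 1 || mtry > 6) {
    stop_domain("invalid rf configuration")
  }
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "rf_config")
}

RF_FEATURES <- c("shear_rate", "time_min", "hematocrit", "platelet_conc",
                 "blood", "tissue")

#' Feature frame for the random-forest baseline
#'
#' The six predictors used by the baseline, in fixed order: four quantitative
#' (shear rate, perfusion time, hematocrit, platelet concentration) and two
#' qualitative (blood treatment, tissue), the latter as factors with the full
#' level sets so encodings are identical across training and test splits.
#'
#' @param records a [perfusion_table].
#' @param features subset of feature names to keep (for leave-one-feature-out).
#' @return a data.frame of predictors.
#' @export
rf_features <- function(records, features = RF_FEATURES) {
  unknown <- setdiff(features, RF_FEATURES)
  if (length(unknown) > 0L) {
    stop_domain("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  full <- data.frame(
    shear_rate = records$shear_rate,
    time_min = records$time_min,
    hematocrit = records$hematocrit,
    platelet_conc = records$platelet_conc,
    blood = factor(records$blood, levels = BLOOD_LEVELS),
    tissue = factor(records$tissue, levels = TISSUE_LEVELS),
    stringsAsFactors = FALSE
  )
  full[, features, drop = FALSE]
}

#' Fit the post-hoc linear correction
#'
#' Simple least-squares regression of observed on predicted log10 deposition;
#' the corrected prediction is `slope * raw + intercept`. Fitted on
#' training-set out-of-bag predictions, never on test data.
#'
#' @param observed observed log10 deposition values.
#' @param predicted raw ensemble predictions for the same records.
#' @return a list of class `linear_correction` with `slope` and `intercept`.
#' @export
fit_linear_correction <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop_domain("need >= 2 paired values")
  }
  if (sd(predicted) == 0) {
    stop_domain("constant predictions: correction slope undefined")
  }
  slope <- cov(observed, predicted) / var(predicted)
  structure(list(slope = slope,
                 intercept = mean(observed) - slope * mean(predicted)),
            class = "linear_correction")
}

#' Train the averaged random-forest ensemble
#'
#' Trains `n_repeats` forests on log10 deposition with seeds derived
#' deterministically from `config$seed`, and predicts with the mean of their
#' outputs. A linear correction ([fit_linear_correction]) is estimated from
#' the averaged out-of-bag predictions of the training set. The training
#' ranges of the quantitative features are stored so test-time extrapolation
#' outside the training hull can be flagged.
#'
#' @param train a [perfusion_table] with measured deposition (>= 2 records).
#' @param config an [rf_config].
#' @param features feature names to use (default all six).
#' @return an object of class `rf_ensemble`.
#' @export
rf_train <- function(train, config = rf_config(), features = RF_FEATURES) {
  train <- train[!is.na(train$deposition), , drop = FALSE]
  if (nrow(train) < 2L) stop_domain("need >= 2 measured training records")
  x <- rf_features(train, features)
  y <- log10(train$deposition)
  seeds <- derive_seeds(config$seed, config$n_repeats)
  forests <- vector("list", config$n_repeats)
  oob <- matrix(NA_real_, nrow(train), config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    forests[[r]] <- with_seed(seeds[r], {
      randomForest::randomForest(x = x, y = y, ntree = config$ntree,
                                 mtry = min(config$mtry, ncol(x)))
    })
    oob[, r] <- forests[[r]]$predicted
  }
  oob_mean <- rowMeans(oob)
  correction <- if (sd(oob_mean) > 0) {
    fit_linear_correction(y, oob_mean)
  } else {
    structure(list(slope = 1, intercept = 0), class = "linear_correction")
  }
  quant <- intersect(features, RF_FEATURES[1:4])
  hull <- lapply(x[, quant, drop = FALSE], range)
  structure(list(forests = forests, correction = correction,
                 features = features, hull = hull, config = config,
                 y_train = y),
            class = "rf_ensemble")
}

#' Predict with the averaged random-forest ensemble
#'
#' Averages the member forests' predictions and applies the linear
#' correction (unless `correct = FALSE`). Records whose quantitative features
#' fall outside the training ranges are flagged in the `"extrapolated"`
#' attribute and a warning is raised: tree ensembles cannot extrapolate, so
#' such predictions are untrustworthy.
#'
#' @param object an [rf_ensemble].
#' @param newdata a [perfusion_table].
#' @param correct apply the linear correction (default `TRUE`).
#' @param ... unused.
#' @return numeric vector of log10 deposition predictions with an
#'   `"extrapolated"` logical attribute.
#' @export
predict.rf_ensemble <- function(object, newdata, correct = TRUE, ...) {
  x <- rf_features(newdata, object$features)
  preds <- sapply(object$forests, function(f) predict(f, x))
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
  raw <- rowMeans(preds)
  out <- if (correct) {
    object$correction$slope * raw + object$correction$intercept
  } else {
    raw
  }
  extrap <- rep(FALSE, nrow(newdata))
  for (f in names(object$hull)) {
    r <- object$hull[[f]]
    extrap <- extrap | x[[f]] < r[1L] | x[[f]] > r[2L]
  }
  if (any(extrap)) {
    warning(sum(extrap), " record(s) outside the training feature ranges: ",
            "predictions are extrapolations", call. = FALSE)
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Leave-one-feature-out importance
#'
#' For each feature, retrains the ensemble without it and reports the change
#' in leave-one-subject-out cross-validated median relative error relative to
#' the full six-feature model (positive = removing the feature hurts, i.e.
#' the feature helps).
#'
#' @param data a [perfusion_table] with >= 2 subjects and measured deposition.
#' @param config an [rf_config].
#' @param error_scale passed to [relative_error]; default log10 scale.
#' @return data.frame with `feature` and `delta_error`, plus the full-model
#'   error as attribute `"baseline_error"`.
#' @export
rf_feature_importance <- function(data, config = rf_config(),
                                  error_scale = c("log10", "linear")) {
  error_scale <- match.arg(error_scale)
  folds <- loso_folds(data)
  cv_err <- function(features) {
    med <- sapply(folds, function(fold) {
      model <- rf_train(fold$train, config, features)
      pred <- suppressWarnings(predict(model, fold$test))
      errs <- if (error_scale == "log10") {
        relative_error(log10(fold$test$deposition), as.numeric(pred))
      } else {
        relative_error(fold$test$deposition, 10^as.numeric(pred))
      }
      median(errs)
    })
    mean(med)
  }
  base <- cv_err(RF_FEATURES)
  delta <- sapply(RF_FEATURES, function(f) {
    cv_err(setdiff(RF_FEATURES, f)) - base
  })
  out <- data.frame(feature = RF_FEATURES, delta_error = unname(delta),
                    stringsAsFactors = FALSE)
  attr(out, "baseline_error") <- base
  out
}
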