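#' Leave-one-subject-out cross-validation folds
#'
#' One fold per subject, ordered lexicographically by subject label: the
#' fold's test set is that subject's records, the training set everyone
#' else's. The folds partition the dataset exactly.
#'
#' @param data a [perfusion_table] with >= 2 distinct subjects.
#' @return a named list of folds, each a list with `held_out_subject`,
#'   `train` and `test`.
#' @export
loso_folds <- function(data) {
  validate_perfusion_table(data)
  subjects <- sort(unique(data$subject_id))
  if (length(subjects) < 2L) {
    stop_domain("leave-one-subject-out requires >= 2 distinct subjects")
  }
  folds <- lapply(subjects, function(s) {
    list(held_out_subject = s,
         train = data[data$subject_id != s, , drop = FALSE],
         test = data[data$subject_id == s, , drop = FALSE])
  })
  names(folds) <- subjects
  folds
}

#' Relative prediction error
#'
#' `|predicted - observed| / |observed|`: the difference between the
#' predicted and the measured value, relative to the measured value.
#' Vectorized; the caller chooses the scale by what it passes in (the
#' package default is log10 deposition).
#'
#' @param observed measured values, none zero.
#' @param predicted predicted values.
#' @return non-negative numeric vector.
#' @export
relative_error <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop_domain("observed and predicted must have equal length")
  }
  if (any(observed == 0)) stop_domain("relative error undefined at observed 0")
  abs(predicted - observed) / abs(observed)
}

#' Median error with MAD-based uncertainty
#'
#' Returns the median of a collection of errors together with its
#' uncertainty, the median absolute deviation divided by the square root of
#' the number of observations. Even-length medians use the midpoint of the
#' two central order statistics.
#'
#' @param errors non-empty numeric vector.
#' @return named numeric vector `c(median, mad_se)`.
#' @export
median_and_mad_se <- function(errors) {
  if (length(errors) == 0L) stop_domain("empty error collection")
  m <- median(errors)
  mad_raw <- median(abs(errors - m))   # no consistency constant
  c(median = m, mad_se = mad_raw / sqrt(length(errors)))
}

# internal: score one fold's paired log10 (obs, pred) on the requested scale
score_fold <- function(obs_log10, pred_log10, error_scale) {
  keep <- !is.na(pred_log10)
  obs_log10 <- obs_log10[keep]
  pred_log10 <- pred_log10[keep]
  if (length(obs_log10) == 0L) return(NULL)
  errs <- if (error_scale == "log10") {
    relative_error(obs_log10, pred_log10)
  } else {
    relative_error(10^obs_log10, 10^pred_log10)
  }
  st <- median_and_mad_se(errs)
  list(median_relative_error = unname(st["median"]),
       mad_se = unname(st["mad_se"]), n_test = length(errs),
       observed = obs_log10, predicted = pred_log10)
}

#' Cross-validated three-model comparison
#'
#' Runs the requested models through identical leave-one-subject-out folds
#' and scores each fold by median relative error with MAD/sqrt(n)
#' uncertainty. The boundary-layer model cannot predict stenosed
#' experiments, so those test records are excluded from its folds; when it
#' participates, a restricted comparison on the non-stenosed records only is
#' reported as well, so that all models are scored on the same data points.
#'
#' @param data a [perfusion_table] with measured deposition and >= 2 subjects.
#' @param models subset of `c("mbl", "pm", "rf")`.
#' @param rf_cfg an [rf_config] for the forest baseline.
#' @param geometry a [chamber_geometry] for the boundary-layer model.
#' @param mbl_grid kinetic search grid for per-fold calibration.
#' @param error_scale `"log10"` (default) or `"linear"`: the scale on which
#'   relative errors are computed.
#' @param seed root seed; per-fold model seeds are derived from it and the
#'   subject label, so runs are bit-reproducible.
#' @return an object of class `cv_comparison`: per-model `cv_result`s
#'   (per-fold scores and the overall mean of per-fold medians), the
#'   restricted comparison (or `NULL`), and a tidy summary `table`.
#' @export
cross_validate <- function(data, models = c("mbl", "pm", "rf"),
                           rf_cfg = rf_config(), geometry = chamber_geometry(),
                           mbl_grid = kinetic_grid(),
                           error_scale = c("log10", "linear"), seed = 1L) {
  error_scale <- match.arg(error_scale)
  models <- match.arg(models, several.ok = TRUE)
  if (any(is.na(data$deposition))) {
    stop_domain("all records need measured deposition for cross-validation")
  }
  folds <- loso_folds(data)

  predictions <- list()  # predictions[[model]][[subject]] = list(obs, pred, applicable)
  for (model in models) {
    per_subject <- list()
    for (fold in folds) {
      s <- fold$held_out_subject
      obs <- log10(fold$test$deposition)
      pred <- switch(
        model,
        pm = pm_predict(pm_fit(fold$train), fold$test),
        rf = {
          cfg <- rf_config(ntree = rf_cfg$ntree, mtry = rf_cfg$mtry,
                           n_repeats = rf_cfg$n_repeats,
                           seed = label_seed(seed, s))
          suppressWarnings(predict(rf_train(fold$train, cfg), fold$test))
        },
        mbl = {
          fits <- lapply(
            sort(unique(fold$train$tissue[!fold$train$stenosis])),
            function(tis) calibrate_kinetics(fold$train, tis, geometry,
                                             grid = mbl_grid)
          )
          params <- setNames(lapply(fits, `[[`, "params"),
                             sapply(fits, `[[`, "tissue"))
          predict_mbl(fold$test, params, geometry, na_stenosed = TRUE)
        }
      )
      per_subject[[s]] <- list(observed = obs, predicted = as.numeric(pred),
                               applicable = !is.na(pred))
    }
    predictions[[model]] <- per_subject
  }

  summarize <- function(restrict_to_applicable) {
    results <- list()
    rows <- list()
    for (model in models) {
      per_fold <- list()
      for (s in names(folds)) {
        p <- predictions[[model]][[s]]
        keep <- if (restrict_to_applicable) {
          !folds[[s]]$test$stenosis
        } else {
          rep(TRUE, length(p$observed))
        }
        sc <- score_fold(p$observed[keep], p$predicted[keep], error_scale)
        if (is.null(sc)) {
          warning("fold ", s, ": model ", model,
                  " not applicable to any test record; excluded",
                  call. = FALSE)
          next
        }
        per_fold[[s]] <- sc
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, fold_subject = s, n_test = sc$n_test,
          median_rel_error = sc$median_relative_error, mad_se = sc$mad_se,
          stringsAsFactors = FALSE
        )
      }
      results[[model]] <- structure(
        list(model_name = model, per_fold = per_fold,
             overall_mean_median_error = mean(sapply(
               per_fold, `[[`, "median_relative_error"))),
        class = "cv_result"
      )
    }
    list(results = results, table = do.call(rbind, rows))
  }

  full <- summarize(FALSE)
  restricted <- if ("mbl" %in% models && any(data$stenosis)) {
    summarize(TRUE)
  } else {
    NULL
  }
  structure(list(results = full$results, table = full$table,
                 restricted = restricted, error_scale = error_scale,
                 models = models, seed = seed),
            class = "cv_comparison")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation result for %s\n", x$model_name))
  for (s in names(x$per_fold)) {
    f <- x$per_fold[[s]]
    cat(sprintf("  %s: median rel. error %.3f +/- %.3f (n = %d)\n",
                s, f$median_relative_error, f$mad_se, f$n_test))
  }
  cat(sprintf("  mean of fold medians: %.3f\n", x$overall_mean_median_error))
  invisible(x)
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat("Leave-one-subject-out model comparison (errors on",
      x$error_scale, "scale)\n")
  for (m in x$models) {
    cat(sprintf("  %-3s mean median relative error: %.3f\n", m,
                x$results[[m]]$overall_mean_median_error))
  }
  if (!is.null(x$restricted)) {
    cat("Restricted to records all models can predict (no stenosis):\n")
    for (m in x$models) {
      cat(sprintf("  %-3s mean median relative error: %.3f\n", m,
                  x$restricted$results[[m]]$overall_mean_median_error))
    }
  }
  invisible(x)
}
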