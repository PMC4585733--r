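#' Parameters of the phenomenological power-law deposition model
#'
#' The phenomenological model expresses the base-10 logarithm of platelet
#' deposition as a linear function of the base-10 logarithms of platelet
#' concentration, perfusion time and shear rate, plus a substrate-specific
#' intercept:
#' `log10 P = beta_c*log10 C + beta_t*log10 t + beta_gamma*log10 gamma + beta(T)`.
#' Covariates enter in presentation units (`C` in 10^3 platelets/ul, `t` in
#' min, `gamma` in 1/s) and `P` is in 10^6 platelets/cm^2.
#'
#' @param beta_c platelet-concentration exponent.
#' @param beta_t perfusion-time exponent.
#' @param beta_gamma shear-rate exponent.
#' @param beta_tissue named numeric vector of per-substrate intercepts,
#'   e.g. `c(PT = -6.4, SE = -6.7, TM = -5.3)`.
#' @param se optional named numeric vector of standard errors (names
#'   `beta_c`, `beta_t`, `beta_gamma`, and one per tissue).
#' @return an object of class `pm_params`.
#' @export
pm_params <- function(beta_c, beta_t, beta_gamma, beta_tissue, se = NULL) {
  stopifnot(is.numeric(beta_tissue), !is.null(names(beta_tissue)))
  structure(list(beta_c = beta_c, beta_t = beta_t, beta_gamma = beta_gamma,
                 beta_tissue = beta_tissue, se = se),
            class = "pm_params")
}

#' @export
print.pm_params <- function(x, ...) {
  fmt <- function(v, s) {
    if (is.null(s) || is.na(s)) sprintf("%.3g", v)
    else sprintf("%.3g (%.1g)", v, s)  # value (error), error to 1 sig fig
  }
  s <- x$se
  cat("Phenomenological log-log deposition model\n")
  cat("  beta_C     =", fmt(x$beta_c, s[["beta_c"]][1]), "\n")
  cat("  beta_t     =", fmt(x$beta_t, s[["beta_t"]][1]), "\n")
  cat("  beta_gamma =", fmt(x$beta_gamma, s[["beta_gamma"]][1]), "\n")
  for (tis in names(x$beta_tissue)) {
    cat(sprintf("  beta(%s)   = %s\n", tis,
                fmt(x$beta_tissue[[tis]], s[[tis]][1])))
  }
  invisible(x)
}

#' Design matrix of the phenomenological model
#'
#' One row per record: `log10 C`, `log10 t`, `log10 gamma`, followed by one
#' indicator column per tissue level present (no global intercept; the
#' tissue block is the full intercept structure).
#'
#' @param records a [perfusion_table].
#' @return numeric matrix with named columns.
#' @export
pm_design <- function(records) {
  if (any(records$platelet_conc <= 0 | records$time_min <= 0 |
            records$shear_rate <= 0)) {
    stop_domain("covariates must be strictly positive for the log-log model")
  }
  tissues <- sort(unique(records$tissue))
  ind <- sapply(tissues, function(t) as.numeric(records$tissue == t))
  if (nrow(records) == 1L) ind <- matrix(ind, nrow = 1L,
                                         dimnames = list(NULL, tissues))
  X <- cbind(log10_C = log10(records$platelet_conc),
             log10_t = log10(records$time_min),
             log10_gamma = log10(records$shear_rate),
             ind)
  X
}

#' Predict log10 deposition with the phenomenological model
#'
#' Evaluates the power-law model; applies equally to stenosed records (their
#' assigned effective shear rate is the covariate).
#'
#' @param params a [pm_params].
#' @param records a [perfusion_table].
#' @return numeric vector of log10(10^6 platelets/cm^2) predictions.
#' @export
pm_predict <- function(params, records) {
  missing <- setdiff(unique(records$tissue), names(params$beta_tissue))
  if (length(missing) > 0L) {
    stop_domain("no tissue intercept for: ", paste(missing, collapse = ", "))
  }
  params$beta_c * log10(records$platelet_conc) +
    params$beta_t * log10(records$time_min) +
    params$beta_gamma * log10(records$shear_rate) +
    unname(params$beta_tissue[records$tissue])
}

#' Fit the phenomenological model by ordinary least squares
#'
#' Regresses log10 deposition on the [pm_design] columns with no global
#' intercept; standard errors come from the usual unbiased residual-variance
#' estimate.
#'
#' @param records a [perfusion_table] with measured deposition for all rows.
#' @return a [pm_params] with the `se` field filled in.
#' @export
pm_fit <- function(records) {
  if (any(is.na(records$deposition))) {
    records <- records[!is.na(records$deposition), , drop = FALSE]
  }
  if (nrow(records) == 0L) stop_domain("no measured records to fit")
  X <- pm_design(records)
  y <- log10(records$deposition)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_domain("rank-deficient design: covariates are confounded ",
                "(rank ", qrX$rank, " < ", ncol(X), " columns)")
  }
  fit <- lm(y ~ X - 1)
  cf <- setNames(coef(fit), colnames(X))
  se <- setNames(sqrt(diag(vcov(fit))), colnames(X))
  tissues <- setdiff(colnames(X), c("log10_C", "log10_t", "log10_gamma"))
  pm_params(
    beta_c = cf[["log10_C"]], beta_t = cf[["log10_t"]],
    beta_gamma = cf[["log10_gamma"]],
    beta_tissue = cf[tissues],
    se = c(beta_c = se[["log10_C"]], beta_t = se[["log10_t"]],
           beta_gamma = se[["log10_gamma"]], se[tissues])
  )
}
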