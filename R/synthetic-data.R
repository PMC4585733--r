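#' Configuration of the synthetic perfusion-experiment generator
#'
#' Emulates the covariate structure of the four-pig Badimon-chamber study:
#' categorical shear-rate and perfusion-time levels, hematocrit and platelet
#' concentration ranges, three substrates, two blood treatments, and a
#' stenosis condition identified by its effective shear rate. Hematocrit and
#' platelet concentration are subject-centred (drawn once per subject, then
#' jittered per record) because concentration clusters strongly by animal.
#'
#' @param n_subjects number of subjects (animals).
#' @param records_per_subject experiments per subject.
#' @param shear_levels shear-rate levels, 1/s.
#' @param time_levels perfusion-time levels, min.
#' @param hematocrit_range hematocrit range in percent.
#' @param concentration_range platelet-concentration range, 10^3/ul.
#' @param tissues substrate levels.
#' @param blood_levels blood-treatment levels.
#' @param stenosis_shear shear level flagged as the 80 percent stenosis
#'   condition (its wall shear was obtained upstream by CFD and is treated
#'   as a given covariate).
#' @param noise_sd_log10 default response noise SD on the log10 scale.
#' @param subject_jitter within-subject jitter, as a fraction of the
#'   configured range, applied to hematocrit and concentration per record.
#' @param seed integer RNG seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 4, records_per_subject = 30,
                             shear_levels = c(212, 1390, 1690),
                             time_levels = c(3, 5, 10, 20, 30),
                             hematocrit_range = c(22.0, 31.3),
                             concentration_range = c(182.0, 449.0),
                             tissues = c("PT", "SE", "TM"),
                             blood_levels = c("native", "heparinized"),
                             stenosis_shear = 1390,
                             noise_sd_log10 = 0.1,
                             subject_jitter = 0.1,
                             seed = 1L) {
  if (n_subjects < 1 || records_per_subject < 1) {
    stop_domain("n_subjects and records_per_subject must be >= 1")
  }
  for (lv in list(shear_levels, time_levels, tissues, blood_levels)) {
    if (length(lv) == 0L) stop_domain("level sets must be non-empty")
  }
  ordered_pair <- function(r, nm) {
    if (length(r) != 2L || r[1L] > r[2L] || any(r <= 0)) {
      stop_domain(nm, " must be an ordered positive pair")
    }
  }
  ordered_pair(hematocrit_range, "hematocrit_range")
  ordered_pair(concentration_range, "concentration_range")
  if (any(hematocrit_range >= 100)) stop_domain("hematocrit_range is in percent")
  if (noise_sd_log10 < 0) stop_domain("noise_sd_log10 must be >= 0")
  structure(
    list(n_subjects = n_subjects, records_per_subject = records_per_subject,
         shear_levels = shear_levels, time_levels = time_levels,
         hematocrit_range = hematocrit_range,
         concentration_range = concentration_range,
         tissues = tissues, blood_levels = blood_levels,
         stenosis_shear = stenosis_shear, noise_sd_log10 = noise_sd_log10,
         subject_jitter = subject_jitter, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Draw per-subject hematological profiles
#'
#' One hematocrit and one platelet-concentration centre per subject, uniform
#' over the configured ranges. Supplying explicit profiles to
#' [sample_covariates] (e.g. a subject whose concentration range sits below
#' the others') reproduces the extrapolation failure seen when one animal's
#' platelet counts lie outside the training range.
#'
#' @param config a [generator_config].
#' @return data.frame with `subject_id`, `hematocrit_pct`, `conc_center`.
#' @export
subject_profiles <- function(config) {
  with_seed(config$seed, {
    data.frame(
      subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
      hematocrit_pct = runif(config$n_subjects, config$hematocrit_range[1L],
                             config$hematocrit_range[2L]),
      conc_center = runif(config$n_subjects, config$concentration_range[1L],
                          config$concentration_range[2L]),
      stringsAsFactors = FALSE
    )
  })
}

#' Sample a covariate-only perfusion dataset
#'
#' Generates `n_subjects * records_per_subject` records: shear rate, time,
#' tissue and blood drawn uniformly from the configured level sets;
#' hematocrit and concentration subject-centred with within-subject jitter,
#' clamped to the configured ranges; the stenosis flag set exactly when the
#' shear level equals `stenosis_shear`. Deposition is left `NA`. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [generator_config].
#' @param profiles optional data.frame as returned by [subject_profiles]
#'   (columns `subject_id`, `hematocrit_pct`, `conc_center`); overrides the
#'   default uniform subject draws.
#' @return a [perfusion_table] without deposition values.
#' @export
sample_covariates <- function(config, profiles = NULL) {
  if (is.null(profiles)) profiles <- subject_profiles(config)
  n <- nrow(profiles) * config$records_per_subject
  clamp <- function(v, r) pmin(pmax(v, r[1L]), r[2L])
  with_seed(config$seed + 1L, {
    idx <- rep(seq_len(nrow(profiles)), each = config$records_per_subject)
    jit_h <- rnorm(n, 0, config$subject_jitter *
                     diff(config$hematocrit_range) / 2)
    jit_c <- rnorm(n, 0, config$subject_jitter *
                     diff(config$concentration_range) / 2)
    shear <- sample(config$shear_levels, n, replace = TRUE)
    perfusion_table(
      subject_id = profiles$subject_id[idx],
      shear_rate = shear,
      time_min = sample(config$time_levels, n, replace = TRUE),
      hematocrit = clamp(profiles$hematocrit_pct[idx] + jit_h,
                         config$hematocrit_range) / 100,
      platelet_conc = clamp(profiles$conc_center[idx] + jit_c,
                            config$concentration_range),
      blood = sample(config$blood_levels, n, replace = TRUE),
      tissue = sample(config$tissues, n, replace = TRUE),
      stenosis = shear == config$stenosis_shear,
      deposition = NA_real_,
      provenance = sprintf("synthetic covariates (seed %d)", config$seed)
    )
  })
}

#' Attach power-law (phenomenological) responses to a dataset
#'
#' Sets each record's deposition to
#' `10^(pm_predict(params, record) + eps)` with `eps ~ N(0, noise_sd_log10^2)`
#' — i.e. lognormal multiplicative noise around the exact power law.
#'
#' @param data a [perfusion_table].
#' @param params a [pm_params] covering every tissue present.
#' @param noise_sd_log10 noise SD on the log10 scale; 0 gives exact responses.
#' @param seed RNG seed.
#' @return `data` with the deposition column filled.
#' @export
attach_pm_response <- function(data, params, noise_sd_log10 = 0.1,
                               seed = 1L) {
  mu <- pm_predict(params, data)
  eps <- if (noise_sd_log10 > 0) {
    with_seed(seed, rnorm(nrow(data), 0, noise_sd_log10))
  } else {
    rep(0, nrow(data))
  }
  data$deposition <- 10^(mu + eps)
  attr(data, "provenance") <- paste0(attr(data, "provenance"),
                                     " + pm response (seed ", seed, ")")
  validate_perfusion_table(data)
  data
}

#' Attach mechanistic (boundary-layer) responses to a dataset
#'
#' Sets each record's deposition to the closed two-layer forward-model areal
#' total at the record's perfusion time, multiplied by `10^eps`,
#' `eps ~ N(0, noise_sd_log10^2)`. The boundary-layer model does not apply to
#' stenosed experiments, so any stenosed record is an error.
#'
#' @param data a [perfusion_table] with no stenosed records.
#' @param params_by_tissue named list of [mbl_params], or a single
#'   [mbl_params] used for every tissue.
#' @param geometry a [chamber_geometry].
#' @param noise_sd_log10 noise SD on the log10 scale.
#' @param seed RNG seed.
#' @return `data` with the deposition column filled.
#' @export
attach_mbl_response <- function(data, params_by_tissue,
                                geometry = chamber_geometry(),
                                noise_sd_log10 = 0.1, seed = 1L) {
  if (any(data$stenosis)) {
    stop_domain("MBL response generation requires non-stenosed records")
  }
  if (inherits(params_by_tissue, "mbl_params")) {
    params_by_tissue <- setNames(
      rep(list(params_by_tissue), length(unique(data$tissue))),
      unique(data$tissue)
    )
  }
  mu <- predict_mbl(data, params_by_tissue, geometry)
  eps <- if (noise_sd_log10 > 0) {
    with_seed(seed, rnorm(nrow(data), 0, noise_sd_log10))
  } else {
    rep(0, nrow(data))
  }
  data$deposition <- 10^(mu + eps)
  attr(data, "provenance") <- paste0(attr(data, "provenance"),
                                     " + mbl response (seed ", seed, ")")
  validate_perfusion_table(data)
  data
}

#' Published all-data parameter estimates
#'
#' Convenience constructors for the reference parameter sets estimated on the
#' full four-pig dataset: the power-law coefficients
#' (`beta_C = 2.2`, `beta_t = 1.4`, `beta_gamma = 0.38`,
#' `beta(PT) = -6.4`, `beta(SE) = -6.7`, `beta(TM) = -5.3`) and the pig-tendon
#' boundary-layer kinetics (`k1 = 9.5e-7` m/s, `k2 = 5.4e-5` m/s). Useful as
#' generator inputs for recovery experiments.
#'
#' @return [reference_pm_params()]: a [pm_params]; [reference_mbl_params()]:
#'   an [mbl_params] for pig tendon.
#' @export
reference_pm_params <- function() {
  pm_params(beta_c = 2.2, beta_t = 1.4, beta_gamma = 0.38,
            beta_tissue = c(PT = -6.4, SE = -6.7, TM = -5.3))
}

#' @rdname reference_pm_params
#' @export
reference_mbl_params <- function() {
  mbl_params(k1 = 9.5e-7, k2 = 5.4e-5)
}
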