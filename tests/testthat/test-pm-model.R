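test_that("design rows are log10 covariates plus a tissue indicator block", {
  d <- perfusion_table(
    subject_id = c("a", "b", "c"),
    shear_rate = c(1000, 1, 1000),
    time_min = c(10, 1, 10),
    hematocrit = 0.25, platelet_conc = c(100, 1, 100),
    blood = "native", tissue = c("PT", "SE", "SE"),
    stenosis = FALSE, deposition = NA_real_
  )
  X <- pm_design(d)
  expect_equal(unname(X[1, c("log10_C", "log10_t", "log10_gamma")]),
               c(2, 1, 3))
  expect_equal(unname(X[2, c("log10_C", "log10_t", "log10_gamma")]),
               c(0, 0, 0))
  expect_equal(unname(X[1, c("PT", "SE")]), c(1, 0))
  expect_equal(unname(X[2, c("PT", "SE")]), c(0, 1))
  # rows 1 and 3 differ only in tissue: same numeric block
  expect_equal(X[1, 1:3], X[3, 1:3])
  expect_false(all(X[1, 4:5] == X[3, 4:5]))
})

test_that("prediction evaluates the power law and is log-linear in time", {
  params <- pm_params(2.2, 1.33, 0.402, c(PT = -6.3, SE = -6.3, TM = -5.8))
  rec <- one_record(tissue = "TM")
  expect_equal(pm_predict(params, rec),
               2.2 * log10(341) + 1.33 + 0.402 * log10(1690) - 5.8)
  expect_equal(pm_predict(params, rec), 2.40, tolerance = 0.005)

  zero <- pm_params(0, 0, 0, c(PT = 0, SE = 0, TM = 0))
  expect_equal(pm_predict(zero, tiny_table()), rep(0, 6))

  # multiplying time by 10 adds exactly beta_t
  rec10 <- rec
  rec10$time_min <- rec$time_min * 10
  expect_equal(pm_predict(params, rec10) - pm_predict(params, rec), 1.33)

  expect_error(pm_predict(pm_params(1, 1, 1, c(PT = 0)), rec), "TM")
})

test_that("noiseless fits recover the generating parameters exactly", {
  d <- attach_pm_response(pm_dataset(noise = 0, seed = 2, 10),
                          reference_pm_params(), 0, seed = 1)
  fit <- pm_fit(d)
  expect_equal(fit$beta_c, 2.2, tolerance = 1e-9)
  expect_equal(fit$beta_t, 1.4, tolerance = 1e-9)
  expect_equal(fit$beta_gamma, 0.38, tolerance = 1e-9)
  expect_equal(unname(fit$beta_tissue[c("PT", "SE", "TM")]),
               c(-6.4, -6.7, -5.3), tolerance = 1e-9)
})

test_that("coefficients and errors equal the normal-equations solution", {
  d <- pm_dataset(noise = 0.15, seed = 13, records_per_subject = 3)[1:10, ]
  fit <- pm_fit(d)
  X <- pm_design(d)
  y <- log10(d$deposition)
  beta <- solve(t(X) %*% X, t(X) %*% y)[, 1]     # independent oracle
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  got <- c(fit$beta_c, fit$beta_t, fit$beta_gamma,
           fit$beta_tissue[setdiff(names(beta),
                                   c("log10_C", "log10_t", "log10_gamma"))])
  expect_equal(unname(got), unname(beta), tolerance = 1e-10)
  expect_equal(unname(fit$se[names(se)[4:length(se)]]),
               unname(se[4:length(se)]), tolerance = 1e-10)
  expect_equal(unname(fit$se[c("beta_c", "beta_t", "beta_gamma")]),
               unname(se[c("log10_C", "log10_t", "log10_gamma")]),
               tolerance = 1e-10)
})

test_that("fitting is invariant under row permutation", {
  d <- pm_dataset(noise = 0.1, seed = 21)
  fit1 <- pm_fit(d)
  fit2 <- pm_fit(d[sample(nrow(d)), ])
  expect_equal(fit1$beta_c, fit2$beta_c)
  expect_equal(fit1$beta_tissue, fit2$beta_tissue)
  expect_equal(pm_predict(fit1, d), pm_predict(fit2, d))
})

test_that("standard errors shrink like 1/sqrt(n)", {
  ses <- sapply(c(50, 200, 800), function(n) {
    cfg <- generator_config(n_subjects = 5, records_per_subject = n / 5,
                            seed = 31)
    d <- attach_pm_response(sample_covariates(cfg), reference_pm_params(),
                            0.1, seed = 32)
    pm_fit(d)$se[["beta_c"]]
  })
  expect_true(all(diff(ses) < 0))
  # quadrupling n roughly halves the standard error
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.4)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.4)
})

test_that("equal generating intercepts stay statistically indistinguishable", {
  # generated with beta(PT) = beta(SE): fitted values differ by < 2 joint SE,
  # mirroring the near-identical tendon/subendothelium thrombogenicity
  params <- pm_params(2.2, 1.4, 0.38, c(PT = -6.4, SE = -6.4, TM = -5.3))
  cfg <- generator_config(records_per_subject = 50, seed = 41)
  d <- attach_pm_response(sample_covariates(cfg), params, 0.1, seed = 42)
  fit <- pm_fit(d)
  diff_hat <- abs(fit$beta_tissue[["PT"]] - fit$beta_tissue[["SE"]])
  expect_lt(diff_hat, 2 * (fit$se[["PT"]] + fit$se[["SE"]]))
})

test_that("rank-deficient designs are refused with a clear message", {
  # constant time and shear make log10_t and log10_gamma collinear with the
  # single tissue indicator
  d <- perfusion_table(
    subject_id = c("a", "b", "c", "d"),
    shear_rate = 1690, time_min = 10, hematocrit = 0.25,
    platelet_conc = c(200, 250, 300, 350),
    blood = "native", tissue = "PT", stenosis = FALSE,
    deposition = c(10, 20, 30, 40)
  )
  expect_error(pm_fit(d), "rank-deficient")
})
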