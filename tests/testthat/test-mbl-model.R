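test_that("diffusivity reduces to the Brownian baseline without shear or cells", {
  law <- diffusivity_law()
  expect_equal(platelet_diffusivity(0.3, 0, law), law$d_brownian)
  expect_equal(platelet_diffusivity(0, 5000, law), law$d_brownian)
  expect_error(platelet_diffusivity(1, 100, law), "hematocrit")
})

test_that("diffusivity matches an independent evaluation of the correlation", {
  law <- diffusivity_law()
  # independent hand evaluation: D_B + C_s a^2 gamma H (1-H)^n
  H <- 0.2646
  gam <- 1690
  expected <- 1.58e-13 + 0.15 * (2.75e-6)^2 * gam * H * (1 - H)^0.8
  expect_equal(platelet_diffusivity(H, gam, law), expected)
  expect_gt(expected, law$d_brownian)
})

test_that("mass-transfer coefficient obeys the cube-root power laws", {
  D <- 1e-11
  gam <- 212
  L <- 0.02
  h <- mass_transfer_coefficient(D, gam, L)
  expect_equal(mass_transfer_coefficient(D, 8 * gam, L), 2 * h)
  expect_equal(mass_transfer_coefficient(D, gam, 8 * L), h / 2)
  expect_equal(mass_transfer_coefficient(8 * D, gam, L), 4 * h)
  expect_error(mass_transfer_coefficient(0, gam, L), "> 0")
})

test_that("length-averaged coefficient equals the quadrature of the local law", {
  # oracle: numerically average the local coefficient 0.5384 (D^2 g / x)^(1/3)
  D <- 1e-11
  gam <- 212
  L <- 0.02
  local <- function(x) 0.5384 * (D^2 * gam / x)^(1 / 3)
  avg <- integrate(local, 0, L)$value / L
  expect_equal(mass_transfer_coefficient(D, gam, L, prefactor = 1.5 * 0.5384),
               avg, tolerance = 1e-6)
  # the default prefactor is that same 3/2 * 0.5384 average
  expect_equal(mass_transfer_coefficient(D, gam, L), avg, tolerance = 1e-3)
})

test_that("series flux has the correct limits, symmetry and monotonicity", {
  h <- 2e-5
  c0 <- 3.41e14
  expect_equal(effective_flux(Inf, h, c0), h * c0)       # transport-limited
  expect_equal(effective_flux(1e-6, Inf, c0), 1e-6 * c0) # reaction-limited
  expect_equal(effective_flux(h, h, c0), h * c0 / 2)     # equal resistances
  expect_equal(effective_flux(0, h, c0), 0)              # no adhesion

  ks <- 10^seq(-8, -3, length.out = 30)
  J <- effective_flux(ks, h, c0)
  expect_true(all(diff(J) > 0))                  # increasing in k
  expect_true(all(J <= pmin(ks, h) * c0 + 1e-9)) # bounded by both resistances
  expect_true(all(diff(effective_flux(1e-6, ks, c0)) > 0))  # increasing in h
  expect_error(effective_flux(1e-6, 0, c0), "> 0")
})

test_that("monolayer capacity is the area over one platelet footprint", {
  d_p <- 2e-6
  g1 <- chamber_geometry(pi * d_p^2 / 4, 1)  # area equal to one footprint
  expect_equal(monolayer_capacity(g1, d_p), 1)
  g <- chamber_geometry(0.02, 0.005)
  g2 <- chamber_geometry(0.04, 0.005)
  expect_equal(monolayer_capacity(g2, d_p), 2 * monolayer_capacity(g, d_p))
  # 1 cm^2 with 2 um platelets: 1e-4 / (pi (2e-6)^2 / 4)
  gcm <- chamber_geometry(0.01, 0.01)
  expect_equal(monolayer_capacity(gcm, 2e-6), 1e-4 / (pi * 1e-12),
               tolerance = 1e-10)
  expect_equal(monolayer_capacity(gcm, 2e-6), 3.183e7, tolerance = 1e-3)
  # square packing differs by the constant 4/pi
  expect_equal(monolayer_capacity(gcm, 2e-6, packing = "square") * (4 / pi),
               monolayer_capacity(gcm, 2e-6), tolerance = 1e-12)
  expect_error(monolayer_capacity(gcm, 0), "> 0")
})

test_that("trajectories start at zero, never decrease and cap the monolayer", {
  params <- reference_mbl_params()
  geometry <- chamber_geometry()
  grid <- seq(0, 30, by = 1)
  for (gam in c(212, 1690)) {
    traj <- simulate_deposition(one_record(shear_rate = gam), params,
                                geometry, grid)
    expect_equal(traj$p1[1], 0)
    expect_equal(traj$p2[1], 0)
    expect_true(all(diff(traj$p1) >= -1e-6))
    expect_true(all(diff(traj$p2) >= -1e-6))
    expect_true(all(traj$p1 <= traj$p1_max * (1 + 1e-9)))
  }
  expect_error(simulate_deposition(one_record(), params, geometry, c(3, 5)),
               "start at 0")
  sten <- one_record()
  sten$stenosis <- TRUE
  expect_error(simulate_deposition(sten, params), "not applicable")
})

test_that("zero multilayer kinetics give a saturating monolayer only", {
  params <- mbl_params(k1 = 5e-6, k2 = 0)
  traj <- simulate_deposition(one_record(), params,
                              time_grid = seq(0, 120, by = 5))
  expect_true(all(traj$p2 == 0))
  expect_true(all(diff(traj$p1) >= 0))
  expect_true(all(diff(traj$p1[traj$p1 < 0.9 * traj$p1_max]) > 0))
  expect_equal(traj$p1[length(traj$p1)], traj$p1_max, tolerance = 1e-3)
})

test_that("the early-time total is linear in time and in bulk concentration", {
  params <- reference_mbl_params()
  geometry <- chamber_geometry()
  rec <- one_record()
  r <- plateletdepo:::mbl_rates(rec, params, geometry)
  # far inside the linear regime: multilayer growth (rate ratio a2/a1 ~ 16)
  # stays negligible only well below the monolayer fill time
  t_lin <- 5e-4 * (r$p1_max / r$a1) / 60
  traj <- simulate_deposition(rec, params, geometry, c(0, t_lin))
  linear <- r$a1 * (t_lin * 60) / geometry$area / 1e10
  expect_equal(traj$total_areal[2], linear, tolerance = 2e-2)

  # flux is linear in C0, so the early-time total doubles with concentration
  rec2 <- one_record(platelet_conc = 2 * 341)
  traj2 <- simulate_deposition(rec2, params, geometry, c(0, t_lin))
  expect_equal(traj2$total_areal[2] / traj$total_areal[2], 2, tolerance = 5e-2)
})

test_that("adaptive integration agrees with a fine fixed-step Euler oracle", {
  params <- reference_mbl_params()
  geometry <- chamber_geometry()
  for (t_end in c(3, 30)) {
    rec <- one_record(time_min = t_end)
    traj <- simulate_deposition(rec, params, geometry, c(0, t_end))
    oracle <- euler_deposition(rec, params, geometry, t_end)
    expect_equal(traj$total_areal[2], oracle, tolerance = 1e-3)
  }
})

test_that("ODE and closed-form paths coincide", {
  params <- reference_mbl_params()
  rec <- one_record()
  grid <- c(0, 3, 5, 10, 20, 30)
  ode <- simulate_deposition(rec, params, time_grid = grid)
  exact <- simulate_deposition(rec, params, time_grid = grid,
                               method = "analytic")
  expect_equal(ode$total_areal[-1], exact$total_areal[-1], tolerance = 1e-5)
})

test_that("predictions agree with the trajectory and refuse stenosed records", {
  params <- list(PT = reference_mbl_params())
  rec <- one_record(time_min = 10)
  pred <- predict_mbl(rec, params)
  traj <- simulate_deposition(rec, params$PT, time_grid = c(0, 10))
  expect_equal(pred, log10(traj$total_areal[2]), tolerance = 1e-6)

  sten <- rec
  sten$stenosis <- TRUE
  expect_error(predict_mbl(sten, params), "not applicable")
  expect_true(is.na(predict_mbl(sten, params, na_stenosed = TRUE)))
  expect_error(predict_mbl(one_record(tissue = "SE"), params), "SE")
})

test_that("grid calibration recovers generating constants exactly when noiseless", {
  grid <- kinetic_grid(per_decade = 6)
  k1_true <- grid[13]
  k2_true <- grid[22]
  d <- pt_recovery_data(mbl_params(k1_true, k2_true))
  fit <- calibrate_kinetics(d, "PT", grid = grid)
  expect_equal(fit$k1, k1_true)
  expect_equal(fit$k2, k2_true)
  expect_lt(fit$loss, 1e-8)
  expect_false(fit$transport_limited)

  expect_error(calibrate_kinetics(d, "PT", grid = numeric()), "empty")
  expect_error(calibrate_kinetics(d, "TM"), "TM")
})

test_that("calibration equals an exhaustive brute-force argmin", {
  # noisy data off the grid so the argmin is non-trivial
  d <- pt_recovery_data()
  set.seed(4)
  d$deposition <- d$deposition * 10^rnorm(nrow(d), 0, 0.2)
  grid <- kinetic_grid(per_decade = 2)   # 11 x 11, small enough to enumerate
  fit <- calibrate_kinetics(d, "PT", grid = grid)

  geometry <- chamber_geometry()
  brute <- expand.grid(k1 = grid, k2 = grid)
  brute$loss <- vapply(seq_len(nrow(brute)), function(i) {
    pred <- vapply(seq_len(nrow(d)), function(j) {
      simulate_deposition(d[j, ], mbl_params(brute$k1[i], brute$k2[i]),
                          geometry, c(0, d$time_min[j]))$total_areal[2]
    }, numeric(1))
    sum(abs(pred - d$deposition))
  }, numeric(1))
  best <- brute[which.min(brute$loss), ]
  expect_equal(fit$k1, best$k1)
  expect_equal(fit$k2, best$k2)
  expect_equal(fit$loss, best$loss, tolerance = 1e-4)
})

test_that("transport-limited substrates are detected and k-invariant", {
  tl <- mbl_params(Inf, Inf, transport_limited = TRUE)
  d <- pt_recovery_data(tl)
  fit <- calibrate_kinetics(d, "PT", grid = kinetic_grid(per_decade = 4))
  expect_true(fit$transport_limited)
  expect_true(is.infinite(fit$params$k1))

  # the transport-limited trajectory is invariant under any kinetic values
  base <- simulate_deposition(one_record(), tl, time_grid = c(0, 10))
  for (k in c(1e-8, 1e-5, 1e-3)) {
    alt <- simulate_deposition(one_record(),
                               mbl_params(k, k, transport_limited = TRUE),
                               time_grid = c(0, 10))
    expect_identical(alt$total_areal, base$total_areal)
  }
})
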