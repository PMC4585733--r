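#' Shear-augmented platelet diffusivity law
#'
#' Effective lateral platelet diffusivity in flowing whole blood. Red-cell
#' tumbling augments the Brownian diffusivity, giving
#' `D = D_B + C_s * a^2 * gamma * H * (1 - H)^n`
#' with `D_B` the Brownian baseline, `C_s` a dimensionless coefficient, `a`
#' the red-cell radius, `gamma` the shear rate and `H` the hematocrit
#' fraction. All four constants are exposed so an alternative correlation can
#' be substituted without touching the transport code.
#'
#' @param d_brownian Brownian platelet diffusivity, m^2/s.
#' @param shear_coeff dimensionless shear-augmentation coefficient.
#' @param rbc_radius red blood cell radius, m.
#' @param hematocrit_exponent exponent on `(1 - H)`.
#' @return an object of class `diffusivity_law`.
#' @export
diffusivity_law <- function(d_brownian = 1.58e-13, shear_coeff = 0.15,
                            rbc_radius = 2.75e-6, hematocrit_exponent = 0.8) {
  vals <- c(d_brownian, shear_coeff, rbc_radius, hematocrit_exponent)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop_domain("all diffusivity-law constants must be positive")
  }
  structure(list(d_brownian = d_brownian, shear_coeff = shear_coeff,
                 rbc_radius = rbc_radius,
                 hematocrit_exponent = hematocrit_exponent),
            class = "diffusivity_law")
}

#' Effective platelet diffusivity
#'
#' Evaluates the [diffusivity_law] at a given hematocrit and shear rate. At
#' zero shear or zero hematocrit this reduces to the Brownian baseline.
#'
#' @param hematocrit red-cell volume fraction in `[0, 1)`.
#' @param shear_rate wall shear rate, 1/s, non-negative.
#' @param law a [diffusivity_law].
#' @return diffusivity in m^2/s (vectorized over `hematocrit`/`shear_rate`).
#' @export
platelet_diffusivity <- function(hematocrit, shear_rate,
                                 law = diffusivity_law()) {
  if (any(hematocrit < 0 | hematocrit >= 1)) {
    stop_domain("hematocrit must lie in [0, 1)")
  }
  if (any(shear_rate < 0)) stop_domain("shear_rate must be >= 0")
  law$d_brownian + law$shear_coeff * law$rbc_radius^2 * shear_rate *
    hematocrit * (1 - hematocrit)^law$hematocrit_exponent
}

#' Length-averaged wall mass-transfer coefficient
#'
#' Thin-concentration-boundary-layer (Leveque) result for a plate of length
#' `L` in a linear shear flow: the length-averaged coefficient is
#' `h = c_L * (D^2 * gamma / L)^(1/3)`. The default prefactor `c_L = 0.8075`
#' is 3/2 of the local Leveque coefficient 0.5384, i.e. the average of the
#' local coefficient over the plate.
#'
#' @param diffusivity platelet diffusivity, m^2/s.
#' @param shear_rate wall shear rate, 1/s.
#' @param length substrate streamwise length, m.
#' @param prefactor the Leveque averaging constant `c_L`.
#' @return mass-transfer coefficient in m/s.
#' @export
mass_transfer_coefficient <- function(diffusivity, shear_rate, length,
                                      prefactor = 0.8075) {
  if (any(diffusivity <= 0) || any(shear_rate <= 0) || any(length <= 0)) {
    stop_domain("diffusivity, shear_rate and length must be > 0")
  }
  prefactor * (diffusivity^2 * shear_rate / length)^(1 / 3)
}

#' Reaction-transport series wall flux
#'
#' Platelet flux to a reactive wall with first-order surface kinetics behind
#' a mass-transfer boundary layer: the two resistances act in series,
#' `J = C0 / (1/k + 1/h)`. `k = Inf` gives the transport-limited flux `h*C0`
#' (the tunica-media regime); `h = Inf` would give the reaction-limited flux
#' `k*C0`.
#'
#' @param k surface kinetic constant, m/s; may be `Inf`.
#' @param h wall mass-transfer coefficient, m/s, positive.
#' @param c0 bulk platelet concentration, platelets/m^3, non-negative.
#' @return wall flux in platelets/(m^2 s).
#' @export
effective_flux <- function(k, h, c0) {
  if (any(h <= 0)) stop_domain("mass-transfer coefficient must be > 0")
  if (any(c0 < 0)) stop_domain("concentration must be >= 0")
  if (any(k < 0)) stop_domain("kinetic constant must be >= 0 (or Inf)")
  c0 / (1 / k + 1 / h)  # k = 0 gives zero flux; k = Inf the transport limit
}

#' Monolayer platelet capacity of the substrate
#'
#' Maximum number of platelets in the first (substrate-contacting) layer:
#' the substrate area divided by one adhered platelet's footprint. With the
#' default circular footprint the capacity is `A / (pi * d_p^2 / 4)`; square
#' packing (`A / d_p^2`) is selectable.
#'
#' @param geometry a [chamber_geometry].
#' @param d_p adhered-platelet diameter, m (default 2 um).
#' @param packing `"circle"` (default) or `"square"` footprint.
#' @return capacity in platelets.
#' @export
monolayer_capacity <- function(geometry, d_p = 2e-6,
                               packing = c("circle", "square")) {
  packing <- match.arg(packing)
  if (d_p <= 0) stop_domain("platelet diameter must be > 0")
  footprint <- if (packing == "circle") pi * d_p^2 / 4 else d_p^2
  geometry$area / footprint
}

#' Kinetic parameters of the two-layer adhesion model
#'
#' Substrate-specific surface kinetic constants: `k1` for platelets binding
#' directly to the substrate (first monolayer) and `k2` for platelets binding
#' onto already-deposited platelets (all subsequent layers). Substrates in
#' the transport-limited regime (deposition set entirely by advective and
#' diffusive supply, as for tunica media) are marked with
#' `transport_limited = TRUE`, which replaces both constants by `Inf`.
#'
#' @param k1 first-monolayer kinetic constant, m/s, in `[1e-8, 1e-3]`.
#' @param k2 multilayer kinetic constant, m/s, in `[1e-8, 1e-3]`.
#' @param d_p adhered-platelet diameter, m.
#' @param diffusivity a [diffusivity_law].
#' @param transport_limited logical; `TRUE` treats kinetics as infinite.
#' @return an object of class `mbl_params`.
#' @export
mbl_params <- function(k1, k2, d_p = 2e-6, diffusivity = diffusivity_law(),
                       transport_limited = FALSE) {
  if (transport_limited) {
    k1 <- Inf
    k2 <- Inf
  }
  chk <- function(k, nm) {
    # 0 (no adhesion) and Inf (transport limit) are admissible degenerate values
    if (!is.infinite(k) && k != 0 && (k < 1e-8 || k > 1e-3)) {
      stop_domain(nm, " must lie in [1e-8, 1e-3] m/s (or be 0 or Inf)")
    }
  }
  chk(k1, "k1")
  chk(k2, "k2")
  if (d_p <= 0) stop_domain("platelet diameter must be > 0")
  structure(list(k1 = k1, k2 = k2, d_p = d_p, diffusivity = diffusivity,
                 transport_limited = isTRUE(transport_limited)),
            class = "mbl_params")
}

#' @export
print.mbl_params <- function(x, ...) {
  if (x$transport_limited) {
    cat("MBL kinetics: transport-limited (k1 = k2 = Inf)\n")
  } else {
    cat(sprintf("MBL kinetics: k1 = %.3g m/s, k2 = %.3g m/s\n", x$k1, x$k2))
  }
  invisible(x)
}

# Per-record transport quantities shared by the ODE and closed-form paths.
# Returns a1, a2 (count deposition rates, platelets/s, at zero / full
# coverage respectively), the monolayer capacity and the substrate area.
mbl_rates <- function(record, params, geometry) {
  D <- platelet_diffusivity(record$hematocrit, record$shear_rate,
                            params$diffusivity)
  h <- mass_transfer_coefficient(D, record$shear_rate,
                                 geometry$substrate_length)
  c0 <- to_si_concentration(record$platelet_conc)
  list(
    a1 = effective_flux(params$k1, h, c0) * geometry$area,
    a2 = effective_flux(params$k2, h, c0) * geometry$area,
    p1_max = monolayer_capacity(geometry, params$d_p),
    area = geometry$area,
    h = h, c0 = c0
  )
}

# Exact solution of the linear two-layer system
#   dP1/dt = a1 (1 - P1/Pmax),  dP2/dt = a2 P1/Pmax,  P1(0)=P2(0)=0
# at time t (seconds). Vectorized over a1, a2 and t.
mbl_closed_form <- function(a1, a2, p1_max, t_sec) {
  x <- a1 * t_sec / p1_max
  p1 <- p1_max * (-expm1(-x))
  p2 <- a2 * (t_sec - (p1_max / a1) * (-expm1(-x)))
  list(p1 = p1, p2 = pmax(p2, 0))
}

#' Simulate the two-layer deposition trajectory for one experiment
#'
#' Integrates the mass-transfer boundary-layer deposition model for a single
#' perfusion record: the first monolayer fills the substrate with rate
#' constant `k1` on the uncovered fraction, while subsequent layers grow with
#' rate constant `k2` on the covered fraction, each layer fed by the
#' reaction-transport series flux [effective_flux]. Deposited platelets never
#' detach, so both counts are non-decreasing.
#'
#' @param record a single-row [perfusion_table] (non-stenosed: the flat-plate
#'   boundary-layer assumptions do not hold in a stenosed conduit).
#' @param params an [mbl_params].
#' @param geometry a [chamber_geometry].
#' @param time_grid minutes; strictly increasing and starting at 0.
#' @param method `"ode"` (adaptive lsoda integration, default) or
#'   `"analytic"` (the exact closed-form solution of the linear system).
#' @return an object of class `deposition_trajectory` with fields `times`
#'   (min), `p1`, `p2` (platelet counts), `p1_max`, and `total_areal`
#'   (10^6 platelets/cm^2).
#' @export
simulate_deposition <- function(record, params, geometry = chamber_geometry(),
                                time_grid = c(0, 3, 5, 10, 20, 30),
                                method = c("ode", "analytic")) {
  method <- match.arg(method)
  if (nrow(record) != 1L) stop_domain("record must be a single row")
  if (isTRUE(record$stenosis)) {
    stop_domain("MBL model is not applicable to stenosed experiments")
  }
  if (time_grid[1L] != 0 || any(diff(time_grid) <= 0)) {
    stop_domain("time_grid must start at 0 and be strictly increasing")
  }
  r <- mbl_rates(record, params, geometry)
  t_sec <- time_grid * 60
  if (method == "analytic") {
    sol <- mbl_closed_form(r$a1, r$a2, r$p1_max, t_sec)
    p1 <- sol$p1
    p2 <- sol$p2
  } else {
    deriv <- function(t, y, parms) {
      cover <- min(max(y[1L] / parms$p1_max, 0), 1)
      list(c(parms$a1 * (1 - cover), parms$a2 * cover))
    }
    out <- deSolve::lsoda(c(P1 = 0, P2 = 0), t_sec, deriv,
                          parms = r, rtol = 1e-8, atol = 1)
    p1 <- pmin(out[, "P1"], r$p1_max)
    p2 <- out[, "P2"]
  }
  structure(
    list(times = time_grid, p1 = p1, p2 = p2, p1_max = r$p1_max,
         total_areal = (p1 + p2) / r$area / 1e10),
    class = "deposition_trajectory"
  )
}

#' @export
print.deposition_trajectory <- function(x, ...) {
  cat("Two-layer deposition trajectory\n")
  print(data.frame(time_min = x$times,
                   p1 = signif(x$p1, 4), p2 = signif(x$p2, 4),
                   total_e6_per_cm2 = signif(x$total_areal, 4)))
  invisible(x)
}

# Vectorized closed-form areal totals (1e6 platelets/cm^2) for many records.
# k1/k2 may be scalars or Inf. Used by prediction and calibration.
mbl_areal_total <- function(records, k1, k2, geometry,
                            d_p = 2e-6, law = diffusivity_law()) {
  D <- platelet_diffusivity(records$hematocrit, records$shear_rate, law)
  h <- mass_transfer_coefficient(D, records$shear_rate,
                                 geometry$substrate_length)
  c0 <- to_si_concentration(records$platelet_conc)
  p1_max <- monolayer_capacity(geometry, d_p)
  a1 <- effective_flux(k1, h, c0) * geometry$area
  a2 <- effective_flux(k2, h, c0) * geometry$area
  sol <- mbl_closed_form(a1, a2, p1_max, records$time_min * 60)
  (sol$p1 + sol$p2) / geometry$area / 1e10
}

#' Predict log10 deposition with the boundary-layer model
#'
#' Forward-simulates each record's perfusion with its substrate's calibrated
#' kinetics and returns the log10 of the areal total at the record's
#' perfusion time. Stenosed records are not applicable (the prediction is
#' undefined, not zero): they error unless `na_stenosed = TRUE`, in which
#' case they yield `NA`.
#'
#' @param records a [perfusion_table].
#' @param params_by_tissue named list mapping tissue codes to [mbl_params].
#' @param geometry a [chamber_geometry].
#' @param na_stenosed return `NA` for stenosed records instead of erroring.
#' @return numeric vector of log10(10^6 platelets/cm^2) predictions.
#' @export
predict_mbl <- function(records, params_by_tissue,
                        geometry = chamber_geometry(), na_stenosed = FALSE) {
  if (any(records$stenosis) && !na_stenosed) {
    stop_domain("MBL model is not applicable to stenosed experiments")
  }
  missing <- setdiff(unique(records$tissue), names(params_by_tissue))
  if (length(missing) > 0L) {
    stop_domain("no calibrated kinetics for tissue(s): ",
                paste(missing, collapse = ", "))
  }
  out <- rep(NA_real_, nrow(records))
  for (tis in unique(records$tissue)) {
    idx <- which(records$tissue == tis & !records$stenosis)
    if (length(idx) == 0L) next
    p <- params_by_tissue[[tis]]
    out[idx] <- log10(mbl_areal_total(records[idx, , drop = FALSE],
                                      p$k1, p$k2, geometry,
                                      d_p = p$d_p, law = p$diffusivity))
  }
  out
}

#' Log-spaced kinetic-constant search grid
#'
#' @param per_decade grid resolution: points are spaced by a factor of
#'   `10^(1/per_decade)`, so a 5-decade range holds `5*per_decade + 1` points.
#' @param range the inclusive search range in m/s.
#' @return numeric vector of candidate kinetic constants.
#' @export
kinetic_grid <- function(per_decade = 26, range = c(1e-8, 1e-3)) {
  if (per_decade < 1 || range[1L] <= 0 || range[2L] <= range[1L]) {
    stop_domain("invalid grid specification")
  }
  decades <- log10(range[2L] / range[1L])
  10^seq(log10(range[1L]), log10(range[2L]),
         length.out = round(decades * per_decade) + 1L)
}

#' Calibrate the adhesion kinetic constants by exhaustive grid search
#'
#' For one substrate, evaluates the forward deposition model at every pair of
#' candidate constants on a log-spaced grid and returns the pair minimizing
#' the summed absolute difference between predicted and measured deposition
#' (on the linear count scale by default, per-record and per-time-point).
#' Ties are broken toward the smallest `k1`, then the smallest `k2`. When the
#' optimum is a plateau extending to infinite kinetics — the minimum loss is
#' matched (relative tolerance 1e-6) by the transport-limited forward model —
#' the substrate is reported as transport-limited rather than an arbitrary
#' grid pair being singled out.
#'
#' @param data a [perfusion_table] with measured deposition.
#' @param tissue substrate code to calibrate (`"PT"`, `"SE"` or `"TM"`).
#' @param geometry a [chamber_geometry].
#' @param grid candidate kinetic constants, m/s (used for both `k1`, `k2`).
#' @param d_p adhered-platelet diameter, m.
#' @param law a [diffusivity_law].
#' @param loss_scale `"linear"` (default: absolute differences of areal
#'   counts) or `"log10"`.
#' @return a list of class `mbl_fit`: `tissue`, `params` (an [mbl_params]),
#'   `loss`, `transport_limited`, `grid`, and the full `loss_matrix`.
#' @export
calibrate_kinetics <- function(data, tissue, geometry = chamber_geometry(),
                               grid = kinetic_grid(), d_p = 2e-6,
                               law = diffusivity_law(),
                               loss_scale = c("linear", "log10")) {
  loss_scale <- match.arg(loss_scale)
  if (length(grid) == 0L) stop_domain("empty kinetic grid")
  sub <- data[data$tissue == tissue & !data$stenosis &
                !is.na(data$deposition), , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_domain("no non-stenosed measured records for tissue ", tissue)
  }
  grid <- sort(grid)
  D <- platelet_diffusivity(sub$hematocrit, sub$shear_rate, law)
  h <- mass_transfer_coefficient(D, sub$shear_rate, geometry$substrate_length)
  c0 <- to_si_concentration(sub$platelet_conc)
  p1_max <- monolayer_capacity(geometry, d_p)
  t_sec <- sub$time_min * 60
  meas <- sub$deposition

  # Per record the total separates as total(k1,k2) = u(k1) + v(k2) * w(k1):
  #   u = P1(k1)/A, w = (t - (Pmax/a1)(1 - exp(-a1 t/Pmax)))/A, v = a2(k2),
  # so the full grid decomposes into outer products record by record.
  n_g <- length(grid)
  loss <- matrix(0, n_g, n_g)
  resid_fun <- if (loss_scale == "linear") {
    function(pred, m) abs(pred - m)
  } else {
    function(pred, m) abs(log10(pmax(pred, 1e-300)) - log10(m))
  }
  for (i in seq_len(nrow(sub))) {
    a1 <- effective_flux(grid, h[i], c0[i]) * geometry$area
    a2 <- effective_flux(grid, h[i], c0[i]) * geometry$area
    x <- a1 * t_sec[i] / p1_max
    u <- p1_max * (-expm1(-x)) / geometry$area / 1e10
    w <- (t_sec[i] - (p1_max / a1) * (-expm1(-x))) / geometry$area / 1e10
    pred <- outer(u, rep(1, n_g)) + outer(w, a2)   # rows k1, cols k2
    loss <- loss + resid_fun(pred, meas[i])
  }
  min_loss <- min(loss)
  hit <- which(loss == min_loss, arr.ind = TRUE)
  # smallest k1 then k2 among exact ties
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  k1_hat <- grid[hit[1L, 1L]]
  k2_hat <- grid[hit[1L, 2L]]

  tl_pred <- mbl_areal_total(sub, Inf, Inf, geometry, d_p = d_p, law = law)
  tl_loss <- sum(resid_fun(tl_pred, meas))
  transport_limited <- tl_loss <= min_loss * (1 + 1e-6)

  params <- if (transport_limited) {
    mbl_params(Inf, Inf, d_p = d_p, diffusivity = law,
               transport_limited = TRUE)
  } else {
    mbl_params(k1_hat, k2_hat, d_p = d_p, diffusivity = law)
  }
  structure(
    list(tissue = tissue, params = params,
         k1 = if (transport_limited) Inf else k1_hat,
         k2 = if (transport_limited) Inf else k2_hat,
         loss = if (transport_limited) tl_loss else min_loss,
         transport_limited = transport_limited,
         grid = grid, loss_matrix = loss, n_records = nrow(sub),
         loss_scale = loss_scale),
    class = "mbl_fit"
  )
}

#' @export
print.mbl_fit <- function(x, ...) {
  cat(sprintf("MBL calibration for %s (%d records, %s-scale loss)\n",
              x$tissue, x$n_records, x$loss_scale))
  if (x$transport_limited) {
    cat("  transport-limited: deposition independent of k1, k2\n")
  } else {
    cat(sprintf("  k1 = %.3g m/s, k2 = %.3g m/s\n", x$k1, x$k2))
  }
  cat(sprintf("  loss = %.6g\n", x$loss))
  invisible(x)
}
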