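#' ITC titration protocol
#'
#' Defaults follow a standard iTC200 run: 550 uM ligand in the syringe
#' titrated into 50 uM macromolecule in a 200 ul cell with 10 ul injections.
#'
#' @param cell_concentration Macromolecule concentration in the cell, uM.
#' @param syringe_concentration Ligand concentration in the syringe, uM.
#' @param cell_volume_ul Calorimeter cell volume, ul.
#' @param injection_volumes_ul Numeric vector of injection volumes, ul.
#' @param temperature_C Temperature, degrees C.
#' @export
itc_protocol <- function(cell_concentration = 50,
                         syringe_concentration = 550,
                         cell_volume_ul = 200,
                         injection_volumes_ul = rep(10, 19),
                         temperature_C = 20) {
  p <- list(cell_concentration = cell_concentration,
            syringe_concentration = syringe_concentration,
            cell_volume_ul = cell_volume_ul,
            injection_volumes_ul = injection_volumes_ul,
            temperature_C = temperature_C)
  if (any(unlist(p[1:4]) <= 0)) stop("protocol volumes and concentrations must be positive")
  if (any(injection_volumes_ul > cell_volume_ul))
    stop("an injection volume exceeds the cell volume")
  if (sum(injection_volumes_ul) > 2 * cell_volume_ul)
    stop("total injected volume exceeds twice the cell volume")
  class(p) <- "itc_protocol"
  p
}

#' Single-site binding model
#'
#' @param N Binding stoichiometry (sites per macromolecule).
#' @param K_d Dissociation constant, uM (> 0).
#' @param dH Binding enthalpy, kcal/mol.
#' @param baseline Constant heat offset per injection, ucal (dilution heat).
#' @export
binding_model <- function(N = 1, K_d, dH, baseline = 0) {
  if (K_d <= 0) stop("K_d must be positive")
  m <- list(N = N, K_d = K_d, dH = dH, baseline = baseline)
  class(m) <- "binding_model"
  m
}

# bound complex concentration (uM) from the single-site quadratic
single_site_bound <- function(N, M_tot, X_tot, K_d) {
  b <- N * M_tot + X_tot + K_d
  disc <- b^2 - 4 * N * M_tot * X_tot
  stopifnot(all(disc >= -1e-9))
  (b - sqrt(pmax(disc, 0))) / 2
}

#' Per-injection heats of a single-site isotherm
#'
#' Uses the displacement-volume convention of a perfusion calorimeter: each
#' injection of volume dV instantaneously mixes into the cell and expels an
#' equal volume, so pre-existing cell contents are diluted by
#' `1 - dV/V0` while the syringe ligand enters at `dV/V0`. The heat of
#' injection i is `dH * V0 * (B_i - B_{i-1} * (1 - dV/V0))` plus the
#' baseline, with `B` the bound-complex concentration solved from the
#' single-site quadratic at the running total concentrations.
#'
#' @param model A [binding_model()].
#' @param protocol An [itc_protocol()].
#' @return Numeric vector of heats in ucal, one per injection.
#' @export
isotherm_heats <- function(model, protocol) {
  stopifnot(inherits(model, "binding_model"), inherits(protocol, "itc_protocol"))
  V0 <- protocol$cell_volume_ul * 1e-6          # liters
  M <- protocol$cell_concentration              # uM
  X <- 0
  B_prev <- 0
  heats <- numeric(length(protocol$injection_volumes_ul))
  for (i in seq_along(heats)) {
    dV <- protocol$injection_volumes_ul[i] * 1e-6
    f <- 1 - dV / (protocol$cell_volume_ul * 1e-6)
    M <- M * f
    X <- X * f + protocol$syringe_concentration * dV / (protocol$cell_volume_ul * 1e-6)
    B <- single_site_bound(model$N, M, X, model$K_d)
    # dH [kcal/mol] * V0 [L] * dB [uM] -> ucal:  kcal/mol * 1e3 cal/kcal * 1e-6 mol = ucal
    heats[i] <- model$dH * 1000 * V0 * (B - B_prev * f) + model$baseline
    B_prev <- B
  }
  heats
}

#' Simulate an ITC experiment
#'
#' @param model A [binding_model()].
#' @param protocol An [itc_protocol()].
#' @param noise_sd Additive Gaussian noise per injection, ucal.
#' @param seed Integer seed.
#' @return Object of class `itc_experiment` with `protocol` and `heats`.
#' @export
simulate_itc <- function(model, protocol, noise_sd = 0, seed = 1L) {
  set.seed(as.integer(seed))
  heats <- isotherm_heats(model, protocol)
  if (noise_sd > 0) heats <- heats + stats::rnorm(length(heats), 0, noise_sd)
  out <- list(protocol = protocol, heats = heats)
  class(out) <- "itc_experiment"
  out
}

#' Fit the single-site isotherm to an ITC experiment
#'
#' Nonlinear least squares (Levenberg-Marquardt) over (N, K_d, dH,
#' baseline). Flat thermograms, in which the enthalpy is unidentifiable,
#' raise an error instead of returning a spurious K_d.
#'
#' @param experiment An `itc_experiment`.
#' @param init Optional [binding_model()] initial guess.
#' @param discard_first Drop injection 1 from the fit (common practice);
#'   default `FALSE`.
#' @return List of class `itc_fit`: `model` (fitted [binding_model()]),
#'   `se` (per-parameter standard errors), `residuals`, `converged`,
#'   `c_value`.
#' @export
fit_isotherm <- function(experiment, init = NULL, discard_first = FALSE) {
  stopifnot(inherits(experiment, "itc_experiment"))
  heats <- experiment$heats
  proto <- experiment$protocol
  keep <- if (discard_first) -1L else seq_along(heats)
  y <- heats[keep]
  if (length(y) < 5L) stop("need >= 5 informative injections")
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y))) || stats::sd(y) == 0)
    stop("flat thermogram: enthalpy unidentifiable")
  if (is.null(init)) {
    total_heat <- sum(y - stats::median(y[(length(y) - 2):length(y)]))
    V0 <- proto$cell_volume_ul * 1e-6
    dH0 <- total_heat / (1000 * V0 * proto$cell_concentration)
    if (!is.finite(dH0) || dH0 == 0) dH0 <- -5
    init <- binding_model(N = 1, K_d = proto$cell_concentration / 10, dH = dH0,
                          baseline = stats::median(y[(length(y) - 2):length(y)]))
  }
  predict_fn <- function(N, K_d, dH, baseline) {
    isotherm_heats(binding_model(N, K_d, dH, baseline), proto)[keep]
  }
  fit <- minpack.lm::nlsLM(
    y ~ predict_fn(N, K_d, dH, baseline),
    start = list(N = init$N, K_d = init$K_d, dH = init$dH, baseline = init$baseline),
    lower = c(1e-3, 1e-6, -Inf, -Inf), upper = c(100, 1e5, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  s <- summary(fit)
  est <- stats::coef(fit)
  se <- s$coefficients[, "Std. Error"]
  model <- binding_model(est[["N"]], est[["K_d"]], est[["dH"]], est[["baseline"]])
  out <- list(model = model, se = se, residuals = stats::residuals(fit),
              converged = fit$convInfo$isConv,
              c_value = est[["N"]] * proto$cell_concentration / est[["K_d"]])
  if (out$c_value < 1 || out$c_value > 1000)
    warning("c-value ", signif(out$c_value, 3), " outside the reliably fittable range")
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("single-site fit: N = %.3g (+/- %.2g), K_d = %.3g uM (+/- %.2g), dH = %.3g kcal/mol, c = %.3g\n",
              m$N, x$se[["N"]], m$K_d, x$se[["K_d"]], m$dH, x$c_value))
  invisible(x)
}

#' Simulate a SEC-MALS elution trace
#'
#' A Gaussian elution peak in the concentration channel; the excess
#' Rayleigh scattering channel is proportional to mass x concentration x
#' dn/dc^2 in the dilute, low-angle limit (instrument optical constant
#' folded into calibrated units).
#'
#' @param mass_kda True molar mass, kDa.
#' @param peak_concentration Peak concentration, mg/ml.
#' @param dn_dc Refractive-index increment, ml/g (default 0.185).
#' @param noise_sd Relative noise (fraction of each channel's peak) added
#'   to both channels.
#' @param peak_center_ml,peak_sd_ml Elution peak center and width, ml.
#' @param volume_range_ml,step_ml Elution volume grid.
#' @param seed Integer seed (used when `noise_sd > 0`).
#' @return Object of class `mals_trace`: data.frame `trace`
#'   (`volume_ml`, `concentration_mg_ml`, `scattering`), plus `dn_dc` and
#'   `true_mass_kda`.
#' @export
simulate_mals_trace <- function(mass_kda, peak_concentration, dn_dc = 0.185,
                                noise_sd = 0, peak_center_ml = 12.5,
                                peak_sd_ml = 0.15,
                                volume_range_ml = c(10, 16), step_ml = 0.01,
                                seed = 1L) {
  if (mass_kda <= 0 || peak_concentration <= 0 || dn_dc <= 0)
    stop("mass, concentration, and dn/dc must be positive")
  set.seed(as.integer(seed))
  v <- seq(volume_range_ml[1], volume_range_ml[2], by = step_ml)
  conc <- peak_concentration * exp(-(v - peak_center_ml)^2 / (2 * peak_sd_ml^2))
  scat <- conc * mass_kda * dn_dc^2
  if (noise_sd > 0) {
    conc <- conc + stats::rnorm(length(v), 0, noise_sd * max(conc))
    scat <- scat + stats::rnorm(length(v), 0, noise_sd * max(scat))
  }
  out <- list(trace = data.frame(volume_ml = v, concentration_mg_ml = conc,
                                 scattering = scat),
              dn_dc = dn_dc, true_mass_kda = mass_kda)
  class(out) <- "mals_trace"
  out
}

#' Weight-averaged molar mass from a SEC-MALS trace
#'
#' Per elution point, mass is proportional to scattering divided by
#' concentration times dn/dc^2 (dilute low-angle limit); the result is the
#' concentration-weighted mean across the peak window, restricted to points
#' above a noise floor.
#'
#' @param trace A `mals_trace`.
#' @param peak_window Numeric `c(lo, hi)` elution volumes, ml; `NULL` uses
#'   the full trace.
#' @param noise_floor_frac Points below this fraction of the maximum
#'   concentration are excluded.
#' @return Weight-averaged molar mass, kDa.
#' @export
mals_mass <- function(trace, peak_window = NULL, noise_floor_frac = 0.05) {
  stopifnot(inherits(trace, "mals_trace"))
  tr <- trace$trace
  if (!is.null(peak_window))
    tr <- tr[tr$volume_ml >= peak_window[1] & tr$volume_ml <= peak_window[2], ]
  if (!nrow(tr)) stop("empty peak window")
  floor_c <- noise_floor_frac * max(tr$concentration_mg_ml)
  tr <- tr[tr$concentration_mg_ml >= floor_c & tr$concentration_mg_ml > 0, ]
  if (!nrow(tr)) stop("no points above the concentration noise floor in the window")
  m_i <- tr$scattering / (tr$concentration_mg_ml * trace$dn_dc^2)
  stats::weighted.mean(m_i, tr$concentration_mg_ml)
}

#' Rank integer stoichiometries against a measured mass
#'
#' Enumerates all copy-number vectors up to `max_copies` per species
#' (excluding all-zero) and ranks them by relative residual
#' `|theoretical - measured| / measured`, breaking ties by fewer total
#' copies. Calls within `tolerance` are flagged consistent.
#'
#' @param measured_mass Measured mass, kDa.
#' @param monomer_masses Named numeric vector of monomer masses, kDa.
#' @param max_copies Maximum copies per species.
#' @param tolerance Relative residual below which a call is "consistent".
#' @return data.frame ranked by residual: one column per species, plus
#'   `theoretical_mass`, `measured_mass`, `relative_residual`, `consistent`.
#' @export
infer_stoichiometry <- function(measured_mass, monomer_masses, max_copies = 4L,
                                tolerance = 0.05) {
  if (!length(monomer_masses)) stop("empty species list")
  if (any(monomer_masses <= 0) || measured_mass <= 0) stop("masses must be positive")
  if (max_copies < 1L) stop("max_copies must be >= 1")
  grid <- do.call(expand.grid, rep(list(0:max_copies), length(monomer_masses)))
  names(grid) <- names(monomer_masses)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  theo <- as.matrix(grid) %*% monomer_masses
  out <- cbind(grid,
               theoretical_mass = as.numeric(theo),
               measured_mass = measured_mass,
               relative_residual = abs(as.numeric(theo) - measured_mass) / measured_mass)
  out$consistent <- out$relative_residual <= tolerance
  out <- out[order(out$relative_residual, rowSums(grid)), ]
  rownames(out) <- NULL
  out
}
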