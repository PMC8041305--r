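# Reduction of light-scattering and viscometry measurements to interaction
# parameters: Stokes-Einstein, the interaction diffusion coefficient kD, the
# Debye analysis for Mw and B22, capillary-viscometry reduction and the
# Jones-Dole A/B fit.

#' Dynamic light scattering series
#'
#' Collective diffusion coefficients versus protein concentration from DLS.
#'
#' @param gamma_mg_ml Protein concentrations in mg/mL (distinct, positive).
#' @param D_m2_s Diffusion coefficients in m^2/s (positive).
#' @param temperature Temperature in K (default 298.15).
#' @param solvent_viscosity_mPas Solvent viscosity in mPa s (default 0.8900,
#'   water at 25 C).
#' @return Object of class `dls_series`.
#' @export
dls_series <- function(gamma_mg_ml, D_m2_s, temperature = 298.15,
                       solvent_viscosity_mPas = 0.8900) {
  stopifnot(length(gamma_mg_ml) == length(D_m2_s))
  if (any(gamma_mg_ml <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(gamma_mg_ml)) stop("concentrations must be distinct")
  if (any(D_m2_s <= 0)) stop("diffusion coefficients must be positive")
  structure(
    list(points = data.frame(gamma_mg_ml = gamma_mg_ml, D_m2_s = D_m2_s),
         temperature = temperature,
         solvent_viscosity_mPas = solvent_viscosity_mPas),
    class = "dls_series")
}

#' Static light scattering configuration
#'
#' Optical constants of the SLS reduction: laser wavelength, solvent
#' refractive index, specific refractive-index increment and the toluene
#' reference Rayleigh ratio.
#'
#' @param wavelength_nm Laser wavelength in vacuo, nm (default 632.8, He-Ne).
#' @param refractive_index Solvent refractive index n0 (default 1.332,
#'   aqueous buffer at 632.8 nm).
#' @param dn_dc_mL_g Specific refractive-index increment in mL/g (default
#'   0.185, globular proteins).
#' @param rayleigh_toluene_cm Toluene Rayleigh ratio in cm^-1 (default
#'   14.0e-6).
#' @return Object of class `sls_config`.
#' @export
sls_config <- function(wavelength_nm = 632.8, refractive_index = 1.332,
                       dn_dc_mL_g = 0.185, rayleigh_toluene_cm = 14.0e-6) {
  stopifnot(wavelength_nm > 0, refractive_index > 0, dn_dc_mL_g > 0,
            rayleigh_toluene_cm > 0)
  structure(list(wavelength_nm = wavelength_nm,
                 refractive_index = refractive_index,
                 dn_dc_mL_g = dn_dc_mL_g,
                 rayleigh_toluene_cm = rayleigh_toluene_cm),
            class = "sls_config")
}

#' Static light scattering series
#'
#' Either raw mean count rates (with a toluene reference) or already reduced
#' `Kc/R` values versus concentration.
#'
#' @param conc_g_ml Protein concentrations in g/mL (positive).
#' @param mcr_cps Mean count rates in counts/s (raw input), or `NULL`.
#' @param kc_over_r Reduced `Kc/R` values in mol/g (pre-reduced input), or
#'   `NULL`. Exactly one of `mcr_cps` / `kc_over_r` must be given.
#' @param laser_intensity Incident laser intensity (arbitrary units) used to
#'   normalise count rates; cancels in the toluene ratio.
#' @param toluene_count_rate Toluene reference mean count rate in counts/s
#'   (required with raw input).
#' @param config An [sls_config()].
#' @return Object of class `sls_series`.
#' @export
sls_series <- function(conc_g_ml, mcr_cps = NULL, kc_over_r = NULL,
                       laser_intensity = 1, toluene_count_rate = NULL,
                       config = sls_config()) {
  if (any(conc_g_ml <= 0)) stop("concentrations must be positive (g/mL)")
  if (is.null(mcr_cps) == is.null(kc_over_r))
    stop("supply exactly one of `mcr_cps` or `kc_over_r`")
  if (!is.null(mcr_cps)) {
    stopifnot(length(mcr_cps) == length(conc_g_ml))
    if (is.null(toluene_count_rate) || toluene_count_rate <= 0)
      stop("raw count rates need a positive `toluene_count_rate`")
  } else {
    stopifnot(length(kc_over_r) == length(conc_g_ml))
  }
  stopifnot(inherits(config, "sls_config"), laser_intensity > 0)
  structure(
    list(points = data.frame(
           conc_g_ml = conc_g_ml,
           mcr_cps = if (is.null(mcr_cps)) NA_real_ else mcr_cps,
           kc_over_r = if (is.null(kc_over_r)) NA_real_ else kc_over_r),
         raw = !is.null(mcr_cps),
         laser_intensity = laser_intensity,
         toluene_count_rate = toluene_count_rate,
         config = config),
    class = "sls_series")
}

#' Capillary viscometry series
#'
#' Either relative viscosities directly, or raw flow times and mass
#' densities together with the water reference.
#'
#' @param conc_M Solute concentrations in mol/L (>= 0).
#' @param eta_rel Relative viscosities eta/eta0 (pre-reduced input), or
#'   `NULL`.
#' @param flow_s Flow times in s (raw input), or `NULL`.
#' @param density_g_cm3 Mass densities in g/cm^3 (raw input), or `NULL`.
#' @param reference List with `flow_s`, `density_g_cm3` and `eta_mPas` for
#'   the reference solvent (required with raw input).
#' @return Object of class `viscosity_series`.
#' @export
viscosity_series <- function(conc_M, eta_rel = NULL, flow_s = NULL,
                             density_g_cm3 = NULL, reference = NULL) {
  if (any(conc_M < 0)) stop("concentrations must be non-negative (mol/L)")
  raw <- is.null(eta_rel)
  if (raw) {
    stopifnot(length(flow_s) == length(conc_M),
              length(density_g_cm3) == length(conc_M))
    if (is.null(reference) ||
        !all(c("flow_s", "density_g_cm3", "eta_mPas") %in% names(reference)))
      stop("raw input needs `reference` with flow_s, density_g_cm3, eta_mPas")
    if (any(unlist(reference[c("flow_s", "density_g_cm3", "eta_mPas")]) <= 0))
      stop("reference values must be positive")
  } else {
    stopifnot(length(eta_rel) == length(conc_M))
    if (any(eta_rel <= 0)) stop("`eta_rel` must be positive")
  }
  structure(
    list(points = data.frame(
           conc_M = conc_M,
           eta_rel = if (raw) NA_real_ else eta_rel,
           flow_s = if (raw) flow_s else NA_real_,
           density_g_cm3 = if (raw) density_g_cm3 else NA_real_),
         raw = raw, reference = reference),
    class = "viscosity_series")
}

#' Stokes-Einstein relation
#'
#' `D = kB * T / (6 pi eta0 Rh)`, converting between the hydrodynamic radius
#' and the infinite-dilution diffusion coefficient. Supply exactly one of
#' `radius_nm` / `diffusion_m2_s`; the other is returned.
#'
#' @param temperature Temperature in K.
#' @param solvent_viscosity_mPas Solvent viscosity in mPa s.
#' @param radius_nm Hydrodynamic radius in nm, or `NULL`.
#' @param diffusion_m2_s Diffusion coefficient in m^2/s, or `NULL`.
#' @return Diffusion coefficient in m^2/s (given a radius) or hydrodynamic
#'   radius in nm (given a diffusion coefficient).
#' @export
stokes_einstein <- function(temperature, solvent_viscosity_mPas,
                            radius_nm = NULL, diffusion_m2_s = NULL) {
  if (temperature <= 0 || solvent_viscosity_mPas <= 0)
    stop("temperature and viscosity must be positive")
  if (is.null(radius_nm) == is.null(diffusion_m2_s))
    stop("supply exactly one of `radius_nm` or `diffusion_m2_s`")
  pref <- .const$boltzmann_J_K * temperature /
    (6 * pi * solvent_viscosity_mPas * 1e-3)   # = D * Rh in m^3/s
  if (!is.null(radius_nm)) {
    if (any(radius_nm <= 0)) stop("`radius_nm` must be positive")
    pref / (radius_nm * 1e-9)
  } else {
    if (any(diffusion_m2_s <= 0)) stop("`diffusion_m2_s` must be positive")
    pref / diffusion_m2_s / 1e-9
  }
}

#' Interaction diffusion coefficient from a DLS series
#'
#' Least-squares fit of `D = D0 (1 + kD * c)` with the concentration in
#' g/mL, so that kD carries mL/g. Reported standard errors come from the OLS
#' covariance (delta method for kD = slope / intercept).
#'
#' @param series A [dls_series()] with >= 2 concentrations, optionally
#'   restricted beforehand to the semidilute window.
#' @param window Optional concentration window `c(min, max)` in mg/mL used
#'   to subset the points before fitting; default uses all points.
#' @return List with `D0_m2_s`, `D0_se`, `kD_mL_g`, `kD_se`, `n` and
#'   `window_mg_ml`.
#' @export
fit_interaction_diffusion <- function(series, window = NULL) {
  stopifnot(inherits(series, "dls_series"))
  pts <- series$points
  if (!is.null(window))
    pts <- pts[pts$gamma_mg_ml >= window[1] & pts$gamma_mg_ml <= window[2], ]
  if (nrow(pts) < 2) stop("need >= 2 concentrations in the fit window")
  cgml <- pts$gamma_mg_ml / 1000
  fit <- stats::lm(pts$D_m2_s ~ cgml)
  cf <- stats::coef(fit); V <- suppressWarnings(stats::vcov(fit))
  d0 <- cf[[1]]; sl <- cf[[2]]
  kd <- sl / d0
  kd_var <- V[2, 2] / d0^2 + sl^2 * V[1, 1] / d0^4 - 2 * sl * V[1, 2] / d0^3
  list(D0_m2_s = d0, D0_se = sqrt(V[1, 1]),
       kD_mL_g = kd, kD_se = sqrt(max(kd_var, 0)),
       n = nrow(pts),
       window_mg_ml = if (is.null(window)) range(pts$gamma_mg_ml) else window)
}

# optical constant K = 4 pi^2 n0^2 (dn/dc)^2 / (N_A lambda^4), cm^2 mol g^-2
.optical_constant <- function(config) {
  lam_cm <- config$wavelength_nm * 1e-7
  4 * pi^2 * config$refractive_index^2 * config$dn_dc_mL_g^2 /
    (.const$avogadro * lam_cm^4)
}

#' Reduce raw static-scattering count rates to Kc/R
#'
#' Sample scattered intensities are the mean count rates normalised by the
#' laser intensity; the sample Rayleigh ratio follows from the toluene
#' reference, `R_sam = (I_sam / I_tol) * R_tol`; the optical constant
#' `K = 4 pi^2 n0^2 (dn/dc)^2 / (N_A lambda0^4)` then gives `Kc/R` per
#' point. Already-reduced series pass through unchanged.
#'
#' @param series An [sls_series()].
#' @return Data frame with columns `conc_g_ml` and `kc_over_r` (mol/g).
#' @export
reduce_sls <- function(series) {
  stopifnot(inherits(series, "sls_series"))
  pts <- series$points
  if (!series$raw)
    return(data.frame(conc_g_ml = pts$conc_g_ml, kc_over_r = pts$kc_over_r))
  i_sam <- pts$mcr_cps / series$laser_intensity
  i_tol <- series$toluene_count_rate / series$laser_intensity
  r_sam <- i_sam / i_tol * series$config$rayleigh_toluene_cm
  K <- .optical_constant(series$config)
  data.frame(conc_g_ml = pts$conc_g_ml, kc_over_r = K * pts$conc_g_ml / r_sam)
}

#' Debye-plot fit for Mw and B22
#'
#' OLS fit of `Kc/R = 1/Mw + 2 B22 c` over the supplied (semidilute)
#' points: the intercept gives the weight-average molar mass, the slope
#' twice the osmotic second virial coefficient in mol mL g^-2.
#'
#' @param points Data frame with columns `conc_g_ml` and `kc_over_r`, e.g.
#'   from [reduce_sls()].
#' @param window Optional concentration window `c(min, max)` in g/mL.
#' @return List with `Mw_g_mol`, `Mw_se`, `B22_mol_mL_g2`, `B22_se`,
#'   `intercept`, `intercept_se`, `n`, `window_g_ml` and `Mw_defined`
#'   (FALSE, with a warning, when the intercept is not positive).
#' @export
debye_fit <- function(points, window = NULL) {
  stopifnot(is.data.frame(points),
            all(c("conc_g_ml", "kc_over_r") %in% names(points)))
  pts <- points
  if (!is.null(window))
    pts <- pts[pts$conc_g_ml >= window[1] & pts$conc_g_ml <= window[2], ]
  if (nrow(pts) < 2) stop("need >= 2 points in the fit window")
  fit <- stats::lm(kc_over_r ~ conc_g_ml, data = pts)
  cf <- suppressWarnings(summary(fit)$coefficients)
  ic <- cf[1, 1]; ic_se <- cf[1, 2]
  mw_ok <- ic > 0
  if (!mw_ok)
    warning("non-positive Debye intercept: Mw undefined, B22 still reported")
  list(Mw_g_mol = if (mw_ok) 1 / ic else NA_real_,
       Mw_se = if (mw_ok) ic_se / ic^2 else NA_real_,
       B22_mol_mL_g2 = cf[2, 1] / 2, B22_se = cf[2, 2] / 2,
       intercept = ic, intercept_se = ic_se,
       n = nrow(pts),
       window_g_ml = if (is.null(window)) range(pts$conc_g_ml) else window,
       Mw_defined = mw_ok)
}

#' Viscosities from capillary flow times
#'
#' Ostwald-viscometer reduction `eta = eta0 * (rho t) / (rho0 t0)` against
#' the water reference, plus the relative viscosity.
#'
#' @param series A raw [viscosity_series()] (flow times + densities +
#'   reference).
#' @return Data frame with columns `conc_M`, `eta_mPas`, `eta_rel`.
#' @export
viscosity_from_flow <- function(series) {
  stopifnot(inherits(series, "viscosity_series"))
  if (!series$raw)
    return(data.frame(conc_M = series$points$conc_M,
                      eta_mPas = series$points$eta_rel * NA_real_,
                      eta_rel = series$points$eta_rel))
  ref <- series$reference
  eta <- ref$eta_mPas * (series$points$density_g_cm3 * series$points$flow_s) /
    (ref$density_g_cm3 * ref$flow_s)
  data.frame(conc_M = series$points$conc_M, eta_mPas = eta,
             eta_rel = eta / ref$eta_mPas)
}

#' Jones-Dole viscosity fit
#'
#' Least-squares fit of `eta/eta0 - 1 = A sqrt(c) + B c` in the linear basis
#' `{sqrt(c), c}`. The electrostatic coefficient A may be pinned to a
#' Debye-Hueckel value instead of fitted.
#'
#' @param conc_M Solute concentrations in mol/L (distinct, positive).
#' @param eta_rel Relative viscosities eta/eta0.
#' @param fix_A Optional fixed value for A (L^1/2 mol^-1/2); when given only
#'   B is fitted.
#' @return List with `A`, `A_se`, `B_L_mol`, `B_se`, `n` and `A_fixed`.
#' @export
jones_dole_fit <- function(conc_M, eta_rel, fix_A = NULL) {
  stopifnot(length(conc_M) == length(eta_rel))
  if (any(conc_M <= 0)) stop("concentrations must be positive for the fit")
  if (length(unique(conc_M)) < 2) stop("need >= 2 distinct concentrations")
  y <- eta_rel - 1
  sq <- sqrt(conc_M)
  if (is.null(fix_A)) {
    fit <- stats::lm(y ~ 0 + sq + conc_M)
    cf <- suppressWarnings(summary(fit)$coefficients)
    list(A = cf["sq", 1], A_se = cf["sq", 2],
         B_L_mol = cf["conc_M", 1], B_se = cf["conc_M", 2],
         n = length(conc_M), A_fixed = FALSE)
  } else {
    y2 <- y - fix_A * sq
    fit <- stats::lm(y2 ~ 0 + conc_M)
    cf <- suppressWarnings(summary(fit)$coefficients)
    list(A = fix_A, A_se = NA_real_,
         B_L_mol = cf[1, 1], B_se = cf[1, 2],
         n = length(conc_M), A_fixed = TRUE)
  }
}
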