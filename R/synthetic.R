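# Seeded synthetic-data generators for every measurement stream the fitting
# functions consume. Each generator evaluates the exact model curve, adds
# additive Gaussian noise on the measured ordinate, and records the ground
# truth as an attribute so fits can be checked against it.

# run `code` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cloud-point series
#'
#' Cloud-point temperatures computed from the phase-equilibrium model with
#' `eps(I) = eps0 + a sqrt(I)`, plus additive Gaussian noise of standard
#' deviation `noise_sd`.
#'
#' @param model A [protein_model()].
#' @param buffer A [buffer_interaction()] providing eps0 and the salt
#'   coefficient.
#' @param gamma Protein concentration in mg/mL (default 90).
#' @param ionic_strengths Ionic strengths in mol/L (default the measured
#'   NaBr range 0.1-0.5 M).
#' @param noise_sd Noise SD on the cloud-point temperature, K (default 0.2).
#' @param seed Integer RNG seed.
#' @return A [cloud_point_series()] whose `sigma_t` column carries
#'   `noise_sd` (when positive) and with attribute `truth` (list of the
#'   generating parameters and noiseless temperatures).
#' @export
gen_cloud_point_series <- function(model, buffer, gamma = 90,
                                   ionic_strengths = seq(0.1, 0.5, by = 0.1),
                                   noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(model, "protein_model"),
            inherits(buffer, "buffer_interaction"), noise_sd >= 0)
  if (length(ionic_strengths) == 0) stop("`ionic_strengths` must be non-empty")
  t0 <- vapply(ionic_strengths, function(I) {
    tryCatch(
      as.numeric(cloud_point_temperature(gamma, model, buffer,
                                         ionic_strength = I)),
      error = function(e) stop(sprintf(
        "cloud point unreachable at I = %.4g mol/L: %s", I,
        conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  tn <- .with_seed(seed, t0 + stats::rnorm(length(t0), sd = noise_sd))
  out <- cloud_point_series(
    buffer$name, gamma, ionic_strengths, tn,
    sigma_t = if (noise_sd > 0) rep(noise_sd, length(t0)) else NULL)
  attr(out, "truth") <- list(eps0 = buffer$eps0, salt_coeff = buffer$salt_coeff,
                             gamma = gamma, t_cloud_noiseless = t0,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic DLS series
#'
#' The linear concentration dependence `D = D0 (1 + kD * gamma)` (gamma in
#' g/mL) plus additive Gaussian noise on D.
#'
#' @param D0 Infinite-dilution diffusion coefficient, m^2/s.
#' @param kD Interaction diffusion coefficient, mL/g.
#' @param gammas Concentrations in mg/mL (default 8 points over the
#'   semidilute DLS range 4-70 mg/mL).
#' @param noise_sd Noise SD on D in m^2/s (default 1% of D0).
#' @param seed Integer RNG seed.
#' @param temperature,solvent_viscosity_mPas Passed to [dls_series()].
#' @return A [dls_series()] with attribute `truth`.
#' @export
gen_dls_series <- function(D0, kD, gammas = seq(4, 70, length.out = 8),
                           noise_sd = 0.01 * D0, seed = 1,
                           temperature = 298.15,
                           solvent_viscosity_mPas = 0.8900) {
  stopifnot(D0 > 0, noise_sd >= 0, all(gammas > 0))
  d0line <- D0 * (1 + kD * gammas / 1000)
  dn <- .with_seed(seed, d0line + stats::rnorm(length(gammas), sd = noise_sd))
  out <- dls_series(gammas, dn, temperature = temperature,
                    solvent_viscosity_mPas = solvent_viscosity_mPas)
  attr(out, "truth") <- list(D0 = D0, kD = kD, noise_sd = noise_sd, seed = seed,
                             D_noiseless = d0line)
  out
}

#' Generate a synthetic SLS series
#'
#' Mean count rates consistent with the Debye line
#' `Kc/R = 1/Mw + 2 B22 c`: the implied sample Rayleigh ratio is converted
#' to a count rate through the toluene reference, then perturbed with
#' multiplicative Gaussian noise (photon count scales with intensity).
#'
#' @param Mw Weight-average molar mass, g/mol.
#' @param B22 Osmotic second virial coefficient, mol mL g^-2.
#' @param concs Concentrations in g/mL (default 8 points over 0.002-0.01,
#'   the semidilute Debye window).
#' @param config An [sls_config()].
#' @param noise_frac Fractional (multiplicative) noise SD on the count rate
#'   (default 0).
#' @param seed Integer RNG seed.
#' @param laser_intensity,toluene_count_rate Instrument scales embedded in
#'   the generated series.
#' @return An [sls_series()] (raw count rates) with attribute `truth`.
#' @export
gen_sls_series <- function(Mw, B22, concs = seq(0.002, 0.01, length.out = 8),
                           config = sls_config(), noise_frac = 0, seed = 1,
                           laser_intensity = 1e3, toluene_count_rate = 3e5) {
  stopifnot(Mw > 0, all(concs > 0), noise_frac >= 0)
  kcr <- 1 / Mw + 2 * B22 * concs
  if (any(kcr <= 0)) stop("Debye line non-positive over `concs`")
  K <- .optical_constant(config)
  r_sam <- K * concs / kcr
  mcr0 <- r_sam / config$rayleigh_toluene_cm * toluene_count_rate
  mcr <- .with_seed(seed,
                    mcr0 * (1 + stats::rnorm(length(concs), sd = noise_frac)))
  out <- sls_series(concs, mcr_cps = mcr, laser_intensity = laser_intensity,
                    toluene_count_rate = toluene_count_rate, config = config)
  attr(out, "truth") <- list(Mw = Mw, B22 = B22, noise_frac = noise_frac,
                             seed = seed, mcr_noiseless = mcr0)
  out
}

#' Generate a synthetic viscometry series
#'
#' Jones-Dole relative viscosities `eta/eta0 = 1 + A sqrt(c) + B c` plus
#' additive Gaussian noise.
#'
#' @param A Electrostatic coefficient, L^1/2 mol^-1/2.
#' @param B Jones-Dole coefficient, L/mol.
#' @param concs Concentrations in mol/L (default 0.02-0.1 M, the measured
#'   buffer range).
#' @param noise_sd Noise SD on eta_rel (default 0.001).
#' @param seed Integer RNG seed.
#' @return A [viscosity_series()] with attribute `truth`.
#' @export
gen_viscosity_series <- function(A, B, concs = seq(0.02, 0.1, by = 0.02),
                                 noise_sd = 0.001, seed = 1) {
  stopifnot(all(concs > 0), noise_sd >= 0)
  er0 <- 1 + A * sqrt(concs) + B * concs
  er <- .with_seed(seed, er0 + stats::rnorm(length(concs), sd = noise_sd))
  out <- viscosity_series(concs, eta_rel = er)
  attr(out, "truth") <- list(A = A, B = B, noise_sd = noise_sd, seed = seed,
                             eta_rel_noiseless = er0)
  out
}
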