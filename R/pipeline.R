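# End-to-end orchestration of the calibration workflow on synthetic data:
# generate cloud-point series per buffer -> per-point well depths -> salt-law
# regression -> predicted phase diagrams -> correlation analyses.

#' Pipeline configuration
#'
#' Bundles the model, buffers, grids and seeds driving [run_pipeline()].
#'
#' @param model A [protein_model()] (default [hewl_model()]).
#' @param buffers Named list of [buffer_interaction()] objects used as
#'   ground truth for the synthetic measurements (default
#'   [buffer_fixtures()]).
#' @param gammas Protein concentrations in mg/mL for cloud-point series
#'   (default `c(90, 125)`).
#' @param ionic_strengths Salt grid in mol/L (default 0.1-0.5 M).
#' @param noise_sd Cloud-point noise SD in K (default 0.2).
#' @param seed Master RNG seed; per-series seeds are derived from it.
#' @param n_temperatures Points per predicted binodal (default 25).
#' @param zero_salt_basis Basis for the zero-salt extrapolation of the
#'   synthetic measured temperatures (`"linear"` or `"sqrt"`).
#' @param on_error `"stop"` (default) or `"continue"` (skip failed buffers,
#'   recording the failure in the log).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(model = hewl_model(), buffers = buffer_fixtures(),
                            gammas = c(90, 125),
                            ionic_strengths = seq(0.1, 0.5, by = 0.1),
                            noise_sd = 0.2, seed = 1, n_temperatures = 25,
                            zero_salt_basis = "linear",
                            on_error = c("stop", "continue")) {
  stopifnot(inherits(model, "protein_model"), length(buffers) >= 1,
            noise_sd >= 0, n_temperatures >= 2)
  structure(list(model = model, buffers = buffers, gammas = gammas,
                 ionic_strengths = ionic_strengths, noise_sd = noise_sd,
                 seed = as.integer(seed), n_temperatures = n_temperatures,
                 zero_salt_basis = zero_salt_basis,
                 on_error = match.arg(on_error)),
            class = "pipeline_config")
}

#' Run the full calibration pipeline
#'
#' For each buffer: generates seeded synthetic cloud-point series at each
#' protein concentration, fits a well depth per salt point, regresses the
#' pooled depths on `sqrt(I)` to recover (eps0, a), extrapolates the
#' synthetic measurements to zero salt, and predicts the full coexistence
#' curve from the fitted eps0. Afterwards it computes the correlation
#' analyses (a vs eps0, Jones-Dole B vs eps0, and zero-salt cloud point vs
#' the measured B22 and kD metadata) and the buffer phase-stability
#' ordering.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `llps_report`: list with `fits` (one row per
#'   buffer: true and fitted parameters with SEs, zero-salt extrapolated and
#'   model cloud points), `binodals` (named list of [binodal_curve()]),
#'   `correlations` (named list of [linear_correlation()] results),
#'   `stability_order` (buffer names, most stable first = lowest cloud
#'   point), `log` (stage messages) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- config$model
  log <- c(sprintf("pipeline seed %d, %d buffers, gammas [%s] mg/mL",
                   config$seed, length(config$buffers),
                   paste(config$gammas, collapse = ", ")))
  rows <- list(); binodals <- list()
  for (bi in seq_along(config$buffers)) {
    buf <- config$buffers[[bi]]
    res <- tryCatch({
      pooled <- list(); t0_ext <- rep(NA_real_, length(config$gammas))
      for (gi in seq_along(config$gammas)) {
        sseed <- config$seed + 1000L * bi + gi   # derived, deterministic
        series <- gen_cloud_point_series(
          model, buf, gamma = config$gammas[gi],
          ionic_strengths = config$ionic_strengths,
          noise_sd = config$noise_sd, seed = sseed)
        log <- c(log, sprintf("  %s gamma=%g: generated %d points (seed %d)",
                              buf$name, config$gammas[gi],
                              nrow(series$observations), sseed))
        pooled[[gi]] <- fit_epsilon_series(series, model)
        ext <- extrapolate_tcloud_zero_salt(
          series$observations$ionic_strength_M,
          series$observations$t_cloud_K, basis = config$zero_salt_basis)
        t0_ext[gi] <- ext$t_cloud_0
      }
      eps_pts <- do.call(rbind, pooled)
      sfit <- fit_salt_coefficients(eps_pts, name = buf$name)
      bc <- binodal_curve(model, sfit$eps0,
                          n_temperatures = config$n_temperatures)
      tcl_model <- vapply(config$gammas, function(g)
        as.numeric(cloud_point_temperature(g, model, sfit$eps0)), numeric(1))
      list(row = data.frame(
             buffer = buf$name,
             eps0_true_K = buf$eps0, eps0_fit_K = sfit$eps0,
             eps0_se_K = sfit$eps0_se,
             a_true = buf$salt_coeff, a_fit = sfit$salt_coeff,
             a_se = sfit$salt_coeff_se,
             t_cloud0_ext_K = t0_ext[1],
             t_cloud0_model_K = tcl_model[1],
             t_cloud0_model_hi_K = tcl_model[min(2, length(tcl_model))],
             jones_dole_B = if (is.null(buf$jones_dole_B)) NA_real_
               else buf$jones_dole_B,
             kD_mL_g = if (is.null(buf$metadata$kD_mL_g)) NA_real_
               else buf$metadata$kD_mL_g,
             B22_mol_mL_g2 = if (is.null(buf$metadata$B22_mol_mL_g2)) NA_real_
               else buf$metadata$B22_mol_mL_g2),
           binodal = bc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("  %s FAILED: %s", buf$name, conditionMessage(res))
      if (config$on_error == "stop") stop(msg)
      log <- c(log, msg)
    } else {
      rows[[buf$name]] <- res$row
      binodals[[buf$name]] <- res$binodal
    }
  }
  fits <- do.call(rbind, rows); rownames(fits) <- NULL
  correlations <- list()
  if (nrow(fits) >= 2) {
    correlations$a_vs_eps0 <- linear_correlation(fits$eps0_fit_K, fits$a_fit)
    if (all(is.finite(fits$jones_dole_B)))
      correlations$jones_dole_B_vs_eps0 <-
        linear_correlation(fits$eps0_fit_K, fits$jones_dole_B)
    if (all(is.finite(fits$B22_mol_mL_g2)))
      correlations$t_cloud_vs_B22 <-
        linear_correlation(fits$B22_mol_mL_g2, fits$t_cloud0_model_K)
    if (all(is.finite(fits$kD_mL_g)))
      correlations$t_cloud_vs_kD <-
        linear_correlation(fits$kD_mL_g, fits$t_cloud0_model_K)
  }
  # most stable buffer = lowest zero-salt cloud point
  ord <- order(fits$t_cloud0_model_K)
  structure(list(fits = fits, binodals = binodals,
                 correlations = correlations,
                 stability_order = fits$buffer[ord],
                 log = log, config = config),
            class = "llps_report")
}

#' @export
print.llps_report <- function(x, ...) {
  cat("LLPS calibration pipeline report\n")
  cat("================================\n")
  print(x$fits[, c("buffer", "eps0_true_K", "eps0_fit_K", "a_true", "a_fit",
                   "t_cloud0_model_K")], row.names = FALSE, digits = 6)
  cat("\nPhase stability (most stable first): ",
      paste(x$stability_order, collapse = " > "), "\n", sep = "")
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  %-24s slope = %10.4g  r = %6.3f\n", nm, co$slope,
                co$pearson_r))
  }
  invisible(x)
}
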