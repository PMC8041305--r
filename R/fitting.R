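# Calibration of the model against cloud-point data: the zero-salt well depth
# eps0 from a single cloud point, per-salt well depths eps(I), the (eps0, a)
# regression against sqrt(I), zero-salt extrapolation of measured cloud
# points, and plain linear correlation summaries.

#' Cloud-point measurement series
#'
#' Container for cloud-point temperatures of one buffer at one protein
#' concentration across added-salt ionic strengths.
#'
#' @param buffer_name Buffer label.
#' @param gamma Protein concentration in mg/mL.
#' @param ionic_strength Ionic strengths in mol/L, non-negative and strictly
#'   increasing.
#' @param t_cloud Cloud-point temperatures in K.
#' @param sigma_t Optional measurement standard deviations in K.
#' @return Object of class `cloud_point_series` with a data frame
#'   `observations`.
#' @export
cloud_point_series <- function(buffer_name, gamma, ionic_strength, t_cloud,
                               sigma_t = NULL) {
  stopifnot(is.character(buffer_name), length(buffer_name) == 1, gamma > 0)
  n <- length(ionic_strength)
  stopifnot(length(t_cloud) == n)
  if (n && any(ionic_strength < 0)) stop("ionic strengths must be non-negative")
  if (n > 1 && any(diff(ionic_strength) <= 0))
    stop("ionic strengths must be strictly increasing")
  if (!is.null(sigma_t)) {
    stopifnot(length(sigma_t) == n)
    if (n && any(sigma_t <= 0)) stop("`sigma_t` must be positive")
  }
  structure(
    list(buffer_name = buffer_name, gamma = as.numeric(gamma),
         observations = data.frame(
           ionic_strength_M = as.numeric(ionic_strength),
           t_cloud_K = as.numeric(t_cloud),
           sigma_t_K = if (is.null(sigma_t)) rep(NA_real_, n) else as.numeric(sigma_t))),
    class = "cloud_point_series")
}

#' @export
print.cloud_point_series <- function(x, ...) {
  cat(sprintf("Cloud-point series: %s, gamma = %.4g mg/mL, %d observations\n",
              x$buffer_name, x$gamma, nrow(x$observations)))
  print(x$observations)
  invisible(x)
}

#' Fit the zero-salt well depth to one cloud point
#'
#' Finds the well depth eps for which the model cloud-point temperature at
#' concentration `gamma` (zero added salt) matches an observed value. The
#' cloud-point temperature is strictly increasing in eps, so the root is
#' unique within the bracket.
#'
#' @param model A [protein_model()].
#' @param gamma Protein concentration in mg/mL.
#' @param t_cloud_obs Observed cloud-point temperature in K.
#' @param bracket Search interval for eps in K (default `c(500, 5000)`).
#' @param tol Tolerance on the matched temperature in K (default 1e-3).
#' @param sigma_t Optional measurement SD of `t_cloud_obs` in K; when given,
#'   the fitted eps carries a standard error propagated through the
#'   numerically evaluated derivative dT_cloud/deps.
#' @return Fitted eps in K (numeric scalar) with attributes `se` (K, or NA)
#'   and `t_residual` (K, achieved misfit).
#' @export
fit_eps0 <- function(model, gamma, t_cloud_obs, bracket = c(500, 5000),
                     tol = 1e-3, sigma_t = NULL) {
  stopifnot(inherits(model, "protein_model"), gamma > 0, t_cloud_obs > 0,
            length(bracket) == 2, bracket[1] > 0, bracket[1] < bracket[2])
  # t_min = 1 K: the eps bracket may reach well depths whose dome lies far
  # below the default 150 K search floor
  tcl <- function(eps) as.numeric(cloud_point_temperature(gamma, model, eps,
                                                          tol = tol / 4,
                                                          t_min = 1))
  f <- function(eps) tcl(eps) - t_cloud_obs
  f_lo <- f(bracket[1]); f_hi <- f(bracket[2])
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf(
      "t_cloud_obs = %.6g K unreachable in eps bracket [%g, %g] K (model T_cloud range [%.6g, %.6g] K)",
      t_cloud_obs, bracket[1], bracket[2], f_lo + t_cloud_obs, f_hi + t_cloud_obs))
  slope0 <- (f_hi - f_lo) / (bracket[2] - bracket[1])   # ~ dT/deps, for tol mapping
  eps_hat <- stats::uniroot(f, bracket, f.lower = f_lo, f.upper = f_hi,
                            tol = max(tol / slope0 / 4, 1e-8))$root
  se <- NA_real_
  if (!is.null(sigma_t)) {
    h <- eps_hat * 1e-3
    dTde <- (tcl(eps_hat + h) - tcl(eps_hat - h)) / (2 * h)
    se <- sigma_t / dTde
  }
  structure(eps_hat, se = se, t_residual = f(eps_hat))
}

#' Per-observation well depths from a cloud-point series
#'
#' Applies [fit_eps0()] at each observation's ionic strength, yielding the
#' effective well depth eps(I) for each measured cloud point. Per-point
#' failures (e.g. unreachable temperatures) are reported in the output, not
#' raised.
#'
#' @param series A [cloud_point_series()].
#' @param model A [protein_model()].
#' @inheritParams fit_eps0
#' @return Data frame with columns `ionic_strength_M`, `eps_K`, `eps_se_K`,
#'   `t_cloud_K`, `converged`, `message`.
#' @export
fit_epsilon_series <- function(series, model, bracket = c(500, 5000),
                               tol = 1e-3) {
  stopifnot(inherits(series, "cloud_point_series"),
            inherits(model, "protein_model"))
  obs <- series$observations
  if (nrow(obs) == 0)
    return(data.frame(ionic_strength_M = numeric(0), eps_K = numeric(0),
                      eps_se_K = numeric(0), t_cloud_K = numeric(0),
                      converged = logical(0), message = character(0)))
  out <- data.frame(ionic_strength_M = obs$ionic_strength_M,
                    eps_K = NA_real_, eps_se_K = NA_real_,
                    t_cloud_K = obs$t_cloud_K,
                    converged = logical(nrow(obs)),
                    message = character(nrow(obs)))
  for (i in seq_len(nrow(obs))) {
    st <- if (is.na(obs$sigma_t_K[i])) NULL else obs$sigma_t_K[i]
    res <- tryCatch(
      fit_eps0(model, series$gamma, obs$t_cloud_K[i], bracket = bracket,
               tol = tol, sigma_t = st),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$message[i] <- conditionMessage(res)
    } else {
      out$eps_K[i] <- as.numeric(res)
      out$eps_se_K[i] <- attr(res, "se")
      out$converged[i] <- TRUE
      out$message[i] <- "ok"
    }
  }
  out
}

#' Fit the salt law eps(I) = eps0 + a*sqrt(I)
#'
#' Least-squares regression of per-salt well depths against the square root
#' of ionic strength: the intercept is the zero-salt depth eps0, the slope
#' the salt coefficient a. Points are weighted by inverse variance when
#' standard errors are supplied for all of them, otherwise unweighted.
#'
#' @param eps_points Data frame with columns `ionic_strength_M`, `eps_K` and
#'   optionally `eps_se_K` (as produced by [fit_epsilon_series()], possibly
#'   pooled over protein concentrations). Rows with missing `eps_K` are
#'   dropped.
#' @param name Buffer label attached to the fitted [buffer_interaction()].
#' @return Object of class `salt_fit`: list with `eps0`, `eps0_se`,
#'   `salt_coeff`, `salt_coeff_se` (K and K L^1/2 mol^-1/2), `pearson_r`,
#'   `weighted`, `n`, `covariance` and `buffer` (the fitted
#'   [buffer_interaction()]).
#' @export
fit_salt_coefficients <- function(eps_points, name = "fitted") {
  stopifnot(is.data.frame(eps_points),
            all(c("ionic_strength_M", "eps_K") %in% names(eps_points)))
  pts <- eps_points[is.finite(eps_points$eps_K), , drop = FALSE]
  if (length(unique(pts$ionic_strength_M)) < 2)
    stop("need >= 2 distinct ionic strengths to fit eps0 and a")
  x <- sqrt(pts$ionic_strength_M)
  w <- NULL
  if ("eps_se_K" %in% names(pts) && all(is.finite(pts$eps_se_K)) &&
      all(pts$eps_se_K > 0)) w <- 1 / pts$eps_se_K^2
  fit <- if (is.null(w)) stats::lm(pts$eps_K ~ x)
  else stats::lm(pts$eps_K ~ x, weights = w)
  cf <- suppressWarnings(summary(fit)$coefficients)
  # two points fit exactly: lm then reports NaN standard errors
  eps0 <- cf[1, 1]; a <- cf[2, 1]
  structure(
    list(eps0 = eps0, eps0_se = cf[1, 2],
         salt_coeff = a, salt_coeff_se = cf[2, 2],
         pearson_r = stats::cor(x, pts$eps_K),
         weighted = !is.null(w), n = nrow(pts),
         covariance = suppressWarnings(stats::vcov(fit)),
         buffer = buffer_interaction(
           name, eps0 = eps0, salt_coeff = a,
           metadata = list(eps0_se = cf[1, 2], salt_coeff_se = cf[2, 2]))),
    class = "salt_fit")
}

#' @export
print.salt_fit <- function(x, ...) {
  cat(sprintf("Salt-law fit eps(I) = eps0 + a*sqrt(I)  [%s, n = %d%s]\n",
              x$buffer$name, x$n, if (x$weighted) ", weighted" else ""))
  cat(sprintf("  eps0 = %.5g +/- %.2g K\n", x$eps0, x$eps0_se))
  cat(sprintf("  a    = %.5g +/- %.2g K L^1/2 mol^-1/2\n",
              x$salt_coeff, x$salt_coeff_se))
  invisible(x)
}

#' Extrapolate measured cloud points to zero added salt
#'
#' Least-squares extrapolation of cloud-point temperatures measured at
#' several salt concentrations down to zero salt. The regression basis is
#' linear in the salt concentration by default; a square-root basis is
#' available and the choice is recorded in the result.
#'
#' @param salt_conc Salt concentrations in mol/L (>= 2 points).
#' @param t_cloud Cloud-point temperatures in K.
#' @param basis `"linear"` (regress on c) or `"sqrt"` (regress on sqrt(c)).
#' @return List with `t_cloud_0` (K), `se` (K), `basis`, `slope` and `n`.
#' @export
extrapolate_tcloud_zero_salt <- function(salt_conc, t_cloud,
                                         basis = c("linear", "sqrt")) {
  basis <- match.arg(basis)
  stopifnot(length(salt_conc) == length(t_cloud))
  if (length(salt_conc) < 2) stop("need >= 2 points to extrapolate")
  x <- if (basis == "linear") salt_conc else sqrt(salt_conc)
  fit <- stats::lm(t_cloud ~ x)
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(t_cloud_0 = cf[1, 1], se = cf[1, 2], basis = basis,
       slope = cf[2, 1], n = length(salt_conc))
}

#' Ordinary least-squares linear correlation
#'
#' Slope, intercept, their standard errors and the Pearson correlation
#' coefficient for a pair of equal-length numeric vectors.
#'
#' @param xs,ys Numeric vectors of equal length >= 2; `xs` must not be
#'   constant.
#' @return Object of class `linear_fit`: list with `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `pearson_r`, `n`.
#' @export
linear_correlation <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  if (length(xs) < 2) stop("need >= 2 points")
  if (stats::sd(xs) == 0) stop("`xs` has zero variance")
  fit <- stats::lm(ys ~ xs)
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(
    list(slope = cf[2, 1], intercept = cf[1, 1],
         slope_se = cf[2, 2], intercept_se = cf[1, 2],
         pearson_r = stats::cor(xs, ys), n = length(xs)),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.5g + %.5g x, r = %.4f\n",
              x$n, x$intercept, x$slope, x$pearson_r))
  cat(sprintf("  SE(intercept) = %.3g, SE(slope) = %.3g\n",
              x$intercept_se, x$slope_se))
  invisible(x)
}
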