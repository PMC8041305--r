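# TPT1 state functions for the patchy hard-sphere protein model.
#
# Conventions used throughout:
#   * all energies are carried as eps/kB in kelvin, so beta*eps = eps/T;
#   * densities are number densities rho in nm^-3 (see number_density());
#   * the ideal term uses a fixed thermal wavelength Lambda = 1 nm -- it shifts
#     the chemical potential by a state-independent constant that cancels in
#     every coexistence condition;
#   * the hard-sphere free energy is Carnahan-Starling, while the contact value
#     inside the association integral is the Percus-Yevick one.

#' Hard-sphere packing fraction
#'
#' `eta = pi * rho * sigma^3 / 6`.
#'
#' @param rho Number density in nm^-3 (vectorised, >= 0).
#' @param sigma Hard-sphere diameter in nm.
#' @return Packing fraction (dimensionless). Densities at or beyond the
#'   close-packing limit `eta >= 0.74` are rejected.
#' @export
packing_fraction <- function(rho, sigma) {
  if (any(rho < 0)) stop("`rho` must be non-negative")
  if (sigma <= 0) stop("`sigma` must be positive")
  eta <- pi * rho * sigma^3 / 6
  if (any(eta >= 0.74))
    stop("packing fraction >= 0.74: density beyond close packing")
  eta
}

#' Percus-Yevick hard-sphere contact value
#'
#' Contact value of the hard-sphere radial distribution function from the
#' Ornstein-Zernike equation with the PY closure,
#' `g_hs(sigma) = (1 + eta/2) / (1 - eta)^2`.
#'
#' @param eta Packing fraction in `[0, 1)` (vectorised).
#' @return `g_hs(sigma)`; equals 1 at `eta = 0` and increases with `eta`.
#' @export
ghs_contact <- function(eta) {
  if (any(eta < 0 | eta >= 1)) stop("`eta` must lie in [0, 1)")
  (1 + eta / 2) / (1 - eta)^2
}

# Sticky-limit bond volume for sites at d = sigma/2 with site-site range omega:
# 4*pi * integral_sigma^{sigma+omega} p(r) r^2 dr with p(r) the orientational
# bonding probability, which evaluates to pi*omega^4*(15*sigma+4*omega)/(30*sigma^2).
.bond_volume <- function(model) {
  s <- model$sigma; w <- model$omega
  pi * w^4 * (15 * s + 4 * w) / (30 * s^2)
}

#' Angular average of the site-site Mayer function
#'
#' For one site pair (A on molecule 1, B on molecule 2), both sites on the
#' sphere surface at `d = sigma/2`, the average over independent uniform
#' orientations of the Mayer function of the square well is
#' `f_ass(r) = (e^{eps/T} - 1) * (omega + sigma - r)^2 (2*omega + r - sigma) / (6 r sigma^2)`
#' for `sigma <= r <= sigma + omega`, and 0 beyond (the sites cannot reach).
#'
#' @param r Centre-centre distance in nm (vectorised, must be `>= sigma`).
#' @param temperature Temperature in K.
#' @param eps Well depth in K (eps/kB).
#' @param model A [protein_model()].
#' @return Dimensionless angular-averaged Mayer function, `>= 0`.
#' @export
mayer_angular_average <- function(r, temperature, eps, model) {
  stopifnot(inherits(model, "protein_model"), temperature > 0)
  s <- model$sigma; w <- model$omega
  if (any(r < s)) stop("`r` must be >= sigma (hard core)")
  p <- ifelse(r <= s + w,
              (w + s - r)^2 * (2 * w + r - s) / (6 * r * s^2),
              0)
  expm1(eps / temperature) * p
}

#' Pair energy of one configuration of two patchy spheres
#'
#' Evaluates `u/kB` for two molecules at centre-centre distance `r` with given
#' site orientations: `+Inf` for hard-sphere overlap (`r < sigma`), otherwise
#' `-eps` per bonded site pair. A site pair bonds when the site-site distance
#' is within `omega`; the single-bond rule allows each site at most one
#' partner (closest pairs bond first). This explicit configurational energy
#' backs the Monte-Carlo orientation-averaging oracle for
#' [mayer_angular_average()].
#'
#' @param r Centre-centre distance in nm (scalar).
#' @param orientations1,orientations2 Matrices with one unit row vector per
#'   site (n_sites x 3), giving the site directions on molecules 1 and 2.
#' @param model A [protein_model()].
#' @param eps Well depth in K.
#' @return Energy in K: `+Inf`, 0, or a negative multiple of `eps`.
#' @export
pair_config_energy <- function(r, orientations1, orientations2, model, eps) {
  stopifnot(inherits(model, "protein_model"), length(r) == 1, r > 0)
  if (r < model$sigma) return(Inf)
  d <- model$site_distance
  p1 <- d * as.matrix(orientations1)
  p2 <- sweep(d * as.matrix(orientations2), 2, c(-r, 0, 0))  # centre 2 at (r,0,0)
  # pairwise squared distances between sites on molecule 1 and molecule 2
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * tcrossprod(p1, p2)
  inrange <- which(d2 <= model$omega^2, arr.ind = TRUE)
  if (nrow(inrange) == 0L) return(0)
  # single-bond rule: greedily match closest pairs, each site bonds once
  ord <- order(d2[inrange])
  used1 <- logical(nrow(p1)); used2 <- logical(nrow(p2)); nb <- 0L
  for (k in ord) {
    i <- inrange[k, 1]; j <- inrange[k, 2]
    if (!used1[i] && !used2[j]) { used1[i] <- TRUE; used2[j] <- TRUE; nb <- nb + 1L }
  }
  -eps * nb
}

#' Sticky-limit association strength
#'
#' The association integral for one site pair evaluated in the sticky limit:
#' the hard-sphere contact value (PY) times the radial integral of the
#' angular-averaged Mayer function,
#' `Delta_AB = g_hs(sigma) * (e^{eps/T} - 1) * v_b`, with bond volume
#' `v_b = pi*omega^4*(15*sigma + 4*omega)/(30*sigma^2)` nm^3.
#'
#' @param temperature Temperature in K.
#' @param eta Packing fraction (vectorised).
#' @param model A [protein_model()].
#' @param eps Well depth in K.
#' @return `Delta_AB` in nm^3; zero when `eps = 0`, increasing in `eps` and
#'   `eta`.
#' @export
association_strength <- function(temperature, eta, model, eps) {
  stopifnot(inherits(model, "protein_model"), temperature > 0)
  ghs_contact(eta) * expm1(eps / temperature) * .bond_volume(model)
}

#' Monomer fraction from the mass-action law
#'
#' For M equivalent sites the fraction X of sites not bonded solves
#' `X + M * rho * Delta * X^2 = 1`. The root in `(0, 1]` has the closed form
#' `X = 2 / (1 + sqrt(1 + 4 * M * rho * Delta))` (numerically stable at
#' `Delta -> 0`).
#'
#' @param rho Number density in nm^-3 (vectorised, >= 0).
#' @param delta Association strength `Delta_AB` in nm^3 (>= 0).
#' @param n_sites Number of equivalent sites M.
#' @return Monomer fraction `X` in `(0, 1]`.
#' @export
monomer_fraction <- function(rho, delta, n_sites) {
  if (any(rho < 0)) stop("`rho` must be non-negative")
  if (any(delta < 0)) stop("`delta` must be non-negative")
  cc <- n_sites * rho * delta
  2 / (1 + sqrt(1 + 4 * cc))
}

# One full state evaluation; every public thermodynamic function funnels
# through here. Vectorised over rho.
.state <- function(rho, temperature, model, eps) {
  eta <- packing_fraction(rho, model$sigma)
  M <- model$n_sites
  delta <- association_strength(temperature, eta, model, eps)
  X <- monomer_fraction(rho, delta, M)
  G <- eta * (1 / (2 + eta) + 2 / (1 - eta))   # eta * dln g_hs/deta (PY)
  a_id <- ifelse(rho > 0, log(rho) - 1, -Inf)  # Lambda = 1 nm
  a_hs <- eta * (4 - 3 * eta) / (1 - eta)^2    # Carnahan-Starling
  a_ass <- M * (log(X) - X / 2 + 0.5)
  bpi <- rho * (1 + eta * (4 - 2 * eta) / (1 - eta)^3) -
    (M / 2) * rho * (1 - X) * (1 + G)
  list(rho = rho, eta = eta, delta = delta, X = X, G = G,
       a_id = a_id, a_hs = a_hs, a_ass = a_ass,
       a_total = a_id + a_hs + a_ass,
       bpi = bpi)
}

#' Helmholtz free energy per particle
#'
#' Evaluates the additive TPT1 free energy `beta*A/N = beta*A_id/N +
#' beta*A_hs/N + beta*A_ass/N` with the association part
#' `M (ln X - X/2 + 1/2)` at the mass-action monomer fraction X.
#'
#' @param rho Number density in nm^-3 (scalar or vector).
#' @param temperature Temperature in K.
#' @param model A [protein_model()].
#' @param eps Well depth in K.
#' @return An object of class `thermo_evaluation`: a list with
#'   `monomer_fraction`, `beta_a_ideal`, `beta_a_hs`, `beta_a_assoc`,
#'   `beta_a` (their sum), `beta_pressure` (nm^-3) and `beta_mu`
#'   (dimensionless, satisfies `beta_mu = beta_a + beta_pi/rho` identically).
#' @export
free_energy <- function(rho, temperature, model, eps) {
  stopifnot(inherits(model, "protein_model"), temperature > 0, eps >= 0)
  st <- .state(rho, temperature, model, eps)
  structure(
    list(rho = rho, temperature = temperature, eps = eps,
         eta = st$eta,
         monomer_fraction = st$X,
         beta_a_ideal = st$a_id,
         beta_a_hs = st$a_hs,
         beta_a_assoc = st$a_ass,
         beta_a = st$a_total,
         beta_pressure = st$bpi,
         beta_mu = st$a_total + st$bpi / rho),
    class = "thermo_evaluation")
}

#' @export
print.thermo_evaluation <- function(x, ...) {
  cat("TPT1 state evaluation\n")
  cat(sprintf("  rho = %.6g nm^-3 (eta = %.4g), T = %.6g K, eps = %.6g K\n",
              x$rho[1], x$eta[1], x$temperature, x$eps))
  cat(sprintf("  X = %.6g   beta*A/N = %.6g (id %.4g, hs %.4g, ass %.4g)\n",
              x$monomer_fraction[1], x$beta_a[1], x$beta_a_ideal[1],
              x$beta_a_hs[1], x$beta_a_assoc[1]))
  cat(sprintf("  beta*Pi = %.6g nm^-3   beta*mu = %.6g\n",
              x$beta_pressure[1], x$beta_mu[1]))
  invisible(x)
}

#' Osmotic pressure and chemical potential
#'
#' `beta*Pi = rho^2 d(beta*A/N)/drho` and `beta*mu = beta*A/N + beta*Pi/rho`,
#' both from analytic differentiation of the TPT1 free energy (the
#' association part uses the closed-form monomer fraction, so no numerical
#' derivative is involved). The two satisfy the Gibbs-Duhem identity
#' exactly.
#'
#' @inheritParams free_energy
#' @return Numeric vector: `beta*Pi` in nm^-3, or `beta*mu` dimensionless.
#' @export
osmotic_pressure <- function(rho, temperature, model, eps) {
  stopifnot(inherits(model, "protein_model"), temperature > 0, eps >= 0)
  .state(rho, temperature, model, eps)$bpi
}

#' @rdname osmotic_pressure
#' @export
chemical_potential <- function(rho, temperature, model, eps) {
  stopifnot(inherits(model, "protein_model"), temperature > 0, eps >= 0)
  if (any(rho <= 0)) stop("`rho` must be positive for the chemical potential")
  st <- .state(rho, temperature, model, eps)
  st$a_total + st$bpi / rho
}

# Analytic d(beta*Pi)/drho (dimensionless). Obtained by differentiating the
# closed-form beta*Pi; cross-checked against finite differences and the
# symbolic derivative .p2_sym in the test suite.
.dbpi_drho <- function(rho, temperature, model, eps) {
  st <- .state(rho, temperature, model, eps)
  eta <- st$eta; X <- st$X; G <- st$G
  M <- model$n_sites
  cc <- M * rho * st$delta
  Gp <- 2 / (2 + eta)^2 + 2 / (1 - eta)^2
  p1_hs <- 1 + 2 * eta * (4 - eta) / (1 - eta)^4
  p1_ass <- -(M / 2) * ((1 - X) * (1 + G) +
                          X^3 * cc * (1 + G)^2 / (2 - X) +
                          (1 - X) * eta * Gp)
  p1_hs + p1_ass
}

# Symbolic derivatives of k*beta*Pi as a function of eta (k = pi*sigma^3/6):
# used for the curvature condition at the critical point. `cc` below is
# M*v_b*(e^{eps/T}-1)/k so that M*rho*Delta = cc*eta*g_hs(eta).
.bpik_expr <- quote(
  eta + eta^2 * (4 - 2 * eta) / (1 - eta)^3 -
    (M / 2) * eta *
      (1 - 2 / (1 + sqrt(1 + 4 * cc * eta * (1 + eta / 2) / (1 - eta)^2))) *
      (1 + eta * (1 / (2 + eta) + 2 / (1 - eta)))
)
.bpik_d1 <- stats::D(.bpik_expr, "eta")
.bpik_d2 <- stats::D(.bpik_d1, "eta")

# d2(beta*Pi)/drho2 (units nm^3), via the symbolic second derivative in eta.
.d2bpi_drho2 <- function(rho, temperature, model, eps) {
  k <- pi * model$sigma^3 / 6
  env <- list(eta = k * rho, M = model$n_sites,
              cc = model$n_sites * .bond_volume(model) *
                expm1(eps / temperature) / k)
  k * eval(.bpik_d2, env)
}

#' Second virial coefficient of the patchy-sphere model
#'
#' Low-density limit of the osmotic pressure:
#' `B2 = B2_hs - (M^2/2) (e^{eps/T} - 1) v_b` with the hard-sphere part
#' `B2_hs = 2*pi*sigma^3/3` and the sticky-limit bond volume `v_b`. The
#' experimental unit conversion is `B22 = B2 * N_A / M2^2` (nm^3 -> mL).
#'
#' @param temperature Temperature in K.
#' @param model A [protein_model()].
#' @param eps Well depth in K.
#' @return List with `B2_nm3`, `B2_hs_nm3` and `B22_mol_mL_g2`.
#' @export
second_virial <- function(temperature, model, eps) {
  stopifnot(inherits(model, "protein_model"), temperature > 0, eps >= 0)
  b2_hs <- 2 * pi * model$sigma^3 / 3
  b2 <- b2_hs - model$n_sites^2 / 2 * expm1(eps / temperature) * .bond_volume(model)
  list(B2_nm3 = b2, B2_hs_nm3 = b2_hs,
       B22_mol_mL_g2 = b2 * .const$mL_per_nm3 * .const$avogadro /
         model$molar_mass^2)
}
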