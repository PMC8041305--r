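# Independent oracles: brute-force or closed-form routes used to check the
# package implementation. Deliberately written against definitions, not
# against the package's internal code paths.

table2_model <- function() protein_model(sigma = 3.43, omega = 0.18,
                                         n_sites = 10, molar_mass = 14300)

# Monte-Carlo angular average of exp(-beta*u_AB) - 1 for one site pair: both
# site directions uniform on the sphere, u_AB = -eps when the site-site
# distance is within omega (the square-well site potential), else 0.
mc_mayer <- function(r, temperature, eps, model, n = 1e6, seed = 1) {
  set.seed(seed)
  d <- model$site_distance
  u1 <- matrix(stats::rnorm(3 * n), ncol = 3)
  u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- matrix(stats::rnorm(3 * n), ncol = 3)
  u2 <- u2 / sqrt(rowSums(u2^2))
  p1 <- d * u1
  p2 <- d * u2
  p2[, 1] <- p2[, 1] + r
  ind <- rowSums((p2 - p1)^2) <= model$omega^2
  fac <- expm1(eps / temperature)
  list(mean = fac * mean(ind), se = fac * stats::sd(ind) / sqrt(n))
}

# association integral by adaptive quadrature of the angular-averaged Mayer
# function (sticky limit: contact value outside the radial integral)
quad_delta <- function(temperature, eta, model, eps) {
  integ <- stats::integrate(function(r)
    mayer_angular_average(r, temperature, eps, model) * r^2,
    lower = model$sigma, upper = model$sigma + model$omega,
    rel.tol = 1e-11, abs.tol = 0)
  4 * pi * ghs_contact(eta) * integ$value
}

# monomer fraction by bisection of the mass-action law
bisect_X <- function(rho, delta, M) {
  stats::uniroot(function(X) X + M * rho * delta * X^2 - 1,
                 c(1e-14, 1), tol = 1e-15)$root
}

beta_a_of <- function(rho, temperature, model, eps)
  free_energy(rho, temperature, model, eps)$beta_a

# central-difference osmotic pressure and chemical potential from beta*A/N
fd_pressure <- function(rho, temperature, model, eps, h = rho * 1e-5) {
  da <- (beta_a_of(rho + h, temperature, model, eps) -
           beta_a_of(rho - h, temperature, model, eps)) / (2 * h)
  rho^2 * da
}
fd_mu <- function(rho, temperature, model, eps, h = rho * 1e-5) {
  fv <- function(r) r * beta_a_of(r, temperature, model, eps)  # beta*A/V
  (fv(rho + h) - fv(rho - h)) / (2 * h)
}

# Andrew monotone-chain lower convex hull (x sorted increasing)
.oracle_lower_hull <- function(x, y) {
  n <- length(x)
  idx <- integer(n); m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      i1 <- idx[m - 1L]; i2 <- idx[m]
      if ((x[i2] - x[i1]) * (y[i] - y[i1]) -
          (y[i2] - y[i1]) * (x[i] - x[i1]) <= 0) m <- m - 1L else break
    }
    m <- m + 1L; idx[m] <- i
  }
  idx[seq_len(m)]
}

# Common-tangent (double-tangent) construction on beta*A/V versus rho over a
# dense grid, with local refinement of the tangent-segment endpoints. Grid
# route to coexistence, fully independent of the Newton solver.
ct_oracle <- function(temperature, model, eps, n_coarse = 10000,
                      n_fine = 4000) {
  rmax <- 0.55 / (pi * model$sigma^3 / 6)
  grid <- exp(seq(log(1e-9), log(rmax), length.out = n_coarse))
  fv <- grid * beta_a_of(grid, temperature, model, eps)
  hull <- .oracle_lower_hull(grid, fv)
  jump <- which.max(grid[hull[-1]] - grid[hull[-length(hull)]])
  i <- hull[jump]; j <- hull[jump + 1L]
  if (j == i + 1L) return(NULL)   # no skipped grid points: single phase
  refine <- function(k) seq(grid[max(k - 1L, 1L)],
                            grid[min(k + 1L, n_coarse)],
                            length.out = n_fine)
  pts <- c(refine(i), refine(j))
  fv2 <- pts * beta_a_of(pts, temperature, model, eps)
  hull2 <- .oracle_lower_hull(pts, fv2)
  jump2 <- which.max(pts[hull2[-1]] - pts[hull2[-length(hull2)]])
  c(pts[hull2[jump2]], pts[hull2[jump2 + 1L]])
}

# random unit vectors as an n x 3 matrix
runit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}
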