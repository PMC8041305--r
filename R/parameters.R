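# Parameter objects: the coarse-grained protein geometry and the per-buffer
# energetics, plus their JSON (de)serialisation.

#' Coarse-grained patchy-sphere protein model
#'
#' A globular protein is represented as a hard sphere of diameter `sigma`
#' carrying `n_sites` equivalent short-range square-well attraction sites on
#' its surface. Sites sit at distance `d = sigma/2` from the centre (on the
#' surface); two sites on different molecules interact with well depth
#' `-eps` whenever their separation is within the well range `omega`.
#'
#' @param sigma Hard-sphere diameter in nm.
#' @param omega Square-well range in nm; must satisfy `0 < omega < sigma`.
#' @param n_sites Number of equivalent attraction sites M (integer >= 1).
#' @param molar_mass Protein molar mass M2 in g/mol.
#' @return An object of class `protein_model` with fields `sigma`, `omega`,
#'   `n_sites`, `molar_mass` and the derived `site_distance = sigma/2`.
#' @examples
#' hewl_model()
#' protein_model(sigma = 3.43, omega = 0.18, n_sites = 10, molar_mass = 14300)
#' @export
protein_model <- function(sigma, omega, n_sites, molar_mass) {
  stopifnot(length(sigma) == 1, length(omega) == 1,
            length(n_sites) == 1, length(molar_mass) == 1)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive (nm)")
  if (!is.finite(omega) || omega <= 0 || omega >= sigma)
    stop("`omega` must satisfy 0 < omega < sigma (nm)")
  if (n_sites < 1 || n_sites != round(n_sites))
    stop("`n_sites` must be a positive integer")
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("`molar_mass` must be positive (g/mol)")
  structure(
    list(sigma = as.numeric(sigma), omega = as.numeric(omega),
         n_sites = as.integer(n_sites), molar_mass = as.numeric(molar_mass),
         site_distance = as.numeric(sigma) / 2),
    class = "protein_model"
  )
}

#' @export
print.protein_model <- function(x, ...) {
  cat("Patchy hard-sphere protein model\n")
  cat(sprintf("  sigma      : %.4g nm (site distance d = %.4g nm)\n",
              x$sigma, x$site_distance))
  cat(sprintf("  omega      : %.4g nm (square-well range)\n", x$omega))
  cat(sprintf("  n_sites    : %d equivalent sites\n", x$n_sites))
  cat(sprintf("  molar mass : %.5g g/mol\n", x$molar_mass))
  invisible(x)
}

#' Hen egg-white lysozyme model geometry
#'
#' The packaged HEWL parameter set: sigma = 3.43 nm (from the solvent-excluded
#' surface volume of the crystal structure), omega = 0.18 nm, M = 10 sites,
#' M2 = 14300 g/mol.
#'
#' @return A [protein_model()].
#' @export
hewl_model <- function() {
  read_protein_model(system.file("extdata", "hewl_model.json",
                                 package = "patchyllps", mustWork = TRUE))
}

#' Buffer-specific interaction parameters
#'
#' Per-buffer energetics of the patchy-sphere model: the square-well depth at
#' zero added salt, `eps0` (in kelvin, i.e. eps0/kB), and the salt coefficient
#' `a` (K L^1/2 mol^-1/2) of the ionic-strength law
#' `eps(I) = eps0 + a * sqrt(I)`. Optionally carries the buffer's Jones-Dole
#' viscosity B coefficient and other measured metadata.
#'
#' @param name Buffer label, e.g. `"phosphate"`.
#' @param eps0 Zero-salt well depth, K (must be positive).
#' @param salt_coeff Salt coefficient a, K L^1/2 mol^-1/2 (finite).
#' @param jones_dole_B Optional Jones-Dole B coefficient, L/mol.
#' @param metadata Optional named list of auxiliary measured values
#'   (uncertainties, kD, B22, ...).
#' @return An object of class `buffer_interaction`.
#' @examples
#' buffer_interaction("phosphate", eps0 = 2250, salt_coeff = 500)
#' @export
buffer_interaction <- function(name, eps0, salt_coeff, jones_dole_B = NULL,
                               metadata = list()) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(eps0) || eps0 <= 0) stop("`eps0` must be positive (K)")
  if (!is.finite(salt_coeff)) stop("`salt_coeff` must be finite")
  if (!is.null(jones_dole_B)) stopifnot(is.finite(jones_dole_B))
  structure(
    list(name = name, eps0 = as.numeric(eps0),
         salt_coeff = as.numeric(salt_coeff),
         jones_dole_B = if (is.null(jones_dole_B)) NULL else as.numeric(jones_dole_B),
         metadata = metadata),
    class = "buffer_interaction"
  )
}

#' @export
print.buffer_interaction <- function(x, ...) {
  cat(sprintf("Buffer interaction: %s\n", x$name))
  cat(sprintf("  eps0       : %.5g K\n", x$eps0))
  cat(sprintf("  salt coeff : %.5g K L^1/2 mol^-1/2\n", x$salt_coeff))
  if (!is.null(x$jones_dole_B))
    cat(sprintf("  Jones-Dole B: %.3g L/mol\n", x$jones_dole_B))
  invisible(x)
}

#' Square-well depth at a given ionic strength
#'
#' Salt dependence of the protein-protein attraction:
#' `eps(I) = eps0 + a * sqrt(I)`. With a > 0 added salt deepens the effective
#' attraction (salting out), raising the cloud-point temperature.
#'
#' @param buffer A [buffer_interaction()].
#' @param ionic_strength Ionic strength I in mol/L (vectorised, >= 0).
#' @return Well depth eps in K.
#' @export
epsilon_at_ionic_strength <- function(buffer, ionic_strength) {
  stopifnot(inherits(buffer, "buffer_interaction"))
  if (any(ionic_strength < 0)) stop("`ionic_strength` must be non-negative")
  buffer$eps0 + buffer$salt_coeff * sqrt(ionic_strength)
}

## ---- JSON parameter files ------------------------------------------------

.PARAM_SCHEMA <- "patchyllps-parameters/1"

#' Read / write model and buffer parameter files
#'
#' Parameter objects round-trip through small JSON files carrying a schema
#' tag. Field names match the constructor arguments exactly.
#'
#' @param path File path.
#' @param x Object to serialise.
#' @return `read_*` return the parameter object; `write_*` return `path`
#'   invisibly.
#' @name parameter_io
NULL

#' @rdname parameter_io
#' @export
read_protein_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  protein_model(sigma = obj$sigma, omega = obj$omega,
                n_sites = obj$n_sites, molar_mass = obj$molar_mass)
}

#' @rdname parameter_io
#' @export
write_protein_model <- function(x, path) {
  stopifnot(inherits(x, "protein_model"))
  jsonlite::write_json(
    list(schema = .PARAM_SCHEMA, type = "protein_model",
         sigma = x$sigma, omega = x$omega, n_sites = x$n_sites,
         molar_mass = x$molar_mass, site_distance = x$site_distance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname parameter_io
#' @export
read_buffer_interaction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  buffer_interaction(name = obj$name, eps0 = obj$eps0,
                     salt_coeff = obj$salt_coeff,
                     jones_dole_B = obj$jones_dole_B,
                     metadata = if (is.null(obj$metadata)) list() else as.list(obj$metadata))
}

#' @rdname parameter_io
#' @export
write_buffer_interaction <- function(x, path) {
  stopifnot(inherits(x, "buffer_interaction"))
  jsonlite::write_json(
    list(schema = .PARAM_SCHEMA, type = "buffer_interaction", name = x$name,
         eps0 = x$eps0, salt_coeff = x$salt_coeff,
         jones_dole_B = x$jones_dole_B, metadata = x$metadata),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Packaged buffer parameter sets
#'
#' The four 0.1 M pH 7.0 buffers studied for HEWL, with their fitted
#' zero-salt well depths eps0, NaBr salt coefficients a, and measured
#' metadata (kD, B22, Jones-Dole B at 5 and 25 degrees C, with printed
#' uncertainties).
#'
#' @return Named list of [buffer_interaction()] objects
#'   (phosphate, HEPES, MOPS, cacodylate).
#' @examples
#' buffer_fixtures()$phosphate
#' @export
buffer_fixtures <- function() {
  path <- system.file("extdata", "buffers.json", package = "patchyllps",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw$buffers, function(b) {
    buffer_interaction(name = b$name, eps0 = b$eps0, salt_coeff = b$salt_coeff,
                       jones_dole_B = b$metadata$jones_dole_B_25C,
                       metadata = b$metadata)
  })
  names(out) <- vapply(out, function(b) b$name, character(1))
  out
}
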