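# Typed CSV readers/writers for the four measurement streams. Dialect:
# comma-separated, '.' decimal, UTF-8, '#'-prefixed "key: value" metadata
# lines before the header. Numeric values are written with 17 significant
# digits so write -> read round-trips exactly.

.SCHEMAS <- list(
  cloudpoint = list(required = c("buffer", "gamma_mg_ml", "ionic_strength_M",
                                 "t_cloud_K"),
                    optional = "sigma_t_K"),
  dls        = list(required = c("gamma_mg_ml", "D_m2_s"), optional = character()),
  sls        = list(required = "conc_g_ml",
                    optional = c("mcr_cps", "kc_over_r")),
  viscosity  = list(required = "conc_M",
                    optional = c("eta_rel", "flow_s", "density_g_cm3"))
)

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_csv_with_meta <- function(df, path, meta = list()) {
  lines <- character(0)
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v) || length(v) == 0) next
    lines <- c(lines, sprintf("# %s: %s", k,
                              paste(vapply(v, function(z)
                                if (is.numeric(z)) sprintf("%.17g", z)
                                else as.character(z), character(1)),
                                collapse = " ")))
  }
  lines <- c(lines, paste(names(df), collapse = ","))
  if (nrow(df)) {
    cols <- lapply(df, function(v) {
      out <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      out[is.na(v)] <- ""
      out
    })
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.read_csv_with_meta <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) == 0) stop("file has no header line: ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(data = df, meta = meta)
}

.check_schema <- function(df, schema_name, path) {
  sc <- .SCHEMAS[[schema_name]]
  have <- names(df)
  missing <- setdiff(sc$required, have)
  extra <- setdiff(have, c(sc$required, sc$optional))
  if (length(missing) || length(extra))
    stop(sprintf(
      "schema '%s' mismatch in %s: expected columns {%s}%s%s",
      schema_name, path,
      paste(c(sc$required, paste0("[", sc$optional, "]")), collapse = ", "),
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else ""))
  num_cols <- setdiff(have, "buffer")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & nzchar(v))
      stop(sprintf("non-numeric values in column '%s' of %s (rows %s)",
                   cl, path, paste(bad, collapse = ", ")))
    }
  }
  invisible(df)
}

#' Read a typed measurement table
#'
#' Parses one of the package's CSV schemas into the corresponding series
#' object. Metadata lines (`# key: value`) supply auxiliary quantities such
#' as the toluene reference count rate or the viscometry water reference.
#'
#' @param path CSV file path.
#' @param schema One of `"cloudpoint"`, `"dls"`, `"sls"`, `"viscosity"`.
#' @return A [cloud_point_series()], [dls_series()], [sls_series()] or
#'   [viscosity_series()]. An empty data section yields a typed empty
#'   series.
#' @export
read_measurement_table <- function(path, schema = c("cloudpoint", "dls",
                                                    "sls", "viscosity")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .read_csv_with_meta(path)
  df <- .check_schema(parsed$data, schema, path)
  meta <- parsed$meta
  switch(schema,
    cloudpoint = {
      if (nrow(df) == 0) {
        return(structure(list(
          buffer_name = if (!is.null(meta$buffer)) as.character(meta$buffer) else "",
          gamma = if (!is.null(meta$gamma_mg_ml)) meta$gamma_mg_ml else NA_real_,
          observations = data.frame(ionic_strength_M = numeric(0),
                                    t_cloud_K = numeric(0),
                                    sigma_t_K = numeric(0))),
          class = "cloud_point_series"))
      }
      if (length(unique(df$buffer)) != 1 || length(unique(df$gamma_mg_ml)) != 1)
        stop("cloudpoint file must contain a single buffer and concentration")
      st <- if ("sigma_t_K" %in% names(df) && all(is.finite(df$sigma_t_K)))
        df$sigma_t_K else NULL
      cloud_point_series(df$buffer[1], df$gamma_mg_ml[1],
                         df$ionic_strength_M, df$t_cloud_K, sigma_t = st)
    },
    dls = {
      if (nrow(df) == 0)
        return(structure(list(points = df, temperature = 298.15,
                              solvent_viscosity_mPas = 0.89),
                         class = "dls_series"))
      dls_series(df$gamma_mg_ml, df$D_m2_s,
                 temperature = if (!is.null(meta$temperature_K))
                   meta$temperature_K else 298.15,
                 solvent_viscosity_mPas = if (!is.null(meta$solvent_viscosity_mPas))
                   meta$solvent_viscosity_mPas else 0.8900)
    },
    sls = {
      if (!any(c("mcr_cps", "kc_over_r") %in% names(df)))
        stop("sls file needs an 'mcr_cps' or 'kc_over_r' column")
      if (nrow(df) == 0)
        return(structure(list(points = df, raw = "mcr_cps" %in% names(df),
                              laser_intensity = 1, toluene_count_rate = NULL,
                              config = sls_config()),
                         class = "sls_series"))
      cfg <- sls_config(
        wavelength_nm = if (!is.null(meta$wavelength_nm)) meta$wavelength_nm else 632.8,
        refractive_index = if (!is.null(meta$refractive_index)) meta$refractive_index else 1.332,
        dn_dc_mL_g = if (!is.null(meta$dn_dc_mL_g)) meta$dn_dc_mL_g else 0.185,
        rayleigh_toluene_cm = if (!is.null(meta$rayleigh_toluene_cm))
          meta$rayleigh_toluene_cm else 14.0e-6)
      if ("mcr_cps" %in% names(df))
        sls_series(df$conc_g_ml, mcr_cps = df$mcr_cps,
                   laser_intensity = if (!is.null(meta$laser_intensity))
                     meta$laser_intensity else 1,
                   toluene_count_rate = meta$toluene_count_rate, config = cfg)
      else
        sls_series(df$conc_g_ml, kc_over_r = df$kc_over_r, config = cfg)
    },
    viscosity = {
      if (nrow(df) == 0)
        return(structure(list(points = df, raw = FALSE, reference = NULL),
                         class = "viscosity_series"))
      if ("eta_rel" %in% names(df))
        viscosity_series(df$conc_M, eta_rel = df$eta_rel)
      else
        viscosity_series(df$conc_M, flow_s = df$flow_s,
                         density_g_cm3 = df$density_g_cm3,
                         reference = list(
                           flow_s = meta$reference_flow_s,
                           density_g_cm3 = meta$reference_density_g_cm3,
                           eta_mPas = meta$reference_eta_mPas))
    })
}

#' Write a measurement series to CSV
#'
#' Inverse of [read_measurement_table()]; ground-truth attributes of
#' synthetic series are embedded as `#` metadata lines so generated fixtures
#' are self-documenting.
#'
#' @param x A series object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(x, path) {
  truth <- attr(x, "truth")
  tmeta <- if (is.null(truth)) list() else {
    flat <- truth[vapply(truth, function(v) is.numeric(v) && length(v) == 1,
                         logical(1))]
    names(flat) <- paste0("truth_", names(flat))
    flat
  }
  if (inherits(x, "cloud_point_series")) {
    df <- data.frame(buffer = rep(x$buffer_name, nrow(x$observations)),
                     gamma_mg_ml = rep(x$gamma, nrow(x$observations)),
                     x$observations)
    .write_csv_with_meta(df, path, tmeta)
  } else if (inherits(x, "dls_series")) {
    .write_csv_with_meta(x$points, path,
                         c(list(temperature_K = x$temperature,
                                solvent_viscosity_mPas = x$solvent_viscosity_mPas),
                           tmeta))
  } else if (inherits(x, "sls_series")) {
    cfg <- x$config
    meta <- list(wavelength_nm = cfg$wavelength_nm,
                 refractive_index = cfg$refractive_index,
                 dn_dc_mL_g = cfg$dn_dc_mL_g,
                 rayleigh_toluene_cm = cfg$rayleigh_toluene_cm)
    if (x$raw) {
      meta$laser_intensity <- x$laser_intensity
      meta$toluene_count_rate <- x$toluene_count_rate
      df <- x$points[, c("conc_g_ml", "mcr_cps")]
    } else df <- x$points[, c("conc_g_ml", "kc_over_r")]
    .write_csv_with_meta(df, path, c(meta, tmeta))
  } else if (inherits(x, "viscosity_series")) {
    if (x$raw) {
      meta <- list(reference_flow_s = x$reference$flow_s,
                   reference_density_g_cm3 = x$reference$density_g_cm3,
                   reference_eta_mPas = x$reference$eta_mPas)
      df <- x$points[, c("conc_M", "flow_s", "density_g_cm3")]
    } else {
      meta <- list()
      df <- x$points[, c("conc_M", "eta_rel")]
    }
    .write_csv_with_meta(df, path, c(meta, tmeta))
  } else stop("unsupported series class: ", paste(class(x), collapse = "/"))
  invisible(path)
}

#' Write a binodal curve to CSV
#'
#' Plot-ready coexistence table with temperatures in K and both branch
#' concentrations in mg/mL.
#'
#' @param x A [binodal_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binodal_csv <- function(x, path) {
  stopifnot(inherits(x, "binodal_curve"))
  df <- x$points[, c("T_K", "gamma_dilute_mg_ml", "gamma_dense_mg_ml")]
  .write_csv_with_meta(df, path,
                       list(eps_K = x$eps,
                            critical_temperature_K = x$critical_temperature,
                            critical_gamma_mg_ml = x$critical_gamma_mg_ml))
}
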