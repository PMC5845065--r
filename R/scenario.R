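# Scenario runner and format plumbing: configuration files (YAML/JSON, SI
# units with optional MPa/mm suffixes), delimited-table import/export for
# records, spectra and fields, and a run manifest. The exec/viscopulse script
# is a thin command-line wrapper over run_scenario().

# ---- unit-aware configuration ------------------------------------------

# Accepts keys like E0_Pa / E0_MPa, r_m / r_mm, and converts to SI.
unit_value <- function(cfg, base, required = TRUE, default = NULL) {
  cand <- list(Pa = 1, MPa = 1e6, kPa = 1e3, m = 1, mm = 1e-3, s = 1)
  for (suffix in names(cand)) {
    key <- paste0(base, "_", suffix)
    if (!is.null(cfg[[key]])) return(as.numeric(cfg[[key]]) * cand[[suffix]])
  }
  if (!is.null(cfg[[base]])) return(as.numeric(cfg[[base]]))
  if (required) stop(sprintf("config field `%s` is missing", base))
  default
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Read or write a material card
#'
#' Material cards are small JSON/YAML files with `model` (`"maxwell"` or
#' `"zener"`) and the moduli/relaxation time, SI by default (`E0_Pa`,
#' `E1_Pa`, `tau_s`), with `*_MPa` accepted and converted on ingest.
#'
#' @param path File path (`.json`, `.yaml`/`.yml`).
#' @return A `maxwell_material` or `zener_material`.
#' @export
read_material_card <- function(path) {
  cfg <- read_config(path)
  material_from_config(cfg)
}

material_from_config <- function(cfg) {
  model <- tolower(cfg$model %||% "zener")
  tau <- unit_value(cfg, "tau", required = FALSE)
  if (is.null(tau)) tau <- unit_value(cfg, "tau_s", required = FALSE)
  if (is.null(tau)) stop("material card needs `tau_s` (or `tau`)")
  if (model == "maxwell") {
    maxwell_material(E1 = unit_value(cfg, "E1"), tau = tau)
  } else if (model == "zener") {
    zener_material(E0 = unit_value(cfg, "E0"),
                   E1 = unit_value(cfg, "E1"), tau = tau)
  } else stop("unknown material model: ", model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_material_card
#' @param material Material object to write.
#' @export
write_material_card <- function(material, path) {
  card <- if (inherits(material, "zener_material")) {
    list(model = "zener", E0_Pa = material$E0, E1_Pa = material$E1,
         tau_s = material$tau)
  } else {
    list(model = "maxwell", E1_Pa = material$E1, tau_s = material$tau)
  }
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

geometry_from_config <- function(cfg) {
  tube_geometry(r = unit_value(cfg, "r"), e = unit_value(cfg, "e"),
                L = unit_value(cfg, "L"),
                rho = unit_value(cfg, "rho", required = FALSE,
                                 default = 1000))
}

# ---- delimited-table IO -------------------------------------------------

#' Read and write stress/strain records
#'
#' Records travel as delimited text with header columns `t`, `eps`, `sigma`,
#' plus an optional JSON sidecar (`<path>.json`) carrying protocol metadata.
#'
#' @param path CSV path.
#' @return A [stress_strain_record()].
#' @export
read_record <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("t", "eps", "sigma") %in% names(d)))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  stress_strain_record(d$t, d$eps, d$sigma, meta = meta)
}

#' @rdname read_record
#' @param record Record to write.
#' @export
write_record <- function(record, path) {
  write.csv(data.frame(t = record$t, eps = record$eps,
                       sigma = record$sigma),
            path, row.names = FALSE)
  if (length(record$meta))
    jsonlite::write_json(record$meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a pressure field as a long-format table
#'
#' Columns `t` (s), `x` (m), `p` (Pa), one row per snapshot-node pair.
#'
#' @param field A `pressure_field`.
#' @param path CSV path.
#' @export
write_field <- function(field, path) {
  long <- data.frame(t = rep(field$t, times = length(field$x)),
                     x = rep(field$x, each = length(field$t)),
                     p = as.vector(field$p))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @return `read_field()` rebuilds the `pressure_field` (wave speed and model
#'   are restored from the sidecar written by [run_scenario()], or NA).
#' @export
read_field <- function(path) {
  long <- read.csv(path)
  t <- sort(unique(long$t)); x <- sort(unique(long$x))
  p <- matrix(long$p[order(long$x, long$t)], nrow = length(t))
  structure(list(x = x, t = t, p = p, c = NA_real_,
                 h = diff(x[1:2]), model = NA_character_, pulse = NULL),
            class = "pressure_field")
}

#' Export a decay spectrum as a delimited table
#'
#' One row per mode: index, spatial eigenvalue, real/imaginary parts of each
#' temporal rate, regime label.
#'
#' @param spectrum A `decay_spectrum`.
#' @param path CSV path.
#' @export
write_spectrum <- function(spectrum, path) {
  m <- spectrum$modes
  out <- data.frame(n = m$n, lambda_n = m$lambda_n)
  for (col in grep("^rate", names(m), value = TRUE)) {
    out[[paste0(col, "_re")]] <- Re(m[[col]])
    out[[paste0(col, "_im")]] <- Im(m[[col]])
  }
  out$omega_n <- m$omega_n
  out$regime <- m$regime
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- scenario runner ----------------------------------------------------

#' Run a scenario from a configuration file
#'
#' A scenario config (YAML or JSON) bundles a material card, tube geometry,
#' pulse and grid settings, an `output` request (`"spectrum"`, `"field"`,
#' `"fit"`, `"map"` or `"synthetic"`) and a seed. The requested computation
#' is dispatched to the spectral / waves / fitting / design layer, artifact
#' files are written under `out_dir`, and a JSON manifest records inputs
#' (config hash), package version, seed and wall-clock time.
#'
#' Config units are SI, with `*_MPa` / `*_mm` suffixed keys converted on load
#' and echoed in the manifest.
#'
#' @param config_path Path to the scenario config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (with `$files` naming the artifacts).
#' @export
run_scenario <- function(config_path, out_dir = ".") {
  t0 <- Sys.time()
  cfg <- read_config(config_path)
  output <- cfg$output %||% stop("config needs an `output` field")
  seed <- as.integer(cfg$seed %||% 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  material <- if (!is.null(cfg$material)) material_from_config(cfg$material)
  geom <- if (!is.null(cfg$geometry)) geometry_from_config(cfg$geometry)

  if (output == "spectrum") {
    n_max <- cfg$n_max %||% 200
    sp <- if (inherits(material, "zener_material"))
      zener_spectrum(material, geom, n_max)
    else maxwell_spectrum(material, geom, n_max)
    f <- file.path(out_dir, "spectrum.csv")
    write_spectrum(sp, f)
    pred <- list(c = sp$c, tau_eq = sp$tau_eq, tau_inf = sp$tau_inf,
                 validity_m2 = sp$validity_m2, valid = sp$valid)
    fj <- file.path(out_dir, "prediction.json")
    jsonlite::write_json(pred, fj, auto_unbox = TRUE, digits = NA)
    files <- c(f, fj)
  } else if (output == "field") {
    pulse <- pulse_spec(p_max = unit_value(cfg$pulse, "p_max"),
                        T = unit_value(cfg$pulse, "T", required = FALSE,
                                       default = 0.2))
    gcfg <- cfg$grid %||% list()
    grid <- simulation_grid(
      N = gcfg$N %||% 512,
      t_end = gcfg$t_end %||% NULL,
      cadence = gcfg$cadence %||% 0.15,
      rtol = gcfg$rtol %||% 1e-8, atol = gcfg$atol %||% 1e-10)
    field <- if (inherits(material, "zener_material"))
      simulate_zener(material, geom, pulse, grid)
    else simulate_maxwell(material, geom, pulse, grid)
    f <- file.path(out_dir, "field.csv")
    write_field(field, f)
    dec <- measure_decay(field, field$c)
    fj <- file.path(out_dir, "decay.json")
    jsonlite::write_json(list(d_m = dec$d, tau_fit_s = dec$tau_fit,
                              r_squared = dec$r_squared,
                              low_confidence = dec$low_confidence),
                         fj, auto_unbox = TRUE, digits = NA)
    files <- c(f, fj)
  } else if (output == "fit") {
    record <- read_record(cfg$data %||% stop("fit scenario needs `data`"))
    fit <- fit_material(record, model = cfg$model %||% "zener",
                        restarts = cfg$restarts %||% 5, seed = seed)
    f <- file.path(out_dir, "fit.json")
    jsonlite::write_json(list(model = fit$model,
                              parameters = as.list(fit$parameters),
                              error = fit$error,
                              iterations = fit$iterations,
                              converged = fit$converged),
                         f, auto_unbox = TRUE, digits = NA)
    files <- f
  } else if (output == "map") {
    dq <- design_query(geom, a = cfg$a, L_device = unit_value(cfg, "L_device"),
                       E0_grid = cfg$E0_grid %||% mpa_grid(),
                       E1_grid = cfg$E1_grid %||% mpa_grid())
    map <- build_design_map(dq)
    f1 <- file.path(out_dir, "tau_required.csv")
    f2 <- file.path(out_dir, "feasible.csv")
    write.csv(map$tau_required, f1, row.names = FALSE)
    write.csv(map$feasible, f2, row.names = FALSE)
    fj <- file.path(out_dir, "map.json")
    jsonlite::write_json(list(E0_grid_Pa = map$E0_grid,
                              E1_grid_Pa = map$E1_grid,
                              a = dq$a, L_device_m = dq$L_device,
                              n_feasible = sum(map$feasible)),
                         fj, digits = NA)
    files <- c(f1, f2, fj)
  } else if (output == "synthetic") {
    p <- cfg$protocol %||% list()
    rec <- generate_synthetic_record(
      material,
      frequency = p$frequency %||% 1, amplitude = p$amplitude %||% 0.07,
      offset = p$offset %||% 0, duration = p$duration %||% 6,
      sample_rate = p$sample_rate %||% 100,
      noise_sd = p$noise_sd %||% 0, seed = seed)
    f <- file.path(out_dir, "record.csv")
    write_record(rec, f)
    files <- f
  } else stop("unknown output kind: ", output)

  manifest <- list(
    config = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    output = output, seed = seed,
    package = "viscopulse",
    version = as.character(packageVersion("viscopulse")),
    r_version = R.version.string,
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
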