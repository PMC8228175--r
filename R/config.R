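# YAML configuration layer and the comparison-sweep driver.

config_defaults <- function() {
  list(
    material = list(name = "silicene"),
    geometry = list(finger_width_um = 10, n_fingers = 200),
    circuit = list(c_semi = 1e-6, c_elec = 1e-6),
    threshold = list(e_ref = 0, chi_sol = 0, phi_si = 0,
                     q_ox = 0, q_ss = 0, q_b = 0, phi_f = 0),
    bias = list(v_gs = 1, v_ds = 0.1),
    readout = list(inductance_nh = 250),
    sweep = list(n_min_per_cm2 = -30e12, n_max_per_cm2 = 30e12, points = 601,
                 eot_min_nm = 1, eot_max_nm = 8, eot_points = 8),
    hybridization = list(ions_per_match = 1, solution_volume_l = 1e-6,
                         baseline_h_mol_per_l = 1e-7,
                         charge_to_density_gain = 1e19,
                         mode = "complement", reverse_target = FALSE),
    constants = list(planck_convention = "reduced"),
    seed = 1L
  )
}

# keys whose values must parse as finite numerics
config_numeric_keys <- c(
  "material.fermi_velocity", "material.band_gap",
  "material.intrinsic_mobility", "material.field_effect_mobility",
  "material.residual_carrier_density", "material.oxide_thickness",
  "material.gate_length",
  "geometry.gate_length_um", "geometry.finger_width_um",
  "geometry.n_fingers", "geometry.eot_nm",
  "circuit.c_semi", "circuit.c_elec",
  "threshold.e_ref", "threshold.chi_sol", "threshold.phi_si",
  "threshold.q_ox", "threshold.q_ss", "threshold.q_b", "threshold.phi_f",
  "bias.v_gs", "bias.v_ds",
  "readout.inductance_nh",
  "sweep.n_min_per_cm2", "sweep.n_max_per_cm2", "sweep.points",
  "sweep.eot_min_nm", "sweep.eot_max_nm", "sweep.eot_points",
  "hybridization.ions_per_match", "hybridization.solution_volume_l",
  "hybridization.baseline_h_mol_per_l",
  "hybridization.charge_to_density_gain",
  "seed"
)

config_other_keys <- c("material.name", "hybridization.mode",
                       "hybridization.reverse_target",
                       "constants.planck_convention")

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration file, validates every key against the schema
#' (unknown keys are rejected with their full path; numeric keys must parse
#' as finite numbers) and merges it over the built-in defaults (silicene
#' preset, standard 200-finger gate, 250 nH readout, the
#' -3e13 ... 3e13 cm^-2 / 1-8 nm sweep grids).  An empty file, or
#' `path = NULL`, yields the all-defaults configuration.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return Object of class `simulation_config` (nested named list).
#' @examples
#' cfg <- load_config(NULL)
#' cfg$material$name
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config file must contain a YAML mapping")
  }
  cfg <- config_defaults()
  flat <- flatten_config(user)
  allowed <- c(config_numeric_keys, config_other_keys)
  for (key in names(flat)) {
    if (!key %in% allowed) {
      stop("unknown configuration key: '", key, "'")
    }
    val <- flat[[key]]
    if (key %in% config_numeric_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (length(num) != 1 || is.na(num) || !is.finite(num)) {
        stop("configuration key '", key, "' must be a finite number, got '",
             paste(val, collapse = ","), "'")
      }
      val <- num
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- val
    else cfg[[parts[1]]][[parts[2]]] <- val
  }
  if (!cfg$material$name %in% c("silicene", "graphene")) {
    stop("unknown material name: '", cfg$material$name, "'")
  }
  if (!cfg$constants$planck_convention %in% c("reduced", "bare")) {
    stop("constants.planck_convention must be 'reduced' or 'bare'")
  }
  structure(cfg, class = "simulation_config")
}

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v)) {
      if (!is.null(prefix)) {
        stop("configuration nested too deeply at '", key, "'")
      }
      out <- c(out, flatten_config(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

# materialize domain objects from a config
config_material <- function(cfg) {
  args <- cfg$material
  do.call(material_params, c(list(name = args$name),
                             args[setdiff(names(args), "name")]))
}

config_geometry <- function(cfg, material = config_material(cfg)) {
  g <- cfg$geometry
  device_geometry(
    gate_length_um = g$gate_length_um %||% material$gate_length,
    finger_width_um = g$finger_width_um,
    n_fingers = g$n_fingers,
    eot_nm = g$eot_nm %||% (material$oxide_thickness / 10)
  )
}

config_constants <- function(cfg) {
  physical_constants(planck_convention = cfg$constants$planck_convention)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full silicene-vs-graphene comparison suite
#'
#' The reproduction driver for the standard sweep analyses: for both
#' channel-material presets it tabulates quantum capacitance, oxide
#' capacitance, tuning ratio and resonant frequency over the configured
#' grids and writes five CSV tables plus a JSON run manifest to `out_dir`:
#' \describe{
#'   \item{cq_vs_n.csv}{quantum capacitance vs carrier concentration.}
#'   \item{cox_vs_eot.csv}{oxide capacitance vs equivalent oxide thickness.}
#'   \item{tuning.csv}{capacitance and tuning ratio vs carrier concentration.}
#'   \item{f_vs_cq.csv}{resonant frequency vs capacitance (1-6 pF).}
#'   \item{f_vs_n.csv}{resonant frequency vs carrier concentration.}
#' }
#' The physics chain is deterministic: identical configurations produce
#' byte-identical CSVs.
#'
#' @param config a [simulation_config] (default: all defaults).
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a named character vector of the CSV paths.
#' @export
run_paper_suite <- function(config = load_config(NULL), out_dir = ".") {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constants <- config_constants(config)
  readout <- lc_readout(config$readout$inductance_nh * 1e-9)
  sw <- config$sweep
  n_grid <- seq(sw$n_min_per_cm2, sw$n_max_per_cm2, length.out = sw$points)
  eot_grid <- seq(sw$eot_min_nm, sw$eot_max_nm, length.out = sw$eot_points)
  materials <- lapply(c("silicene", "graphene"), material_params)

  per_material <- lapply(materials, function(m) {
    geo <- device_geometry_for(m, config$geometry$finger_width_um,
                               config$geometry$n_fingers)
    sweep <- frequency_sweep(n_grid, m, geo, readout, constants)
    cox <- vapply(eot_grid, function(e) {
      oxide_capacitance(device_geometry(geo$gate_length_um,
                                        geo$finger_width_um,
                                        geo$n_fingers, eot_nm = e),
                        constants)
    }, numeric(1))
    list(material = m$name, sweep = sweep,
         cox = data.frame(material = m$name, eot_nm = eot_grid,
                          cox_farad = cox))
  })

  cq_vs_n <- do.call(rbind, lapply(per_material, function(x) {
    data.frame(material = x$material, n_per_cm2 = x$sweep$n_per_cm2,
               cq_farad = x$sweep$cq_farad)
  }))
  cox_vs_eot <- do.call(rbind, lapply(per_material, `[[`, "cox"))
  tuning <- do.call(rbind, lapply(per_material, function(x) {
    data.frame(material = x$material, n_per_cm2 = x$sweep$n_per_cm2,
               cq_farad = x$sweep$cq_farad,
               tuning_ratio = x$sweep$tuning_ratio)
  }))
  cq_axis <- seq(1e-12, 6e-12, length.out = 101)
  f_vs_cq <- data.frame(cq_farad = cq_axis,
                        freq_hz = resonant_frequency(readout, cq_axis))
  f_vs_n <- do.call(rbind, lapply(per_material, function(x) {
    data.frame(material = x$material, n_per_cm2 = x$sweep$n_per_cm2,
               freq_hz = x$sweep$freq_hz)
  }))

  tables <- list(cq_vs_n = cq_vs_n, cox_vs_eot = cox_vs_eot,
                 tuning = tuning, f_vs_cq = f_vs_cq, f_vs_n = f_vs_n)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  write_run_manifest(out_dir, config, paths)
  invisible(paths)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, timestamp and MD5
#' checksums of the output files as `manifest.json` in `out_dir`; written
#' exactly once per run.
#'
#' @param out_dir output directory.
#' @param config the [simulation_config] used.
#' @param files character vector of output files to checksum.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(out_dir, config, files) {
  manifest <- list(
    tool = "isfetsim",
    version = as.character(utils::packageVersion("isfetsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    outputs = lapply(unname(files), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
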