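# schema-checked TSV reader: required columns present, extras kept with a
# warning, numeric columns coerced
read_table_checked <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    abort(paste0("File '", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(tb), required)
  if (length(extra)) {
    warn(paste0("File '", path, "' has extra column(s), preserved: ",
                paste(extra, collapse = ", ")))
  }
  for (cl in intersect(numeric_cols, names(tb))) {
    tb[[cl]] <- as.numeric(tb[[cl]])
    if (any(is.na(tb[[cl]]))) {
      abort(paste0("Column '", cl, "' in '", path, "' is not numeric."))
    }
  }
  tb
}

#' Read a decay bundle from a manifest
#'
#' The manifest is a TSV with columns `file` and `wavelength_nm`; each listed
#' file is a TSV with columns `channel` and `counts`. Paths are resolved
#' relative to the manifest's directory.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return Tibble with columns `wavelength_nm`, `channel`, `counts`.
#' @export
read_decays <- function(manifest_path) {
  man <- read_table_checked(manifest_path, c("file", "wavelength_nm"),
                            numeric_cols = "wavelength_nm")
  base <- dirname(manifest_path)
  purrr::map2_dfr(man$file, man$wavelength_nm, function(f, wl) {
    tr <- read_table_checked(file.path(base, f), c("channel", "counts"))
    tibble(wavelength_nm = wl, channel = tr$channel, counts = tr$counts)
  })
}

#' Read an IRF histogram (TSV with columns channel, counts)
#' @param path Path to the TSV file.
#' @return Tibble with columns `channel`, `counts`.
#' @export
read_irf <- function(path) read_table_checked(path, c("channel", "counts"))

#' Read a steady-state emission spectrum (TSV: wavelength_nm, intensity)
#' @param path Path to the TSV file.
#' @return Tibble with columns `wavelength_nm`, `intensity`.
#' @export
read_spectrum <- function(path) {
  tb <- read_table_checked(path, c("wavelength_nm", "intensity"))
  if (any(diff(tb$wavelength_nm) <= 0)) {
    abort("Spectrum wavelengths must be strictly increasing.")
  }
  tb
}

#' Read a denaturant transition curve (TSV: urea_M, signal)
#' @param path Path to the TSV file.
#' @return Tibble with columns `urea_M`, `signal`.
#' @export
read_transition_curve <- function(path) {
  tb <- read_table_checked(path, c("urea_M", "signal"))
  if (any(diff(tb$urea_M) <= 0)) {
    abort("`urea_M` must be strictly increasing.")
  }
  tb
}

#' Write a simulated decay bundle in the pipeline's input layout
#'
#' Writes one TSV per wavelength plus `manifest.tsv` and `irf.tsv` into a
#' directory, exactly the format [read_decays()] and [read_irf()] consume.
#'
#' @param sim Output of [simulate_decays()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decay_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wls <- unique(sim$decays$wavelength_nm)
  files <- sprintf("decay_%03dnm.tsv", wls)
  for (i in seq_along(wls)) {
    tr <- sim$decays[sim$decays$wavelength_nm == wls[i],
                     c("channel", "counts")]
    readr::write_tsv(tr, file.path(dir, files[i]), progress = FALSE)
  }
  readr::write_tsv(tibble(file = files, wavelength_nm = wls),
                   file.path(dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(sim$irf, file.path(dir, "irf.tsv"), progress = FALSE)
  invisible(dir)
}

#' Serialize a decay fit to JSON
#'
#' @param fit A `decay_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    units = list(lifetime = "ns", wavelength = "nm", background =
                   "counts/channel"),
    lifetimes = fit$lifetimes,
    amplitudes = fit$amplitudes,
    backgrounds = fit$backgrounds,
    chi2_global = fit$chi2_global,
    chi2_reduced = fit$chi2_reduced,
    converged = fit$converged,
    warnings = fit$warnings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a decay-associated-spectra table to TSV
#' @param das Output of [decay_associated_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_das_tsv <- function(das, path) {
  readr::write_tsv(as_tibble(das), path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' A YAML file of plain key-value entries. Recognized keys: `decays_manifest`,
#' `irf`, `spectrum`, `transition_curves` (named map signal -> path), `pdb`,
#' `chain_roles` (map chain -> alpha/beta), `cterm` (map with `chain`,
#' `from`, `to`), `fret_pairs` (list of maps with `donor`, `acceptor`),
#' `neighbor_cutoff`, `quencher_cutoff`, `probe`, `r0`, `dipole_angle`,
#' `temperature`, `n_components`, `channel_width`, `seed`, `out_dir`.
#' Unknown keys raise an error; file paths are resolved relative to the
#' config file and checked for existence.
#'
#' @param path Path to the YAML config.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  cfg <- yaml::read_yaml(path)
  run_config_from_list(cfg, base = dirname(path))
}

#' Build a pipeline run configuration in code
#' @param ... Configuration entries, see [read_run_config()].
#' @param base Directory against which relative paths are resolved.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(..., base = ".") {
  run_config_from_list(list(...), base = base)
}

run_config_from_list <- function(cfg, base = ".") {
  known <- c("decays_manifest", "irf", "spectrum", "transition_curves",
             "pdb", "chain_roles", "cterm", "fret_pairs",
             "neighbor_cutoff", "quencher_cutoff", "probe", "r0",
             "dipole_angle", "temperature", "n_components", "channel_width",
             "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste("Unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  defaults <- list(neighbor_cutoff = 7, quencher_cutoff = 5.5, probe = 1.4,
                   r0 = 7.8, dipole_angle = -38, temperature = 298.15,
                   n_components = 3, channel_width = 0.027, seed = 1)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("neighbor_cutoff", "quencher_cutoff", "probe", "r0")) {
    if (cfg[[k]] <= 0) abort(paste0("`", k, "` must be > 0."))
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    rp <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(rp)) abort(paste("Configured input does not exist:", p))
    rp
  }
  for (k in c("decays_manifest", "irf", "spectrum", "pdb")) {
    cfg[[k]] <- resolve(cfg[[k]])
  }
  if (!is.null(cfg$transition_curves)) {
    cfg$transition_curves <- lapply(cfg$transition_curves, resolve)
  }
  class(cfg) <- "run_config"
  cfg
}
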