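#' Transition registry of proteo-specific globin peptides
#'
#' Loads the registry of monitored precursor/product ion transitions: one row
#' per transition, covering the seven core globin-chain peptides (analyte and
#' stable-isotope-labeled internal-standard forms) and the mutant peptides
#' used to detect structural hemoglobin variants.
#'
#' @param path Path to a registry JSON file. Defaults to the registry shipped
#'   with the package.
#' @return A tibble with columns `peptide_id`, `sequence`, `precursor_mz`,
#'   `product_mz`, `retention_time` (minutes), `collision_energy`,
#'   `is_internal_standard`, `chain`, `variant_name`, and optionally `note`.
#' @examples
#' transition_registry()
#' @export
transition_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "transition_registry.json",
                                package = "hemoscreen")
  reg <- jsonlite::fromJSON(path)
  reg <- as_tibble(reg)
  if (!"note" %in% names(reg)) reg$note <- NA_character_
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  required <- c("peptide_id", "sequence", "precursor_mz", "product_mz",
                "retention_time", "collision_energy", "is_internal_standard",
                "chain")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    abort(paste0("registry is missing columns: ", paste(missing, collapse = ", ")),
          class = "hemoscreen_config_error")
  }
  if (any(reg$precursor_mz <= 0) || any(reg$product_mz <= 0)) {
    abort("registry m/z values must be positive", class = "hemoscreen_config_error")
  }
  # the chromatographic run is 2.6 min; retention outside it is a config error
  if (any(reg$retention_time < 0 | reg$retention_time > 2.6)) {
    abort("retention times must lie within the 2.6-minute run window",
          class = "hemoscreen_config_error")
  }
  if (any(!grepl("^[A-Z]+$", reg$sequence))) {
    abort("peptide sequences must be uppercase one-letter amino-acid codes",
          class = "hemoscreen_config_error")
  }
  # every IS entry must pair with exactly one analyte entry of the same id
  is_ids <- reg$peptide_id[reg$is_internal_standard]
  for (id in is_ids) {
    n_analyte <- sum(reg$peptide_id == id & !reg$is_internal_standard)
    if (n_analyte != 1) {
      abort(paste0("internal standard '", id, "' must pair with exactly one analyte entry"),
            class = "hemoscreen_config_error")
    }
  }
  invisible(reg)
}

#' Internal-standard concentrations
#'
#' The spiked concentration (mg/L) of each stable-isotope-labeled internal
#' standard, keyed by peptide id. Defaults reproduce the assay's spiking mix:
#' aT1 2, aT3 10, bT1 5, bT2 5, gT10 0.5, dT2 0.2, zT8 0.1 mg/L.
#'
#' @param path Path to a JSON map `peptide_id -> mg/L`; defaults to the
#'   shipped configuration.
#' @return Named numeric vector of concentrations (mg/L).
#' @examples
#' internal_standards()
#' @export
internal_standards <- function(path = NULL) {
  path <- path %||% system.file("extdata", "internal_standards.json",
                                package = "hemoscreen")
  cfg <- unlist(jsonlite::fromJSON(path))
  if (length(cfg) == 0 || is.null(names(cfg)) || any(!nzchar(names(cfg)))) {
    abort("internal-standard config must be a named map peptide_id -> mg/L",
          class = "hemoscreen_config_error")
  }
  if (any(!is.finite(cfg)) || any(cfg <= 0)) {
    abort("all internal-standard concentrations must be positive",
          class = "hemoscreen_config_error")
  }
  cfg
}
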