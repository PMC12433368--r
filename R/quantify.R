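#' Peptide concentration from analyte and internal-standard peak areas
#'
#' Isotope-dilution single-point quantification: the analyte concentration is
#' the analyte peak area divided by the internal-standard (IS) peak area,
#' scaled by the known spiked IS concentration. No calibration curve is used.
#'
#' @param area Analyte mass-spectra peak area (arbitrary units, >= 0).
#' @param is_area Internal-standard peak area (same units, > 0).
#' @param c_is Internal-standard concentration, mg/L (> 0).
#' @return Concentration in mg/L, `area * c_is / is_area`. Vectorized.
#' @examples
#' compute_concentration(1500, 500, 10) # 30 mg/L
#' @export
compute_concentration <- function(area, is_area, c_is) {
  if (any(!is.finite(area)) || any(area < 0)) {
    abort("analyte peak area must be finite and >= 0",
          class = "hemoscreen_measurement_error")
  }
  if (any(!is.finite(is_area)) || any(is_area <= 0)) {
    abort("internal-standard peak area must be > 0 for an evaluable measurement",
          class = "hemoscreen_measurement_error")
  }
  if (any(!is.finite(c_is)) || any(c_is <= 0)) {
    abort("internal-standard concentration must be > 0",
          class = "hemoscreen_measurement_error")
  }
  area * c_is / is_area
}

#' Globin-chain ratio of two quantified peptides
#'
#' Ratio of the numerator peptide's concentration to the denominator
#' peptide's concentration, expanded so it is computed directly from the four
#' peak areas and the two IS concentrations:
#' `(num_area * den_is_area * c_num) / (num_is_area * den_area * c_den)`.
#' Dimensionless; invariant to any common scaling of the peak areas.
#'
#' @param num_area,num_is_area Analyte and IS peak areas of the numerator
#'   peptide.
#' @param den_area,den_is_area Analyte and IS peak areas of the denominator
#'   peptide.
#' @param c_num,c_den IS concentrations (mg/L) of the two peptides.
#' @return Dimensionless ratio; `NA_real_` when the denominator area is zero
#'   (the sample is flagged non-evaluable upstream rather than dividing by an
#'   absent chain).
#' @examples
#' compute_chain_ratio(200, 400, 800, 400, c_num = 0.1, c_den = 5) # 0.005
#' @export
compute_chain_ratio <- function(num_area, num_is_area, den_area, den_is_area,
                                c_num, c_den) {
  if (any(!is.finite(c(c_num, c_den))) || any(c(c_num, c_den) <= 0)) {
    abort("missing or non-positive internal-standard concentration",
          class = "hemoscreen_config_error")
  }
  if (any(!is.finite(c(num_is_area, den_is_area))) ||
      any(c(num_is_area, den_is_area) <= 0)) {
    abort("internal-standard peak areas must be > 0",
          class = "hemoscreen_measurement_error")
  }
  ifelse(den_area > 0,
         (num_area * den_is_area * c_num) / (num_is_area * den_area * c_den),
         NA_real_)
}

#' Mutant-to-wild-type variant ratio
#'
#' Ratio of a mutant globin peptide to the wild-type beta-chain peptide,
#' computed from peak areas normalized by their IS areas only:
#' `(mut_area * wt_is_area) / (mut_is_area * wt_area)`. Unlike the chain
#' ratio, no IS concentration terms enter (the mutant and wild-type peptide
#' share a backbone, so the scale factors are not needed for a detection
#' readout).
#'
#' @param mut_area,mut_is_area Mutant peptide analyte and IS peak areas.
#' @param wt_area,wt_is_area Wild-type beta peptide analyte and IS peak areas.
#' @param detected Logical; whether the mutant peptide passed detection
#'   (S/N >= 10). Undetected mutants report a ratio of 0 so that "> 0"
#'   cutoffs read as "variant detected".
#' @return Dimensionless ratio; `NA_real_` when the wild-type area is zero.
#' @examples
#' compute_variant_ratio(300, 400, 600, 400) # 0.5
#' @export
compute_variant_ratio <- function(mut_area, mut_is_area, wt_area, wt_is_area,
                                  detected = TRUE) {
  if (any(!is.finite(c(mut_is_area, wt_is_area))) ||
      any(c(mut_is_area, wt_is_area) <= 0)) {
    abort("internal-standard peak areas must be > 0",
          class = "hemoscreen_measurement_error")
  }
  out <- ifelse(wt_area > 0,
                (mut_area * wt_is_area) / (mut_is_area * wt_area),
                NA_real_)
  ifelse(detected, out, 0)
}

#' Signal-to-noise detection filter
#'
#' A peptide is considered detected when its signal-to-noise ratio is at
#' least 10. When no noise estimate accompanies the measurement, detection
#' falls back to an area threshold (`floor`, default 0, i.e. any positive
#' area), which can be set per peptide to emulate a lower limit of
#' quantitation.
#'
#' @param area Analyte peak area (>= 0).
#' @param noise Baseline noise level in the same units (>= 0), or `NA` when
#'   unavailable.
#' @param floor Detection floor used when `noise` is missing.
#' @return Logical. Vectorized.
#' @examples
#' is_detected(100, 10)  # TRUE  (S/N = 10)
#' is_detected(99, 10)   # FALSE (S/N = 9.9)
#' @export
is_detected <- function(area, noise = NA_real_, floor = 0) {
  if (any(area < 0, na.rm = TRUE) || any(noise < 0, na.rm = TRUE) ||
      any(floor < 0)) {
    abort("areas, noise and detection floor must be non-negative",
          class = "hemoscreen_measurement_error")
  }
  n <- pmax(length(area), length(noise))
  area <- rep_len(area, n)
  noise <- rep_len(noise, n)
  ifelse(!is.na(noise),
         noise > 0 & area / ifelse(noise > 0, noise, Inf) >= 10,
         area > floor)
}

#' Quantify a cohort of samples into globin-chain ratio profiles
#'
#' The first pipeline stage: turns a long per-measurement peak-area table
#' into one ratio profile per sample. For each sample the six named chain
#' ratios (`aT1_bT1`, `zT8_bT2`, `aT3_bT1`, `dT2_bT2`, `gT10_aT3`,
#' `gT10_bT1`) are computed from IS-normalized concentrations, and a
#' mutant-to-wild-type ratio is computed for every variant peptide in the
#' registry that was measured (referenced against wild-type `bT1`).
#' Undetected numerators contribute a ratio of 0; an undetected or
#' zero-area denominator makes the affected ratio unavailable, and a sample
#' whose `bT1` or `bT2` channel is missing or undetected is flagged
#' non-evaluable.
#'
#' @param peak_table Data frame with columns `sample_id`, `peptide_id`,
#'   `area`, `is_area`, and optionally `noise`, `age_days`, `genotype`.
#'   One row per analyte peptide per sample.
#' @param is_config Named numeric vector of IS concentrations (mg/L);
#'   defaults to [internal_standards()].
#' @param registry Transition registry tibble; defaults to
#'   [transition_registry()]. Used to recognize variant peptides.
#' @param detection_floor Named numeric vector of per-peptide detection
#'   floors applied when a measurement carries no noise estimate; a single
#'   unnamed value is recycled. Default 0.
#' @return A tibble with one row per sample: `sample_id`, `age_days`,
#'   `genotype` (if supplied), `evaluable`, `reason`, the six ratio columns,
#'   and list-columns `variant_ratios` (named numeric per sample) and
#'   `detected` (named logical per peptide).
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = "s1",
#'   peptide_id = c("aT1", "aT3", "bT1", "bT2", "gT10", "dT2", "zT8"),
#'   area = 500, is_area = 500
#' )
#' quantify_cohort(tbl)
#' @export
quantify_cohort <- function(peak_table,
                            is_config = internal_standards(),
                            registry = transition_registry(),
                            detection_floor = 0) {
  peak_table <- as_tibble(peak_table)
  required <- c("sample_id", "peptide_id", "area", "is_area")
  missing_cols <- setdiff(required, names(peak_table))
  if (length(missing_cols) > 0) {
    abort(paste0("peak table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hemoscreen_input_error")
  }
  if (!"noise" %in% names(peak_table)) peak_table$noise <- NA_real_
  if (!"age_days" %in% names(peak_table)) peak_table$age_days <- NA_integer_
  if (!"genotype" %in% names(peak_table)) peak_table$genotype <- NA_character_

  dup <- peak_table |>
    dplyr::count(.data$sample_id, .data$peptide_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate peptide_id within sample: ",
                 paste(unique(dup$sample_id), collapse = ", ")),
          class = "hemoscreen_input_error")
  }

  known <- unique(registry$peptide_id[!registry$is_internal_standard])
  unknown <- setdiff(unique(peak_table$peptide_id), known)
  if (length(unknown) > 0) {
    warn(paste0("skipping measurements for unknown peptide_id: ",
                paste(unknown, collapse = ", ")))
    peak_table <- dplyr::filter(peak_table, .data$peptide_id %in% known)
  }

  variant_map <- registry |>
    dplyr::filter(.data$chain == "variant", !.data$is_internal_standard) |>
    dplyr::select("peptide_id", "variant_name")

  peak_table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_split() |>
    purrr::map(quantify_one, is_config = is_config,
               variant_map = variant_map, detection_floor = detection_floor) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$sample_id)
}

# One sample's measurements -> one ratio-profile row.
quantify_one <- function(meas, is_config, variant_map, detection_floor) {
  floor_of <- function(id) {
    if (length(detection_floor) == 1 && is.null(names(detection_floor))) {
      detection_floor
    } else {
      unname(detection_floor[id]) %||% 0
    }
  }
  ids <- meas$peptide_id
  det <- vapply(seq_along(ids), function(i) {
    fl <- floor_of(ids[i])
    is_detected(meas$area[i], meas$noise[i], floor = if (is.na(fl)) 0 else fl)
  }, logical(1))
  names(det) <- ids
  evaluable_meas <- is.finite(meas$is_area) & meas$is_area > 0

  get <- function(id) {
    i <- match(id, ids)
    if (is.na(i) || !evaluable_meas[i]) return(NULL)
    list(area = meas$area[i], is_area = meas$is_area[i],
         detected = det[[id]] %||% FALSE)
  }

  reason <- NA_character_
  for (denom in c("bT1", "bT2")) {
    m <- get(denom)
    if (is.null(m)) {
      reason <- paste0("missing or non-evaluable ", denom, " measurement")
      break
    }
    if (!m$detected || m$area <= 0) {
      reason <- paste0(denom, " not detected")
      break
    }
  }
  evaluable <- is.na(reason)

  ratios <- setNames(rep(NA_real_, nrow(RATIO_DEFINITIONS)),
                     RATIO_DEFINITIONS$ratio)
  for (k in seq_len(nrow(RATIO_DEFINITIONS))) {
    num <- get(RATIO_DEFINITIONS$numerator[k])
    den <- get(RATIO_DEFINITIONS$denominator[k])
    if (is.null(num) || is.null(den) || !den$detected || den$area <= 0) next
    c_num <- is_config[RATIO_DEFINITIONS$numerator[k]]
    c_den <- is_config[RATIO_DEFINITIONS$denominator[k]]
    if (is.na(c_num) || is.na(c_den)) {
      abort(paste0("no internal-standard concentration configured for ",
                   RATIO_DEFINITIONS$numerator[k], " or ",
                   RATIO_DEFINITIONS$denominator[k]),
            class = "hemoscreen_config_error")
    }
    num_area <- if (num$detected) num$area else 0
    ratios[k] <- compute_chain_ratio(num_area, num$is_area,
                                     den$area, den$is_area,
                                     unname(c_num), unname(c_den))
  }

  variant_ratios <- numeric(0)
  wt <- get("bT1")
  measured_variants <- intersect(ids, variant_map$peptide_id)
  for (vid in measured_variants) {
    vname <- variant_map$variant_name[match(vid, variant_map$peptide_id)]
    mv <- get(vid)
    if (is.null(mv)) next
    if (!mv$detected) {
      variant_ratios[vname] <- 0
    } else if (!is.null(wt) && wt$detected && wt$area > 0) {
      variant_ratios[vname] <- compute_variant_ratio(
        mv$area, mv$is_area, wt$area, wt$is_area, detected = mv$detected)
    } else {
      variant_ratios[vname] <- NA_real_
    }
  }

  tibble(
    sample_id = meas$sample_id[1],
    age_days = meas$age_days[1],
    genotype = meas$genotype[1],
    evaluable = evaluable,
    reason = reason,
    !!!as.list(ratios),
    variant_ratios = list(variant_ratios),
    detected = list(det)
  )
}
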