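# Baseline peak areas for a healthy newborn (arbitrary units). Chosen so
# that, at the default IS concentrations and a common IS area, the
# noise-free chain ratios are aT1_bT1 = aT3_bT1 = 4.5 (alpha-chain output
# exceeds beta-chain output in HbF-dominant newborns), dT2_bT2 = 0.04
# (delta barely expressed at birth), zT8_bT2 = 0.002 (trace embryonic
# zeta), gT10_aT3 = 0.8 (gamma the dominant non-alpha chain).
BASELINE_AREAS <- c(aT1 = 22500, aT3 = 4500, bT1 = 2000, bT2 = 1000,
                    gT10 = 72000, dT2 = 1000, zT8 = 100)

PEPTIDE_CHAIN <- c(aT1 = "alpha", aT3 = "alpha", bT1 = "beta", bT2 = "beta",
                   gT10 = "gamma", dT2 = "delta", zT8 = "zeta")

# variant peptide id, display name, and the wild-type peptide whose signal
# the mutant allele replaces in the simulation
VARIANT_INFO <- data.frame(
  peptide_id = c("HbS_T1", "HbE_T3", "HbD_T13", "HbG_T3",
                 "HbWatford_T1", "HbNanchang_T3", "HbHekinan_T4"),
  variant_name = c("Hb S", "Hb E", "Hb D-Los Angeles", "Hb G-Coushatta",
                   "Hb Watford", "Hb Nanchang", "Hb Hekinan II"),
  host_peptide = c("bT1", "bT1", "bT1", "bT1", "bT1", "aT3", "aT3"),
  stringsAsFactors = FALSE
)

#' Genotype effect presets for the synthetic cohort generator
#'
#' Each preset describes how a genotype class distorts the baseline globin
#' chain output: a positive multiplier per chain (alpha, beta, gamma, delta,
#' zeta) relative to the healthy-newborn baseline, and, for structural
#' variants, the fraction of the affected chain's signal carried by the
#' mutant peptide.
#'
#' All magnitudes here are synthetic calibration choices, not measured
#' biology: they are set so the qualitative ordering of the disease groups
#' (normal < single-gene alpha deletion < --SEA double deletion < HbH in
#' P(alpha); beta-thalassemia carriers elevated in delta/beta) holds, which
#' is what the pipeline's behavior depends on. The direction of each effect
#' does follow the known physiology: alpha-gene deletions depress alpha-chain
#' output and prolong embryonic zeta (and gamma) expression, beta-thalassemia
#' mutations depress beta-chain output and so raise the delta/beta ratio, and
#' a heterozygous structural variant moves roughly half the affected chain's
#' output onto the mutant peptide.
#'
#' @return Named list of `GenotypeEffect` lists with elements `label`,
#'   `multipliers` (named, chains), `variant_fractions` (named by variant).
#' @examples
#' names(preset_effects())
#' @export
preset_effects <- function() {
  eff <- function(label, mult = c(), variants = c()) {
    m <- c(alpha = 1, beta = 1, gamma = 1, delta = 1, zeta = 1)
    m[names(mult)] <- mult
    list(label = label, multipliers = m, variant_fractions = variants)
  }
  list(
    normal = eff("normal"),
    alpha_plus_het = eff("aa/-a3.7",
                         c(alpha = 0.7, zeta = 8, gamma = 1.2)),
    alpha_plus_homo = eff("-a3.7/-a3.7",
                          c(alpha = 0.55, zeta = 15, gamma = 1.3)),
    sea_het = eff("aa/--SEA",
                  c(alpha = 0.5, zeta = 50, gamma = 1.3)),
    hbh = eff("--SEA/-a3.7",
              c(alpha = 0.25, zeta = 100, gamma = 1.5)),
    beta_plus_het = eff("bN/bIVS-II-654",
                        c(beta = 0.7, delta = 1.8, gamma = 1.3)),
    beta0_het = eff("bN/bCodon17",
                    c(beta = 0.5, delta = 1.8, gamma = 1.4)),
    alpha_beta_combined = eff("aa/--SEA;bN/b-28",
                              c(alpha = 0.5, beta = 0.6, zeta = 40,
                                delta = 1.6, gamma = 1.4)),
    hbs_het = eff("bN/bHbS", variants = c("Hb S" = 0.5)),
    hbe_het = eff("bN/bHbE", c(beta = 0.85), c("Hb E" = 0.45)),
    hbd_het = eff("bN/bHbD", variants = c("Hb D-Los Angeles" = 0.5)),
    # mutant/beta response differs between peptides; fraction set so the
    # simulated ratio clears the 2.19 screening threshold for carriers
    hbg_het = eff("bN/bHbG", variants = c("Hb G-Coushatta" = 0.75))
  )
}

#' Specification of a synthetic genotype-stratified cohort
#'
#' @param strata Named integer vector: preset name (see [preset_effects()])
#'   to number of samples, or a list of `GenotypeEffect` objects paired with
#'   counts via `custom_effects`.
#' @param cv Multiplicative measurement CV of analyte peak areas, percent
#'   (default 10; assay CVs run up to ~15).
#' @param is_cv CV of internal-standard areas, percent (default 10).
#' @param is_area_mean Mean internal-standard peak area (default 500).
#' @param detection_floor Area below which a channel is reported with
#'   S/N < 10 (default 0, i.e. everything above zero is detectable).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param custom_effects Optional named list of `GenotypeEffect` lists used
#'   to resolve `strata` names not found among the presets.
#' @return A `hemo_cohort_spec` list.
#' @export
cohort_spec <- function(strata = c(normal = 200, sea_het = 50, beta0_het = 50),
                        cv = 10, is_cv = 10, is_area_mean = 500,
                        detection_floor = 0, seed,
                        custom_effects = list()) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("a seed is mandatory for a reproducible cohort",
          class = "hemoscreen_config_error")
  }
  if (any(strata < 0) || any(strata != round(strata))) {
    abort("stratum sizes must be non-negative integers",
          class = "hemoscreen_config_error")
  }
  if (cv < 0 || is_cv < 0 || is_area_mean <= 0 || detection_floor < 0) {
    abort("CVs and detection floor must be >= 0 and IS mean > 0",
          class = "hemoscreen_config_error")
  }
  effects <- utils::modifyList(preset_effects(), custom_effects)
  unknown <- setdiff(names(strata), names(effects))
  if (length(unknown) > 0) {
    abort(paste0("unknown genotype preset(s): ", paste(unknown, collapse = ", ")),
          class = "hemoscreen_config_error")
  }
  for (e in effects[names(strata)]) {
    if (any(e$multipliers <= 0)) {
      abort("chain multipliers must be > 0", class = "hemoscreen_config_error")
    }
    if (any(e$variant_fractions < 0 | e$variant_fractions > 1)) {
      abort("variant fractions must lie in [0, 1]",
            class = "hemoscreen_config_error")
    }
  }
  structure(list(strata = strata, effects = effects, cv = cv, is_cv = is_cv,
                 is_area_mean = is_area_mean,
                 detection_floor = detection_floor, seed = as.integer(seed)),
            class = "hemo_cohort_spec")
}

# lognormal deviates with mean m and coefficient of variation cv (percent)
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic genotype-stratified peak-area cohort
#'
#' Draws per-sample peptide peak areas with the chain-imbalance structure
#' the screening models assume: each chain's abundance is the healthy
#' baseline times the genotype's multiplier times multiplicative lognormal
#' noise at the configured CV; internal-standard areas are drawn
#' independently; heterozygous structural variants move `variant fraction`
#' of the affected wild-type peptide's signal onto the mutant peptide. All
#' variant transitions are monitored for every sample (non-carriers report
#' zero mutant area), as a targeted assay would. Channels whose area falls
#' below the detection floor are reported with S/N < 10.
#'
#' Sets the RNG seed from the spec, so the same spec always yields an
#' identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A peak table tibble (columns `sample_id`, `peptide_id`, `area`,
#'   `is_area`, `noise`, `age_days`, `genotype`) ready for
#'   [quantify_cohort()]; the truth genotype preset of each sample is in the
#'   `genotype` column.
#' @examples
#' tbl <- generate_cohort(cohort_spec(c(normal = 3, sea_het = 2), seed = 42))
#' dplyr::n_distinct(tbl$sample_id)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "hemo_cohort_spec"))
  set.seed(spec$seed)
  total <- sum(spec$strata)
  if (total == 0) {
    return(tibble(sample_id = character(0), peptide_id = character(0),
                  area = numeric(0), is_area = numeric(0), noise = numeric(0),
                  age_days = integer(0), genotype = character(0)))
  }
  width <- nchar(as.character(total))
  idx <- 0
  rows <- list()
  for (stratum in names(spec$strata)) {
    n <- spec$strata[[stratum]]
    if (n == 0) next
    effect <- spec$effects[[stratum]]
    for (i in seq_len(n)) {
      idx <- idx + 1
      sid <- sprintf(paste0("S%0", width, "d"), idx)
      age <- sample(2:30, 1)
      mult <- effect$multipliers
      areas <- vapply(names(BASELINE_AREAS), function(p) {
        rlnorm_cv(1, BASELINE_AREAS[[p]] * mult[[PEPTIDE_CHAIN[[p]]]], spec$cv)
      }, numeric(1))
      variant_areas <- setNames(rep(0, nrow(VARIANT_INFO)),
                                VARIANT_INFO$peptide_id)
      for (vname in names(effect$variant_fractions)) {
        f <- effect$variant_fractions[[vname]]
        vi <- match(vname, VARIANT_INFO$variant_name)
        host <- VARIANT_INFO$host_peptide[vi]
        variant_areas[VARIANT_INFO$peptide_id[vi]] <-
          rlnorm_cv(1, f * areas[[host]], spec$cv)
        areas[[host]] <- areas[[host]] * (1 - f)
      }
      all_areas <- c(areas, variant_areas)
      # baseline electronic noise ~ 1/1000 of each channel's healthy area;
      # channels under the detection floor get noise = area so S/N = 1
      base_noise <- c(BASELINE_AREAS / 1000,
                      setNames(BASELINE_AREAS[VARIANT_INFO$host_peptide] / 1000,
                               VARIANT_INFO$peptide_id))
      noise <- pmax(base_noise[names(all_areas)],
                    ifelse(all_areas < spec$detection_floor, all_areas, 0))
      is_areas <- rlnorm_cv(length(all_areas), spec$is_area_mean, spec$is_cv)
      rows[[idx]] <- tibble(
        sample_id = sid,
        peptide_id = names(all_areas),
        area = unname(all_areas),
        is_area = is_areas,
        noise = unname(noise),
        age_days = age,
        genotype = effect$label
      )
    }
  }
  purrr::list_rbind(rows)
}

#' Truth labels of a generated cohort
#'
#' Convenience extractor: one row per sample with its generating genotype
#' label and the disease group it belongs to.
#'
#' @param peak_table A table from [generate_cohort()].
#' @return Tibble: `sample_id`, `genotype`, `group` (one of `normal`,
#'   `alpha_thalassemia`, `beta_thalassemia`, `alpha_and_beta_thalassemia`,
#'   `abnormal_hb`).
#' @export
cohort_truth <- function(peak_table) {
  labels <- dplyr::distinct(peak_table, .data$sample_id, .data$genotype)
  group_of <- function(g) {
    if (g == "normal") return("normal")
    has_alpha <- grepl("--SEA|-a3\\.7|-a4\\.2|a[A-Z]+a", g) && !grepl("^bN", g)
    has_beta <- grepl("bN/b", g)
    has_variant <- grepl("Hb[SEDG]", g)
    if (has_variant) return("abnormal_hb")
    if (has_alpha && has_beta) return("alpha_and_beta_thalassemia")
    if (has_beta) return("beta_thalassemia")
    "alpha_thalassemia"
  }
  labels$group <- vapply(labels$genotype, group_of, character(1))
  dplyr::arrange(labels, .data$sample_id)
}
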