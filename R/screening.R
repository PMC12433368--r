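#' Screening cutoff table
#'
#' The decision thresholds used to turn predicted probabilities and variant
#' ratios into screening calls. The shipped defaults are the optimized
#' screening cutoffs: call alpha-thalassemia when P(alpha) >= 0.33 and
#' beta-thalassemia when P(beta) >= 0.13; descriptive severity bands layer on
#' top of the alpha screen (alpha0-type deletions >= 0.66, the Southeast-Asian
#' --SEA double deletion >= 0.87, HbH disease >= 0.88); a structural variant
#' is flagged when its mutant/wild-type ratio exceeds its threshold (all
#' "> 0", i.e. mutant peptide detected, except Hb G-Coushatta at >= 2.19).
#'
#' The severity bands are descriptive, not diagnostic: genotype is unknown at
#' screening time, so the single probability pair drives the primary call and
#' the band only indicates which genotype class the probability is most
#' consistent with.
#'
#' `preset = "roc"` switches the screen thresholds to the un-rounded
#' ROC-derived decision points (0.329 / 0.126) reported alongside the rounded
#' table values; both are exposed because the source is ambiguous about which
#' was applied prospectively.
#'
#' @param preset `"reported"` (default; 0.33 / 0.13) or `"roc"`
#'   (0.329 / 0.126).
#' @param path Optional path to a cutoff JSON file; overrides `preset`.
#' @return A `hemo_cutoffs` object: list with `p_alpha_screen`,
#'   `p_beta_screen`, `severity_bands` (named, non-decreasing), and
#'   `variant_thresholds` (named; 0 means "detected at all").
#' @examples
#' default_cutoffs()
#' @export
default_cutoffs <- function(preset = c("reported", "roc"), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_cutoffs.json", package = "hemoscreen")
  }
  obj <- jsonlite::fromJSON(path)
  cut <- new_cutoffs(
    p_alpha_screen = obj$p_alpha_screen,
    p_beta_screen = obj$p_beta_screen,
    severity_bands = unlist(obj$severity_bands),
    variant_thresholds = unlist(obj$variant_thresholds)
  )
  preset <- match.arg(preset)
  if (preset == "roc") {
    cut$p_alpha_screen <- 0.329
    cut$p_beta_screen <- 0.126
  }
  cut
}

#' Construct a cutoff table
#'
#' @param p_alpha_screen,p_beta_screen Screen thresholds in (0, 1).
#' @param severity_bands Named numeric vector of P(alpha) severity
#'   thresholds (e.g. `alpha0`, `sea_deletion`, `hbh`), non-decreasing and
#'   all at or above `p_alpha_screen`.
#' @param variant_thresholds Named numeric vector, one per variant; 0 means
#'   "flag when the mutant peptide is detected at any positive ratio".
#' @return A `hemo_cutoffs` object.
#' @export
new_cutoffs <- function(p_alpha_screen, p_beta_screen,
                        severity_bands = numeric(0),
                        variant_thresholds = numeric(0)) {
  probs <- c(p_alpha_screen, p_beta_screen, severity_bands)
  if (any(probs <= 0) || any(probs >= 1)) {
    abort("probability thresholds must lie strictly between 0 and 1",
          class = "hemoscreen_config_error")
  }
  if (length(severity_bands) > 0) {
    bands <- c(screen = p_alpha_screen, severity_bands)
    if (is.unsorted(bands)) {
      abort("severity bands must be non-decreasing from the screen threshold",
            class = "hemoscreen_config_error")
    }
  }
  if (any(variant_thresholds < 0)) {
    abort("variant thresholds must be >= 0", class = "hemoscreen_config_error")
  }
  structure(list(p_alpha_screen = p_alpha_screen,
                 p_beta_screen = p_beta_screen,
                 severity_bands = severity_bands,
                 variant_thresholds = variant_thresholds),
            class = "hemo_cutoffs")
}

#' @export
print.hemo_cutoffs <- function(x, ...) {
  cat("<hemo_cutoffs> screen: P(alpha) >= ", x$p_alpha_screen,
      ", P(beta) >= ", x$p_beta_screen, "\n", sep = "")
  if (length(x$severity_bands)) {
    cat("  severity bands:",
        paste(names(x$severity_bands), ">=", x$severity_bands, collapse = "; "),
        "\n")
  }
  if (length(x$variant_thresholds)) {
    thr <- ifelse(x$variant_thresholds == 0, "> 0",
                  paste0(">= ", x$variant_thresholds))
    cat("  variants:", paste(names(x$variant_thresholds), thr, collapse = "; "),
        "\n")
  }
  invisible(x)
}

severity_band_of <- function(p_alpha, cutoffs) {
  if (is.na(p_alpha) || p_alpha < cutoffs$p_alpha_screen) return(NA_character_)
  bands <- sort(cutoffs$severity_bands)
  band <- "alpha_plus_range"
  labels <- c(alpha0 = "alpha0_range", sea_deletion = "sea_range",
              hbh = "hbh_range")
  # the highest band whose threshold is met
  for (nm in names(bands)) {
    if (p_alpha >= bands[[nm]]) band <- labels[[nm]] %||% nm
  }
  band
}

#' Classify one sample from its predictions and variant ratios
#'
#' Applies the cutoff table: the alpha and beta screen thresholds fire
#' independently (both firing yields the combined category), variant flags
#' fire independently of the thalassemia flags and are carried in
#' `variants_detected` whatever the category, and the severity band is the
#' highest band whose P(alpha) threshold is met. Missing probabilities
#' propagate to `non_evaluable`.
#'
#' @param p_alpha,p_beta Predicted probabilities in \[0, 1\] (or `NA`).
#' @param variant_ratios Named numeric vector of mutant/wild-type ratios.
#' @param cutoffs A `hemo_cutoffs` table.
#' @param sample_id Identifier carried into the result.
#' @param reason Optional upstream non-evaluability reason.
#' @return One-row tibble: `sample_id`, `p_alpha`, `p_beta`, `category`,
#'   `severity_band`, `variants_detected` (";"-separated), `reasons`.
#' @examples
#' classify_sample(0.90, 0.05, c("Hb S" = 0), default_cutoffs())
#' @export
classify_sample <- function(p_alpha, p_beta, variant_ratios = numeric(0),
                            cutoffs = default_cutoffs(), sample_id = NA_character_,
                            reason = NA_character_) {
  if (!is.na(reason) || is.na(p_alpha) || is.na(p_beta)) {
    return(tibble(sample_id = sample_id, p_alpha = p_alpha, p_beta = p_beta,
                  category = "non_evaluable", severity_band = NA_character_,
                  variants_detected = "",
                  reasons = reason %|na|% "missing prediction"))
  }
  if (p_alpha < 0 || p_alpha > 1 || p_beta < 0 || p_beta > 1) {
    abort("probabilities must lie in [0, 1]", class = "hemoscreen_input_error")
  }
  if (any(variant_ratios < 0, na.rm = TRUE)) {
    abort("variant ratios must be >= 0", class = "hemoscreen_input_error")
  }

  fired <- character(0)
  alpha_pos <- p_alpha >= cutoffs$p_alpha_screen
  beta_pos <- p_beta >= cutoffs$p_beta_screen
  if (alpha_pos) {
    fired <- c(fired, sprintf("P(alpha)=%.3f >= %.3g", p_alpha,
                              cutoffs$p_alpha_screen))
  }
  if (beta_pos) {
    fired <- c(fired, sprintf("P(beta)=%.3f >= %.3g", p_beta,
                              cutoffs$p_beta_screen))
  }

  variants <- character(0)
  for (vname in names(variant_ratios)) {
    r <- variant_ratios[[vname]]
    if (is.na(r)) next
    thr <- cutoffs$variant_thresholds[vname]
    thr <- if (is.na(thr)) 0 else unname(thr)
    hit <- if (thr == 0) r > 0 else r >= thr
    if (hit) {
      variants <- c(variants, vname)
      fired <- c(fired, sprintf("%s ratio %.3f %s", vname, r,
                                if (thr == 0) "> 0" else paste0(">= ", thr)))
    }
  }

  category <- if (alpha_pos && beta_pos) {
    "alpha_and_beta_thalassemia"
  } else if (alpha_pos) {
    "alpha_thalassemia"
  } else if (beta_pos) {
    "beta_thalassemia"
  } else if (length(variants) > 0) {
    "abnormal_hb"
  } else {
    "normal"
  }

  tibble(sample_id = sample_id, p_alpha = p_alpha, p_beta = p_beta,
         category = category,
         severity_band = severity_band_of(p_alpha, cutoffs),
         variants_detected = paste(variants, collapse = ";"),
         reasons = paste(fired, collapse = "; "))
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

#' Screen a quantified cohort
#'
#' Runs prediction and classification over a ratio-profile table: applies the
#' alpha and beta risk models, then the cutoff table, producing one screening
#' call per sample (non-evaluable samples are kept, never dropped) plus
#' summary counts per category.
#'
#' @param profiles Tibble from [quantify_cohort()].
#' @param model_alpha,model_beta `hemo_model` objects; default to the shipped
#'   models.
#' @param cutoffs A `hemo_cutoffs` table.
#' @return A `hemo_screen` object: list with `calls` (tibble ordered by
#'   `sample_id`) and `summary` (category counts).
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = "s1",
#'   peptide_id = c("aT1", "aT3", "bT1", "bT2", "gT10", "dT2", "zT8"),
#'   area = 500, is_area = 500
#' )
#' screen_cohort(quantify_cohort(tbl))
#' @export
screen_cohort <- function(profiles,
                          model_alpha = default_model("alpha"),
                          model_beta = default_model("beta"),
                          cutoffs = default_cutoffs()) {
  if (nrow(profiles) == 0) {
    calls <- classify_sample(NA, NA)[0, ]
    return(structure(list(calls = calls,
                          summary = tibble(category = character(0),
                                           n = integer(0))),
                     class = "hemo_screen"))
  }
  needed_a <- names(model_alpha$coefficients)
  needed_b <- names(model_beta$coefficients)

  calls <- purrr::map(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, ]
    reason <- if (!isTRUE(row$evaluable %||% TRUE)) {
      row$reason %||% "non-evaluable sample"
    } else {
      NA_character_
    }
    needed <- unique(c(needed_a, needed_b))
    have <- vapply(needed, function(r) is.finite(row[[r]] %||% NA_real_),
                   logical(1))
    if (is.na(reason) && !all(have)) {
      reason <- paste0("missing ratio(s): ",
                       paste(needed[!have], collapse = ", "))
    }
    if (!is.na(reason)) {
      return(classify_sample(NA_real_, NA_real_, cutoffs = cutoffs,
                             sample_id = row$sample_id, reason = reason))
    }
    pa <- predict_risk(row, model_alpha, col = ".pa")$.pa
    pb <- predict_risk(row, model_beta, col = ".pb")$.pb
    vr <- if ("variant_ratios" %in% names(row)) row$variant_ratios[[1]] else numeric(0)
    classify_sample(pa, pb, vr, cutoffs = cutoffs, sample_id = row$sample_id)
  }) |> purrr::list_rbind() |>
    dplyr::arrange(.data$sample_id)

  summary <- calls |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  structure(list(calls = calls, summary = summary), class = "hemo_screen")
}

#' @export
print.hemo_screen <- function(x, ...) {
  cat("<hemo_screen> ", nrow(x$calls), " samples\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Probability-plane plot of screening calls
#'
#' Scatter of P(beta) against P(alpha) colored by call category, with the
#' screen thresholds drawn as reference lines.
#'
#' @param object A `hemo_screen` result.
#' @param cutoffs Cutoff table used for the reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hemo_screen <- function(object, cutoffs = default_cutoffs(), ...) {
  df <- dplyr::filter(object$calls, .data$category != "non_evaluable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_alpha, y = .data$p_beta,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = cutoffs$p_alpha_screen, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cutoffs$p_beta_screen, linetype = "dashed") +
    ggplot2::labs(x = "P(alpha)", y = "P(beta)", colour = "call")
}
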