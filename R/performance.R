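#' Confusion matrix of binary calls against truth
#'
#' @param calls Predicted binary labels (0/1 or logical).
#' @param truth True binary labels, same length.
#' @return A `hemo_confusion` object: list with integer `tp`, `fp`, `fn`,
#'   `tn` (counts partition the cohort).
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_matrix <- function(calls, truth) {
  calls <- as.numeric(calls)
  truth <- as.numeric(truth)
  if (length(calls) != length(truth)) {
    abort("calls and truth must have the same length",
          class = "hemoscreen_input_error")
  }
  if (any(!calls %in% c(0, 1)) || any(!truth %in% c(0, 1))) {
    abort("calls and truth must be binary", class = "hemoscreen_input_error")
  }
  new_confusion(tp = sum(calls == 1 & truth == 1),
                fp = sum(calls == 1 & truth == 0),
                fn = sum(calls == 0 & truth == 1),
                tn = sum(calls == 0 & truth == 0))
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn Non-negative integer counts (for building a matrix
#'   directly from published counts).
#' @export
new_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers",
          class = "hemoscreen_input_error")
  }
  counts <- setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "hemo_confusion")
}

#' @export
print.hemo_confusion <- function(x, ...) {
  cat("<hemo_confusion> tp=", x$tp, " fp=", x$fp, " fn=", x$fn, " tn=", x$tn,
      "\n", sep = "")
  invisible(x)
}

# round half away from zero to `digits` places (matches how the clinical
# tables print percentages; R's round() would round half to even)
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Sensitivity and specificity of a confusion matrix
#'
#' Sensitivity = 100 tp/(tp+fn); specificity = 100 tn/(tn+fp), both reported
#' as percentages rounded half-up to two decimals. A zero denominator gives
#' `NA` (undefined metric), not an error.
#'
#' @param cm A `hemo_confusion`.
#' @return One-row tibble: `sensitivity`, `specificity` (percent).
#' @examples
#' sensitivity_specificity(new_confusion(44, 60, 20, 239)) # 68.75 / 79.93
#' @export
sensitivity_specificity <- function(cm) {
  stopifnot(inherits(cm, "hemo_confusion"))
  sens <- if (cm$tp + cm$fn > 0) round_half_up(100 * cm$tp / (cm$tp + cm$fn)) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) round_half_up(100 * cm$tn / (cm$tn + cm$fp)) else NA_real_
  tibble(sensitivity = sens, specificity = spec)
}

#' Youden index from percentage sensitivity and specificity
#'
#' J = sensitivity/100 + specificity/100 - 1, in \[-1, 1\].
#'
#' @param sensitivity,specificity Percentages in \[0, 100\].
#' @return J.
#' @examples
#' youden_index(97.50, 89.63) # 0.8713
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 100)) {
    abort("sensitivity and specificity must be percentages in [0, 100]",
          class = "hemoscreen_input_error")
  }
  sensitivity / 100 + specificity / 100 - 1
}

#' Coefficient of variation of replicate measurements
#'
#' 100 x sample standard deviation (n-1 denominator) / mean.
#'
#' @param x Numeric replicates (>= 2 values, non-zero mean).
#' @return CV in percent; `NA` when undefined.
#' @examples
#' coefficient_of_variation(c(9, 11)) # ~14.14
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || mean(x) == 0) return(NA_real_)
  100 * sd(x) / mean(x)
}

#' Carryover rate
#'
#' Signal carried from a high-concentration injection into the following
#' blank, as a percentage of the high signal; blank excess below the baseline
#' blank is clamped at zero.
#'
#' @param high_signal Peak area of the high-concentration sample (> 0).
#' @param following_blank_signal Peak area of the blank injected right after.
#' @param baseline_blank_signal Peak area of an independent blank.
#' @return Carryover in percent.
#' @examples
#' carryover_rate(1000, 15, 5) # 1
#' @export
carryover_rate <- function(high_signal, following_blank_signal,
                           baseline_blank_signal = 0) {
  if (any(high_signal <= 0)) {
    abort("high-concentration signal must be > 0",
          class = "hemoscreen_input_error")
  }
  100 * pmax(following_blank_signal - baseline_blank_signal, 0) / high_signal
}

#' Matrix effect
#'
#' Relative deviation (percent) of the response in matrix from the neat
#' (matrix-free) response.
#'
#' @param matrix_spiked_response Response of the analyte spiked into matrix.
#' @param neat_response Response of the analyte in neat solvent (> 0).
#' @return Absolute percent deviation.
#' @examples
#' matrix_effect(0.92, 1.00) # 8
#' @export
matrix_effect <- function(matrix_spiked_response, neat_response) {
  if (any(neat_response <= 0)) {
    abort("neat response must be > 0", class = "hemoscreen_input_error")
  }
  100 * abs(matrix_spiked_response / neat_response - 1)
}

#' Spike recovery
#'
#' Percentage of an added (spiked) amount recovered on top of the endogenous
#' level.
#'
#' @param measured_total Measured concentration after spiking.
#' @param endogenous Endogenous (pre-spike) concentration.
#' @param added Spiked amount (> 0).
#' @return Recovery in percent.
#' @examples
#' recovery_pct(18, 10, 10) # 80
#' @export
recovery_pct <- function(measured_total, endogenous, added) {
  if (any(added <= 0)) {
    abort("spiked amount must be > 0", class = "hemoscreen_input_error")
  }
  100 * (measured_total - endogenous) / added
}

#' Storage-stability flag for a ratio series
#'
#' A stored-sample ratio is considered stable under a condition when its CV
#' across the timepoints stays below 20%.
#'
#' @param x Ratio values over successive timepoints (>= 2).
#' @param cv_limit Stability limit in percent (default 20).
#' @return Logical; `NA` when the CV is undefined.
#' @examples
#' stability_flag(c(1.00, 1.04, 0.97))
#' @export
stability_flag <- function(x, cv_limit = 20) {
  cv <- coefficient_of_variation(x)
  if (is.na(cv)) return(NA)
  cv < cv_limit
}

#' Shipped clinical-performance reference counts
#'
#' Published validation-cohort confusion counts for the mass-spectrometry
#' screen and the capillary-electrophoresis comparator, per disorder
#' category (tp/fp/fn/tn against sequencing-confirmed truth). Useful for
#' recomputing the headline sensitivity/specificity figures.
#'
#' @return Tibble: `disorder`, `method`, `tp`, `fp`, `fn`, `tn`.
#' @export
clinical_performance_reference <- function() {
  readr::read_csv(system.file("extdata", "clinical_performance_counts.csv",
                              package = "hemoscreen"),
                  show_col_types = FALSE)
}

#' Shipped per-genotype detection reference counts
#'
#' Published per-genotype detection counts from the validation cohort: how
#' many sequencing-confirmed cases of each genotype each screening method
#' detected.
#'
#' @return Tibble: `disorder`, `genotype`, `total`, `detected_hplc_hrms`,
#'   `detected_sebia_ce`.
#' @export
genotype_detection_reference <- function() {
  readr::read_csv(system.file("extdata", "genotype_detection_counts.csv",
                              package = "hemoscreen"),
                  show_col_types = FALSE)
}

#' Per-genotype detection rates
#'
#' Detection rate (percent, two decimals) of each genotype by each method,
#' computed from detection counts.
#'
#' @param counts Tibble in the shape of [genotype_detection_reference()].
#' @return `counts` with `rate_hplc_hrms` and `rate_sebia_ce` columns.
#' @export
detection_rates <- function(counts = genotype_detection_reference()) {
  counts |>
    dplyr::mutate(
      rate_hplc_hrms = round_half_up(100 * .data$detected_hplc_hrms / .data$total),
      rate_sebia_ce = round_half_up(100 * .data$detected_sebia_ce / .data$total)
    )
}

#' Clinical performance summary from confusion counts
#'
#' Expands a table of per-category confusion counts into sensitivity,
#' specificity and Youden index per row.
#'
#' @param counts Tibble in the shape of [clinical_performance_reference()].
#' @return `counts` with `sensitivity`, `specificity`, `youden` columns.
#' @export
clinical_performance <- function(counts = clinical_performance_reference()) {
  metrics <- purrr::pmap(counts[c("tp", "fp", "fn", "tn")], function(tp, fp, fn, tn) {
    sensitivity_specificity(new_confusion(tp, fp, fn, tn))
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(counts, metrics)
  out$youden <- youden_index(out$sensitivity, out$specificity)
  out
}
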