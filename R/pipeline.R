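# Pipeline entry points behind the command-line wrapper
# (inst/scripts/hemoscreen.R). Each takes and returns file paths so a lab
# can run the stages from a shell; the heavy lifting stays in the exported
# tibble-first functions.

#' Simulate a synthetic cohort to disk
#'
#' Generates a genotype-stratified synthetic cohort and writes the peak-area
#' CSV plus a sidecar truth TSV (`<out>_truth.tsv`).
#'
#' @param out Output CSV path for the peak table.
#' @param strata Named vector of preset stratum sizes (see [cohort_spec()]).
#' @param seed Integer seed.
#' @param cv,is_cv Measurement CVs, percent.
#' @return Invisibly, a list with `peaks` and `truth` paths.
#' @export
run_simulate <- function(out, strata = c(normal = 200, sea_het = 50, beta0_het = 50),
                         seed, cv = 10, is_cv = 10) {
  spec <- cohort_spec(strata = strata, cv = cv, is_cv = is_cv, seed = seed)
  tbl <- generate_cohort(spec)
  write_peak_table(tbl, out)
  truth_path <- sub("\\.csv$", "", out)
  truth_path <- paste0(truth_path, "_truth.tsv")
  readr::write_tsv(cohort_truth(tbl), truth_path)
  invisible(list(peaks = out, truth = truth_path))
}

#' Quantify and screen a peak table from disk
#'
#' Runs quantification, risk prediction and classification over a peak-area
#' CSV, writing the calls TSV and a JSON summary (category counts plus the
#' configuration digest). Non-evaluable samples are listed in the calls with
#' their reason, never dropped.
#'
#' @param peak_path Input peak-area CSV.
#' @param out Output calls TSV path; the summary is written next to it as
#'   `<out>.summary.json`.
#' @param model_alpha_path,model_beta_path Optional model JSON paths
#'   (default: shipped models).
#' @param cutoffs_path Optional cutoff JSON path (default: shipped table).
#' @param is_path Optional internal-standard JSON path.
#' @return Invisibly, the `hemo_screen` result.
#' @export
run_screen <- function(peak_path, out,
                       model_alpha_path = NULL, model_beta_path = NULL,
                       cutoffs_path = NULL, is_path = NULL) {
  peaks <- read_peak_table(peak_path)
  model_a <- if (is.null(model_alpha_path)) default_model("alpha") else read_model(model_alpha_path)
  model_b <- if (is.null(model_beta_path)) default_model("beta") else read_model(model_beta_path)
  cutoffs <- if (is.null(cutoffs_path)) default_cutoffs() else read_cutoffs(cutoffs_path)
  is_cfg <- internal_standards(path = is_path)
  profiles <- quantify_cohort(peaks, is_config = is_cfg)
  result <- screen_cohort(profiles, model_a, model_b, cutoffs)
  write_calls(result$calls, out)
  summary <- list(
    n = nrow(result$calls),
    categories = setNames(as.list(result$summary$n), result$summary$category),
    non_evaluable = result$calls$sample_id[result$calls$category == "non_evaluable"],
    version = as.character(utils::packageVersion("hemoscreen"))
  )
  jsonlite::write_json(summary, paste0(out, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' Refit a risk model from a labeled peak table
#'
#' Quantifies the cohort, fits a logistic model for the requested target on
#' the target's standard ratio pair (alpha: `zT8_bT2` + `aT1_bT1`; beta:
#' `dT2_bT2` + `aT3_bT1`), and writes the fitted model JSON (readable by
#' [read_model()]) plus a ROC/Youden report TSV (`<out>.roc.tsv`).
#'
#' @param peak_path Input peak-area CSV with a `genotype` column.
#' @param truth_path Truth TSV (`sample_id`, `group`) as written by
#'   [run_simulate()]; the binary label is `group ==` the target disease.
#' @param target `"alpha"` or `"beta"`.
#' @param out Output model JSON path.
#' @return Invisibly, the `hemo_fit`.
#' @export
run_fit <- function(peak_path, truth_path, target = c("alpha", "beta"), out) {
  target <- match.arg(target)
  peaks <- read_peak_table(peak_path)
  truth <- readr::read_tsv(truth_path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_character()))
  profiles <- quantify_cohort(peaks)
  data <- dplyr::inner_join(profiles, truth, by = "sample_id")
  if (nrow(data) < nrow(profiles)) {
    abort("truth table does not cover every quantified sample",
          class = "hemoscreen_input_error")
  }
  features <- if (target == "alpha") c("zT8_bT2", "aT1_bT1") else c("dT2_bT2", "aT3_bT1")
  disease <- paste0(target, "_thalassemia")
  data$y <- as.integer(data$group %in%
                         c(disease, "alpha_and_beta_thalassemia"))
  data <- dplyr::filter(data, .data$evaluable)
  if (length(unique(data$y)) < 2) {
    abort("truth labels contain a single class; cannot fit",
          class = "hemoscreen_degenerate_error")
  }
  fit <- fit_logistic(data, features, "y", name = paste0("P_", target))
  write_model(fit$model, out)
  scores <- predict_risk(data, fit$model, col = ".p")$.p
  curve <- roc_curve(scores, data$y)
  write_roc_report(curve, paste0(out, ".roc.tsv"))
  invisible(fit)
}

#' Evaluate screening calls against truth
#'
#' Per disease group, builds the confusion matrix of calls against truth and
#' writes a TSV report with sensitivity, specificity and Youden index.
#'
#' @param calls_path Calls TSV (from [run_screen()]).
#' @param truth_path Truth TSV (`sample_id`, `group`).
#' @param out Output report TSV path.
#' @return Invisibly, the report tibble.
#' @export
run_evaluate <- function(calls_path, truth_path, out) {
  calls <- read_calls(calls_path)
  truth <- readr::read_tsv(truth_path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_character()))
  merged <- dplyr::inner_join(calls, truth, by = "sample_id")
  if (nrow(merged) != nrow(calls) || nrow(merged) != nrow(truth)) {
    abort("sample ids of calls and truth tables do not match",
          class = "hemoscreen_input_error")
  }
  groups <- c("alpha_thalassemia", "beta_thalassemia",
              "alpha_and_beta_thalassemia", "abnormal_hb")
  report <- purrr::map(groups, function(g) {
    pred <- as.integer(merged$category == g |
                         (g %in% c("alpha_thalassemia", "beta_thalassemia") &
                            merged$category == "alpha_and_beta_thalassemia"))
    tru <- as.integer(merged$group == g |
                        (g %in% c("alpha_thalassemia", "beta_thalassemia") &
                           merged$group == "alpha_and_beta_thalassemia"))
    if (sum(tru) == 0) return(NULL)
    cm <- confusion_matrix(pred, tru)
    ss <- sensitivity_specificity(cm)
    tibble(group = g, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
           sensitivity = ss$sensitivity, specificity = ss$specificity,
           youden = youden_index(ss$sensitivity, ss$specificity))
  }) |> purrr::list_rbind()
  readr::write_tsv(report, out)
  invisible(report)
}
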