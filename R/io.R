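#' Read and write peak-area tables
#'
#' The pipeline's on-disk exchange format: CSV, UTF-8, header row, dot
#' decimal separator, columns `sample_id, peptide_id, area, is_area, noise,
#' age_days, genotype` (the last three optional; empty cells allowed).
#'
#' @param path File path.
#' @param peak_table Tibble to write.
#' @return `read_peak_table` returns a tibble; `write_peak_table` returns
#'   `path` invisibly.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("peak table not found: ", path),
          class = "hemoscreen_input_error")
  }
  spec <- list(sample_id = readr::col_character(),
               peptide_id = readr::col_character(),
               area = readr::col_double(),
               is_area = readr::col_double(),
               noise = readr::col_double(),
               age_days = readr::col_integer(),
               genotype = readr::col_character())
  present <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  tbl <- readr::read_csv(
    path,
    col_types = do.call(readr::cols,
                        c(spec[intersect(names(spec), present)],
                          .default = list(readr::col_guess())))
  )
  required <- c("sample_id", "peptide_id", "area", "is_area")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("peak table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hemoscreen_input_error")
  }
  tbl
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(peak_table, path) {
  cols <- intersect(c("sample_id", "peptide_id", "area", "is_area", "noise",
                      "age_days", "genotype"), names(peak_table))
  readr::write_csv(peak_table[cols], path)
  invisible(path)
}

#' Read and write screening-call tables
#'
#' Calls are exchanged as TSV with columns `sample_id, p_alpha, p_beta,
#' category, severity_band, variants_detected, reasons`.
#'
#' @param calls Calls tibble (from [screen_cohort()]`$calls`).
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("calls table not found: ", path),
          class = "hemoscreen_input_error")
  }
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    p_alpha = readr::col_double(),
    p_beta = readr::col_double(),
    category = readr::col_character(),
    severity_band = readr::col_character(),
    variants_detected = readr::col_character(),
    reasons = readr::col_character()
  ))
}

#' Read and write cutoff tables as JSON
#'
#' @param cutoffs A `hemo_cutoffs` object.
#' @param path File path.
#' @return The cutoffs (read) or `path` invisibly (write).
#' @export
write_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "hemo_cutoffs"))
  jsonlite::write_json(
    list(p_alpha_screen = cutoffs$p_alpha_screen,
         p_beta_screen = cutoffs$p_beta_screen,
         severity_bands = as.list(cutoffs$severity_bands),
         variant_thresholds = as.list(cutoffs$variant_thresholds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  default_cutoffs(path = path)
}
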