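#' Shipped logistic risk models for alpha- and beta-thalassemia
#'
#' The two binary logistic models that turn globin-chain ratios into a
#' predicted probability of disease:
#' \deqn{P(\alpha) = \mathrm{logit}^{-1}(30.444\,\zeta T8/\beta T2
#'   - 1.030\,\alpha T1/\beta T1 + 1.771)}
#' \deqn{P(\beta) = \mathrm{logit}^{-1}(105.132\,\delta T2/\beta T2
#'   + 0.388\,\alpha T3/\beta T1 - 13.195)}
#' The alpha model rises with the embryonic zeta-chain ratio and falls with
#' the alpha/beta ratio; the beta model rises steeply with the delta/beta
#' ratio.
#'
#' @param target `"alpha"` or `"beta"`.
#' @param path Optional path to a model JSON file
#'   (`{name, intercept, coefficients}`); overrides `target`.
#' @return A `hemo_model` object: list with `name`, `intercept`, and named
#'   `coefficients`.
#' @examples
#' default_model("alpha")
#' @export
default_model <- function(target = c("alpha", "beta"), path = NULL) {
  if (is.null(path)) {
    target <- match.arg(target)
    path <- system.file("extdata", paste0("p_", target, ".json"),
                        package = "hemoscreen")
  }
  read_model(path)
}

#' Read / write a prediction model
#'
#' Models are stored as JSON objects `{name, intercept, coefficients}` where
#' `coefficients` maps ratio names to real slopes.
#'
#' @param path File path.
#' @param model A `hemo_model` object (for writing).
#' @return `read_model` returns a `hemo_model`; `write_model` returns `path`
#'   invisibly.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_model(obj$name, obj$intercept, unlist(obj$coefficients))
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hemo_model"))
  jsonlite::write_json(
    list(name = model$name, intercept = model$intercept,
         coefficients = as.list(model$coefficients)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a prediction model
#'
#' @param name Model name, e.g. `"P_alpha"`.
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector of slopes; names must be valid
#'   ratio names (see [ratio_names()]).
#' @return A `hemo_model` object.
#' @export
new_model <- function(name, intercept, coefficients) {
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    abort("model intercept must be a single finite number",
          class = "hemoscreen_config_error")
  }
  bad <- setdiff(names(coefficients), ratio_names())
  if (length(bad) > 0) {
    abort(paste0("unknown ratio name(s) in model coefficients: ",
                 paste(bad, collapse = ", ")),
          class = "hemoscreen_config_error")
  }
  structure(list(name = name, intercept = unname(intercept),
                 coefficients = coefficients),
            class = "hemo_model")
}

#' @export
print.hemo_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat("<hemo_model> ", x$name, ": logit(p) = ",
      sprintf("%.4g ", x$intercept), terms, "\n", sep = "")
  invisible(x)
}

# Overflow-safe inverse logit: exp() is only ever taken of a non-positive
# argument, so slopes like 105.132 cannot overflow.
inv_logit <- function(eta) {
  out <- numeric(length(eta))
  pos <- !is.na(eta) & eta >= 0
  out[pos] <- 1 / (1 + exp(-eta[pos]))
  neg <- !is.na(eta) & eta < 0
  out[neg] <- exp(eta[neg]) / (1 + exp(eta[neg]))
  out[is.na(eta)] <- NA_real_
  out
}

#' Predict disease probability from ratio profiles
#'
#' Applies a logistic risk model to a ratio-profile table, adding a
#' probability column. Samples missing any ratio the model references get an
#' `NA` prediction (propagated, never silently zero).
#'
#' @param profiles Tibble from [quantify_cohort()], or any data frame holding
#'   the model's ratio columns.
#' @param model A `hemo_model`.
#' @param col Name of the output probability column (default derived from
#'   the model name, e.g. `p_alpha`).
#' @return `profiles` with the probability column appended.
#' @examples
#' profiles <- tibble::tibble(aT1_bT1 = c(4.5, 2.0), zT8_bT2 = c(0.002, 0.1))
#' predict_risk(profiles, default_model("alpha"))
#' @export
predict_risk <- function(profiles, model, col = NULL) {
  stopifnot(inherits(model, "hemo_model"))
  col <- col %||% tolower(gsub("[()]", "", sub("^P", "p", model$name)))
  needed <- names(model$coefficients)
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("profiles are missing ratio column(s) required by ", model$name,
                 ": ", paste(missing_cols, collapse = ", ")),
          class = "hemoscreen_input_error")
  }
  x <- as.matrix(profiles[needed])
  eta <- model$intercept + drop(x %*% model$coefficients)
  profiles[[col]] <- inv_logit(eta)
  as_tibble(profiles)
}
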