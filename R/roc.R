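#' ROC curve of a score against binary truth
#'
#' Builds the empirical receiver operating characteristic curve. Thresholds
#' are the distinct observed scores plus `-Inf`/`+Inf` sentinels; a sample is
#' called positive when its score is greater than or equal to the threshold
#' (matching the ">=" convention of the screening cutoff table), so
#' sensitivity is non-increasing in the threshold.
#'
#' @param scores Numeric scores (higher = more disease-like).
#' @param labels Binary truth (0/1 or logical), same length.
#' @return A `hemo_roc` tibble with columns `threshold`, `sensitivity`,
#'   `specificity`, and attributes `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length",
          class = "hemoscreen_input_error")
  }
  if (any(!labels %in% c(0, 1))) {
    abort("labels must be binary", class = "hemoscreen_input_error")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to build a ROC curve",
          class = "hemoscreen_degenerate_error")
  }
  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thresholds,
                 function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds,
                 function(t) sum(scores < t & labels == 0) / n_neg,
                 numeric(1))
  out <- tibble(threshold = thresholds, sensitivity = sens, specificity = spec)
  structure(out, class = c("hemo_roc", class(out)),
            n_pos = n_pos, n_neg = n_neg)
}

#' Area under a ROC curve
#'
#' Trapezoidal area in (1 - specificity, sensitivity) space. For curves from
#' [roc_curve()] this equals the Mann-Whitney concordance: the fraction of
#' (positive, negative) score pairs where the positive scores higher,
#' counting ties as one half.
#'
#' @param curve A `hemo_roc` object.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "hemo_roc"))
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Maximizes the Youden index J = sensitivity + specificity - 1 over the
#' curve's thresholds. Ties are broken toward higher sensitivity (a screening
#' assay penalizes false negatives), then toward the lower threshold.
#'
#' @param curve A `hemo_roc` object.
#' @return One-row tibble: `cutoff`, `youden`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "hemo_roc"))
  finite <- is.finite(curve$threshold)
  cand <- curve[finite | curve$threshold == -Inf, ]
  j <- cand$sensitivity + cand$specificity - 1
  ord <- order(-j, -cand$sensitivity, cand$threshold)
  best <- ord[1]
  tibble(cutoff = cand$threshold[best], youden = j[best],
         sensitivity = cand$sensitivity[best],
         specificity = cand$specificity[best])
}

#' Select candidate ratio biomarkers by AUC
#'
#' Screens each candidate ratio for discriminative value: a ratio is oriented
#' so its AUC is at least 0.5 (a ratio that falls in disease is as useful as
#' one that rises) and kept when the oriented AUC exceeds the threshold.
#'
#' @param ratio_table Data frame of candidate ratio columns (complete cases).
#' @param labels Binary truth vector.
#' @param ratios Character vector of columns to test; defaults to every
#'   [ratio_names()] column present.
#' @param threshold AUC selection threshold (default 0.850).
#' @return Tibble of all candidates: `ratio`, `auc` (oriented), `direction`
#'   (`"increases"`/`"decreases"` in disease), `selected`.
#' @export
select_candidates <- function(ratio_table, labels,
                              ratios = intersect(ratio_names(), names(ratio_table)),
                              threshold = 0.850) {
  res <- purrr::map(ratios, function(r) {
    v <- ratio_table[[r]]
    if (any(is.na(v))) {
      abort(paste0("candidate ratio '", r, "' has missing values"),
            class = "hemoscreen_input_error")
    }
    a <- roc_auc(roc_curve(v, labels))
    tibble(ratio = r,
           auc = max(a, 1 - a),
           direction = if (a >= 0.5) "increases" else "decreases")
  }) |> purrr::list_rbind()
  res$selected <- res$auc > threshold
  dplyr::arrange(res, dplyr::desc(.data$auc))
}

#' Plot a ROC curve
#'
#' @param object A `hemo_roc`.
#' @param mark_youden Mark the Youden-optimal operating point.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hemo_roc <- function(object, mark_youden = TRUE, ...) {
  df <- tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", roc_auc(object)))
  if (mark_youden) {
    yc <- youden_cutoff(object)
    p <- p + ggplot2::annotate("point", x = 1 - yc$specificity,
                               y = yc$sensitivity, colour = "red") +
      ggplot2::annotate("text", x = 1 - yc$specificity, y = yc$sensitivity,
                        label = sprintf(" cutoff %.3g (J=%.2f)",
                                        yc$cutoff, yc$youden),
                        hjust = 0, vjust = 1, size = 3)
  }
  p
}

#' Write a ROC curve report as TSV
#'
#' Columns: threshold, sensitivity, specificity, youden.
#'
#' @param curve A `hemo_roc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_report <- function(curve, path) {
  stopifnot(inherits(curve, "hemo_roc"))
  df <- as_tibble(curve)
  df$youden <- df$sensitivity + df$specificity - 1
  readr::write_tsv(df, path)
  invisible(path)
}
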