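#' Fit a binary logistic risk model by IRLS
#'
#' Maximum-likelihood logistic regression implemented in this package via
#' iteratively reweighted least squares (IRLS). Convergence is declared when
#' the largest parameter change drops below `tol`; a tiny ridge is added to
#' the weighted normal equations for numerical stability. Complete or
#' quasi-complete separation (coefficients running away) is reported through
#' `separation_flag` rather than an error, since separated data still yield a
#' usable — if degenerate — classifier.
#'
#' @param data Data frame holding the feature columns and the response.
#' @param features Character vector of feature column names (ratio names).
#' @param response Name of the 0/1 (or logical) response column.
#' @param name Name recorded on the resulting model.
#' @param tol Convergence tolerance on the max absolute parameter change
#'   (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param ridge Ridge added to the diagonal of the weighted normal equations
#'   (default 1e-8).
#' @param divergence_guard Coefficient magnitude beyond which separation is
#'   flagged (default 1e4).
#' @return A `hemo_fit` object: `model` (a [new_model()] object),
#'   `log_likelihood`, `converged`, `iterations`, `standard_errors`,
#'   `separation_flag`, plus the per-iteration log-likelihood trace.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(dT2_bT2 = runif(200, 0, 0.2))
#' d$y <- rbinom(200, 1, plogis(-4 + 40 * d$dT2_bT2))
#' fit_logistic(d, "dT2_bT2", "y")
#' @export
fit_logistic <- function(data, features, response, name = "fitted",
                         tol = 1e-8, max_iter = 100, ridge = 1e-8,
                         divergence_guard = 1e4) {
  x <- as.matrix(data[features])
  if (any(!is.finite(x))) {
    abort("features must be complete and finite", class = "hemoscreen_input_error")
  }
  y <- as.numeric(data[[response]])
  if (!all(y %in% c(0, 1))) {
    abort("response must be binary (0/1 or logical)",
          class = "hemoscreen_input_error")
  }
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    abort("need at least 2 samples in each class to fit",
          class = "hemoscreen_degenerate_error")
  }

  design <- cbind(`(Intercept)` = 1, x)
  p <- ncol(design)
  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- drop(design %*% b)
    # log(1+exp(eta)) computed stably
    sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
  }
  ll_trace <- loglik(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(design %*% beta)
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / pmax(w, .Machine$double.eps)
    xtw <- t(design * w)
    a <- xtw %*% design + diag(ridge, p)
    beta_new <- drop(solve(a, xtw %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_trace <- c(ll_trace, loglik(beta))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  eta <- drop(design %*% beta)
  mu <- inv_logit(eta)
  w <- mu * (1 - mu)
  info <- t(design * w) %*% design
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  names(se) <- colnames(design)
  # complete/quasi-complete separation: the fitted probabilities sit on the
  # labels (IRLS stalls on the ridge long before beta reaches the guard)
  separation <- max(abs(beta)) > divergence_guard || all(abs(y - mu) < 1e-5)

  coefs <- setNames(beta[-1], features)
  structure(list(
    model = new_model(name, beta[1], coefs),
    log_likelihood = ll_trace[length(ll_trace)],
    ll_trace = ll_trace,
    converged = converged,
    iterations = iter,
    standard_errors = se,
    separation_flag = separation,
    n = length(y),
    n_pos = sum(y == 1)
  ), class = "hemo_fit")
}

#' @export
print.hemo_fit <- function(x, ...) {
  cat("<hemo_fit> logistic model '", x$model$name, "' on n = ", x$n,
      " (", x$n_pos, " positive)\n", sep = "")
  print(tidy(x))
  cat(sprintf("log-likelihood %.4f; %s in %d iterations%s\n",
              x$log_likelihood,
              if (x$converged) "converged" else "did NOT converge",
              x$iterations,
              if (x$separation_flag) "; SEPARATION flagged" else ""))
  invisible(x)
}

#' Tidy a fitted logistic risk model
#'
#' @param x A `hemo_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z), `p.value`.
#' @export
tidy.hemo_fit <- function(x, ...) {
  est <- c(x$model$intercept, x$model$coefficients)
  names(est)[1] <- "(Intercept)"
  z <- est / x$standard_errors
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$standard_errors),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' One-row fit summary
#'
#' @param x A `hemo_fit` object.
#' @param ... Unused.
#' @return Tibble with `log_likelihood`, `converged`, `iterations`,
#'   `separation_flag`, `n`, `n_pos`.
#' @export
glance.hemo_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    converged = x$converged,
    iterations = x$iterations,
    separation_flag = x$separation_flag,
    n = x$n,
    n_pos = x$n_pos
  )
}

#' Coefficient plot for a fitted risk model
#'
#' @param object A `hemo_fit`.
#' @param ... Unused.
#' @return A ggplot: point estimates with Wald 95% intervals.
#' @export
autoplot.hemo_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "coefficient (logit scale)", y = NULL,
                  title = paste0("Logistic model '", object$model$name, "'"))
}
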