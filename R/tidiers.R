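#' Tidy a fitted sparse-testing model
#'
#' One row per variance component with its posterior mean, posterior
#' standard deviation and effective sample size.
#'
#' @param x An `"smet_fit"` from [fit_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `ess`.
#' @export
tidy.smet_fit <- function(x, ...) {
  tibble::tibble(term = x$diagnostics$term,
                 estimate = x$diagnostics$posterior_mean,
                 std.error = x$diagnostics$posterior_sd,
                 ess = x$diagnostics$ess)
}

#' Glance at a fitted sparse-testing model
#'
#' @param x An `"smet_fit"` from [fit_model()].
#' @param ... Unused.
#' @return A one-row tibble: `model`, `mu_hat`, `pct_unexplained`,
#'   `n_train`, `n_iter`, `min_ess`.
#' @export
glance.smet_fit <- function(x, ...) {
  tibble::tibble(model = x$model, mu_hat = x$mu_hat,
                 pct_unexplained = x$pct_unexplained,
                 n_train = x$n_train, n_iter = x$config$n_iter,
                 min_ess = min(x$diagnostics$ess))
}

#' Plot predictive ability over the design grid
#'
#' Mean within-environment Pearson correlation (averaged over
#' environments, then repetitions) against the overlapping count `O`, one
#' line per model, with a mean +/- 1 sd band over repetitions; faceted by
#' per-environment sample size when several are present.
#'
#' @param object An `"smet_cv_summary"` from [summarize_cv()].
#' @param metric `"accuracy"` (mean Pearson r) or `"unexplained"`
#'   (mean residual-variance percentage).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smet_cv_summary <- function(object, metric = c("accuracy", "unexplained"),
                                     ...) {
  metric <- match.arg(metric)
  if (metric == "accuracy") {
    y <- "mean_r"; s <- "sd_r"; lab <- "Mean Pearson correlation"
  } else {
    y <- "mean_pct_unexplained"; s <- "sd_pct_unexplained"
    lab <- "Unexplained variance (%)"
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$o, y = .data[[y]], colour = .data$model, fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[y]] - .data[[s]],
                                      ymax = .data[[y]] + .data[[s]]),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Overlapping genotypes (O)", y = lab,
                  colour = "Model", fill = "Model") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$sample_size) > 1) {
    p <- p + ggplot2::facet_wrap(~sample_size)
  }
  p
}
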