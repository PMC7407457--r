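#' Within-environment predictive ability
#'
#' Pearson correlation between observed BLUEs and predicted values over
#' the prediction cells of one environment. An undefined correlation
#' (fewer than 3 cells with data, or zero variance in either vector) is
#' returned as `NA` with a warning — never silently coerced to 0.
#'
#' @param observed Tibble `env`, `genotype`, `blue`.
#' @param predicted Tibble `env`, `genotype`, `predicted` (e.g.
#'   `fit$cell_predictions`).
#' @param prediction_cells Tibble `env`, `genotype` delimiting the cells
#'   to score (e.g. `design$prediction_cells`).
#' @param env Environment ID.
#' @return A single correlation (or `NA_real_`).
#' @export
pearson_by_env <- function(observed, predicted, prediction_cells, env) {
  cells <- dplyr::filter(prediction_cells, .data$env == !!env)
  df <- cells |>
    dplyr::inner_join(observed, by = c("env", "genotype")) |>
    dplyr::inner_join(dplyr::select(predicted, "env", "genotype", "predicted"),
                      by = c("env", "genotype"))
  if (nrow(df) < 3) {
    warn(sprintf("Fewer than 3 scorable prediction cells in '%s': correlation undefined.", env))
    return(NA_real_)
  }
  if (sd(df$blue) == 0 || sd(df$predicted) == 0) {
    warn(sprintf("Zero variance in observed or predicted values in '%s': correlation undefined.", env))
    return(NA_real_)
  }
  cor(df$blue, df$predicted)
}

#' Repetition-by-design-by-model cross-validation
#'
#' The complete BLUE table over the full environment-by-genotype factorial
#' is treated as ground truth; for each repetition and each design of the
#' grid, the prediction cells are masked, each model is fitted on the
#' calibration cells, and the masked cells are predicted and scored per
#' environment. Repetition `r` builds its allocation with seed
#' `base_seed + r`; each model fit gets its own derived RNG stream so a
#' failed fit does not shift later draws. A failed fit is recorded
#' (message) and skipped; the run continues.
#'
#' @param blues Complete BLUE tibble (`env`, `genotype`, `blue`) covering
#'   every cell of the factorial.
#' @param grm Genomic relationship matrix.
#' @param grid Design grid tibble (`sample_size`, `no`, `o`) from
#'   [enumerate_grid()], or any tibble with those columns.
#' @param models Character subset of `c("M1", "M2", "M3")`.
#' @param n_reps Random repetitions (default 25).
#' @param base_seed Base integer seed.
#' @param config [gibbs_config()] used for every fit (its `seed` field is
#'   overridden per fit).
#' @param progress Print a line per design (default `FALSE`).
#' @return Tibble of class `"smet_cv"`: one row per
#'   (rep, design, model, environment) with `pearson_r`,
#'   `pct_unexplained` and the fitted variance components.
#' @export
run_cv <- function(blues, grm, grid, models = c("M1", "M2", "M3"),
                   n_reps = 25, base_seed = 1L, config = gibbs_config(),
                   progress = FALSE) {
  stopifnot(all(models %in% c("M1", "M2", "M3")),
            all(c("sample_size", "no", "o") %in% names(grid)))
  envs <- unique(blues$env)
  genos <- unique(blues$genotype)
  n_envs <- length(envs)

  records <- list()
  for (rep_i in seq_len(n_reps)) {
    for (d in seq_len(nrow(grid))) {
      design <- make_design(genos, n_envs, grid$no[d], grid$o[d],
                            seed = base_seed + rep_i, env_ids = envs)
      if (progress) {
        inform(sprintf("rep %d design %d/%d (%d/%d)", rep_i, d, nrow(grid),
                       grid$no[d], grid$o[d]))
      }
      for (m in seq_along(models)) {
        fit_seed <- (base_seed + rep_i * 1000L + d * 10L + m) %% 2147483647L
        cfg <- config
        cfg$seed <- as.integer(fit_seed)
        rec <- tryCatch({
          kern <- build_kernels(blues, grm, design, models[m])
          fit <- suppressWarnings(fit_model(kern, cfg))
          r_env <- vapply(envs, function(ev) {
            suppressWarnings(pearson_by_env(blues, fit$cell_predictions,
                                            design$prediction_cells, ev))
          }, numeric(1))
          vc <- as.list(fit$varcomps)
          names(vc) <- names(fit$varcomps)
          tibble::tibble(rep = rep_i, sample_size = grid$sample_size[d],
                         no = grid$no[d], o = grid$o[d], model = models[m],
                         env = envs, pearson_r = r_env,
                         pct_unexplained = fit$pct_unexplained,
                         !!!vc)
        }, error = function(e) {
          inform(sprintf("fit skipped (rep %d, %d/%d, %s): %s", rep_i,
                         grid$no[d], grid$o[d], models[m], conditionMessage(e)))
          NULL
        })
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("smet_cv", class(out))
  out
}

#' Summarise a cross-validation run
#'
#' For every (sample size, NO/O, model): the per-repetition accuracy is
#' first averaged over environments, then the mean and standard deviation
#' are taken over repetitions (matching the convention of averaging
#' Pearson correlations across environments and reporting the spread over
#' random partitions). Undefined correlations are excluded from the
#' environment average, with the number of missing values reported.
#'
#' @param result An `"smet_cv"` tibble from [run_cv()].
#' @return Tibble of class `"smet_cv_summary"` keyed by
#'   (`sample_size`, `no`, `o`, `model`) with `mean_r`, `sd_r`,
#'   `mean_pct_unexplained`, `sd_pct_unexplained`, `n_reps`, `n_missing_r`.
#' @export
summarize_cv <- function(result) {
  if (nrow(result) == 0) {
    abort("Empty cross-validation result.", class = "smet_config_error")
  }
  per_rep <- result |>
    dplyr::group_by(.data$sample_size, .data$no, .data$o, .data$model,
                    .data$rep) |>
    dplyr::summarise(
      r_bar = mean(.data$pearson_r, na.rm = TRUE),
      n_missing_r = sum(is.na(.data$pearson_r)),
      pct_unexplained = mean(.data$pct_unexplained),
      .groups = "drop")
  out <- per_rep |>
    dplyr::group_by(.data$sample_size, .data$no, .data$o, .data$model) |>
    dplyr::summarise(
      mean_r = mean(.data$r_bar, na.rm = TRUE),
      sd_r = sd(.data$r_bar, na.rm = TRUE),
      mean_pct_unexplained = mean(.data$pct_unexplained),
      sd_pct_unexplained = sd(.data$pct_unexplained),
      n_reps = dplyr::n(),
      n_missing_r = sum(.data$n_missing_r),
      .groups = "drop") |>
    dplyr::mutate(sd_r = dplyr::coalesce(.data$sd_r, 0),
                  sd_pct_unexplained = dplyr::coalesce(.data$sd_pct_unexplained, 0))
  class(out) <- c("smet_cv_summary", class(out))
  out
}

#' Lay a CV summary out as a Table-1-style grid
#'
#' One row per (model, sample size), one column per NO/O composition.
#'
#' @param summary An `"smet_cv_summary"` tibble.
#' @param value Which summary column to spread (default `"mean_r"`).
#' @return A wide tibble with `model`, `sample_size` and one `NO/O` column
#'   per design.
#' @export
summary_grid <- function(summary, value = "mean_r") {
  summary |>
    dplyr::mutate(design = sprintf("%d/%d", .data$no, .data$o)) |>
    dplyr::select("model", "sample_size", "design", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "design", values_from = dplyr::all_of(value))
}
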