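#' Gibbs sampler configuration
#'
#' Chain and prior settings for [fit_model()]. Variance components get
#' scaled-inverse-chi-square priors with `prior_df` degrees of freedom;
#' the prior modes split `prior_R2` of the phenotypic variance equally
#' among the non-residual kernels, with the remaining `1 - prior_R2`
#' assigned to the residual — the conventional weakly-informative default
#' for Bayesian kernel regression.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before accumulating posterior means.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param prior_df Prior degrees of freedom for every variance component.
#' @param prior_R2 Prior proportion of phenotypic variance assigned to the
#'   non-residual terms jointly, in `(0, 1)`.
#' @param seed Integer seed for the chain.
#' @return List of class `"gibbs_config"`.
#' @export
gibbs_config <- function(n_iter = 12000, burn_in = 2000, thin = 5,
                         prior_df = 5, prior_R2 = 0.5, seed = 1L) {
  stopifnot(is_count(n_iter), is_count(burn_in, 0), is_count(thin),
            burn_in < n_iter, prior_df > 0)
  if (!(prior_R2 > 0 && prior_R2 < 1)) {
    abort("`prior_R2` must be in (0, 1).", class = "smet_config_error")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior_df = prior_df,
                 prior_R2 = prior_R2, seed = as.integer(seed)),
            class = "gibbs_config")
}

model_kernel_labels <- function(model) {
  switch(model,
         M1 = c("E", "L"),
         M2 = c("E", "L", "G"),
         M3 = c("E", "L", "G", "GE"),
         abort(sprintf("Unknown model '%s' (expected M1, M2 or M3).", model),
               class = "smet_config_error"))
}

#' Build cell-level covariance kernels for a model on a design
#'
#' Assembles the random-effect covariance matrices over the concatenation
#' of calibration and prediction cells of an allocation design:
#' * `E`  — environment main effect, `Z_E Z_E'` (1 iff same environment);
#' * `L`  — iid line main effect, `Z_g Z_g'` (1 iff same genotype);
#' * `G`  — genomic main effect, `Z_g G Z_g'`;
#' * `GE` — genotype-by-environment interaction,
#'   `(Z_g G Z_g') ∘ (Z_E Z_E')`, the Hadamard (elementwise) product of
#'   the genomic and environment kernels.
#'
#' Model M1 uses `{E, L}`, M2 `{E, L, G}`, M3 `{E, L, G, GE}`.
#'
#' @param blues Tibble with columns `env`, `genotype`, `blue`: the observed
#'   per-environment genotype means. Every calibration cell of the design
#'   must have a BLUE.
#' @param grm Genomic relationship matrix with genotype IDs as dimnames
#'   (from [compute_grm()]). Required for M2/M3; may be `NULL` for M1.
#' @param design An [make_design()] allocation.
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @return List of class `"smet_kernels"`: `cells` (tibble `env`,
#'   `genotype`, `set`, `observed`, calibration rows first), `K` (named
#'   list of cell-level kernel matrices), `n_train`, and `model`.
#' @export
build_kernels <- function(blues, grm, design, model = c("M3", "M2", "M1")) {
  model <- match.arg(model)
  labels <- model_kernel_labels(model)
  stopifnot(inherits(design, "smet_design"))

  cells <- dplyr::bind_rows(
    dplyr::mutate(design$calibration_cells, set = "calibration"),
    dplyr::mutate(design$prediction_cells, set = "prediction"))
  cells <- dplyr::left_join(cells, blues, by = c("env", "genotype")) |>
    dplyr::rename(observed = "blue")
  miss <- cells$set == "calibration" & is.na(cells$observed)
  if (any(miss)) {
    abort(sprintf("%d calibration cell(s) have no BLUE (first: %s / %s).",
                  sum(miss), cells$env[miss][1], cells$genotype[miss][1]),
          class = "smet_id_mismatch_error")
  }

  same_env <- outer(cells$env, cells$env, "==") * 1
  same_gen <- outer(cells$genotype, cells$genotype, "==") * 1
  K <- list(E = same_env, L = same_gen)
  if (any(c("G", "GE") %in% labels)) {
    if (is.null(grm)) {
      abort("Model requires a genomic relationship matrix (`grm`).",
            class = "smet_config_error")
    }
    absent <- setdiff(unique(cells$genotype), rownames(grm))
    if (length(absent) > 0) {
      abort(sprintf("%d genotype(s) missing from the GRM (first: %s).",
                    length(absent), absent[1]),
            class = "smet_id_mismatch_error")
    }
    idx <- match(cells$genotype, rownames(grm))
    Kg <- grm[idx, idx]
    K$G <- Kg
    if ("GE" %in% labels) K$GE <- Kg * same_env
  }
  K <- K[labels]
  structure(list(cells = cells, K = K, model = model,
                 n_train = sum(cells$set == "calibration")),
            class = "smet_kernels")
}

#' Percentage of unexplained (residual) variance
#'
#' `100 * var_e / (sum of all fitted variance components including var_e)`.
#'
#' @param varcomps Named numeric vector of variance components containing
#'   `var_e` (e.g. `c(var_E = .2, var_L = .1, var_e = .3)`).
#' @return A percentage in `[0, 100]`.
#' @export
#' @examples
#' pct_unexplained(c(var_E = 3, var_L = 6, var_e = 1))  # 10
pct_unexplained <- function(varcomps) {
  if (!("var_e" %in% names(varcomps))) {
    abort("`varcomps` must contain a `var_e` entry.",
          class = "smet_config_error")
  }
  tot <- sum(varcomps)
  if (tot <= 0) {
    abort("All variance components are zero: percentage undefined.",
          class = "smet_numerical_error")
  }
  100 * varcomps[["var_e"]] / tot
}
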