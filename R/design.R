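#' Construct a non-overlapping/overlapping sparse-testing allocation
#'
#' Splits a plot budget of `n_envs * (no_per_env + o_count)` calibration
#' cells across environments: `o_count` *overlapping* genotypes are sampled
#' first (uniformly, without replacement) and observed in every
#' environment; then `n_envs` pairwise-disjoint sets of `no_per_env`
#' *non-overlapping* genotypes are sampled from the remainder, one set per
#' environment. All other genotype-in-environment combinations form the
#' prediction set; genotypes outside every set are never observed at all.
#'
#' @param genotype_ids Character vector of unique genotype IDs.
#' @param n_envs Number of environments.
#' @param no_per_env Non-overlapping genotypes per environment (NO).
#' @param o_count Overlapping genotypes common to all environments (O).
#' @param seed Integer seed; the allocation is reproducible from it.
#' @param env_ids Optional environment labels (default `Env1..EnvK`).
#' @return A list of class `"smet_design"` with `env_sets` (per-environment
#'   calibration genotype IDs), `calibration_cells` and `prediction_cells`
#'   tibbles (columns `env`, `genotype`), the overlapping ID set, and the
#'   design parameters.
#' @export
#' @examples
#' d <- make_design(sprintf("G%03d", 1:843), n_envs = 3,
#'                  no_per_env = 241, o_count = 40, seed = 1)
#' nrow(d$calibration_cells)  # 843
make_design <- function(genotype_ids, n_envs, no_per_env, o_count, seed = 1L,
                        env_ids = NULL) {
  stopifnot(is.character(genotype_ids) || is.numeric(genotype_ids),
            is_count(n_envs), is_count(no_per_env, 0), is_count(o_count, 0))
  genotype_ids <- as.character(genotype_ids)
  if (anyDuplicated(genotype_ids)) {
    abort("`genotype_ids` must be unique.", class = "smet_config_error")
  }
  need <- n_envs * no_per_env + o_count
  n <- length(genotype_ids)
  if (need > n) {
    abort(sprintf(paste0("Infeasible design: %d environments x %d NO + %d O ",
                         "requires %d distinct genotypes but only %d are ",
                         "available (short by %d)."),
                  n_envs, no_per_env, o_count, need, n, need - n),
          class = "smet_budget_error")
  }
  envs <- env_ids %||% env_ids(n_envs)
  stopifnot(length(envs) == n_envs)

  with_local_seed(seed, {
    o_set <- sort(sample(genotype_ids, o_count))
    remainder <- setdiff(genotype_ids, o_set)
    no_pool <- sample(remainder, n_envs * no_per_env)
    no_sets <- split(no_pool, rep(seq_len(n_envs), each = no_per_env))
    env_sets <- lapply(seq_len(n_envs), function(i) {
      sort(c(o_set, if (no_per_env > 0) no_sets[[as.character(i)]] else character()))
    })
    names(env_sets) <- envs

    calib <- purrr::imap_dfr(env_sets, function(ids, env) {
      tibble::tibble(env = env, genotype = ids)
    })
    full <- tidyr::expand_grid(env = envs, genotype = genotype_ids)
    pred <- dplyr::anti_join(full, calib, by = c("env", "genotype"))

    structure(list(n_envs = n_envs, no_per_env = as.integer(no_per_env),
                   o_count = as.integer(o_count), seed = as.integer(seed),
                   env_ids = envs, genotype_ids = genotype_ids,
                   overlap_set = o_set, env_sets = env_sets,
                   calibration_cells = calib, prediction_cells = pred),
              class = "smet_design")
  })
}

#' Summarise an allocation design
#'
#' Reports the plot budget, per-environment sample size, how many
#' genotypes are observed in exactly `k` environments for
#' `k = 0, ..., n_envs`, and the overlap percentage
#' `100 * O / (NO + O)`.
#'
#' @param design An [make_design()] object.
#' @param total_genotypes Total genotypes in the study (defaults to the
#'   number of IDs the design was built from).
#' @return A one-row tibble with columns `plots`, `per_env_size`, `no`,
#'   `o`, `overlap_pct`, and `observed_in_0` ... `observed_in_<n_envs>`.
#' @export
design_summary <- function(design, total_genotypes = length(design$genotype_ids)) {
  stopifnot(inherits(design, "smet_design"))
  counts <- design$calibration_cells |>
    dplyr::count(.data$genotype, name = "k")
  k_tab <- table(factor(counts$k, levels = seq_len(design$n_envs)))
  observed <- c(total_genotypes - nrow(counts), as.integer(k_tab))
  s <- design$no_per_env + design$o_count
  out <- tibble::tibble(plots = nrow(design$calibration_cells),
                        per_env_size = s,
                        no = design$no_per_env, o = design$o_count,
                        overlap_pct = 100 * design$o_count / s)
  obs <- tibble::as_tibble(as.list(setNames(
    observed, paste0("observed_in_", 0:design$n_envs))))
  dplyr::bind_cols(out, obs)
}

#' Enumerate the NO/O design grid for one or more sample sizes
#'
#' For each per-environment sample size `s`, lists the designs
#' `(s, 0), (s - o_step, o_step), ...` obtained by shifting genotypes from
#' the non-overlapping to the overlapping set in steps of `o_step`,
#' stopping at the last design with `NO >= 1` (so a grid with
#' `s = 281, o_step = 10` ends at `1/280`). Designs whose genotype demand
#' `n_envs * NO + O` exceeds `total_genotypes` are excluded as infeasible.
#'
#' @param total_genotypes Total genotypes available.
#' @param n_envs Number of environments.
#' @param sample_sizes Integer vector of per-environment sample sizes.
#' @param o_step Step by which the overlapping count grows.
#' @return A tibble with columns `sample_size`, `no`, `o`, one row per
#'   design, of class `"smet_grid"`.
#' @export
#' @examples
#' enumerate_grid(843, 3, 281)       # 29 designs: 281/0 ... 1/280
#' enumerate_grid(6, 2, 2, o_step = 1)
enumerate_grid <- function(total_genotypes, n_envs, sample_sizes,
                           o_step = 10) {
  stopifnot(is_count(total_genotypes), is_count(n_envs), is_count(o_step),
            all(vapply(sample_sizes, is_count, logical(1))))
  grid <- purrr::map_dfr(as.integer(sample_sizes), function(s) {
    o <- seq(0L, s - 1L, by = o_step)
    tibble::tibble(sample_size = s, no = s - o, o = o)
  }) |>
    dplyr::filter(n_envs * .data$no + .data$o <= total_genotypes)
  class(grid) <- c("smet_grid", class(grid))
  grid
}

#' @export
print.smet_design <- function(x, ...) {
  cat(sprintf("Sparse-testing allocation: %d/%d (NO/O), %d environments\n",
              x$no_per_env, x$o_count, x$n_envs))
  cat(sprintf("  %d calibration cells, %d prediction cells, seed %d\n",
              nrow(x$calibration_cells), nrow(x$prediction_cells), x$seed))
  invisible(x)
}
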