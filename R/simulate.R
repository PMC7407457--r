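#' Simulation configuration for a sparse-testing study
#'
#' Bundles every parameter of the synthetic multi-environment trial
#' generator: marker panel shape, the variance components of the
#' cell-level model (environment, line, genomic, genotype-by-environment,
#' residual), and the plot-level replicate/incomplete-block layout.
#'
#' The cell-level model generated by [simulate_phenotypes()] is
#' `y_ij = mu + E_i + L_j + g_j + gE_ij + e_ij`, with `E_i ~ N(0, var_E)`,
#' `L_j ~ N(0, var_L)`, `g ~ MVN(0, G * var_g)` for the genomic relationship
#' matrix `G` of the simulated markers, `gE` with covariance
#' `var_gE * G_jj'` between cells sharing an environment (and 0 across
#' environments), and iid residuals `e_ij ~ N(0, var_e)`.
#'
#' Defaults are a desk-scale shape that mirrors a large maize hybrid trial:
#' 300 genotypes, 2,000 SNPs, 3 environments. The default variances make
#' the expected between-environment correlation of cell values,
#' `(var_L + var_g) / (var_L + var_g + var_gE + var_e)`, equal to 0.16 —
#' inside the low-to-moderate band (roughly 0.07 to 0.37) observed between
#' stress and optimal sites in large maize hybrid trials, with the
#' genotype-by-environment and residual terms carrying most of the
#' within-environment variance.
#'
#' @param n_genotypes Number of genotypes (lines) simulated.
#' @param n_markers Number of biallelic SNP markers.
#' @param n_envs Number of environments.
#' @param maf_range Length-2 numeric in `(0, 0.5]`; per-marker allele
#'   frequencies are drawn uniformly on this interval.
#' @param geno_missing_rate Proportion of marker calls set missing, in `[0, 1)`.
#' @param mu Overall trait mean (trait units).
#' @param var_E,var_L,var_g,var_gE,var_e Variance components of the
#'   cell-level model (all `>= 0`).
#' @param n_reps Replicates per environment in the plot-level layout.
#' @param n_blocks Incomplete blocks per replicate.
#' @param var_rep,var_block,var_plot Replicate, block-within-replicate and
#'   plot residual variances of the plot-level model.
#' @param seed Integer seed; the full dataset is reproducible from it.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_dataset()], [simulate_phenotypes()]
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 50, n_markers = 200, seed = 1)
#' cfg$var_gE
sim_config <- function(n_genotypes = 300, n_markers = 2000, n_envs = 3,
                       maf_range = c(0.05, 0.5), geno_missing_rate = 0,
                       mu = 5, var_E = 0.2, var_L = 0.03, var_g = 0.17,
                       var_gE = 0.5, var_e = 0.55,
                       n_reps = 2, n_blocks = 5,
                       var_rep = 0.05, var_block = 0.05, var_plot = 0.2,
                       seed = 1L) {
  stopifnot(is_count(n_genotypes, 2), is_count(n_markers), is_count(n_envs),
            is_count(n_reps), is_count(n_blocks))
  check_maf_range(maf_range)
  if (!(geno_missing_rate >= 0 && geno_missing_rate < 1)) {
    abort("`geno_missing_rate` must be in [0, 1).", class = "smet_config_error")
  }
  vars <- c(var_E = var_E, var_L = var_L, var_g = var_g, var_gE = var_gE,
            var_e = var_e, var_rep = var_rep, var_block = var_block,
            var_plot = var_plot)
  if (any(vars < 0)) {
    abort(paste0("Variance components must be >= 0; offending: ",
                 paste(names(vars)[vars < 0], collapse = ", ")),
          class = "smet_config_error")
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_markers = as.integer(n_markers),
                 n_envs = as.integer(n_envs),
                 maf_range = as.numeric(maf_range),
                 geno_missing_rate = geno_missing_rate,
                 mu = mu, var_E = var_E, var_L = var_L, var_g = var_g,
                 var_gE = var_gE, var_e = var_e,
                 n_reps = as.integer(n_reps), n_blocks = as.integer(n_blocks),
                 var_rep = var_rep, var_block = var_block, var_plot = var_plot,
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_maf_range <- function(maf_range) {
  if (!is.numeric(maf_range) || length(maf_range) != 2 || anyNA(maf_range) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be two values in (0, 0.5] with min <= max.",
          class = "smet_config_error")
  }
  invisible(maf_range)
}

#' Simulate a biallelic SNP dosage matrix
#'
#' Each marker gets an allele frequency drawn uniformly on `maf_range`;
#' dosages are independent `Binomial(2, f_m)` draws, so the panel carries
#' no linkage disequilibrium. Missing calls are flagged as `NA` at rate
#' `geno_missing_rate`, independently per call.
#'
#' @inheritParams sim_config
#' @return An integer matrix (genotypes x markers) with values in
#'   `{0, 1, 2}` or `NA`, with genotype IDs as rownames and marker IDs as
#'   colnames. The drawn allele frequencies are attached as attribute
#'   `"allele_freq"`.
#' @export
#' @examples
#' M <- simulate_markers(10, 5, maf_range = c(0.5, 0.5), seed = 1)
#' table(M)
simulate_markers <- function(n_genotypes, n_markers,
                             maf_range = c(0.05, 0.5),
                             geno_missing_rate = 0, seed = 1L) {
  stopifnot(is_count(n_genotypes, 2), is_count(n_markers))
  check_maf_range(maf_range)
  if (!(geno_missing_rate >= 0 && geno_missing_rate < 1)) {
    abort("`geno_missing_rate` must be in [0, 1).", class = "smet_config_error")
  }
  with_local_seed(seed, {
    f <- runif(n_markers, maf_range[1], maf_range[2])
    M <- vapply(f, function(fm) rbinom(n_genotypes, 2L, fm),
                integer(n_genotypes))
    M <- matrix(as.integer(M), nrow = n_genotypes, ncol = n_markers)
    if (geno_missing_rate > 0) {
      M[runif(length(M)) < geno_missing_rate] <- NA_integer_
    }
    dimnames(M) <- list(geno_ids(n_genotypes), marker_ids(n_markers))
    attr(M, "allele_freq") <- setNames(f, colnames(M))
    M
  })
}

geno_ids <- function(n) sprintf("G%04d", seq_len(n))
marker_ids <- function(p) sprintf("M%05d", seq_len(p))
env_ids <- function(k) sprintf("Env%d", seq_len(k))

#' Simulate cell-level phenotypes with genotype-by-environment interaction
#'
#' Draws one phenotypic value per genotype-in-environment cell under the
#' random-effects model `y_ij = mu + E_i + L_j + g_j + gE_ij + e_ij`.
#' The genomic main effect `g` is multivariate normal with covariance
#' `G * var_g`, where `G` is the VanRaden relationship matrix computed from
#' `markers` (after default QC). The interaction `gE` is drawn per
#' environment as an independent `MVN(0, G * var_gE)` vector, which realises
#' the Hadamard-kernel covariance `var_gE * G_jj' * 1[i = i']` for a
#' complete one-cell-per-combination layout.
#'
#' `G` receives a `1e-8` diagonal jitter before the Cholesky factorisation;
#' standardized-marker relationship matrices are routinely rank-deficient.
#' If the factorisation still fails the error is surfaced, not papered over.
#'
#' @param markers Dosage matrix from [simulate_markers()] (rows must match
#'   `config$n_genotypes`).
#' @param config A [sim_config()] object.
#' @return A list of class `"smet_sim"` with elements `markers`, `grm`,
#'   `effects` (list of `E`, `L`, `g` named vectors and a `gE` tibble),
#'   and `cells`, a tibble with columns `env`, `genotype`, `value`
#'   (`n_envs * n_genotypes` rows).
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 40, n_markers = 120, seed = 3)
#' M <- simulate_markers(cfg$n_genotypes, cfg$n_markers, seed = cfg$seed)
#' sim <- simulate_phenotypes(M, cfg)
#' head(sim$cells)
simulate_phenotypes <- function(markers, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(markers) != config$n_genotypes) {
    abort("`markers` rows must match `config$n_genotypes`.",
          class = "smet_config_error")
  }
  n <- config$n_genotypes
  k <- config$n_envs
  genos <- rownames(markers)
  envs <- env_ids(k)

  G <- compute_grm(impute_and_standardize(qc_filter(markers)))
  R <- chol_psd(G)

  with_local_seed(config$seed + 1L, {
    E <- setNames(rnorm(k, 0, sqrt(config$var_E)), envs)
    L <- setNames(rnorm(n, 0, sqrt(config$var_L)), genos)
    g <- setNames(drop(crossprod(R, rnorm(n))) * sqrt(config$var_g), genos)
    gE_mat <- vapply(seq_len(k), function(i) {
      drop(crossprod(R, rnorm(n))) * sqrt(config$var_gE)
    }, numeric(n))
    e <- matrix(rnorm(n * k, 0, sqrt(config$var_e)), n, k)

    cells <- tidyr::expand_grid(env = envs, genotype = genos)
    idx_env <- match(cells$env, envs)
    idx_gen <- match(cells$genotype, genos)
    cells$value <- config$mu + unname(E[idx_env]) + unname(L[idx_gen]) +
      unname(g[idx_gen]) + gE_mat[cbind(idx_gen, idx_env)] +
      e[cbind(idx_gen, idx_env)]

    gE_tbl <- tibble::tibble(env = cells$env, genotype = cells$genotype,
                             gE = gE_mat[cbind(idx_gen, idx_env)])
    structure(list(markers = markers, grm = G, config = config,
                   effects = list(E = E, L = L, g = g, gE = gE_tbl),
                   cells = cells),
              class = "smet_sim")
  })
}

# Cholesky of a PSD matrix with a documented 1e-8 diagonal jitter; raises a
# numerical error if the jittered matrix is still not factorisable.
chol_psd <- function(G, jitter = 1e-8) {
  out <- tryCatch(chol(G + diag(jitter, nrow(G))), error = function(e) e)
  if (inherits(out, "error")) {
    abort(paste0("Relationship matrix is not positive semidefinite even ",
                 "after a ", format(jitter), " diagonal jitter."),
          class = "smet_numerical_error")
  }
  out
}

#' Expand cell values into a replicated incomplete-block plot trial
#'
#' Within each environment every genotype is planted once per replicate;
#' the genotypes of each replicate are partitioned at random into
#' `n_blocks` near-equal incomplete blocks (the partition is re-randomised
#' per replicate). Plot values are
#' `cell value + replicate effect + block-within-replicate effect + plot noise`,
#' matching the stage-1 adjustment model used downstream.
#'
#' @param cell_values Tibble with columns `env`, `genotype`, `value`
#'   (for example `simulate_phenotypes(...)$cells`).
#' @param n_reps Replicates per environment.
#' @param n_blocks Incomplete blocks per replicate.
#' @param var_rep,var_block,var_plot Variances of the replicate effects,
#'   block-within-replicate effects and plot residuals.
#' @param seed Integer seed.
#' @return A tibble with columns `env`, `rep`, `block`, `genotype`, `value`;
#'   block labels are nested within (env, rep).
#' @export
#' @examples
#' cells <- tibble::tibble(env = "Env1", genotype = sprintf("G%02d", 1:6),
#'                         value = rnorm(6))
#' simulate_plot_trial(cells, n_reps = 2, n_blocks = 3, seed = 1)
simulate_plot_trial <- function(cell_values, n_reps = 2, n_blocks = 5,
                                var_rep = 0.05, var_block = 0.05,
                                var_plot = 0.2, seed = 1L) {
  stopifnot(is_count(n_reps), is_count(n_blocks),
            all(c("env", "genotype", "value") %in% names(cell_values)))
  if (any(c(var_rep, var_block, var_plot) < 0)) {
    abort("Plot-level variances must be >= 0.", class = "smet_config_error")
  }
  with_local_seed(seed, {
    cell_values |>
      dplyr::group_by(.data$env) |>
      dplyr::group_modify(function(df, key) {
        purrr::map_dfr(seq_len(n_reps), function(r) {
          n <- nrow(df)
          blk <- sample(rep(seq_len(n_blocks), length.out = n))
          r_eff <- rnorm(1, 0, sqrt(var_rep))
          b_eff <- rnorm(n_blocks, 0, sqrt(var_block))
          tibble::tibble(rep = sprintf("R%d", r),
                         block = sprintf("B%d", blk),
                         genotype = df$genotype,
                         value = df$value + r_eff + b_eff[blk] +
                           rnorm(n, 0, sqrt(var_plot)))
        })
      }) |>
      dplyr::ungroup() |>
      dplyr::select("env", "rep", "block", "genotype", "value")
  })
}

#' Simulate a complete sparse-testing study dataset
#'
#' Convenience wrapper chaining [simulate_markers()],
#' [simulate_phenotypes()] and [simulate_plot_trial()] from a single
#' [sim_config()].
#'
#' @param config A [sim_config()] object.
#' @param plots If `TRUE` (default) also expand cells to a plot-level trial.
#' @return An `"smet_sim"` list as from [simulate_phenotypes()], with an
#'   additional `plots` tibble when `plots = TRUE`.
#' @export
simulate_dataset <- function(config = sim_config(), plots = TRUE) {
  M <- simulate_markers(config$n_genotypes, config$n_markers,
                        config$maf_range, config$geno_missing_rate,
                        seed = config$seed)
  sim <- simulate_phenotypes(M, config)
  if (plots) {
    sim$plots <- simulate_plot_trial(sim$cells, config$n_reps,
                                     config$n_blocks, config$var_rep,
                                     config$var_block, config$var_plot,
                                     seed = config$seed + 2L)
  }
  sim
}

#' @export
print.smet_sim <- function(x, ...) {
  cat("Simulated multi-environment trial\n")
  cat(sprintf("  %d genotypes x %d markers, %d environments\n",
              x$config$n_genotypes, x$config$n_markers, x$config$n_envs))
  cat(sprintf("  %d cell values%s\n", nrow(x$cells),
              if (!is.null(x$plots)) sprintf(", %d plots", nrow(x$plots)) else ""))
  invisible(x)
}
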