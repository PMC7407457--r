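toy_plots <- function() {
  # 3 genotypes x 2 reps, one block per rep
  tibble::tibble(env = "E1",
                 rep = rep(c("R1", "R2"), each = 3),
                 block = "B1",
                 genotype = rep(c("g1", "g2", "g3"), 2),
                 value = c(1.0, 2.5, 3.0, 2.0, 3.5, 4.5))
}

test_that("BLUEs at fixed variance components equal the dense GLS oracle", {
  plots <- toy_plots()
  vc <- c(var_rep = 0.5, var_block = 0, var_e = 1.0)
  blues <- compute_blues(plots, varcomps = vc)

  # brute-force oracle: V assembled entry by entry, direct solve
  X <- matrix(0, 6, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  X[cbind(1:6, match(plots$genotype, colnames(X)))] <- 1
  V <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    V[i, j] <- 0.5 * (plots$rep[i] == plots$rep[j]) + 1.0 * (i == j)
  }
  beta <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% plots$value)
  expect_equal(blues$blue, as.numeric(beta), tolerance = 1e-8)
})

test_that("balanced complete designs give genotype means; OLS in the zero-variance limit", {
  plots <- toy_plots()
  means <- tapply(plots$value, plots$genotype, mean)
  # balance forces cancellation of replicate effects at any variance ratio
  b1 <- compute_blues(plots, varcomps = c(var_rep = 2, var_block = 0.7, var_e = 1))
  expect_equal(b1$blue, as.numeric(means), tolerance = 1e-10)
  b0 <- compute_blues(plots, varcomps = c(var_rep = 0, var_block = 0, var_e = 0))
  expect_equal(b0$blue, as.numeric(means), tolerance = 1e-10)

  # single plot per genotype: BLUE is the observation itself
  single <- dplyr::filter(plots, rep == "R1")
  bs <- compute_blues(single, varcomps = c(var_rep = 0, var_block = 0, var_e = 0))
  expect_equal(bs$blue, single$value[order(single$genotype)])
})

test_that("BLUEs are shift-equivariant and invariant to rep/block relabeling", {
  cells <- tibble::tibble(env = "Env1", genotype = sprintf("G%03d", 1:60),
                          value = rnorm(60, 10))
  plots <- simulate_plot_trial(cells, n_reps = 2, n_blocks = 4,
                               var_rep = 0.3, var_block = 0.2, var_plot = 0.5,
                               seed = 11)
  b <- compute_blues(plots)
  b_shift <- compute_blues(dplyr::mutate(plots, value = value + 3.7))
  expect_equal(b_shift$blue, b$blue + 3.7, tolerance = 1e-6)

  relab <- plots |>
    dplyr::mutate(rep = chartr("12", "ba", rep),
                  block = paste0("blk_", block))
  expect_equal(compute_blues(relab)$blue, b$blue, tolerance = 1e-8)
})

test_that("stage-1 REML recovers known variance components", {
  cells <- tibble::tibble(env = "Env1", genotype = sprintf("G%03d", 1:500),
                          value = rnorm(500, 10, 0.3))
  plots <- simulate_plot_trial(cells, n_reps = 6, n_blocks = 10,
                               var_rep = 0.5, var_block = 0.3, var_plot = 1.0,
                               seed = 21)
  # genotype signal is fixed, so only the design variances remain random
  vc <- estimate_stage1_varcomps(plots, "Env1")
  expect_lt(abs(vc[["var_block"]] - 0.3) / 0.3, 0.3)
  expect_lt(abs(vc[["var_e"]] - 1.0) / 1.0, 0.3)
  # replicate variance has only 6 effective observations; just sanity-bound it
  expect_lt(vc[["var_rep"]], 2.5)

  # zero replicate variance stays near the boundary
  plots0 <- simulate_plot_trial(cells, n_reps = 6, n_blocks = 10,
                                var_rep = 0, var_block = 0, var_plot = 1.0,
                                seed = 22)
  vc0 <- estimate_stage1_varcomps(plots0, "Env1")
  expect_lte(vc0[["var_rep"]], 0.05 * vc0[["var_e"]])

  # degenerate data: all components zero
  flat <- dplyr::mutate(plots, value = 2)
  expect_equal(unname(estimate_stage1_varcomps(flat, "Env1")), c(0, 0, 0))
})

test_that("default BLUEs agree with an independent lme4 fixed-effect fit", {
  cells <- tibble::tibble(env = "Env1", genotype = sprintf("G%03d", 1:80),
                          value = rnorm(80, 10))
  plots <- simulate_plot_trial(cells, n_reps = 3, n_blocks = 4,
                               var_rep = 0.4, var_block = 0.3, var_plot = 0.8,
                               seed = 31)
  b <- compute_blues(plots)
  df <- dplyr::mutate(plots, blk = interaction(rep, block))
  fit <- lme4::lmer(value ~ 0 + genotype + (1 | rep) + (1 | blk), data = plots |>
                      dplyr::mutate(blk = interaction(rep, block)),
                    REML = TRUE)
  ref <- lme4::fixef(fit)
  names(ref) <- sub("^genotype", "", names(ref))
  expect_equal(b$blue, unname(ref[b$genotype]), tolerance = 1e-6)
})

test_that("rank-deficiency and absent environments raise classed errors", {
  plots <- toy_plots()
  expect_error(compute_blues(plots, env = "nope"), class = "smet_config_error")
  expect_error(estimate_stage1_varcomps(plots, "nope"),
               class = "smet_config_error")
})
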