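test_that("cell kernels match brute-force pairwise construction", {
  ids <- c("g1", "g2", "g3")
  G <- matrix(c(1.0, 0.5, -0.2,
                0.5, 1.1, 0.1,
                -0.2, 0.1, 0.9), 3, dimnames = list(ids, ids))
  blues <- tidyr::expand_grid(env = c("E1", "E2"), genotype = ids)
  blues$blue <- seq_len(6)
  d <- make_design(ids, 2, 1, 1, seed = 3, env_ids = c("E1", "E2"))
  k <- build_kernels(blues, G, d, "M3")
  cells <- k$cells
  n <- nrow(cells)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      same_e <- as.numeric(cells$env[a] == cells$env[b])
      same_g <- as.numeric(cells$genotype[a] == cells$genotype[b])
      gg <- G[cells$genotype[a], cells$genotype[b]]
      expect_equal(k$K$E[a, b], same_e)
      expect_equal(k$K$L[a, b], same_g)
      expect_equal(k$K$G[a, b], gg)
      expect_equal(k$K$GE[a, b], gg * same_e)
    }
  }
  # definitional identity and the identity-G special case
  expect_equal(k$K$GE, k$K$G * k$K$E)
  ids2 <- c("x", "y")
  I2 <- diag(2); dimnames(I2) <- list(ids2, ids2)
  b2 <- tidyr::expand_grid(env = c("E1", "E2"), genotype = ids2)
  b2$blue <- 1:4
  d2 <- make_design(ids2, 2, 1, 0, seed = 1, env_ids = c("E1", "E2"))
  k2 <- build_kernels(b2, I2, d2, "M3")
  expect_equal(k2$K$GE, diag(4), ignore_attr = TRUE)

  # kernel lists track the model definition
  expect_named(build_kernels(blues, G, d, "M1")$K, c("E", "L"))
  expect_named(build_kernels(blues, G, d, "M2")$K, c("E", "L", "G"))
  expect_error(build_kernels(blues, G[1:2, 1:2], d, "M3"),
               class = "smet_id_mismatch_error")
})

test_that("a constant response is fitted as pure mean", {
  ids <- sprintf("G%04d", 1:12)
  G <- make_family_grm(12, 4)
  blues <- tidyr::expand_grid(env = c("Env1", "Env2"), genotype = ids)
  blues$blue <- 7
  d <- make_design(ids, 2, 4, 2, seed = 2)
  fit <- suppressWarnings(
    fit_model(build_kernels(blues, G, d, "M2"),
              gibbs_config(n_iter = 1200, burn_in = 200, seed = 1)))
  expect_lt(abs(fit$mu_hat - 7), 0.05 * 7)
  expect_true(all(abs(fit$cell_predictions$predicted - 7) < 0.05 * 7))
})

test_that("with fixed variance components the sampler reproduces Henderson BLUP", {
  set.seed(42)
  n <- 20
  G <- make_family_grm(n, 5)
  ids <- rownames(G)
  blues <- simulate_cells_oracle(G, 2, mu = 5, var_E = 0.3, var_L = 0.2,
                                 var_g = 0.5, var_gE = 0.4, var_e = 0.35,
                                 seed = 7)
  d <- make_design(ids, 2, 6, 4, seed = 9)
  k <- build_kernels(blues, G, d, "M3")
  vc <- c(E = 0.3, L = 0.2, G = 0.5, GE = 0.4, var_e = 0.35)
  fit <- fit_model(k, gibbs_config(n_iter = 12000, burn_in = 2000, thin = 2,
                                   seed = 5), fix_varcomps = vc)
  oracle <- blup_oracle(k, as.list(vc[c("E", "L", "G", "GE")]), 0.35)
  te <- which(k$cells$set == "prediction")
  gap <- abs(fit$cell_predictions$predicted[te] - oracle$pred)
  expect_true(all(gap <= 3 * pmax(fit$cell_predictions$predicted_se[te], 1e-4)))
})

test_that("M3 with the interaction variance pinned at zero collapses to M2", {
  set.seed(3)
  n <- 24
  G <- make_family_grm(n, 6)
  blues <- simulate_cells_oracle(G, 2, 5, 0.2, 0.1, 0.4, 0.3, 0.3, seed = 13)
  d <- make_design(rownames(G), 2, 8, 4, seed = 4)
  vc2 <- c(E = 0.2, L = 0.1, G = 0.4, var_e = 0.3)
  vc3 <- c(vc2[c("E", "L", "G")], GE = 0, var_e = 0.3)
  f2 <- fit_model(build_kernels(blues, G, d, "M2"),
                  gibbs_config(n_iter = 8000, burn_in = 1500, thin = 2, seed = 6),
                  fix_varcomps = vc2)
  f3 <- fit_model(build_kernels(blues, G, d, "M3"),
                  gibbs_config(n_iter = 8000, burn_in = 1500, thin = 2, seed = 7),
                  fix_varcomps = vc3)
  te <- which(f2$cell_predictions$set == "prediction")
  se <- sqrt(f2$cell_predictions$predicted_se[te]^2 +
               f3$cell_predictions$predicted_se[te]^2)
  gap <- abs(f2$cell_predictions$predicted[te] - f3$cell_predictions$predicted[te])
  expect_true(all(gap <= 4 * pmax(se, 1e-4)))
})

test_that("rescaling the response rescales variances by c^2 and predictions by c", {
  n <- 18
  G <- make_family_grm(n, 6)
  blues <- simulate_cells_oracle(G, 2, 5, 0.2, 0.1, 0.4, 0.3, 0.3, seed = 23)
  d <- make_design(rownames(G), 2, 6, 3, seed = 8)
  cfg <- gibbs_config(n_iter = 1500, burn_in = 300, seed = 9)
  f1 <- suppressWarnings(fit_model(build_kernels(blues, G, d, "M3"), cfg))
  blues_c <- dplyr::mutate(blues, blue = blue * 2.5)
  f2 <- suppressWarnings(fit_model(build_kernels(blues_c, G, d, "M3"), cfg))
  # priors and every conditional scale exactly, so the chains map 1:1
  expect_equal(f2$varcomps, f1$varcomps * 2.5^2, tolerance = 1e-8)
  expect_equal(f2$cell_predictions$predicted,
               f1$cell_predictions$predicted * 2.5, tolerance = 1e-8)
  expect_equal(f2$pct_unexplained, f1$pct_unexplained, tolerance = 1e-8)
})

test_that("residual-variance percentage follows its definition", {
  expect_equal(pct_unexplained(c(var_E = 4, var_L = 5, var_e = 1)), 10)
  expect_equal(pct_unexplained(c(var_e = 1)), 100)
  expect_equal(pct_unexplained(c(var_E = 0.2, var_L = 0.1, var_g = 0.4,
                                 var_gE = 0.3, var_e = 0.3)),
               100 * 0.3 / 1.3)
  expect_error(pct_unexplained(c(var_E = 0, var_e = 0)),
               class = "smet_numerical_error")
  expect_error(pct_unexplained(c(var_E = 1)), class = "smet_config_error")
})

test_that("tidy and glance expose the posterior summaries", {
  n <- 15
  G <- make_family_grm(n, 5)
  blues <- simulate_cells_oracle(G, 2, 5, 0.2, 0.1, 0.4, 0.3, 0.3, seed = 33)
  d <- make_design(rownames(G), 2, 5, 2, seed = 3)
  fit <- suppressWarnings(
    fit_model(build_kernels(blues, G, d, "M2"),
              gibbs_config(n_iter = 800, burn_in = 200, seed = 2)))
  td <- tidy(fit)
  expect_equal(td$term, c("var_E", "var_L", "var_g", "var_e"))
  expect_true(all(td$estimate >= 0))
  gl <- glance(fit)
  expect_equal(gl$model, "M2")
  expect_true(gl$pct_unexplained >= 0 && gl$pct_unexplained <= 100)
})
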