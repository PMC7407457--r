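# Shared fixtures, built in code.

# kinship with block family structure: strong, well-conditioned, far from I
make_family_grm <- function(n, fam_size = 10, rho = 0.6) {
  fam <- rep(seq_len(ceiling(n / fam_size)), each = fam_size)[seq_len(n)]
  G <- rho * outer(fam, fam, "==") + (1 - rho) * diag(n)
  ids <- sprintf("G%04d", seq_len(n))
  dimnames(G) <- list(ids, ids)
  G
}

# independent generator for the cell-level model, written as plain loops so
# it does not share code with simulate_phenotypes()
simulate_cells_oracle <- function(G, n_envs, mu, var_E, var_L, var_g, var_gE,
                                  var_e, seed) {
  set.seed(seed)
  n <- nrow(G)
  ids <- rownames(G)
  envs <- sprintf("Env%d", seq_len(n_envs))
  R <- chol(G + diag(1e-8, n))
  E <- rnorm(n_envs, 0, sqrt(var_E))
  L <- rnorm(n, 0, sqrt(var_L))
  g <- drop(crossprod(R, rnorm(n))) * sqrt(var_g)
  out <- vector("list", n_envs)
  for (i in seq_len(n_envs)) {
    gE_i <- drop(crossprod(R, rnorm(n))) * sqrt(var_gE)
    out[[i]] <- tibble::tibble(
      env = envs[i], genotype = ids,
      blue = mu + E[i] + L + g + gE_i + rnorm(n, 0, sqrt(var_e)))
  }
  dplyr::bind_rows(out)
}

# hand-made kernels object over an explicit cell table (bypasses designs)
kernels_from_cells <- function(cells, K_list, model = "M3") {
  structure(list(cells = cells, K = K_list, model = model,
                 n_train = sum(cells$set == "calibration")),
            class = "smet_kernels")
}

# dense GLS / Henderson oracle: predictions of test cells at fixed
# variance components, assembled with explicit kernel sums
blup_oracle <- function(kern, vc, var_e) {
  tr <- which(kern$cells$set == "calibration")
  te <- which(kern$cells$set == "prediction")
  y <- kern$cells$observed[tr]
  V <- var_e * diag(length(tr))
  C <- matrix(0, length(te), length(tr))
  for (k in names(kern$K)) {
    V <- V + vc[[k]] * kern$K[[k]][tr, tr]
    C <- C + vc[[k]] * kern$K[[k]][te, tr]
  }
  Vi <- solve(V)
  one <- rep(1, length(tr))
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  list(mu = mu, pred = mu + drop(C %*% Vi %*% (y - mu)))
}
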