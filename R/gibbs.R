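#' Fit a random-effects genomic model by eigendecomposition-accelerated Gibbs
#'
#' Fits `y = mu + sum_k u_k + e` on the calibration cells of a design,
#' where each `u_k ~ N(0, K_k sigma2_k)` for the kernels assembled by
#' [build_kernels()], and predicts every cell (calibration and
#' prediction).
#'
#' Each effect is represented in the eigenbasis of its kernel restricted
#' to the calibration cells: `K_k[train, train] = V_k D_k V_k'` with
#' orthonormal `V_k`, so `u_k = V_k b_k` with independent prior
#' `b_kj ~ N(0, d_kj sigma2_k)` and a *diagonal* full conditional for
#' `b_k` — one Gibbs block per kernel costs two matrix-vector products.
#' Negative eigenvalues are clipped at zero (the maximum clip magnitude is
#' reported in the diagnostics) and eigenvalues below `1e-8` of the
#' largest are dropped. Variance components get scaled-inverse-chi-square
#' updates; `mu` has a flat prior. Masked cells are predicted by the
#' joint-kernel conditional mean
#' `K_k[test, train] V_k D_k^{-1} b_k`, accumulated over the kept draws,
#' so the reported prediction is the posterior mean of
#' `mu + sum_k u_k(test)`.
#'
#' Never-observed genotypes receive no contribution from the iid line
#' kernel `L` (their `K_L[test, train]` rows are zero); information flows
#' to them only through the genomic kernels `G` and `GE`.
#'
#' @param kernels An [build_kernels()] object.
#' @param config A [gibbs_config()].
#' @param fix_varcomps Optional named vector fixing the variance
#'   components (kernel labels plus `var_e`); disables variance updates —
#'   mainly for validation against closed-form mixed-model predictions.
#' @return List of class `"smet_fit"`: `model`, `varcomps` (posterior
#'   means, named `var_E`, `var_L`, `var_g`, `var_gE` as applicable, and
#'   `var_e`), `mu_hat`, `cell_predictions` (tibble `env`, `genotype`,
#'   `set`, `observed`, `predicted`, `predicted_se`), `pct_unexplained`,
#'   `diagnostics` (per-component effective sample sizes), and the config.
#' @export
fit_model <- function(kernels, config = gibbs_config(), fix_varcomps = NULL) {
  stopifnot(inherits(kernels, "smet_kernels"), inherits(config, "gibbs_config"))
  cells <- kernels$cells
  tr <- which(cells$set == "calibration")
  te <- which(cells$set == "prediction")
  y <- cells$observed[tr]
  n <- length(y)
  if (n < 2) {
    abort("Need at least 2 calibration cells.", class = "smet_config_error")
  }
  labels <- names(kernels$K)
  nk <- length(labels)

  # eigen-structures per kernel, training block only
  max_clip <- 0
  eig <- lapply(kernels$K, function(K) {
    es <- eigen(K[tr, tr, drop = FALSE], symmetric = TRUE)
    d <- es$values
    max_clip <<- max(max_clip, -min(0, min(d)))
    d[d < 0] <- 0
    keep <- d > max(d) * 1e-8
    V <- es$vectors[, keep, drop = FALSE]
    d <- d[keep]
    B <- if (length(te) > 0) {
      sweep(K[te, tr, drop = FALSE] %*% V, 2, d, "/")
    } else {
      matrix(0, 0, length(d))
    }
    list(V = V, d = d, B = B, r = length(d))
  })

  vy <- var(y)
  if (vy == 0) vy <- 1e-12
  df0 <- config$prior_df
  # scaled-inv-chi-square scale chosen so the prior mode hits the target split
  mode_k <- config$prior_R2 * vy / nk
  S_k <- mode_k * (df0 + 2) / df0
  S_e <- (1 - config$prior_R2) * vy * (df0 + 2) / df0

  fixed <- !is.null(fix_varcomps)
  if (fixed) {
    need <- c(labels, "var_e")
    if (!all(need %in% names(fix_varcomps))) {
      abort(sprintf("`fix_varcomps` must name: %s.", paste(need, collapse = ", ")),
            class = "smet_config_error")
    }
  }

  with_local_seed(config$seed, {
    sig2 <- if (fixed) fix_varcomps[labels] else rep(mode_k, nk)
    names(sig2) <- labels
    sig2e <- if (fixed) fix_varcomps[["var_e"]] else (1 - config$prior_R2) * vy
    mu <- mean(y)
    b <- lapply(eig, function(e) numeric(e$r))
    u <- lapply(eig, function(e) numeric(n))
    e_vec <- y - mu

    kept <- 0L
    n_keep <- length(seq(config$burn_in + 1L, config$n_iter, by = config$thin))
    vc_draws <- matrix(NA_real_, n_keep, nk + 1,
                       dimnames = list(NULL, c(labels, "e")))
    mu_sum <- 0
    pred_sum <- numeric(nrow(cells))
    # batch means over kept draws give an autocorrelation-robust MC
    # standard error for the posterior-mean predictions
    n_batch <- max(2L, min(25L, n_keep %/% 4L))
    batch_size <- ceiling(n_keep / n_batch)
    pred_batch <- matrix(0, nrow(cells), n_batch)
    batch_n <- numeric(n_batch)

    for (it in seq_len(config$n_iter)) {
      # intercept (flat prior)
      e_vec <- e_vec + mu
      mu <- rnorm(1, mean(e_vec), sqrt(sig2e / n))
      e_vec <- e_vec - mu
      for (k in seq_len(nk)) {
        ek <- eig[[k]]
        e_vec <- e_vec + u[[k]]
        z <- crossprod(ek$V, e_vec)
        pv <- 1 / (1 / sig2e + 1 / (ek$d * sig2[k]))
        b[[k]] <- rnorm(ek$r, pv * z / sig2e, sqrt(pv))
        u[[k]] <- drop(ek$V %*% b[[k]])
        e_vec <- e_vec - u[[k]]
        if (!fixed) {
          ss <- sum(b[[k]]^2 / ek$d)
          sig2[k] <- (ss + df0 * S_k) / rchisq(1, df0 + ek$r)
        }
      }
      if (!fixed) {
        sig2e <- (sum(e_vec^2) + df0 * S_e) / rchisq(1, df0 + n)
      }
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        vc_draws[kept, ] <- c(sig2, sig2e)
        mu_sum <- mu_sum + mu
        pred <- numeric(nrow(cells))
        pred[tr] <- mu + Reduce(`+`, u)
        if (length(te) > 0) {
          pred[te] <- mu + Reduce(`+`, purrr::map2(eig, b, function(e, bk) {
            drop(e$B %*% bk)
          }))
        }
        pred_sum <- pred_sum + pred
        bi <- 1L + (kept - 1L) %/% batch_size
        pred_batch[, bi] <- pred_batch[, bi] + pred
        batch_n[bi] <- batch_n[bi] + 1
      }
    }

    vc_mean <- colMeans(vc_draws[seq_len(kept), , drop = FALSE])
    pred_mean <- pred_sum / kept
    used <- batch_n > 0
    bm <- sweep(pred_batch[, used, drop = FALSE], 2, batch_n[used], "/")
    pred_se <- apply(bm, 1, sd) / sqrt(sum(used))

    vc_named <- setNames(vc_mean, varcomp_names(c(labels, "e")))
    ess <- apply(vc_draws[seq_len(kept), , drop = FALSE], 2, ess_chain)
    diagnostics <- tibble::tibble(term = names(vc_named),
                                  posterior_mean = as.numeric(vc_mean),
                                  posterior_sd = apply(
                                    vc_draws[seq_len(kept), , drop = FALSE], 2, sd),
                                  ess = as.numeric(ess),
                                  max_eigen_clip = max_clip)
    if (!fixed && any(ess < 10)) {
      warn(sprintf("Low effective sample size for %s; inspect `diagnostics`.",
                   paste(names(vc_named)[ess < 10], collapse = ", ")))
    }

    preds <- cells
    preds$predicted <- pred_mean
    preds$predicted_se <- pred_se

    structure(list(model = kernels$model, varcomps = vc_named,
                   mu_hat = mu_sum / kept,
                   cell_predictions = preds,
                   pct_unexplained = pct_unexplained(vc_named),
                   diagnostics = diagnostics, n_train = n,
                   config = config, fixed_varcomps = fixed),
              class = "smet_fit")
  })
}

varcomp_names <- function(labels) {
  map <- c(E = "var_E", L = "var_L", G = "var_g", GE = "var_gE", e = "var_e")
  unname(map[labels])
}

# effective sample size by the initial-positive-sequence estimator
ess_chain <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos) > 0) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' @export
print.smet_fit <- function(x, ...) {
  cat(sprintf("Model %s fit (%d calibration cells, %d iterations)\n",
              x$model, x$n_train, x$config$n_iter))
  cat("  posterior mean variance components:\n")
  print(round(x$varcomps, 4))
  cat(sprintf("  mu_hat = %.4f, unexplained variance = %.1f%%\n",
              x$mu_hat, x$pct_unexplained))
  invisible(x)
}
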