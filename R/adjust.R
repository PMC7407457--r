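#' Stage-1 variance components for one environment
#'
#' Fits the per-environment adjustment model
#' `y = mu + genotype (fixed) + replicate (random) + block-within-replicate
#' (random) + plot error` by REML and returns the three random variance
#' components. Estimation is delegated to [lme4::lmer()]; boundary (zero)
#' estimates are allowed. Terms that are structurally inestimable — a
#' single replicate, or a single block per replicate — are fixed at 0 with
#' a message.
#'
#' @param plots Plot tibble with columns `env`, `rep`, `block`, `genotype`,
#'   `value`; `block` is interpreted as nested within `(env, rep)`.
#' @param env Environment ID to fit (must be present in `plots`).
#' @return Named numeric vector `c(var_rep, var_block, var_e)`.
#' @export
estimate_stage1_varcomps <- function(plots, env) {
  df <- dplyr::filter(plots, .data$env == !!env)
  if (nrow(df) == 0) {
    abort(sprintf("No plots found for environment '%s'.", env),
          class = "smet_config_error")
  }
  if (length(unique(df$value)) < 2) {
    return(c(var_rep = 0, var_block = 0, var_e = 0))
  }
  n_rep <- length(unique(df$rep))
  df$blk <- interaction(df$rep, df$block, drop = TRUE)
  n_blk <- length(unique(df$blk))

  terms <- character()
  if (n_rep > 1) terms <- c(terms, "(1 | rep)")
  if (n_blk > n_rep) terms <- c(terms, "(1 | blk)")
  if (length(terms) == 0) {
    inform("Single replicate and single block: replicate and block variances fixed at 0.")
    res <- stats::lm(value ~ 0 + genotype, data = df)
    rdf <- res$df.residual
    var_e <- if (rdf > 0) sum(res$residuals^2) / rdf else 0
    return(c(var_rep = 0, var_block = 0, var_e = var_e))
  }

  fml <- stats::as.formula(paste("value ~ 0 + genotype +",
                                 paste(terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  c(var_rep = pick("rep"), var_block = pick("blk"),
    var_e = pick("Residual"))
}

#' Per-environment BLUEs of genotype means
#'
#' Computes best linear unbiased estimates of each genotype's mean within
#' an environment by generalised least squares at the stage-1 variance
#' components: `V = var_rep Zr Zr' + var_block Zb Zb' + var_e I`, fixed
#' effects in cell-means coding so the reported `blue` is directly
#' `mu + L_j` on the trait scale (identical to an intercept +
#' sum-to-zero-genotype parameterisation, and independent of any
#' reference-level choice).
#'
#' With all random variances zero this reduces to ordinary least squares
#' (genotype means); for a balanced complete design the GLS and plain
#' genotype means coincide.
#'
#' @param plots Plot tibble with columns `env`, `rep`, `block`, `genotype`,
#'   `value`.
#' @param env Environment(s) to adjust; default all environments present,
#'   each fitted strictly on its own (no cross-environment pooling).
#' @param varcomps Optional named vector `c(var_rep, var_block, var_e)` to
#'   use instead of REML estimates (e.g. for oracle checks).
#' @return Tibble with columns `env`, `genotype`, `blue`.
#' @export
#' @examples
#' plots <- tibble::tibble(env = "E1", rep = rep(c("R1", "R2"), each = 3),
#'                         block = "B1", genotype = rep(c("g1", "g2", "g3"), 2),
#'                         value = c(1, 2, 3, 2, 3, 4))
#' compute_blues(plots)  # balanced: genotype means
compute_blues <- function(plots, env = NULL, varcomps = NULL) {
  envs <- env %||% unique(plots$env)
  purrr::map_dfr(envs, function(ev) {
    df <- dplyr::filter(plots, .data$env == !!ev)
    if (nrow(df) == 0) {
      abort(sprintf("No plots found for environment '%s'.", ev),
            class = "smet_config_error")
    }
    vc <- varcomps %||% estimate_stage1_varcomps(plots, ev)
    blues_one_env(df, vc) |>
      dplyr::mutate(env = ev, .before = 1)
  })
}

# GLS solve for one environment at fixed variance components
blues_one_env <- function(df, vc) {
  genos <- sort(unique(df$genotype))
  X <- stats::model.matrix(~ 0 + factor(genotype, levels = genos), data = df)
  colnames(X) <- genos
  if (qr(X)$rank < ncol(X)) {
    abort("Fixed-effect design is rank deficient (confounded genotype labels).",
          class = "smet_rank_error")
  }
  n <- nrow(df)
  var_e <- vc[["var_e"]]
  if (var_e <= 0) var_e <- 1  # OLS limit: scale of V is immaterial
  V <- diag(var_e, n)
  if (vc[["var_rep"]] > 0) {
    Zr <- stats::model.matrix(~ 0 + factor(rep), data = df)
    V <- V + vc[["var_rep"]] * tcrossprod(Zr)
  }
  if (vc[["var_block"]] > 0) {
    blk <- interaction(df$rep, df$block, drop = TRUE)
    Zb <- stats::model.matrix(~ 0 + blk)
    V <- V + vc[["var_block"]] * tcrossprod(Zb)
  }
  W <- solve(V, cbind(X, y = df$value))
  XtVinvX <- crossprod(X, W[, seq_along(genos), drop = FALSE])
  XtVinvy <- crossprod(X, W[, length(genos) + 1L])
  beta <- solve(XtVinvX, XtVinvy)
  tibble::tibble(genotype = genos, blue = as.numeric(beta))
}
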