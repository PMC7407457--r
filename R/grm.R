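#' Marker quality control
#'
#' Removes SNPs with a missing fraction above `max_missing` or a minor
#' allele frequency (computed on non-missing calls) below `min_maf`.
#' Both cut-offs follow the conventional strict reading: a marker is
#' dropped when its missingness is *more than* `max_missing` or its MAF is
#' *lower than* `min_maf`, so a marker sitting exactly on either threshold
#' is retained. Monomorphic markers (MAF 0) are always removed.
#' Genotype rows are never touched.
#'
#' @param markers Dosage matrix (genotypes x markers, values 0/1/2 or `NA`).
#' @param max_missing Maximum tolerated missing fraction per marker.
#' @param min_maf Minimum tolerated minor allele frequency.
#' @return The filtered dosage matrix (same class/attributes shape).
#' @export
#' @examples
#' M <- rbind(c(0, 0, 0), c(NA, 0, 1), c(NA, 0, 1), c(NA, 0, 2))
#' colnames(M) <- c("A", "B", "C"); rownames(M) <- paste0("G", 1:4)
#' colnames(qc_filter(M))  # only "C" survives
qc_filter <- function(markers, max_missing = 0.5, min_maf = 0.03) {
  stopifnot(is.matrix(markers))
  miss <- colMeans(is.na(markers))
  f <- colMeans(markers, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0  # all-missing column: treated as monomorphic
  # constant columns (e.g. every call heterozygous) carry no information and
  # would break standardization, whatever their nominal MAF
  v <- apply(markers, 2, function(col) var(col[!is.na(col)]))
  v[is.na(v)] <- 0
  keep <- miss <= max_missing & maf >= min_maf & maf > 0 & v > 0
  if (!any(keep)) {
    abort("Marker QC removed every marker; the panel is empty.",
          class = "smet_empty_panel_error")
  }
  out <- markers[, keep, drop = FALSE]
  af <- attr(markers, "allele_freq")
  if (!is.null(af)) attr(out, "allele_freq") <- af[keep]
  out
}

#' Impute and column-standardize a dosage matrix
#'
#' Missing dosages are replaced by their marker mean, then each column is
#' centred to mean zero and scaled to unit *population* (divisor-n)
#' standard deviation. Divisor-n scaling makes the mean diagonal of the
#' downstream relationship matrix exactly 1 (`trace(G) = n`); the divisor
#' is configurable for users who prefer the sample (n-1) convention.
#'
#' @param markers Dosage matrix, every column polymorphic with at least one
#'   non-missing call (run [qc_filter()] first).
#' @param divisor `"n"` (default) or `"n-1"` standard-deviation divisor.
#' @return Numeric matrix `X` of standardized dosages, same dimnames.
#' @export
#' @examples
#' X <- impute_and_standardize(cbind(m1 = c(0, 1, 2)))
#' colMeans(X)  # 0
impute_and_standardize <- function(markers, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  stopifnot(is.matrix(markers))
  X <- apply(markers, 2, function(col) {
    if (all(is.na(col))) return(col)
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    as.numeric(col)
  })
  X <- matrix(X, nrow = nrow(markers), dimnames = dimnames(markers))
  mu <- colMeans(X)
  n <- nrow(X)
  denom <- if (divisor == "n") n else n - 1
  sds <- sqrt(colSums(sweep(X, 2, mu)^2) / denom)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    abort(paste0("Zero-variance column(s) after imputation (should have ",
                 "been removed by QC): ",
                 paste(colnames(X)[bad] %||% which(bad), collapse = ", ")),
          class = "smet_standardize_error")
  }
  sweep(sweep(X, 2, mu), 2, sds, "/")
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Computes `G = X X' / p` from a column-standardized marker matrix `X`
#' with `p` markers. Under divisor-n standardization the diagonal of `G`
#' averages exactly 1 and `trace(G) = n`.
#'
#' @param X Column-standardized marker matrix from
#'   [impute_and_standardize()].
#' @return Symmetric `n x n` matrix with genotype IDs as dimnames.
#' @export
#' @examples
#' X <- impute_and_standardize(cbind(a = c(0, 1, 2), b = c(2, 1, 0)))
#' compute_grm(X)
compute_grm <- function(X) {
  stopifnot(is.matrix(X))
  p <- ncol(X)
  if (p == 0) {
    abort("Cannot build a relationship matrix from zero markers.",
          class = "smet_empty_panel_error")
  }
  G <- tcrossprod(X) / p
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}
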