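#' Read a marker dosage matrix
#'
#' TSV layout: first column genotype IDs, remaining columns marker IDs,
#' values 0/1/2 or `NA`. VCF input maps diploid biallelic GT fields to
#' dosages (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, missing -> `NA`);
#' records with more than one ALT allele are skipped and counted in a
#' message. VCF reading uses the `vcfR` package.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return Integer dosage matrix, genotypes x markers, with dimnames.
#' @export
read_markers <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Marker file not found: %s", path), class = "smet_io_error")
  }
  if (format == "vcf") return(read_markers_vcf(path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(sprintf("Empty or ID-only marker file: %s", path),
          class = "smet_io_error")
  }
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.integer(vals), nrow(vals), ncol(vals)))
  bad <- which((!is.na(vals) & vals != "NA" & is.na(num)) |
                 (!is.na(num) & !(num %in% 0:2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Invalid dosage '%s' at row %d (genotype %s), marker %s: expected 0/1/2 or NA.",
                  vals[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                  colnames(vals)[bad[1, 2]]),
          class = "smet_io_error")
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

read_markers_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the 'vcfR' package.", class = "smet_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi)) {
    inform(sprintf("Skipped %d non-biallelic VCF record(s).", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[gt %in% "0/0"] <- 0L
  dosage[gt %in% c("0/1", "1/0")] <- 1L
  dosage[gt %in% "1/1"] <- 2L
  t(dosage)  # genotypes x markers
}

#' Write a marker dosage matrix as TSV
#'
#' @param markers Dosage matrix with genotype rownames and marker colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  df <- tibble::as_tibble(markers, rownames = "genotype")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read/write the tabular interchange files
#'
#' Plot tables (`env, rep, block, genotype, value`), BLUE tables
#' (`env, genotype, blue`), design masks (`env, genotype, set` with `set`
#' in calibration/prediction) and square GRM CSVs (header row and first
#' column carry genotype IDs) all round-trip through these helpers.
#'
#' @param path File path.
#' @name smet_io
#' @return The read functions return tibbles (the GRM reader a matrix);
#'   writers return `path` invisibly.
NULL

#' @rdname smet_io
#' @export
read_plots <- function(path) {
  read_table_checked(path, c("env", "rep", "block", "genotype", "value"),
                     readr::cols(value = readr::col_double(),
                                 .default = readr::col_character()))
}

#' @rdname smet_io
#' @param plots,blues,mask,design,grm Objects to serialise.
#' @export
write_plots <- function(plots, path) {
  readr::write_csv(plots, path, progress = FALSE)
  invisible(path)
}

#' @rdname smet_io
#' @export
read_blues <- function(path) {
  read_table_checked(path, c("env", "genotype", "blue"),
                     readr::cols(blue = readr::col_double(),
                                 .default = readr::col_character()))
}

#' @rdname smet_io
#' @export
write_blues <- function(blues, path) {
  readr::write_csv(blues, path, progress = FALSE)
  invisible(path)
}

#' @rdname smet_io
#' @export
read_grm <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "smet_io_error")
  }
  df <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "double"
  dimnames(G) <- list(ids, colnames(df)[-1])
  G
}

#' @rdname smet_io
#' @export
write_grm <- function(grm, path) {
  df <- tibble::as_tibble(grm, rownames = "genotype")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname smet_io
#' @export
write_design_mask <- function(design, path) {
  mask <- dplyr::bind_rows(
    dplyr::mutate(design$calibration_cells, set = "calibration"),
    dplyr::mutate(design$prediction_cells, set = "prediction"))
  readr::write_csv(mask, path, progress = FALSE)
  invisible(path)
}

#' @rdname smet_io
#' @export
read_design_mask <- function(path) {
  read_table_checked(path, c("env", "genotype", "set"),
                     readr::cols(.default = readr::col_character()))
}

read_table_checked <- function(path, cols, col_types) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "smet_io_error")
  }
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "smet_io_error")
  }
  df
}
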