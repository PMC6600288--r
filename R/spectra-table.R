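#' The spectra-table dialect
#'
#' Throughout the package a dataset is a wide tibble: `sample_id`
#' (character), `adulterant` (character), `fraction_vv_pct` (numeric
#' reference value in % v/v), then one numeric absorbance column per
#' wavenumber whose name is the wavenumber in cm^-1 printed to two
#' decimals. These helpers move between that table and the plain
#' matrix/vector view the numerical core works on.
#'
#' @param data A spectra tibble.
#' @return `as_spectra_matrix()`: numeric matrix (samples x wavenumbers,
#'   rownames = sample ids); `spectra_wavenumbers()`: numeric vector of
#'   wavenumbers; `spectra_response()`: numeric reference vector.
#' @name spectra_table
NULL

meta_cols <- c("sample_id", "adulterant", "fraction_vv_pct")

spectral_col_names <- function(data) {
  setdiff(names(data), meta_cols)
}

#' @rdname spectra_table
#' @export
as_spectra_matrix <- function(data) {
  cols <- spectral_col_names(data)
  if (length(cols) == 0) stop("no spectral columns found.", call. = FALSE)
  X <- as.matrix(data[, cols, drop = FALSE])
  if (!is.numeric(X)) stop("spectral columns must be numeric.", call. = FALSE)
  if ("sample_id" %in% names(data)) rownames(X) <- data$sample_id
  X
}

#' @rdname spectra_table
#' @export
spectra_wavenumbers <- function(data) {
  wn <- suppressWarnings(as.numeric(spectral_col_names(data)))
  if (anyNA(wn)) {
    stop("spectral column names must be numeric wavenumbers.", call. = FALSE)
  }
  wn
}

#' @rdname spectra_table
#' @export
spectra_response <- function(data) {
  if (!"fraction_vv_pct" %in% names(data)) {
    stop("`fraction_vv_pct` column is missing.", call. = FALSE)
  }
  data$fraction_vv_pct
}

#' Read / write spectra CSV
#'
#' Plain UTF-8 CSV with "." decimal separator in the spectra-table dialect
#' (see [spectra_table]): `sample_id`, `adulterant`, `fraction_vv_pct`,
#' then one column per wavenumber.
#'
#' @param path File path.
#' @param data A spectra tibble.
#' @return `read_spectra()` returns a spectra tibble; `write_spectra()`
#'   returns `data` invisibly.
#' @export
read_spectra <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(meta_cols, names(out))
  if (length(missing) > 0) {
    stop("spectra CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  spectra_wavenumbers(out) # validates header
  out
}

#' @rdname read_spectra
#' @export
write_spectra <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
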