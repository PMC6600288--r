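#' Standard normal variate (SNV) transform
#'
#' Row-wise spectral normalization: each spectrum is centered to mean zero
#' and scaled to unit standard deviation (n-1 denominator). SNV removes
#' the per-spectrum multiplicative gain and additive baseline offset that
#' surface scattering and optical path-length variation impose, and is
#' invariant under any positive affine transform of a spectrum. It is
#' strictly row-local, so calibration and validation spectra can be
#' transformed independently without information leaking across the split.
#'
#' @param x A spectra tibble (spectral columns are transformed, metadata
#'   kept) or a numeric matrix (samples in rows).
#' @param ... Unused.
#' @return Object of the same shape as `x`.
#' @examples
#' snv(matrix(c(1, 2, 3), 1)) # -1 0 1
#' @export
snv <- function(x, ...) UseMethod("snv")

#' @rdname snv
#' @export
snv.matrix <- function(x, ...) {
  if (ncol(x) < 2) stop("SNV needs at least 2 points per row.", call. = FALSE)
  mu <- rowMeans(x)
  ctr <- x - mu
  sd_row <- sqrt(rowSums(ctr^2) / (ncol(x) - 1))
  bad <- which(sd_row < 1e-300)
  if (length(bad) > 0) {
    ids <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop("constant spectrum (zero variance) for sample(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  ctr / sd_row
}

#' @rdname snv
#' @export
snv.data.frame <- function(x, ...) {
  cols <- spectral_col_names(x)
  X <- snv(as_spectra_matrix(x))
  out <- x
  out[, cols] <- tibble::as_tibble(X)
  tibble::as_tibble(out)
}
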