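#' Uniform descending wavenumber grid
#'
#' FT-NIR spectrometers report absorbance on an evenly spaced wavenumber
#' axis running from high to low wavenumber. The defaults reproduce a
#' 1557-point grid spanning 9999.10 to 3999.64 cm^-1, the axis of a typical
#' transmission acquisition over 10,000-4000 cm^-1 at 4 cm^-1 resolution.
#'
#' @param start_cm1 First (largest) wavenumber in cm^-1.
#' @param end_cm1 Last (smallest) wavenumber in cm^-1; must be `< start_cm1`.
#' @param n_points Number of grid points (>= 2).
#'
#' @return A numeric vector of `n_points` strictly decreasing, uniformly
#'   spaced wavenumbers with exact endpoints.
#' @examples
#' g <- make_grid()
#' length(g)      # 1557
#' range(diff(g)) # constant spacing of about -3.8557 cm^-1
#' @export
make_grid <- function(start_cm1 = 9999.10, end_cm1 = 3999.64,
                      n_points = 1557) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 2 ||
      n_points != round(n_points)) {
    stop("`n_points` must be a single integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(start_cm1) || !is.numeric(end_cm1) ||
      start_cm1 <= end_cm1) {
    stop("`start_cm1` must be greater than `end_cm1` (descending grid).",
         call. = FALSE)
  }
  seq(start_cm1, end_cm1, length.out = n_points)
}

# column labels used in the spectra table / CSV dialect
wn_labels <- function(grid) sprintf("%.2f", grid)

#' @keywords internal
validate_grid <- function(grid) {
  if (length(grid) < 2) stop("grid needs at least 2 points.", call. = FALSE)
  d <- diff(grid)
  if (any(d >= 0)) stop("grid must be strictly descending.", call. = FALSE)
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
    stop("grid must be uniformly spaced.", call. = FALSE)
  }
  invisible(grid)
}
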