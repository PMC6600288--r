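#' Fit a single-response PLS regression (PLS1)
#'
#' Partial least squares projects predictors and response onto shared
#' latent factors and regresses through them, which makes it usable when
#' the predictors are many and collinear — the normal state of NIR
#' spectra. The fit uses the NIPALS algorithm with X-deflation; for a
#' single response NIPALS and SIMPLS coincide to numerical precision, and
#' at the maximal factor count the fit reproduces ordinary least squares
#' on full-rank data. If a factor's weight norm underflows (rank
#' deficiency) the factor count is reduced with a warning.
#'
#' @param x A spectra tibble (the response is taken from
#'   `fraction_vv_pct`) or a numeric predictor matrix.
#' @param y Numeric response; ignored when `x` is a spectra tibble.
#' @param ncomp Number of latent factors, `1 <= ncomp <= min(N - 1, P)`.
#' @return An object of class `pls1` with the centered-space coefficient
#'   vector, centering parameters, fitted values and the coefficient path
#'   over 1..ncomp factors.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' y <- X %*% c(1, -1, 0, 0, 0.5) + rnorm(8, sd = 0.01)
#' fit <- fit_pls(X, y, ncomp = 3)
#' glance(fit)
#' @export
fit_pls <- function(x, y = NULL, ncomp) {
  xy <- resolve_xy(x, y)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  p <- ncol(X)
  max_allowed <- min(n - 1, p)
  if (!is.numeric(ncomp) || length(ncomp) != 1 || ncomp < 1 ||
      ncomp != round(ncomp) || ncomp > max_allowed) {
    stop("`ncomp` must be an integer in [1, min(N - 1, P)] = [1, ",
         max_allowed, "].", call. = FALSE)
  }
  fit <- pls1_fit_cpp(X, y, as.integer(ncomp))
  if (fit$ncomp_used < ncomp) {
    warning("factor weights underflowed; using ", fit$ncomp_used,
            " of the requested ", ncomp, " factors.", call. = FALSE)
  }
  ncomp_used <- max(1L, fit$ncomp_used)
  b <- fit$coef_path[, ncomp, drop = TRUE]
  x_mean <- drop(fit$x_mean)
  fitted <- drop(sweep(X, 2, x_mean) %*% b) + fit$y_mean
  structure(list(
    ncomp = as.integer(ncomp),
    ncomp_used = as.integer(ncomp_used),
    coefficients = b,
    coef_path = fit$coef_path,
    x_mean = x_mean,
    y_mean = fit$y_mean,
    wavenumbers = colnames(X),
    fitted = fitted,
    y = y
  ), class = "pls1")
}

# accept a spectra tibble or matrix + response vector
resolve_xy <- function(x, y) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- spectra_response(x)
    X <- as_spectra_matrix(x)
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("`y` is required when `x` is a matrix.",
                         call. = FALSE)
  }
  if (nrow(X) != length(y)) {
    stop("number of rows of X must equal length of y.", call. = FALSE)
  }
  list(X = X, y = as.numeric(y))
}

#' Predict from a fitted PLS1 model
#'
#' @param object A `pls1` fit.
#' @param newdata A spectra tibble or numeric matrix with the same
#'   predictor columns as the training data.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as_spectra_matrix(newdata)
       else as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop("`newdata` has ", ncol(X), " predictor columns; the model was ",
         "fitted with ", length(object$coefficients), ".", call. = FALSE)
  }
  drop(sweep(X, 2, object$x_mean) %*% object$coefficients) + object$y_mean
}

#' @export
tidy.pls1 <- function(x, ...) {
  wn <- x$wavenumbers
  tibble::tibble(
    term = if (is.null(wn)) as.character(seq_along(x$coefficients)) else wn,
    estimate = unname(x$coefficients)
  )
}

#' @export
glance.pls1 <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp,
    ncomp_used = x$ncomp_used,
    r_squared = r_squared(x$y, x$fitted),
    rmse = sqrt(mean((x$y - x$fitted)^2)),
    nobs = length(x$y)
  )
}

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 model:", length(x$coefficients), "variables,",
      x$ncomp, "latent factors\n")
  invisible(x)
}

#' Root-mean-square error of prediction
#'
#' `sqrt(mean((y - yhat)^2))` over an independent validation set, in the
#' units of the response (% v/v here).
#'
#' @param y_true,y_pred Numeric vectors of equal positive length.
#' @return A single number.
#' @export
rmsep <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal positive length.",
         call. = FALSE)
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` against the mean of `y_true`; can be negative for
#' models worse than the mean, and errors on a constant reference vector.
#'
#' @inheritParams rmsep
#' @return A single number, at most 1.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length.", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) {
    stop("`y_true` is constant; R^2 is undefined.", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

# seeded shuffle, then contiguous blocks; earlier folds get the remainder
make_folds <- function(n, n_folds, seed = NULL) {
  if (n_folds < 2 || n_folds > n) {
    stop("`n_folds` must lie in [2, N].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(floor(n / n_folds), n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  fold <- integer(n)
  fold[sample.int(n)] <- rep.int(seq_len(n_folds), sizes)
  fold
}

#' Cross-validated RMSECV curve over factor counts
#'
#' Partitions the samples into `n_folds` shuffled contiguous-block folds,
#' refits on each fold's complement for every factor count 1..`max_factors`
#' (capped at `min(N - 1, P)` and at what each training fold supports),
#' and pools the out-of-fold residuals. `rmsecv()` evaluates the curve at
#' one factor count; with `n_folds = N` it is exact leave-one-out.
#'
#' @inheritParams fit_pls
#' @param max_factors Largest factor count to evaluate.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Optional seed for the fold shuffle.
#' @param folds Optional explicit integer fold assignment (values in
#'   `1..n_folds`), overriding `n_folds`/`seed`.
#' @return `rmsecv_curve()`: tibble with `ncomp` and `rmsecv`;
#'   `rmsecv()`: a single number in response units.
#' @export
rmsecv_curve <- function(x, y = NULL, max_factors = 15, n_folds = 5,
                         seed = NULL, folds = NULL) {
  xy <- resolve_xy(x, y)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  if (is.null(folds)) {
    folds <- make_folds(n, n_folds, seed)
  } else if (length(folds) != n) {
    stop("`folds` must assign one fold per sample.", call. = FALSE)
  }
  a_max <- max(1L, min(as.integer(max_factors), n - 1L, ncol(X)))
  pred <- pls1_cv_cpp(X, y, a_max, as.integer(folds))
  tibble::tibble(
    ncomp = seq_len(a_max),
    rmsecv = sqrt(colMeans((pred - y)^2))
  )
}

#' @rdname rmsecv_curve
#' @param ncomp Factor count at which to report the RMSECV.
#' @export
rmsecv <- function(x, y = NULL, ncomp, n_folds = 5, seed = NULL,
                   folds = NULL) {
  curve <- rmsecv_curve(x, y, max_factors = ncomp, n_folds = n_folds,
                        seed = seed, folds = folds)
  if (ncomp > nrow(curve)) {
    stop("`ncomp` exceeds the feasible factor count ", nrow(curve), ".",
         call. = FALSE)
  }
  curve$rmsecv[ncomp]
}

#' Choose the PLS factor count by cross-validation
#'
#' Returns the factor count minimizing the RMSECV curve, ties broken
#' toward fewer factors. The curve is attached as attribute
#' `"rmsecv_curve"` and the attained minimum as `"rmsecv"`.
#'
#' @inheritParams rmsecv_curve
#' @return An integer factor count.
#' @export
select_n_factors <- function(x, y = NULL, max_factors = 15, n_folds = 5,
                             seed = NULL, folds = NULL) {
  curve <- rmsecv_curve(x, y, max_factors = max_factors, n_folds = n_folds,
                        seed = seed, folds = folds)
  best <- which.min(curve$rmsecv) # which.min takes the first = fewest
  structure(as.integer(curve$ncomp[best]),
            rmsecv = curve$rmsecv[best],
            rmsecv_curve = curve)
}
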