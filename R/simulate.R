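#' Parametric pure-oil spectrum model
#'
#' A pure-component NIR spectrum is represented as a sum of Gaussian
#' absorption bands on a smooth polynomial background. This is not a
#' physical band assignment; it is the minimal shape family that gives
#' mixtures the statistical structure a linear calibration assumes:
#' localized concentration-dependent signal on a smooth uninformative
#' baseline.
#'
#' @param name Species label, e.g. `"evoo"` or `"sunflower"`.
#' @param bands Data frame with columns `center` (cm^-1), `width` (cm^-1,
#'   Gaussian sigma, > 0) and `amplitude` (absorbance units, >= 0); at
#'   least one band.
#' @param background Polynomial coefficients (constant first) evaluated on
#'   the wavenumber axis rescaled to \[-1, 1\], so coefficients stay O(1).
#'
#' @return An object of class `oil_spectrum`.
#' @export
oil_spectrum <- function(name, bands, background = 0) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)))
  if (nrow(bands) < 1) stop("need at least one band.", call. = FALSE)
  if (any(bands$width <= 0)) stop("band widths must be > 0.", call. = FALSE)
  if (any(bands$amplitude < 0)) {
    stop("band amplitudes must be >= 0.", call. = FALSE)
  }
  structure(list(name = name, bands = bands,
                 background = as.numeric(background)),
            class = "oil_spectrum")
}

#' Per-spectrum measurement artifact model
#'
#' Each simulated spectrum is distorted by a global multiplicative gain
#' (surface scattering / effective path-length change), a global additive
#' baseline offset, and i.i.d. point noise — exactly the distortions the
#' standard normal variate transform is designed to remove. The default
#' `noise_sd` is small because instruments average replicate scans (three
#' in a typical acquisition) before analysis; the generator emulates that
#' averaging with a single reduced-noise draw.
#'
#' @param multiplicative_scatter_sd SD of the gain around 1 (dimensionless).
#' @param additive_baseline_sd SD of the baseline offset (absorbance).
#' @param noise_sd SD of per-point noise (absorbance).
#' @return An object of class `artifact_model`.
#' @export
artifact_model <- function(multiplicative_scatter_sd = 0.05,
                           additive_baseline_sd = 0.02,
                           noise_sd = 5e-4) {
  sds <- c(multiplicative_scatter_sd, additive_baseline_sd, noise_sd)
  if (any(sds < 0)) stop("artifact sds must be >= 0.", call. = FALSE)
  structure(list(multiplicative_scatter_sd = multiplicative_scatter_sd,
                 additive_baseline_sd = additive_baseline_sd,
                 noise_sd = noise_sd),
            class = "artifact_model")
}

#' Adulteration sampling design
#'
#' The default design mixes each of five cheaper edible oils into extra
#' virgin olive oil at volume fractions 2.5 to 50 % v/v in 2.5 % steps:
#' 20 levels x 5 adulterants = 100 samples.
#'
#' @param adulterants Character vector of adulterant species names.
#' @param fraction_min,fraction_max,fraction_step Volume-fraction range and
#'   step in % v/v.
#' @return An object of class `adulteration_design`.
#' @export
adulteration_design <- function(adulterants = c("peanut", "sunflower",
                                                "soybean", "sesame",
                                                "maize"),
                                fraction_min = 2.5, fraction_max = 50,
                                fraction_step = 2.5) {
  if (!(fraction_min > 0 && fraction_min <= fraction_max &&
        fraction_max <= 100 && fraction_step > 0)) {
    stop("need 0 < fraction_min <= fraction_max <= 100 and step > 0.",
         call. = FALSE)
  }
  structure(list(adulterants = adulterants, fraction_min = fraction_min,
                 fraction_max = fraction_max, fraction_step = fraction_step),
            class = "adulteration_design")
}

#' @rdname adulteration_design
#' @param design An `adulteration_design`.
#' @export
fraction_levels <- function(design) {
  n_levels <- floor((design$fraction_max - design$fraction_min) /
                      design$fraction_step) + 1
  design$fraction_min + design$fraction_step * (seq_len(n_levels) - 1)
}

#' Evaluate a pure-oil model on a wavenumber grid
#'
#' Deterministic: background polynomial plus the sum of the Gaussian
#' bands; no measurement artifacts.
#'
#' @param model An [oil_spectrum()].
#' @param grid Wavenumber grid from [make_grid()].
#' @return Numeric vector of absorbance, one value per grid point.
#' @export
simulate_pure_spectrum <- function(model, grid) {
  stopifnot(inherits(model, "oil_spectrum"))
  validate_grid(grid)
  tt <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  s <- rep(0, length(grid))
  for (j in seq_along(model$background)) {
    s <- s + model$background[j] * tt^(j - 1)
  }
  for (i in seq_len(nrow(model$bands))) {
    b <- model$bands[i, ]
    s <- s + b$amplitude * exp(-0.5 * ((grid - b$center) / b$width)^2)
  }
  s
}

#' Simulate one adulterated-oil spectrum
#'
#' Ideal Beer-Lambert volumetric mixing of the two pure-component spectra,
#' followed by the per-spectrum artifacts: the returned spectrum is
#' `m * clean + b + eps` with `m ~ 1 + N(0, scatter_sd)`,
#' `b ~ N(0, baseline_sd)` and i.i.d. point noise `eps`. Draws come from
#' the current R random number stream; seed the stream for reproducibility.
#'
#' @param evoo,adulterant [oil_spectrum()] models.
#' @param fraction Adulterant volume fraction in % v/v, within \[0, 100\].
#' @param grid Wavenumber grid.
#' @param artifacts An [artifact_model()].
#' @return Numeric absorbance vector on `grid`.
#' @export
simulate_mixture <- function(evoo, adulterant, fraction, grid,
                             artifacts = artifact_model()) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 100) {
    stop("`fraction` must lie in [0, 100] % v/v.", call. = FALSE)
  }
  f <- fraction / 100
  clean <- (1 - f) * simulate_pure_spectrum(evoo, grid) +
    f * simulate_pure_spectrum(adulterant, grid)
  m <- 1 + stats::rnorm(1, 0, artifacts$multiplicative_scatter_sd)
  b <- stats::rnorm(1, 0, artifacts$additive_baseline_sd)
  eps <- stats::rnorm(length(grid), 0, artifacts$noise_sd)
  m * clean + b + eps
}

#' Built-in pure-oil spectral library
#'
#' One model for extra virgin olive oil plus one per default adulterant.
#' All oils share the dominant C-H overtone and combination bands of
#' triacylglycerols; the adulterants carry additional weak bands near
#' 5900 cm^-1 and 4670 cm^-1 (with species-specific amplitudes and small
#' center shifts) so that their difference spectra against olive oil are
#' concentrated there. A correct wavenumber selector run on mixtures from
#' this library should therefore pick channels in the 5750-5940 and
#' 4370-4710 cm^-1 regions.
#'
#' @return Named list of [oil_spectrum()] objects, first element `evoo`.
#' @export
default_oil_library <- function() {
  base_bands <- tibble::tibble(
    center    = c(8260, 7180, 6900, 5790, 5670, 4720, 4335, 4260),
    width     = c(130, 90, 140, 62, 58, 55, 42, 46),
    amplitude = c(0.14, 0.06, 0.10, 0.55, 0.46, 0.12, 0.72, 0.66)
  )
  bg <- c(0.12, 0.025, 0.012)
  evoo <- oil_spectrum("evoo", base_bands, bg)

  # adulterant = shared skeleton with slightly perturbed shared bands plus
  # extra bands in the regions where seed oils differ from olive oil
  make_adulterant <- function(name, a59, c59, a467, c467, tweak) {
    bands <- base_bands
    bands$amplitude <- bands$amplitude * tweak
    extra <- tibble::tibble(
      center    = c(c59, 5870, c467, 4405),
      width     = c(28, 35, 34, 30),
      amplitude = c(a59, 0.6 * a59, a467, 0.45 * a467)
    )
    oil_spectrum(name, rbind(bands, extra), bg)
  }

  list(
    evoo      = evoo,
    peanut    = make_adulterant("peanut",    0.060, 5902, 0.050, 4676, 0.985),
    sunflower = make_adulterant("sunflower", 0.072, 5898, 0.058, 4670, 1.015),
    soybean   = make_adulterant("soybean",   0.066, 5905, 0.054, 4673, 1.010),
    sesame    = make_adulterant("sesame",    0.057, 5896, 0.047, 4668, 0.990),
    maize     = make_adulterant("maize",     0.069, 5900, 0.056, 4679, 1.005)
  )
}

#' Simulate a full adulteration dataset
#'
#' One sample per (adulterant, volume-fraction level) pair of the design;
#' with the defaults that is 100 samples on a 1557-point grid. Output is a
#' wide tibble in the package's spectra-table dialect: `sample_id`,
#' `adulterant`, `fraction_vv_pct`, then one absorbance column per
#' wavenumber, named with the wavenumber printed to two decimals.
#'
#' @param design An [adulteration_design()].
#' @param oils Named list of [oil_spectrum()] models containing `evoo` and
#'   one entry per adulterant in the design.
#' @param grid Wavenumber grid.
#' @param artifacts An [artifact_model()].
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return A spectra tibble with `n_adulterants * n_levels` rows.
#' @examples
#' ds <- simulate_adulteration(seed = 1)
#' dim(ds) # 100 x 1560
#' @export
simulate_adulteration <- function(design = adulteration_design(),
                                  oils = default_oil_library(),
                                  grid = make_grid(),
                                  artifacts = artifact_model(),
                                  seed = NULL) {
  missing_oil <- setdiff(c("evoo", design$adulterants), names(oils))
  if (length(missing_oil) > 0) {
    stop("missing oil model(s): ", paste(missing_oil, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  levels <- fraction_levels(design)
  combos <- tidyr::expand_grid(adulterant = design$adulterants,
                               fraction_vv_pct = levels)
  X <- matrix(0, nrow(combos), length(grid))
  for (i in seq_len(nrow(combos))) {
    X[i, ] <- simulate_mixture(oils$evoo, oils[[combos$adulterant[i]]],
                               combos$fraction_vv_pct[i], grid, artifacts)
  }
  colnames(X) <- wn_labels(grid)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(nrow(combos)))),
    combos,
    tibble::as_tibble(X)
  )
}

#' Split a dataset into calibration and validation sets
#'
#' Stratified by concentration: for every distinct reference value,
#' `per_level` samples are drawn at random into the calibration set and
#' the rest go to validation. With the default 100-sample design and
#' `per_level = 3` this yields the classic 60/40 split (3 of the 5
#' same-concentration samples calibrate, 2 validate, at each of 20 levels).
#'
#' @param data A spectra tibble (see [simulate_adulteration()]).
#' @param per_level Calibration samples per distinct concentration.
#' @param seed Optional integer seed for the draw.
#' @return List with tibbles `calibration` and `validation`; together they
#'   partition the input rows.
#' @export
split_calibration <- function(data, per_level = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- spectra_response(data)
  counts <- table(y)
  if (any(counts < per_level)) {
    stop("some concentration level has fewer than `per_level` samples.",
         call. = FALSE)
  }
  cal_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    ix[sample.int(length(ix), per_level)]
  }), use.names = FALSE)
  cal_idx <- sort(cal_idx)
  list(calibration = data[cal_idx, , drop = FALSE],
       validation  = data[setdiff(seq_along(y), cal_idx), , drop = FALSE])
}

#' Simulate a planted-signal benchmark matrix
#'
#' A ground-truth testbed for variable selection: `n_informative` columns
#' carry an affine signal in the reference value (distinct amplitudes,
#' independent measurement noise), while the remaining columns are
#' correlated distractors built from a few smooth latent factors plus
#' noise — structure, but none of it related to y. A further `n_wild`
#' distractor columns get `wild_noise_mult` times the base noise SD,
#' emulating the near-overflow channels of real FT-NIR acquisitions;
#' their large y-unrelated variance is what genuinely degrades a
#' full-spectrum calibration and what a variable selector is expected to
#' remove. The response follows the adulteration design (20 levels,
#' 2.5-50 % v/v, replicated).
#'
#' @param n_samples Number of rows (default 100).
#' @param p Number of columns (default 200).
#' @param n_informative Number of signal-carrying columns (default 10).
#' @param signal_amplitudes Absorbance change over the full concentration
#'   range for each informative column; recycled/truncated to
#'   `n_informative`.
#' @param noise_sd Per-point noise SD (absorbance).
#' @param n_latent Number of smooth distractor factors.
#' @param n_wild Number of high-noise ("near overflow") distractor columns.
#' @param wild_noise_mult Noise-SD multiplier for the wild columns.
#' @param seed Integer seed.
#' @return List with matrix `X` (n x p), vector `y` (% v/v), integer
#'   vector `informative` of planted column indices, and integer vector
#'   `wild` of high-noise column indices.
#' @export
simulate_planted <- function(n_samples = 100, p = 200, n_informative = 10,
                             signal_amplitudes = seq(0.04, 0.12,
                                                     length.out = n_informative),
                             noise_sd = 0.005, n_latent = 3, n_wild = 30,
                             wild_noise_mult = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  levels <- seq(2.5, 50, by = 2.5)
  y <- rep(levels, length.out = n_samples)
  amp <- rep_len(signal_amplitudes, n_informative)
  informative <- sort(sample.int(p, n_informative))
  wild <- sample(setdiff(seq_len(p), informative), n_wild)

  # smooth latent distractor structure shared by all columns
  grid01 <- seq(0, 1, length.out = p)
  loadings <- sapply(seq_len(n_latent), function(k) {
    0.05 * sin(pi * k * grid01 + stats::runif(1, 0, 2 * pi))
  })
  scores <- matrix(stats::rnorm(n_samples * n_latent), n_samples, n_latent)
  X <- scores %*% t(loadings) +
    matrix(stats::rnorm(n_samples * p, 0, noise_sd), n_samples, p)
  if (n_wild > 0) {
    X[, wild] <- X[, wild] +
      matrix(stats::rnorm(n_samples * n_wild, 0, noise_sd * wild_noise_mult),
             n_samples, n_wild)
  }
  for (j in seq_len(n_informative)) {
    X[, informative[j]] <- X[, informative[j]] + amp[j] * y / 50
  }
  list(X = X, y = y, informative = informative, wild = sort(wild))
}
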