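# small fixtures shared across test files; everything is generated in code

# tiny noise-free oil models: one shared band, one band only the
# adulterant has, flat background
tiny_oils <- function() {
  evoo <- oil_spectrum(
    "evoo",
    data.frame(center = c(5800, 4300), width = c(50, 40),
               amplitude = c(0.5, 0.4)),
    background = 0.1
  )
  adult <- oil_spectrum(
    "adult",
    data.frame(center = c(5800, 4300, 5900), width = c(50, 40, 30),
               amplitude = c(0.45, 0.42, 0.2)),
    background = 0.1
  )
  adult2 <- oil_spectrum(
    "adult2",
    data.frame(center = c(5800, 4300, 5850), width = c(50, 40, 35),
               amplitude = c(0.48, 0.38, 0.15)),
    background = 0.1
  )
  list(evoo = evoo, adult = adult, adult2 = adult2)
}

no_artifacts <- function() artifact_model(0, 0, 0)

tiny_grid <- function(n = 60) make_grid(6200, 4000, n)

# noise-free single-adulterant dataset: y is exactly affine in X
tiny_dataset <- function(seed = 1, n_grid = 60) {
  oils <- tiny_oils()
  simulate_adulteration(
    design = adulteration_design(adulterants = "adult"),
    oils = oils, grid = tiny_grid(n_grid), artifacts = no_artifacts(),
    seed = seed
  )
}

# matrix with a handful of exactly informative columns and pure-noise
# columns; y noise-free linear in the informative block
planted_matrix <- function(n = 24, p = 6, informative = c(2, 5),
                           noise_cols_sd = 1, seed = 42) {
  set.seed(seed)
  y <- rep(seq(2.5, 30, by = 2.5), length.out = n)
  X <- matrix(stats::rnorm(n * p, sd = noise_cols_sd), n, p)
  for (k in seq_along(informative)) {
    X[, informative[k]] <- (0.5 + 0.3 * k) * y
  }
  list(X = X, y = y, informative = informative)
}

# stratified calibration/validation split of a planted list (matrix form)
split_planted <- function(pl, per_level = 3, seed = 1) {
  set.seed(seed)
  cal_idx <- sort(unlist(lapply(split(seq_along(pl$y), pl$y), function(ix) {
    ix[sample.int(length(ix), per_level)]
  }), use.names = FALSE))
  list(cal_idx = cal_idx, val_idx = setdiff(seq_along(pl$y), cal_idx))
}
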