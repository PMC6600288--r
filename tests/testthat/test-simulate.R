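grid <- tiny_grid()

test_that("pure spectra are background plus Gaussian bands, linearly", {
  zero <- oil_spectrum("zero", data.frame(center = 5000, width = 10,
                                          amplitude = 0), background = 0)
  expect_identical(simulate_pure_spectrum(zero, grid), rep(0, length(grid)))

  # single band centered on a grid point peaks at its amplitude there
  center <- grid[17]
  one <- oil_spectrum("one", data.frame(center = center, width = 30,
                                        amplitude = 0.7), background = 0)
  s1 <- simulate_pure_spectrum(one, grid)
  expect_equal(s1[17], 0.7)
  expect_equal(which.max(s1), 17L)

  two_a <- oil_spectrum("a", data.frame(center = 5000, width = 40,
                                        amplitude = 0.3), background = 0)
  two_b <- oil_spectrum("b", data.frame(center = 4400, width = 25,
                                        amplitude = 0.5), background = 0)
  both <- oil_spectrum("ab", rbind(two_a$bands, two_b$bands), background = 0)
  expect_equal(simulate_pure_spectrum(both, grid),
               simulate_pure_spectrum(two_a, grid) +
                 simulate_pure_spectrum(two_b, grid))
})

test_that("mixing is volumetric and degenerate fractions recover the pure oils", {
  oils <- tiny_oils()
  pure_e <- simulate_pure_spectrum(oils$evoo, grid)
  pure_a <- simulate_pure_spectrum(oils$adult, grid)
  expect_equal(simulate_mixture(oils$evoo, oils$adult, 0, grid,
                                no_artifacts()), pure_e)
  expect_equal(simulate_mixture(oils$evoo, oils$adult, 100, grid,
                                no_artifacts()), pure_a)
  expect_equal(simulate_mixture(oils$evoo, oils$adult, 50, grid,
                                no_artifacts()), (pure_e + pure_a) / 2)
  expect_error(simulate_mixture(oils$evoo, oils$adult, -1, grid), "0, 100")
  expect_error(simulate_mixture(oils$evoo, oils$adult, 101, grid), "0, 100")
})

test_that("the default design yields 100 samples and simulation is seed-deterministic", {
  ds <- simulate_adulteration(grid = grid, seed = 11)
  expect_identical(nrow(ds), 100L)
  expect_identical(ncol(ds), length(grid) + 3L)
  expect_setequal(unique(ds$adulterant),
                  c("peanut", "sunflower", "soybean", "sesame", "maize"))
  expect_true(all(ds$fraction_vv_pct >= 0 & ds$fraction_vv_pct <= 100))

  ds2 <- simulate_adulteration(grid = grid, seed = 11)
  expect_identical(ds, ds2)

  single <- simulate_adulteration(
    design = adulteration_design(adulterants = "adult", fraction_min = 10,
                                 fraction_max = 10, fraction_step = 2.5),
    oils = tiny_oils(), grid = grid, seed = 1
  )
  expect_identical(nrow(single), 1L)

  expect_error(
    simulate_adulteration(design = adulteration_design(),
                          oils = tiny_oils(), grid = grid),
    "missing oil model"
  )
})

test_that("the calibration/validation split is a stratified partition", {
  ds <- simulate_adulteration(grid = grid, seed = 5)
  sp <- split_calibration(ds, per_level = 3, seed = 9)
  expect_identical(nrow(sp$calibration), 60L)
  expect_identical(nrow(sp$validation), 40L)
  # exactly 3 calibration samples per concentration level
  expect_true(all(table(sp$calibration$fraction_vv_pct) == 3))

  for (s in 1:5) {
    sp_s <- split_calibration(ds, per_level = 3, seed = s)
    ids <- c(sp_s$calibration$sample_id, sp_s$validation$sample_id)
    expect_setequal(ids, ds$sample_id)
    expect_length(intersect(sp_s$calibration$sample_id,
                            sp_s$validation$sample_id), 0)
  }

  # per_level equal to the level multiplicity empties the validation set
  sp_all <- split_calibration(ds, per_level = 5, seed = 1)
  expect_identical(nrow(sp_all$validation), 0L)
  expect_error(split_calibration(ds, per_level = 6), "fewer than")
})

test_that("without artifacts the band-center absorbance is affine in the fraction", {
  ds <- tiny_dataset(seed = 3)
  wn <- spectra_wavenumbers(ds)
  X <- as_spectra_matrix(ds)
  # the adulterant-only band sits at 5900 cm^-1
  j <- which.min(abs(wn - 5900))
  expect_gt(stats::cor(X[, j], ds$fraction_vv_pct)^2, 1 - 1e-12)
})

test_that("the planted benchmark is reproducible and marks its structure", {
  p1 <- simulate_planted(seed = 8)
  p2 <- simulate_planted(seed = 8)
  expect_identical(p1, p2)
  expect_identical(dim(p1$X), c(100L, 200L))
  expect_length(p1$informative, 10)
  expect_length(p1$wild, 30)
  expect_length(intersect(p1$informative, p1$wild), 0)
})

test_that("spectra survive a CSV round trip", {
  ds <- tiny_dataset(seed = 2, n_grid = 12)
  path <- tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)
  expect_identical(spectra_wavenumbers(back), spectra_wavenumbers(ds))
  unlink(path)
})
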