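test_that("subset draws honour the weights", {
  set.seed(1)
  w <- rep(0, 10)
  w[4] <- 2.5
  subs <- draw_subsets(10, w, n_subsets = 50, n_draws = 7)
  expect_true(all(vapply(subs, identical, logical(1), 4L)))

  # zero-weight variables are never drawn
  w2 <- c(rep(1, 6), rep(0, 4))
  subs2 <- draw_subsets(10, w2, n_subsets = 200, n_draws = 10)
  expect_false(any(unlist(subs2) > 6))

  expect_error(draw_subsets(5, rep(0, 5), 10, 5), "zero")
  expect_error(draw_subsets(5, rep(1, 4), 10, 5), "non-negative")
})

test_that("sub-models carry cross-validated errors and unit-length evidence", {
  pl <- planted_matrix()
  folds <- make_folds(length(pl$y), 5, seed = 3)

  sm <- fit_submodels(pl$X, pl$y, list(pl$informative, 3L, pl$informative),
                      max_factors = 5, folds = folds)
  # the exactly informative subset interpolates
  expect_lt(sm$rmsecv[1], 1e-6)
  # single-variable subsets have trivially unit coefficient evidence
  expect_equal(sm$b_norm[[2]], 1)
  # duplicate subsets under one fold assignment are identical
  expect_identical(sm$rmsecv[1], sm$rmsecv[3])
  expect_identical(sm$b_norm[[1]], sm$b_norm[[3]])
  # coefficient evidence is an absolute unit-norm vector
  expect_equal(sqrt(sum(sm$b_norm[[1]]^2)), 1, tolerance = 1e-10)
  expect_true(all(sm$b_norm[[1]] >= 0))

  expect_error(fit_submodels(pl$X, pl$y, list(c(1L, 99L)), folds = folds),
               "out-of-range")
})

test_that("top extraction is an order statistic with pinned tie-breaks", {
  sm <- tibble::tibble(
    vars = list(1:3, 1:2, 1L, 1:4, 2:3),
    n_vars = c(3L, 2L, 1L, 4L, 2L),
    ncomp = 1L,
    rmsecv = c(0.5, 0.2, 0.9, 0.2, 0.1),
    b_norm = list(rep(1, 3), rep(1, 2), 1, rep(1, 4), rep(1, 2))
  )
  top1 <- select_top(sm[1:5, ], 0.10) # ceiling(5 * 0.1) = 1
  expect_identical(top1$rmsecv, 0.1)
  top3 <- select_top(sm, 0.5)
  expect_lte(max(top3$rmsecv), min(sm$rmsecv[!sm$rmsecv %in% top3$rmsecv]))
  # ties: fewer variables first, then input order
  expect_identical(top3$n_vars, c(2L, 2L, 4L))

  tied <- sm
  tied$rmsecv <- rep(0.3, 5)
  expect_identical(select_top(tied, 0.5)$n_vars, c(1L, 2L, 2L))
})

test_that("weight accumulation is additive, zero-padded and Cauchy-Schwarz bounded", {
  one <- tibble::tibble(vars = list(c(3L, 6L)), n_vars = 2L, ncomp = 1L,
                        rmsecv = 0.1, b_norm = list(c(0.6, 0.8)))
  expect_equal(update_weights(one, 6), c(0, 0, 0.6, 0, 0, 0.8))
  two <- dplyr::bind_rows(one, one)
  expect_equal(update_weights(two, 6), 2 * update_weights(one, 6))

  set.seed(11)
  pl <- planted_matrix(n = 30, p = 8)
  folds <- make_folds(30, 5, seed = 1)
  subs <- draw_subsets(8, rep(1, 8), 40, 8)
  sm <- fit_submodels(pl$X, pl$y, subs, max_factors = 4, folds = folds)
  top <- select_top(sm, 0.25)
  w <- update_weights(top, 8)
  # each sub-model's l1 evidence is at most sqrt(its size)
  expect_true(all(vapply(top$b_norm, sum, numeric(1)) <=
                    sqrt(top$n_vars) + 1e-10))
  expect_lte(sum(w), nrow(top) * sqrt(max(top$n_vars)) + 1e-10)
  # variables in no top sub-model have weight exactly zero
  absent <- setdiff(1:8, unlist(top$vars))
  expect_true(all(w[absent] == 0))
})

test_that("the next draw count is the rounded mean top sub-model size", {
  mk <- function(sizes) tibble::tibble(
    vars = lapply(sizes, seq_len), n_vars = as.integer(sizes),
    ncomp = 1L, rmsecv = 0.1, b_norm = lapply(sizes, function(s) rep(1, s))
  )
  expect_identical(next_n_draws(mk(c(10, 12, 14))), 12L)
  expect_identical(next_n_draws(mk(c(1, 1, 1))), 1L)
  expect_identical(next_n_draws(mk(c(1, 2))), 2L) # round half up
})

test_that("BOSS isolates an informative variable from pure noise", {
  set.seed(20)
  y <- rep(seq(2, 24, by = 2), 2)
  for (s in 1:5) {
    set.seed(100 + s)
    X <- cbind(0.8 * y, rnorm(length(y)))
    b <- run_boss(X, y, n_subsets = 30, top_fraction = 0.1, n_folds = 4,
                  max_factors = 1, seed = s)
    expect_identical(b$selected_idx, 1L)
    expect_lt(b$rmsecv, 1e-8)
  }
})

test_that("weight support only ever shrinks and runs are reproducible", {
  pl <- simulate_planted(p = 40, n_informative = 4,
                         signal_amplitudes = seq(0.05, 0.12, length.out = 4),
                         n_wild = 6, seed = 2)
  b1 <- run_boss(pl$X, pl$y, n_subsets = 50, seed = 77)
  b2 <- run_boss(pl$X, pl$y, n_subsets = 50, seed = 77)
  expect_identical(b1[setdiff(names(b1), "trajectory")],
                   b2[setdiff(names(b2), "trajectory")])
  expect_identical(b1$trajectory, b2$trajectory)

  W <- b1$trajectory$weights
  for (t in 2:length(W)) {
    expect_length(setdiff(which(W[[t]] > 0), which(W[[t - 1]] > 0)), 0)
  }
  # the selected set is the best sub-model at the chosen iteration
  expect_identical(b1$selected_idx,
                   sort(b1$trajectory$best_vars[[b1$chosen_iteration]]))
})

test_that("the trajectory shrinks to one variable with an interior RMSECV minimum", {
  pl <- simulate_planted(seed = 3)
  b <- run_boss(pl$X, pl$y, n_subsets = 200, seed = 7)
  tr <- b$trajectory
  expect_true(all(diff(tr$n_draws) < 0))
  expect_identical(tr$n_draws[nrow(tr)], 1L)
  r <- tr$best_rmsecv
  tmin <- which.min(r)
  expect_gt(tmin, 1)
  expect_lt(tmin, nrow(tr))
  expect_gt(r[nrow(tr)], r[tmin]) # rises again once too much is discarded
  expect_gte(b$chosen_iteration, 2)
})
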