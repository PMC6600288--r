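#' Draw bootstrap variable subsets
#'
#' One subset is the set of distinct indices among `n_draws` independent
#' draws with replacement from `1..p`, with draw probability proportional
#' to the current variable weights. Uniform weights give plain bootstrap
#' sampling (expected coverage `1 - (1 - 1/p)^n_draws`, about 63.2% when
#' `n_draws = p`); zero-weight variables can never enter a subset, which
#' is what makes the shrinkage "soft but irreversible" once a variable
#' drops out of every top sub-model.
#'
#' @param p Number of candidate variables.
#' @param weights Non-negative weight per variable; not all zero.
#' @param n_subsets Number of subsets K to draw.
#' @param n_draws Draws with replacement per subset.
#' @return List of `n_subsets` sorted integer index vectors.
#' @export
draw_subsets <- function(p, weights, n_subsets, n_draws) {
  if (length(weights) != p || any(weights < 0)) {
    stop("`weights` must be ", p, " non-negative values.", call. = FALSE)
  }
  if (all(weights == 0)) stop("all weights are zero.", call. = FALSE)
  if (n_draws < 1) stop("`n_draws` must be >= 1.", call. = FALSE)
  uniform <- length(unique(weights)) == 1
  lapply(seq_len(n_subsets), function(i) {
    draws <- if (uniform) sample.int(p, n_draws, replace = TRUE)
             else sample.int(p, n_draws, replace = TRUE, prob = weights)
    sort(unique(draws))
  })
}

#' Fit one PLS sub-model per variable subset
#'
#' For each subset the factor count is chosen by cross-validated RMSECV on
#' the subset's columns (capped at `min(max_factors, |subset|, N - 1)`),
#' the sub-model's RMSECV is recorded, and the regression coefficient
#' vector refitted on all samples is normalized to unit Euclidean length
#' and made absolute — the per-variable evidence that drives the weight
#' update. All sub-models share one fold assignment so their RMSECV values
#' are comparable.
#'
#' @param X Preprocessed predictor matrix (N x P).
#' @param y Response vector.
#' @param subsets List of integer index vectors (non-empty, within 1..P).
#' @param max_factors Cap on latent factors per sub-model.
#' @param folds Integer fold assignment of length N (see `make_folds`).
#' @return Tibble with one row per subset: list-column `vars`, `n_vars`,
#'   `ncomp`, `rmsecv`, and list-column `b_norm` (absolute unit-length
#'   coefficients aligned with `vars`).
#' @export
fit_submodels <- function(X, y, subsets, max_factors = 15, folds = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(folds)) folds <- make_folds(n, min(5, n))
  bad <- vapply(subsets, function(s) {
    length(s) == 0 || any(s < 1 | s > p)
  }, logical(1))
  if (any(bad)) {
    stop("subset(s) ", paste(which(bad), collapse = ", "),
         " are empty or reference out-of-range columns.", call. = FALSE)
  }
  folds <- as.integer(folds)
  rows <- lapply(subsets, function(s) {
    Xs <- X[, s, drop = FALSE]
    a_max <- max(1L, min(as.integer(max_factors), length(s), n - 1L))
    pred <- pls1_cv_cpp(Xs, y, a_max, folds)
    curve <- sqrt(colMeans((pred - y)^2))
    a_best <- which.min(curve)
    fit <- pls1_fit_cpp(Xs, y, a_best)
    b <- fit$coef_path[, a_best]
    nb <- sqrt(sum(b^2))
    b_norm <- if (nb < 1e-300) rep(0, length(b)) else abs(b) / nb
    list(vars = s, n_vars = length(s), ncomp = a_best,
         rmsecv = curve[a_best], b_norm = b_norm)
  })
  tibble::tibble(
    vars   = lapply(rows, `[[`, "vars"),
    n_vars = vapply(rows, `[[`, integer(1), "n_vars"),
    ncomp  = vapply(rows, function(r) as.integer(r$ncomp), integer(1)),
    rmsecv = vapply(rows, `[[`, numeric(1), "rmsecv"),
    b_norm = lapply(rows, `[[`, "b_norm")
  )
}

#' Extract the top fraction of sub-models by RMSECV
#'
#' Sorts ascending by RMSECV, breaking ties by fewer variables and then by
#' stable input order, and keeps the best `ceiling(K * top_fraction)`.
#'
#' @param submodels Tibble from [fit_submodels()].
#' @param top_fraction Proportion in (0, 1), default 0.10.
#' @return The selected rows, in rank order.
#' @export
select_top <- function(submodels, top_fraction = 0.10) {
  k <- nrow(submodels)
  if (k == 0) stop("`submodels` is empty.", call. = FALSE)
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("`top_fraction` must lie in (0, 1).", call. = FALSE)
  }
  keep <- ceiling(k * top_fraction)
  ord <- order(submodels$rmsecv, submodels$n_vars, seq_len(k))
  submodels[ord[seq_len(keep)], , drop = FALSE]
}

#' Accumulate variable weights from the extracted sub-models
#'
#' The new weight of variable i is the sum over the extracted sub-models
#' of the absolute normalized regression coefficient it received there;
#' variables absent from a sub-model contribute zero, and a variable in no
#' top sub-model gets weight exactly 0 and can never be redrawn.
#'
#' @param top Tibble of extracted sub-models (from [select_top()]).
#' @param p Total number of candidate variables.
#' @return Numeric weight vector of length `p`.
#' @export
update_weights <- function(top, p) {
  if (nrow(top) == 0) stop("`top` is empty.", call. = FALSE)
  w <- numeric(p)
  for (i in seq_len(nrow(top))) {
    v <- top$vars[[i]]
    w[v] <- w[v] + top$b_norm[[i]]
  }
  w
}

#' Number of bootstrap draws for the next iteration
#'
#' The mean distinct-variable count of the extracted sub-models, rounded
#' half-up, floored at 1. This is what shrinks the subsets from the full
#' spectrum down to a single variable over the iterations.
#'
#' @param top Tibble of sub-models.
#' @return A positive integer.
#' @export
next_n_draws <- function(top) {
  if (nrow(top) == 0) stop("`top` is empty.", call. = FALSE)
  max(1L, as.integer(floor(mean(top$n_vars) + 0.5)))
}

#' Bootstrapping soft shrinkage (BOSS) wavenumber selection
#'
#' Model-population analysis for variable selection in PLS calibration.
#' Starting from uniform weights over all P wavenumbers, each iteration
#' (1) draws `n_subsets` bootstrap variable subsets with probability
#' proportional to the current weights, (2) fits a cross-validated PLS
#' sub-model on every subset, (3) extracts the top `top_fraction` of
#' sub-models by RMSECV, (4) sums their absolute unit-length regression
#' coefficients into new weights, and (5) sets the next draw count to the
#' average size of the extracted sub-models (forced to decrease by at
#' least one per iteration, so the loop always terminates even when the
#' rounded mean plateaus on a small surviving subset). Subsets shrink
#' until a single variable remains; the returned subset is the best sub-model's variable
#' set at the iteration chosen by `choice_rule` (`"first_local_min"`: the
#' first iteration whose best RMSECV falls below its predecessor and does
#' not exceed its successor; `"global_min"`: the lowest RMSECV anywhere in
#' the trajectory; both fall back to the global minimum when no interior
#' local minimum exists).
#'
#' @param x A preprocessed spectra tibble (response `fraction_vv_pct`) or
#'   numeric matrix; apply [snv()] first for real spectra.
#' @param y Response vector when `x` is a matrix.
#' @param n_subsets Bootstrap subsets per iteration (K, default 1000).
#' @param top_fraction Fraction of sub-models extracted (default 0.10).
#' @param n_folds Cross-validation folds (default 5).
#' @param max_factors Cap on latent factors (default 15).
#' @param seed Integer seed making the whole run reproducible.
#' @param choice_rule `"first_local_min"` (default) or `"global_min"`.
#' @param draw_pool Whether the next draw count averages the extracted
#'   top sub-models (`"top"`, default) or all K sub-models (`"all"`).
#' @param max_iterations Safety cap on iterations.
#' @return An object of class `boss`: selected indices and wavenumbers,
#'   chosen iteration, RMSECV at the choice, per-iteration trajectory
#'   (with the best sub-model and post-update weights of each iteration),
#'   and the final weights. Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
run_boss <- function(x, y = NULL, n_subsets = 1000, top_fraction = 0.10,
                     n_folds = 5, max_factors = 15, seed = NULL,
                     choice_rule = c("first_local_min", "global_min"),
                     draw_pool = c("top", "all"), max_iterations = 100) {
  choice_rule <- match.arg(choice_rule)
  draw_pool <- match.arg(draw_pool)
  wavenumbers <- if (is.data.frame(x)) spectra_wavenumbers(x) else NULL
  xy <- resolve_xy(x, y)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 candidate variables.", call. = FALSE)
  if (n < n_folds) stop("need at least `n_folds` samples.", call. = FALSE)
  col_sd <- apply(X, 2, stats::sd)
  if (all(col_sd == 0)) {
    stop("all predictor columns are constant.", call. = FALSE)
  }
  if (n_subsets < 10 || n_subsets * top_fraction < 1) {
    stop("`n_subsets` must be >= 10 with `n_subsets * top_fraction >= 1`.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- make_folds(n, n_folds)

  w <- rep(1, p)
  n_draws <- p
  recs <- vector("list", max_iterations)
  t <- 0L
  repeat {
    t <- t + 1L
    subsets <- draw_subsets(p, w, n_subsets, n_draws)
    sm <- fit_submodels(X, y, subsets, max_factors, folds)
    top <- select_top(sm, top_fraction)
    w_new <- update_weights(top, p)
    best <- top[1, ]
    recs[[t]] <- tibble::tibble(
      iteration = t,
      n_draws = n_draws,
      n_support = sum(w > 0),
      mean_top_size = mean(top$n_vars),
      best_rmsecv = best$rmsecv,
      best_n_vars = best$n_vars,
      best_ncomp = best$ncomp,
      best_vars = list(best$vars[[1]]),
      weights = list(w_new)
    )
    if (n_draws == 1L || all(w_new == 0) || t >= max_iterations) break
    nd <- next_n_draws(if (draw_pool == "top") top else sm)
    # stall breaker: the rounded mean cannot be allowed to plateau, or the
    # loop would never reach a single variable once the surviving subset
    # is small and every top sub-model uses all of it
    n_draws <- if (sum(w_new > 0) <= 1L) 1L
               else if (nd >= n_draws) n_draws - 1L
               else nd
    w <- w_new
  }
  if (t >= max_iterations) {
    warning("BOSS stopped at the iteration cap (", max_iterations, ").",
            call. = FALSE)
  }
  trajectory <- dplyr::bind_rows(recs[seq_len(t)])
  chosen <- choose_iteration(trajectory$best_rmsecv, choice_rule)
  selected <- sort(trajectory$best_vars[[chosen]])

  structure(list(
    selected_idx = selected,
    selected_wavenumbers = if (is.null(wavenumbers)) NULL
                           else wavenumbers[selected],
    chosen_iteration = chosen,
    rmsecv = trajectory$best_rmsecv[chosen],
    n_factors = trajectory$best_ncomp[chosen],
    trajectory = trajectory,
    weights_at_choice = trajectory$weights[[chosen]],
    final_weights = trajectory$weights[[t]],
    config = list(n_subsets = n_subsets, top_fraction = top_fraction,
                  n_folds = n_folds, max_factors = max_factors,
                  seed = seed, choice_rule = choice_rule,
                  draw_pool = draw_pool),
    folds = folds
  ), class = "boss")
}

# first interior local minimum of the RMSECV trajectory, else global min
choose_iteration <- function(r, rule) {
  T_ <- length(r)
  if (rule == "first_local_min" && T_ >= 3) {
    for (t in 2:(T_ - 1)) {
      if (r[t] < r[t - 1] && r[t] <= r[t + 1]) return(t)
    }
  }
  which.min(r)
}

#' @export
tidy.boss <- function(x, ...) {
  tibble::tibble(
    index = x$selected_idx,
    wavenumber = if (is.null(x$selected_wavenumbers)) NA_real_
                 else x$selected_wavenumbers,
    weight = x$weights_at_choice[x$selected_idx]
  )
}

#' @export
glance.boss <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected_idx),
    chosen_iteration = x$chosen_iteration,
    rmsecv = x$rmsecv,
    n_factors = x$n_factors,
    n_iterations = nrow(x$trajectory),
    choice_rule = x$config$choice_rule
  )
}

#' @export
print.boss <- function(x, ...) {
  cat("BOSS selection: ", length(x$selected_idx), " variables at iteration ",
      x$chosen_iteration, " of ", nrow(x$trajectory),
      " (RMSECV ", signif(x$rmsecv, 5), ")\n", sep = "")
  invisible(x)
}

#' Plot the BOSS iteration trajectory
#'
#' Two panels against the iteration number: the number of variables drawn
#' into each subset, and the best sub-model RMSECV (chosen iteration
#' marked). The variable count decays towards one while the RMSECV
#' typically falls to a minimum and then rises as informative variables
#' start being discarded.
#'
#' @param object A `boss` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boss <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(
    tr[, c("iteration", "n_draws", "best_rmsecv")],
    cols = c("n_draws", "best_rmsecv"),
    names_to = "panel", values_to = "value"
  )
  long$panel <- factor(long$panel, c("n_draws", "best_rmsecv"),
                       c("variables per subset", "best RMSECV (% v/v)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$chosen_iteration,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "BOSS iteration", y = NULL)
}

#' Plot the selected-variable weights across the spectrum
#'
#' @param object A `boss` object fitted on a spectra tibble (so that
#'   wavenumbers are known).
#' @return A ggplot object.
#' @export
plot_boss_weights <- function(object) {
  stopifnot(inherits(object, "boss"))
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$wavenumber, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm^-1)", y = "BOSS weight")
}
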