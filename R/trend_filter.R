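# l1 trend filtering of per-mouse body-weight series. The fitted trend
# minimizes 0.5 * sum((y - x)^2) + lambda * sum(|D x|), where D takes
# second differences along the measurement grid, yielding a piecewise
# linear trend whose knots are the ages where the slope changes. Growth
# rate is the exact slope between consecutive fitted points.

# second-difference operator on (possibly irregular) age grid; equals the
# plain second difference for uniform spacing, and its kernel is exactly
# the set of series linear in age
second_diff_op <- function(ages) {
  n <- length(ages)
  h <- diff(ages)
  hbar <- mean(h)
  i <- seq_len(n - 2)
  rows <- rep(i, 3)
  cols <- c(i, i + 1, i + 2)
  vals <- c(hbar / h[i], -hbar / h[i] - hbar / h[i + 1], hbar / h[i + 1])
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n - 2, n))
}

#' Fit an l1 trend filter to one weight series
#'
#' Solves the convex program
#' `minimize 0.5 * sum((y - x)^2) + lambda * sum(|second differences of x|)`
#' over the measurement grid by ADMM with a cached sparse Cholesky
#' factorization for the quadratic step. At `lambda = 0` the fit
#' interpolates the data; as `lambda` grows the fit tends to the ordinary
#' least-squares straight line in age.
#'
#' @param series Data frame with columns `age_days` and `weight_g` (one
#'   mouse), or a list with `ages`/`weights`.
#' @param lambda Non-negative smoothing penalty.
#' @param mouse_id Identifier attached to the fit.
#' @param tol Convergence tolerance on the ADMM primal and dual residuals.
#' @param max_iter Iteration cap.
#' @return A `trend_fit` object: list with `mouse_id`, `grid_ages`,
#'   `fitted_weights`, `growth_rate` (slope of each inter-age segment,
#'   grams/day), `lambda`, `objective`, `iterations`, `converged`.
#' @export
fit_l1_trend <- function(series, lambda, mouse_id = NULL,
                         tol = 1e-8, max_iter = 50000L) {
  ages <- series$age_days %||% series$ages
  y <- series$weight_g %||% series$weights
  mouse_id <- mouse_id %||% (series$mouse_id[1] %||% NA_character_)
  if (length(ages) < 3) {
    stop_validation("l1 trend filtering needs at least 3 measurement ages (got %d)",
                    length(ages))
  }
  if (lambda < 0) stop_validation("lambda must be non-negative")
  ord <- order(ages)
  ages <- as.numeric(ages[ord]); y <- as.numeric(y[ord])
  n <- length(y)
  D <- second_diff_op(ages)
  if (lambda == 0) {
    x <- y
    iter <- 0L; converged <- TRUE
  } else {
    rho <- lambda
    Dt <- Matrix::t(D)
    ch <- Matrix::Cholesky(Matrix::Diagonal(n) + rho * (Dt %*% D), LDL = FALSE)
    m <- n - 2
    z <- numeric(m); u <- numeric(m)
    x <- y
    converged <- FALSE
    iter <- 0L
    thresh <- lambda / rho
    for (iter in seq_len(max_iter)) {
      rhs <- y + rho * as.vector(Dt %*% (z - u))
      x <- as.vector(Matrix::solve(ch, rhs))
      Dx <- as.vector(D %*% x)
      z_old <- z
      w <- Dx + u
      z <- sign(w) * pmax(abs(w) - thresh, 0)
      u <- u + Dx - z
      r_primal <- max(abs(Dx - z))
      s_dual <- rho * max(abs(z - z_old))
      if (r_primal < tol && s_dual < tol) { converged <- TRUE; break }
    }
  }
  slopes <- diff(x) / diff(ages)
  obj <- 0.5 * sum((y - x)^2) + lambda * sum(abs(as.vector(D %*% x)))
  structure(list(mouse_id = mouse_id, grid_ages = ages, fitted_weights = x,
                 growth_rate = slopes, lambda = lambda, objective = obj,
                 iterations = iter, converged = converged),
            class = "trend_fit")
}

#' Evaluate the trend-filter objective for a candidate fit
#'
#' @param ages,y The measurement grid and raw weights.
#' @param x Candidate fitted values on the same grid.
#' @param lambda Penalty.
#' @return Scalar objective value.
#' @export
trend_objective <- function(ages, y, x, lambda) {
  D <- second_diff_op(ages)
  0.5 * sum((y - x)^2) + lambda * sum(abs(as.vector(D %*% x)))
}

#' Select the smoothing penalty by held-out prediction error
#'
#' For each mouse, a fraction of interior measurement ages is held out at
#' random; the trend is fit to the remaining ages at each candidate
#' `lambda`, the held-out weights are predicted by linear interpolation of
#' the fit, and the squared errors are pooled across mice. The `lambda`
#' minimizing the pooled mean squared error is returned (ties go to the
#' smaller penalty).
#'
#' @param phen A `bw_phenotypes` object or a list of per-mouse data frames
#'   (see [split_by_mouse()]).
#' @param holdout_fraction Fraction of each mouse's ages held out
#'   (default 0.1); at least one age is held out and at least three kept.
#'   Mice with fewer than four ages are used for fitting only.
#' @param seed Integer seed fixing the holdout.
#' @param lambda_grid Candidate penalties; default 30 log-spaced points
#'   from 1e-2 to 1e4.
#' @return The selected penalty, with attribute `cv` (data frame `lambda`,
#'   `mse`, `n_holdout`).
#' @export
select_lambda <- function(phen, holdout_fraction = 0.1, seed = NULL,
                          lambda_grid = 10^seq(-2, 4, length.out = 30)) {
  if (length(lambda_grid) == 0) stop_validation("empty lambda grid")
  series_list <- if (inherits(phen, "bw_phenotypes")) split_by_mouse(phen) else phen
  if (!is.null(seed)) set.seed(seed)
  holdouts <- lapply(series_list, function(s) {
    n <- nrow(s)
    if (n < 4) return(integer(0))
    interior <- 2:(n - 1)
    k <- min(max(1L, floor(holdout_fraction * n)), n - 3L)
    sort(sample(interior, k))
  })
  mse <- vapply(lambda_grid, function(lam) {
    se <- 0; cnt <- 0
    for (j in seq_along(series_list)) {
      hold <- holdouts[[j]]
      if (length(hold) == 0) next
      s <- series_list[[j]]
      fit <- fit_l1_trend(s[-hold, , drop = FALSE], lam)
      pred <- stats::approx(fit$grid_ages, fit$fitted_weights,
                            xout = s$age_days[hold])$y
      se <- se + sum((pred - s$weight_g[hold])^2)
      cnt <- cnt + length(hold)
    }
    se / cnt
  }, numeric(1))
  best <- which.min(mse)  # which.min takes the first (smallest lambda) on ties
  structure(lambda_grid[best],
            cv = data.frame(lambda = lambda_grid, mse = mse,
                            n_holdout = sum(lengths(holdouts))))
}

#' Sample a fitted trend at requested ages
#'
#' Weights are linear interpolations of the piecewise-linear fit; the
#' growth rate at an age is the slope of the segment containing it
#' (right-continuous; the final age takes the last segment's slope). Ages
#' outside the mouse's measurement span yield `NA`, so the mouse drops out
#' of that age's cross-section.
#'
#' @param fit A `trend_fit` object.
#' @param ages Ages (days) at which to sample.
#' @return Data frame `age`, `weight`, `growth_rate`.
#' @export
sample_at_ages <- function(fit, ages) {
  w <- stats::approx(fit$grid_ages, fit$fitted_weights, xout = ages,
                     rule = 1)$y
  seg <- findInterval(ages, fit$grid_ages)
  seg[seg >= length(fit$grid_ages)] <- length(fit$grid_ages) - 1L
  gr <- ifelse(is.na(w) | seg < 1, NA_real_, fit$growth_rate[pmax(seg, 1L)])
  data.frame(age = ages, weight = w, growth_rate = gr)
}

#' Fit trends for every mouse and assemble age cross-sections
#'
#' Convenience wrapper: fits [fit_l1_trend()] per mouse and samples all
#' fits on a common age grid, returning a mouse x age matrix of fitted
#' weights (and one of growth rates) with `NA` where a mouse's measurement
#' span does not cover the age.
#'
#' @param phen A `bw_phenotypes` object.
#' @param lambda Penalty (e.g. from [select_lambda()]).
#' @param ages Common age grid (days).
#' @return List with matrices `weight` and `growth_rate`
#'   (mouse x age), and `fits` (list of `trend_fit`).
#' @export
fit_trends <- function(phen, lambda, ages = seq(30, 660, by = 10)) {
  series_list <- split_by_mouse(phen)
  fits <- lapply(names(series_list), function(id) {
    fit_l1_trend(series_list[[id]], lambda, mouse_id = id)
  })
  names(fits) <- names(series_list)
  weight <- t(vapply(fits, function(f) sample_at_ages(f, ages)$weight,
                     numeric(length(ages))))
  growth <- t(vapply(fits, function(f) sample_at_ages(f, ages)$growth_rate,
                     numeric(length(ages))))
  dimnames(weight) <- dimnames(growth) <- list(names(fits), ages)
  list(weight = weight, growth_rate = growth, fits = fits)
}
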