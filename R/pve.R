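# Variance decomposition: total and environment-conditional proportion of
# phenotypic variance explained by genetics (PVE), its standard error, and
# the kinship-vs-phenotypic-covariance diagnostic that motivates modelling
# environment-specific genetic variance.
#
# The decompositions are exact expectations of the sample variance under
# the fitted model: with W_e = Z_e Z_e^T,
#   VarG   = rho2 (tr(K)/N - sum(K)/N^2)
#            + sum_e Omega_ee (tr(K o W_e)/N - sum(K o W_e)/N^2)
#   VarY   = VarG + fixed-effect variance + tr(Theta) (N-1)/N^2
# and conditional on environment e, with traces and sums restricted
# through Hadamard products with W_e.

pve_terms <- function(vc, K, Z, mu, members = NULL) {
  K <- unclass(K)
  N_all <- nrow(K)
  if (vc$model == "emma") {
    Z <- matrix(1, N_all, 1)
    omega <- 0
    theta_nn <- rep(vc$sigma2[1], N_all)
  } else {
    Z <- as.matrix(Z)
    omega <- rep_len(vc$omega %||% 0, ncol(Z))
    theta_nn <- as.vector(Z %*% rep_len(vc$sigma2, ncol(Z)))
  }
  mu <- rep_len(if (is.null(mu)) 0 else mu, N_all)
  if (is.null(members)) {
    ne <- N_all
    kd <- diag(K)
    g_shared <- sum(kd) / ne - sum(K) / ne^2
    g_env <- vapply(seq_len(ncol(Z)), function(e) {
      ze <- Z[, e]
      sum(kd * ze) / ne - as.vector(crossprod(ze, K %*% ze)) / ne^2
    }, numeric(1))
    fixed <- sum(mu^2) / ne - (sum(mu))^2 / ne^2
    resid <- sum(theta_nn) * (ne - 1) / ne^2
  } else {
    zm <- as.numeric(members)          # indicator of environment e
    ne <- sum(zm)
    if (ne < 2) stop_validation("conditional variance needs at least 2 members")
    kd <- diag(K)
    g_shared <- sum(kd * zm) / ne - as.vector(crossprod(zm, K %*% zm)) / ne^2
    g_env <- vapply(seq_len(ncol(Z)), function(e) {
      w <- Z[, e] * zm                 # members of both e' and e
      sum(kd * w) / ne - as.vector(crossprod(w, K %*% w)) / ne^2
    }, numeric(1))
    fixed <- sum(mu^2 * zm) / ne - (sum(mu * zm))^2 / ne^2
    resid <- sum(theta_nn * zm) * (ne - 1) / ne^2
  }
  list(g_shared = g_shared, g_env = g_env, fixed = fixed, resid = resid,
       omega = omega, n = ne)
}

pve_from_terms <- function(vc, tm) {
  var_g <- vc$rho2 * tm$g_shared + sum(tm$omega * tm$g_env)
  var_y <- var_g + tm$fixed + tm$resid
  list(var_g = var_g, var_y = var_y)
}

#' Total proportion of phenotypic variance explained by genetics
#'
#' Computes `PVE_tot = VarG / VarY` from fitted variance components, where
#' both terms are the model-implied expectations of the sample variance
#' (genetic, fixed-effect and residual pieces sum to VarY exactly).
#'
#' @param vc A fitted `variance_components` object.
#' @param K Kinship matrix used in the fit.
#' @param Z Environment matrix used in the fit.
#' @param mu Fixed-effect mean vector (`X %*% vc$alpha`); 0 if NULL.
#' @param clip Clip the reported PVE to `[0, 1]` (only applied when the
#'   components were constrained non-negative); the raw ratio is kept in
#'   `pve_raw`.
#' @return A `pve_estimate` object: list with `pve`, `pve_raw`, `var_g`,
#'   `var_y`, `var_fixed`, `var_resid`, `model`, `scope`, `n`.
#' @export
pve_total <- function(vc, K, Z = NULL, mu = NULL, clip = TRUE) {
  tm <- pve_terms(vc, K, Z, mu)
  v <- pve_from_terms(vc, tm)
  new_pve_estimate(v, tm, vc, scope = "total", clip = clip)
}

#' Environment-conditional PVE
#'
#' `PVE_e = VarG|e / VarY|e`, with traces and sums restricted to members
#' of environment `e` through Hadamard products with `W_e = Z_e Z_e^T`.
#'
#' @inheritParams pve_total
#' @param e Environment column (index or column name of `Z`).
#' @return A `pve_estimate` object with `scope` set to the environment.
#' @export
pve_env <- function(vc, K, Z, mu = NULL, e, clip = TRUE) {
  Z <- as.matrix(Z)
  if (is.character(e)) e <- match(e, colnames(Z))
  tm <- pve_terms(vc, K, Z, mu, members = Z[, e])
  v <- pve_from_terms(vc, tm)
  new_pve_estimate(v, tm, vc, scope = colnames(Z)[e] %||% paste0("env", e),
                   clip = clip)
}

#' PVE under the EMMA model
#'
#' The single-component special case: genetic variance
#' `rho2 (tr(K)/N - sum(K)/N^2)` over the total expected sample variance
#' with homoscedastic residual `theta2`.
#'
#' @inheritParams pve_total
#' @return A `pve_estimate` object.
#' @export
pve_emma <- function(vc, K, mu = NULL, clip = TRUE) {
  stopifnot(vc$model == "emma")
  tm <- pve_terms(vc, K, NULL, mu)
  v <- pve_from_terms(vc, tm)
  new_pve_estimate(v, tm, vc, scope = "total", clip = clip)
}

new_pve_estimate <- function(v, tm, vc, scope, clip) {
  raw <- if (v$var_y > 0) v$var_g / v$var_y else NA_real_
  pve <- if (clip && isTRUE(vc$constrained)) min(max(raw, 0), 1) else raw
  structure(list(pve = pve, pve_raw = raw, var_g = v$var_g, var_y = v$var_y,
                 var_fixed = tm$fixed, var_resid = tm$resid,
                 model = vc$model, scope = scope, n = tm$n, se = NA_real_),
            class = "pve_estimate")
}

#' @export
print.pve_estimate <- function(x, ...) {
  cat(sprintf("PVE (%s, %s): %.4f", x$model, x$scope, x$pve))
  if (is.finite(x$se)) cat(sprintf(" (SE %.4f)", x$se))
  cat("\n")
  invisible(x)
}

#' Delta-method standard error for a PVE estimate
#'
#' Propagates the observed-information covariance of the variance
#' components `(sigma2, rho2, Omega)` through the PVE ratio. The
#' information matrix is the numerical Hessian of the profile negative log
#' likelihood, obtained by central differences of the analytic gradients;
#' the PVE gradient is analytic (VarG and VarY are linear in the
#' components). A nonparametric bootstrap over mice is available as an
#' alternative.
#'
#' @param vc Fitted `variance_components` (GxEMM).
#' @param Y,X,K,Z Data used in the fit.
#' @param e Optional environment column for a conditional PVE; NULL for
#'   total PVE.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return The corresponding `pve_estimate` with its `se` field filled
#'   (NA with a warning when the information matrix is singular).
#' @export
pve_standard_error <- function(vc, Y, X, K, Z, e = NULL,
                               method = c("delta", "bootstrap"),
                               n_boot = 50, seed = NULL) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  E <- ncol(Z)
  mu <- as.vector(as.matrix(X) %*% vc$alpha)
  est <- if (is.null(e)) pve_total(vc, K, Z, mu) else pve_env(vc, K, Z, mu, e)
  if (method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    n <- length(Y)
    reps <- replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      vcb <- fit_gxemm(Y[idx], as.matrix(X)[idx, , drop = FALSE],
                       unclass(K)[idx, idx], Z[idx, , drop = FALSE],
                       constrained = vc$constrained, n_starts = 1)
      mub <- as.vector(as.matrix(X)[idx, , drop = FALSE] %*% vcb$alpha)
      if (is.null(e)) pve_total(vcb, unclass(K)[idx, idx], Z[idx, , drop = FALSE], mub)$pve
      else pve_env(vcb, unclass(K)[idx, idx], Z[idx, , drop = FALSE], mub, e)$pve
    })
    est$se <- stats::sd(reps)
    return(est)
  }
  prep <- gxemm_prep(Y, X, K, Z)
  par <- c(rep_len(vc$sigma2, E), vc$rho2, rep_len(vc$omega %||% 0, E))
  npar <- length(par)
  H <- matrix(NA_real_, npar, npar)
  h <- 1e-4 * (1 + abs(par))
  for (j in seq_len(npar)) {
    pp <- par; pp[j] <- pp[j] + h[j]
    pm <- par; pm[j] <- pm[j] - h[j]
    gp <- gxemm_nll_core(pp, prep, want_grad = TRUE)$grad
    gm <- gxemm_nll_core(pm, prep, want_grad = TRUE)$grad
    H[j, ] <- (gp - gm) / (2 * h[j])
  }
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(err) NULL)
  if (is.null(V)) {
    warning("singular observed information; PVE standard error unavailable")
    return(est)
  }
  # analytic gradient of PVE wrt (sigma2, rho2, omega)
  tm <- pve_terms(vc, K, Z, mu,
                  members = if (is.null(e)) NULL else {
                    if (is.character(e)) Z[, match(e, colnames(Z))] else Z[, e]
                  })
  a <- vc$rho2 * tm$g_shared + sum(tm$omega * tm$g_env)   # VarG
  b <- a + tm$fixed + tm$resid                            # VarY
  # d resid / d sigma2_e: members of e weighted within scope
  d_resid <- vapply(seq_len(E), function(ee) {
    if (is.null(e)) sum(Z[, ee]) * (tm$n - 1) / tm$n^2
    else {
      zm <- if (is.character(e)) Z[, match(e, colnames(Z))] else Z[, e]
      sum(Z[, ee] * zm) * (tm$n - 1) / tm$n^2
    }
  }, numeric(1))
  da <- c(rep(0, E), tm$g_shared, tm$g_env)
  db <- c(d_resid, tm$g_shared, tm$g_env)
  grad_pve <- (da * b - a * db) / b^2
  se2 <- as.vector(t(grad_pve) %*% V %*% grad_pve)
  if (!is.finite(se2) || se2 < 0) {
    warning("negative delta-method variance; PVE standard error unavailable")
    return(est)
  }
  est$se <- sqrt(se2)
  est
}

#' Kinship-covariance diagnostic for environment-dependent genetics
#'
#' For each diet group, forms all animal pairs, scores each pair by the
#' product of the two animals' deviations from their diet-mean weight (a
#' pairwise phenotypic covariance), splits pairs into high-kinship
#' (`K_mn > threshold`) and low-kinship groups, and tests separability of
#' the two score distributions with a two-sided Mann-Whitney U test
#' (normal approximation with tie correction). The AUC is the standard
#' transformation `U / (n1 n2)`. A clear separation in some diets but not
#' others indicates diet-dependent genetic variance.
#'
#' @param weights Body weight per mouse at one age.
#' @param K Kinship matrix.
#' @param diet Diet label per mouse.
#' @param threshold Kinship cutoff between groups (default 0.2).
#' @return Data frame with one row per diet: `diet`, `n_high`, `n_low`,
#'   `U`, `auc`, `p_value`. Diets with an empty group are skipped with a
#'   warning.
#' @export
kinship_covariance_diagnostic <- function(weights, K, diet, threshold = 0.2) {
  K <- unclass(K)
  diets <- unique(as.character(diet))
  rows <- lapply(diets, function(d) {
    idx <- which(diet == d)
    if (length(idx) < 3) {
      warning("diet ", d, " has too few animals; diagnostic skipped")
      return(NULL)
    }
    dev <- weights[idx] - mean(weights[idx])
    pc <- tcrossprod(dev)
    kin <- K[idx, idx]
    ut <- upper.tri(kin)
    stat <- pc[ut]; kv <- kin[ut]
    hi <- stat[kv > threshold]; lo <- stat[kv <= threshold]
    if (length(hi) < 2 || length(lo) < 2) {
      warning("diet ", d, " has an empty kinship group; diagnostic skipped")
      return(NULL)
    }
    wt <- stats::wilcox.test(hi, lo, exact = FALSE)
    data.frame(diet = d, n_high = length(hi), n_low = length(lo),
               U = unname(wt$statistic),
               auc = unname(wt$statistic) / (length(hi) * length(lo)),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
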