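# Gene-environment mixed model (GxEMM) core.
#
# Phenotype model: Y = alpha0 + sum_e Ze alpha_e + sum_v Gv beta_v
#                    + sum_{e,v} Gv Ze gamma_ve + eps,
# with normal priors beta_v ~ N(0, rho2 / V), gamma_v. ~ N(0, Omega / V)
# (Omega diagonal), and heteroscedastic noise eps ~ N(0, Theta),
# Theta_nn = sum_e Z_ne sigma2_e. Integrating out the random effects,
# Y ~ N(mu, Lambda) with mu = X alpha and
#   Lambda = Theta + rho2 K + sum_e Omega_ee (K o Ze Ze^T),
# where K is the kinship matrix K_mn = (1/V) sum_v G_mv^T G_nv and "o" is
# the Hadamard product. Fixed effects are profiled out by GLS and the
# profile likelihood maximized by bounded quasi-Newton with analytic
# gradients. EMMA is the special case Omega = 0 with a single
# homoscedastic noise term, fit via the spectral decomposition of K.

#' Compute a kinship matrix from founder probabilities or dosages
#'
#' In `founder_prob` mode, `K_mn = (1/V) sum_v G_mv^T G_nv` with `G_nv` the
#' 8-vector of founder-of-origin probabilities; diagonal entries then lie in
#' `[1/8, 1]`. In `dosage` mode each marker's dosage column is centered and
#' scaled to unit variance and `K = X X^T / V` (the usual GWAS genetic
#' relationship matrix); zero-variance markers are dropped.
#'
#' @param G A `founder_probs` object, a `dosage_matrix` object, or (dosage
#'   mode) a plain N x V matrix.
#' @param mode `"founder_prob"` or `"dosage"`; inferred from the class of
#'   `G` when omitted.
#' @param exclude_chrom Optional chromosome name; markers on it are removed
#'   before computing kinship (the leave-one-chromosome-out kinship used in
#'   association scans, which avoids proximal contamination).
#' @return N x N symmetric matrix of class `kinship` with attributes
#'   `mode`, `excluded_chrom`, and `n_markers`.
#' @export
compute_kinship <- function(G, mode = NULL, exclude_chrom = NULL) {
  if (is.null(mode)) {
    mode <- if (inherits(G, "founder_probs")) "founder_prob" else "dosage"
  }
  mode <- match.arg(mode, c("founder_prob", "dosage"))
  if (mode == "founder_prob") {
    probs <- G$probs
    if (!is.null(exclude_chrom)) {
      keep <- !(G$map$chrom %in% exclude_chrom)
      if (!any(keep)) stop_validation("excluding chromosome %s leaves no markers",
                                      paste(exclude_chrom, collapse = ","))
      probs <- probs[, keep, , drop = FALSE]
    }
    n <- dim(probs)[1]; v <- dim(probs)[2]
    M <- matrix(probs, nrow = n)           # N x (V*8) unfolding
    K <- tcrossprod(M) / v
  } else {
    if (inherits(G, "dosage_matrix")) {
      D <- G$dosages
      if (!is.null(exclude_chrom)) {
        keep <- !(G$map$chrom %in% exclude_chrom)
        if (!any(keep)) stop_validation("excluding chromosome %s leaves no markers",
                                        paste(exclude_chrom, collapse = ","))
        D <- D[, keep, drop = FALSE]
      }
    } else {
      D <- as.matrix(G)
    }
    sds <- apply(D, 2, stats::sd)
    D <- D[, sds > 0, drop = FALSE]
    if (ncol(D) == 0) stop_validation("no polymorphic markers for kinship")
    Ds <- scale(D)
    v <- ncol(Ds)
    K <- tcrossprod(Ds) / v
  }
  dimnames(K) <- NULL
  structure(K, mode = mode, excluded_chrom = exclude_chrom,
            n_markers = v, class = c("kinship", "matrix", "array"))
}

#' Leave-one-chromosome-out kinship matrices
#'
#' @param G A `founder_probs` or `dosage_matrix` object with a marker map.
#' @param mode Passed to [compute_kinship()].
#' @return Named list of `kinship` matrices, one per chromosome in the map,
#'   each computed with that chromosome's markers excluded.
#' @export
loco_kinship <- function(G, mode = NULL) {
  chroms <- unique(G$map$chrom)
  if (length(chroms) < 2) {
    stop_validation("LOCO kinship needs markers on at least 2 chromosomes")
  }
  out <- lapply(chroms, function(cc) compute_kinship(G, mode, exclude_chrom = cc))
  names(out) <- chroms
  out
}

#' Construct a variance-components object
#'
#' @param sigma2 Per-environment noise variances (length E, or scalar for
#'   the homoscedastic EMMA model).
#' @param rho2 Environment-independent polygenic variance.
#' @param omega Per-environment polygenic interaction variances (diagonal
#'   of Omega; zero-length or all-zero under EMMA).
#' @param alpha Fixed-effect coefficients (optional).
#' @param model `"gxemm"` or `"emma"`.
#' @param constrained Whether components were constrained non-negative.
#' @return A `variance_components` object.
#' @export
variance_components <- function(sigma2, rho2, omega = numeric(0),
                                alpha = NULL, model = c("gxemm", "emma"),
                                constrained = TRUE) {
  model <- match.arg(model)
  structure(list(sigma2 = sigma2, rho2 = rho2, omega = omega,
                 alpha = alpha, model = model, constrained = constrained),
            class = "variance_components")
}

#' Model covariance implied by variance components
#'
#' `Lambda = Theta + rho2 K + sum_e Omega_ee (K o Ze Ze^T)` with
#' `Theta_nn = sum_e Z_ne sigma2_e` (GxEMM) or
#' `Lambda = theta2 I + rho2 K` (EMMA).
#'
#' @param vc A `variance_components` object.
#' @param K Kinship matrix.
#' @param Z N x E binary environment matrix (ignored for EMMA).
#' @return N x N covariance matrix.
#' @export
model_covariance <- function(vc, K, Z = NULL) {
  n <- nrow(K)
  if (vc$model == "emma") {
    return(vc$rho2 * unclass(K) + diag(vc$sigma2[1], n))
  }
  Z <- as.matrix(Z)
  Lambda <- vc$rho2 * unclass(K)
  for (e in seq_len(ncol(Z))) {
    if (length(vc$omega) >= e && vc$omega[e] != 0) {
      Lambda <- Lambda + vc$omega[e] * (unclass(K) * tcrossprod(Z[, e]))
    }
  }
  Lambda + diag(as.vector(Z %*% vc$sigma2), n)
}

# internal: precompute the per-environment Hadamard kinships K o (Ze Ze^T)
gxemm_prep <- function(Y, X, K, Z) {
  Y <- as.numeric(Y); X <- as.matrix(X); Z <- as.matrix(Z)
  K <- unclass(K)
  stopifnot(length(Y) == nrow(K), nrow(X) == length(Y), nrow(Z) == length(Y))
  Ke <- lapply(seq_len(ncol(Z)), function(e) K * tcrossprod(Z[, e]))
  list(Y = Y, X = X, K = K, Z = Z, Ke = Ke, N = length(Y), E = ncol(Z))
}

# internal: profile negative log likelihood and its gradient at
# par = c(sigma2[1..E], rho2, omega[1..E]). Returns list(value, grad,
# alpha, PY, logdet); on a non-PD covariance returns a large value.
gxemm_nll_core <- function(par, prep, want_grad = TRUE) {
  E <- prep$E; N <- prep$N
  sigma2 <- par[seq_len(E)]
  rho2 <- par[E + 1]
  omega <- par[E + 1 + seq_len(E)]
  Lambda <- rho2 * prep$K
  for (e in seq_len(E)) {
    if (omega[e] != 0) Lambda <- Lambda + omega[e] * prep$Ke[[e]]
  }
  diag(Lambda) <- diag(Lambda) + as.vector(prep$Z %*% sigma2)
  ch <- tryCatch(chol(Lambda), error = function(e) NULL)
  if (is.null(ch)) {
    return(list(value = 1e12 * (1 + sum(pmax(-par, 0))), grad = rep(0, length(par))))
  }
  logdet <- 2 * sum(log(diag(ch)))
  Li <- chol2inv(ch)
  LiY <- Li %*% prep$Y
  LiX <- Li %*% prep$X
  XtLiX <- crossprod(prep$X, LiX)
  XtLiY <- crossprod(prep$X, LiY)
  alpha <- tryCatch(solve(XtLiX, XtLiY), error = function(e) NULL)
  if (is.null(alpha)) stop_validation("collinear fixed effects: X^T Lambda^-1 X is singular")
  PY <- as.vector(LiY - LiX %*% alpha)
  YPY <- sum(prep$Y * LiY) - sum(XtLiY * alpha)
  value <- 0.5 * (N * log(2 * pi) + logdet + YPY)
  out <- list(value = value, alpha = as.vector(alpha), PY = PY, logdet = logdet)
  if (want_grad) {
    dLi <- diag(Li)
    g_sigma <- 0.5 * (crossprod(prep$Z, dLi) - crossprod(prep$Z, PY^2))
    g_rho <- 0.5 * (sum(Li * prep$K) - sum(PY * (prep$K %*% PY)))
    g_omega <- vapply(seq_len(E), function(e) {
      0.5 * (sum(Li * prep$Ke[[e]]) - sum(PY * (prep$Ke[[e]] %*% PY)))
    }, numeric(1))
    out$grad <- c(as.vector(g_sigma), g_rho, g_omega)
  }
  out
}

#' Profile negative log likelihood of the GxEMM model
#'
#' Evaluates `-L_alpha-hat`, the negative log likelihood with the fixed
#' effects profiled out by generalized least squares,
#' `alpha-hat = (X^T Lambda^-1 X)^-1 X^T Lambda^-1 Y`.
#'
#' @param vc A `variance_components` object.
#' @param Y Phenotype vector (length N).
#' @param X Fixed-effect design matrix (N x C, full rank).
#' @param K Kinship matrix.
#' @param Z Environment membership matrix (N x E).
#' @return Scalar negative log likelihood; attribute `alpha` holds the
#'   profiled GLS fixed effects.
#' @export
neg_log_likelihood <- function(vc, Y, X, K, Z = NULL) {
  if (vc$model == "emma") {
    n <- length(Y)
    Z1 <- matrix(1, n, 1)
    prep <- gxemm_prep(Y, X, K, Z1)
    par <- c(vc$sigma2[1], vc$rho2, 0)
  } else {
    prep <- gxemm_prep(Y, X, K, Z)
    E <- ncol(as.matrix(Z))
    omega <- vc$omega
    if (length(omega) != E) omega <- rep_len(omega %||% 0, E)
    par <- c(rep_len(vc$sigma2, E), vc$rho2, omega)
  }
  res <- gxemm_nll_core(par, prep, want_grad = FALSE)
  structure(res$value, alpha = res$alpha)
}

#' Analytic gradients of the profile log likelihood
#'
#' Gradient of `L_alpha-hat` with respect to each `sigma2_e`, `rho2`, and
#' `Omega_ee`:
#' `dL/d(theta_j) = -tr(Lambda^-1 A_j)/2 + Y^T P A_j P Y / 2`
#' where `A_j` is the derivative of `Lambda` for component j (`I_Ze`, `K`,
#' or `K o Ze Ze^T`) and `P` is the GLS projection
#' `Lambda^-1 - Lambda^-1 X (X^T Lambda^-1 X)^-1 X^T Lambda^-1`.
#'
#' @inheritParams neg_log_likelihood
#' @return Named numeric vector: gradients of the log likelihood (not its
#'   negative) for `sigma2_1..E`, `rho2`, `omega_1..E`.
#' @export
gxemm_gradients <- function(vc, Y, X, K, Z) {
  prep <- gxemm_prep(Y, X, K, Z)
  E <- prep$E
  par <- c(rep_len(vc$sigma2, E), vc$rho2, rep_len(vc$omega %||% 0, E))
  res <- gxemm_nll_core(par, prep, want_grad = TRUE)
  g <- -res$grad  # core returns gradient of the negative log likelihood
  names(g) <- c(paste0("sigma2_", seq_len(E)), "rho2",
                paste0("omega_", seq_len(E)))
  g
}

# internal: moment-based starting point plus seeded random restarts
gxemm_starts <- function(Y, X, E, n_starts, seed) {
  r <- stats::lm.fit(X, Y)$residuals
  s2 <- max(stats::var(r), 1e-4)
  base <- c(rep(0.5 * s2, E), 0.3 * s2, rep(0.2 * s2, E))
  starts <- list(base)
  if (n_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- base * stats::runif(length(base), 0.2, 2.5)
    }
  }
  starts
}

#' Fit the GxEMM model by constrained maximum likelihood
#'
#' Maximizes the profile likelihood over `(sigma2_1..E, rho2, Omega_11..EE)`
#' by bounded quasi-Newton (L-BFGS-B) with analytic gradients, constraining
#' all variance components to be non-negative by default (set
#' `constrained = FALSE` to relax the bound on the genetic components).
#' Multiple seeded starts guard against local optima; the best likelihood
#' is kept.
#'
#' @inheritParams neg_log_likelihood
#' @param constrained Constrain variance components to be non-negative.
#' @param n_starts Number of optimization starts (first is moment-based).
#' @param seed Integer seed controlling the random restarts.
#' @param pgtol Projected-gradient tolerance for convergence.
#' @param maxit Iteration cap per start.
#' @return A `variance_components` object with elements `sigma2`, `rho2`,
#'   `omega`, `alpha` (GLS fixed effects at the optimum), `loglik`,
#'   `converged`, `n_iter`, and `start_values` (per-start final
#'   likelihoods).
#' @export
fit_gxemm <- function(Y, X, K, Z, constrained = TRUE, n_starts = 3,
                      seed = NULL, pgtol = 1e-6, maxit = 500) {
  prep <- gxemm_prep(Y, X, K, Z)
  E <- prep$E
  npar <- 2 * E + 1
  lower <- if (constrained) c(rep(1e-8, E), rep(0, E + 1))
           else c(rep(1e-8, E), rep(-Inf, E + 1))
  # memoize: L-BFGS-B asks for fn and gr at the same point
  last <- new.env(parent = emptyenv())
  evalfn <- function(par) {
    if (!is.null(last$par) && identical(par, last$par)) return(last$res)
    res <- gxemm_nll_core(par, prep, want_grad = TRUE)
    last$par <- par; last$res <- res
    res
  }
  starts <- gxemm_starts(prep$Y, prep$X, E, n_starts, seed)
  best <- NULL; start_values <- numeric(0)
  for (st in starts) {
    opt <- stats::optim(pmax(st, lower), fn = function(p) evalfn(p)$value,
                        gr = function(p) evalfn(p)$grad,
                        method = "L-BFGS-B", lower = lower,
                        control = list(maxit = maxit, pgtol = pgtol))
    start_values <- c(start_values, -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  final <- gxemm_nll_core(best$par, prep, want_grad = TRUE)
  sigma2 <- best$par[seq_len(E)]
  vc <- variance_components(sigma2 = sigma2, rho2 = best$par[E + 1],
                            omega = best$par[E + 1 + seq_len(E)],
                            alpha = final$alpha, model = "gxemm",
                            constrained = constrained)
  names(vc$sigma2) <- names(vc$omega) <- colnames(prep$Z)
  vc$loglik <- -best$value
  vc$converged <- best$convergence == 0
  vc$n_iter <- best$counts[1]
  vc$grad_norm <- sqrt(sum(final$grad^2))
  vc$start_values <- start_values
  if (!vc$converged) {
    warning("GxEMM fit did not converge within ", maxit,
            " iterations (gradient norm ", signif(vc$grad_norm, 3), ")")
  }
  vc
}

#' Fit the EMMA model (single genetic variance, homoscedastic noise)
#'
#' The classic linear mixed model `Lambda = rho2 K + theta2 I`, the GxEMM
#' special case with `Omega = 0` and tied noise. Fitting uses the spectral
#' decomposition of K, which reduces every likelihood evaluation to
#' diagonal operations, and the same profile-likelihood objective as
#' [fit_gxemm()].
#'
#' @inheritParams fit_gxemm
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)`, reusable
#'   across fits that share a kinship matrix.
#' @return A `variance_components` object with `model = "emma"`; `sigma2`
#'   holds the single homoscedastic noise variance theta2.
#' @export
fit_emma <- function(Y, X, K, constrained = TRUE, n_starts = 3,
                     seed = NULL, pgtol = 1e-6, maxit = 500, eig = NULL) {
  Y <- as.numeric(Y); X <- as.matrix(X)
  N <- length(Y)
  eg <- eig %||% eigen(unclass(K), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Yr <- crossprod(eg$vectors, Y)
  Xr <- crossprod(eg$vectors, X)
  nll <- function(par) {
    w <- par[1] + par[2] * d
    if (any(w <= 0)) return(list(value = 1e12, grad = c(0, 0)))
    iw <- 1 / w
    XtLiX <- crossprod(Xr, Xr * iw)
    XtLiY <- crossprod(Xr, Yr * iw)
    alpha <- tryCatch(solve(XtLiX, XtLiY), error = function(e) NULL)
    if (is.null(alpha)) stop_validation("collinear fixed effects: X^T Lambda^-1 X is singular")
    PY <- as.vector(Yr * iw - (Xr * iw) %*% alpha)
    value <- 0.5 * (N * log(2 * pi) + sum(log(w)) +
                      sum(Yr * iw * Yr) - sum(XtLiY * alpha))
    grad <- c(0.5 * (sum(iw) - sum(PY^2)),
              0.5 * (sum(d * iw) - sum(d * PY^2)))
    list(value = value, grad = grad, alpha = as.vector(alpha))
  }
  r <- stats::lm.fit(X, Y)$residuals
  s2 <- max(stats::var(r), 1e-4)
  starts <- list(c(0.5, 0.5) * s2)
  if (n_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- c(0.5, 0.5) * s2 * stats::runif(2, 0.2, 2.5)
    }
  }
  lower <- c(1e-8, if (constrained) 0 else -Inf)
  best <- NULL; start_values <- numeric(0)
  for (st in starts) {
    opt <- stats::optim(pmax(st, lower), fn = function(p) nll(p)$value,
                        gr = function(p) nll(p)$grad,
                        method = "L-BFGS-B", lower = lower,
                        control = list(maxit = maxit, pgtol = pgtol))
    start_values <- c(start_values, -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  final <- nll(best$par)
  vc <- variance_components(sigma2 = best$par[1], rho2 = best$par[2],
                            omega = numeric(0), alpha = final$alpha,
                            model = "emma", constrained = constrained)
  vc$loglik <- -best$value
  vc$converged <- best$convergence == 0
  vc$n_iter <- best$counts[1]
  vc$start_values <- start_values
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("%s fit (%s)\n", toupper(x$model),
              if (x$constrained) "non-negative components" else "unconstrained"))
  cat("  rho2  :", signif(x$rho2, 4), "\n")
  if (length(x$omega) > 0) {
    cat("  omega :", paste(signif(x$omega, 4), collapse = " "), "\n")
  }
  cat("  sigma2:", paste(signif(x$sigma2, 4), collapse = " "), "\n")
  if (!is.null(x$loglik)) cat("  loglik:", format(x$loglik), "\n")
  invisible(x)
}
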