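test_that("kinship from founder probabilities matches its definition", {
  # identical one-hot mosaics: K_mn = K_nn = 1
  probs <- array(0, dim = c(2, 10, 8))
  probs[1, , 1] <- 1; probs[2, , 1] <- 1
  map <- data.frame(marker = paste0("m", 1:10), chrom = "1", pos_bp = 1:10)
  K <- compute_kinship(as_founder_probs(probs, map))
  expect_equal(unclass(K), matrix(1, 2, 2), ignore_attr = TRUE)
  # disjoint one-hot mosaics: K_mn = 0
  probs[2, , 1] <- 0; probs[2, , 2] <- 1
  K2 <- compute_kinship(as_founder_probs(probs, map))
  expect_equal(K2[1, 2], 0)
  expect_equal(diag(K2), c(1, 1), ignore_attr = TRUE)

  # random fixture vs brute-force double loop
  set.seed(9)
  raw <- array(runif(20 * 50 * 8), dim = c(20, 50, 8))
  fp <- as_founder_probs(raw, data.frame(marker = paste0("m", 1:50),
                                         chrom = rep(c("1", "2"), each = 25),
                                         pos_bp = rep(1:25, 2)))
  Kb <- matrix(0, 20, 20)
  for (m in 1:20) for (n in 1:20) {
    Kb[m, n] <- mean(vapply(1:50, function(v) sum(fp$probs[m, v, ] * fp$probs[n, v, ]),
                            numeric(1)))
  }
  expect_equal(unclass(compute_kinship(fp)), Kb, ignore_attr = TRUE,
               tolerance = 1e-12)

  # founder-probability diagonal lies in [1/8, 1]
  expect_true(all(diag(compute_kinship(fp)) >= 1 / 8 - 1e-12))
  expect_true(all(diag(compute_kinship(fp)) <= 1 + 1e-12))

  # LOCO excludes every marker on the named chromosome
  K_loco <- compute_kinship(fp, exclude_chrom = "1")
  expect_equal(attr(K_loco, "n_markers"), 25)
  fp1 <- as_founder_probs(raw[, 26:50, , drop = FALSE], fp$map[26:50, ])
  expect_equal(unclass(K_loco), unclass(compute_kinship(fp1)), ignore_attr = TRUE)
  expect_error(compute_kinship(fp1, exclude_chrom = "2"),
               class = "dietqtl_validation_error")
})

test_that("profile likelihood matches a dense multivariate-normal evaluation", {
  pop <- make_population(n = 5, n_markers = 20, seed = 3)
  vc <- variance_components(sigma2 = c(0.5, 1.2), rho2 = 0.4, omega = c(0.3, 0.1))
  set.seed(6)
  Y <- rnorm(5, 20, 2)
  nll <- neg_log_likelihood(vc, Y, pop$X, pop$K, pop$Z)
  # dense oracle: explicit inverse and determinant, GLS mean
  L <- model_covariance(vc, pop$K, pop$Z)
  Li <- solve(L)
  a <- solve(t(pop$X) %*% Li %*% pop$X, t(pop$X) %*% Li %*% Y)
  r <- Y - pop$X %*% a
  dense <- 0.5 * (5 * log(2 * pi) + as.numeric(determinant(L)$modulus) +
                    as.numeric(t(r) %*% Li %*% r))
  expect_equal(as.numeric(nll), dense, tolerance = 1e-10)
  expect_equal(attr(nll, "alpha"), as.vector(a), tolerance = 1e-10)

  # invariance to simultaneous sample permutation
  set.seed(1)
  p <- sample(5)
  nll_p <- neg_log_likelihood(vc, Y[p], pop$X[p, ], unclass(pop$K)[p, p],
                              pop$Z[p, ])
  expect_equal(as.numeric(nll_p), as.numeric(nll), tolerance = 1e-10)

  # iid reduction: K = I, omega = 0, tied sigma -> OLS Gaussian likelihood
  n <- 40
  set.seed(12)
  Zi <- assign_environments(n, c(1, 1))
  Xi <- fixed_effects_design(Zi)
  Yi <- rnorm(n, 10, 2)
  vci <- variance_components(sigma2 = c(0.7, 0.7), rho2 = 0.6, omega = c(0, 0))
  nll_iid <- neg_log_likelihood(vci, Yi, Xi, diag(n), Zi)
  v <- 0.7 + 0.6
  rss <- sum(lm.fit(Xi, Yi)$residuals^2)
  expect_equal(as.numeric(nll_iid),
               0.5 * (n * log(2 * pi) + n * log(v) + rss / v),
               tolerance = 1e-10)
})

test_that("analytic gradients agree with central finite differences", {
  pop <- make_population(n = 30, n_markers = 50, seed = 9)
  vc0 <- solve_components_for_pve(c(0.4, 0.5), c(1, 1), pop$K, pop$Z)
  Y <- simulate_phenotypes(vc0, pop$K, pop$Z, mu = 3, seed = 5)
  set.seed(33)
  h <- 1e-6
  for (rep in 1:10) {
    par <- runif(5, 0.2, 1.5)
    vc <- variance_components(sigma2 = par[1:2], rho2 = par[3], omega = par[4:5])
    g <- gxemm_gradients(vc, Y, pop$X, pop$K, pop$Z)
    fd <- vapply(1:5, function(j) {
      up <- par; up[j] <- up[j] + h
      dn <- par; dn[j] <- dn[j] - h
      mk <- function(p) variance_components(sigma2 = p[1:2], rho2 = p[3],
                                            omega = p[4:5])
      -(neg_log_likelihood(mk(up), Y, pop$X, pop$K, pop$Z) -
          neg_log_likelihood(mk(dn), Y, pop$X, pop$K, pop$Z)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  }
})

test_that("fitting finds a stationary optimum no worse than any start", {
  inst <- fit_small_instance()
  fit <- inst$fit
  expect_true(fit$converged)
  expect_true(all(fit$start_values <= fit$loglik + 1e-6))
  # interior components have near-zero gradient at the optimum
  g <- gxemm_gradients(fit, inst$Y, inst$pop$X, inst$pop$K, inst$pop$Z)
  interior <- c(fit$sigma2 > 1e-6, fit$rho2 > 1e-6, fit$omega > 1e-6)
  expect_lt(max(abs(g[interior])), 1e-4)
  # determinism given seed
  fit2 <- fit_gxemm(inst$Y, inst$pop$X, inst$pop$K, inst$pop$Z, seed = 2)
  expect_equal(fit2$loglik, fit$loglik)
  expect_equal(fit2$omega, fit$omega)
})

test_that("constrained fits return exact zeros when the optimum is negative", {
  # phenotype with no interaction variance: unconstrained omega often goes
  # negative; the constrained fit must sit exactly on the boundary
  pop <- make_population(n = 100, n_markers = 50, seed = 17)
  vc0 <- variance_components(sigma2 = c(1, 1), rho2 = 0.3, omega = c(0, 0))
  found_boundary <- FALSE
  for (s in 1:5) {
    Y <- simulate_phenotypes(vc0, pop$K, pop$Z, mu = 10, seed = 40 + s)
    # the unconstrained surface can be flat near the edge of positive
    # definiteness; a non-convergence flag there is expected behavior
    fu <- suppressWarnings(
      fit_gxemm(Y, pop$X, pop$K, pop$Z, constrained = FALSE, seed = 1))
    if (any(fu$omega < -1e-4)) {
      fc <- fit_gxemm(Y, pop$X, pop$K, pop$Z, constrained = TRUE, seed = 1)
      expect_identical(unname(fc$omega[which.min(fu$omega)]), 0)
      found_boundary <- TRUE
      break
    }
  }
  expect_true(found_boundary)
})

test_that("EMMA is the homoscedastic special case of the GxEMM likelihood", {
  inst <- fit_small_instance()
  pop <- inst$pop
  fe <- fit_emma(inst$Y, pop$X, pop$K, seed = 3)
  # plugging (theta2, rho2, Omega = 0) into the GxEMM likelihood gives the
  # same value (environments are disjoint, so tied sigma2 collapses Theta)
  vc_tied <- variance_components(sigma2 = rep(fe$sigma2[1], 2), rho2 = fe$rho2,
                                 omega = c(0, 0))
  nll_g <- neg_log_likelihood(vc_tied, inst$Y, pop$X, pop$K, pop$Z)
  expect_equal(as.numeric(nll_g), -fe$loglik, tolerance = 1e-8)
  # nesting: GxEMM optimum is at least as good
  expect_gte(inst$fit$loglik, fe$loglik - 1e-6)

  # K = I reduces to OLS: theta2 + rho2 equals the ML residual variance
  n <- 120
  set.seed(3)
  Zi <- assign_environments(n, c(1, 1))
  Xi <- fixed_effects_design(Zi)
  Yi <- rnorm(n, 30, 1.7)
  fi <- fit_emma(Yi, Xi, diag(n), n_starts = 1)
  rss <- sum(lm.fit(Xi, Yi)$residuals^2)
  expect_equal(unname(fi$sigma2[1] + fi$rho2), rss / n, tolerance = 1e-6)
})

test_that("null-truth fits estimate near-zero genetic variance", {
  pop <- make_population(n = 150, n_markers = 50, seed = 23)
  vc0 <- variance_components(sigma2 = c(1, 1), rho2 = 0, omega = c(0, 0))
  fracs <- vapply(1:8, function(s) {
    Y <- simulate_phenotypes(vc0, pop$K, pop$Z, mu = 0, seed = 60 + s)
    f <- fit_gxemm(Y, pop$X, pop$K, pop$Z, n_starts = 1, seed = s)
    pve_total(f, pop$K, pop$Z, as.vector(pop$X %*% f$alpha))$pve
  }, numeric(1))
  expect_lt(median(fracs), 0.05)
})
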