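test_that("scan statistics match a dense GLS oracle under fixed components", {
  pop <- make_population(n = 30, n_markers = 20, seed = 61)
  vc <- solve_components_for_pve(c(0.4, 0.4), c(1, 1), pop$K, pop$Z)
  vc$alpha <- NULL
  Y <- simulate_phenotypes(vc, pop$K, pop$Z, mu = 10, seed = 3)
  G <- pop$sim$founder_probs
  res <- scan_additive(Y, G, pop$X, pop$Z, pop$K, vc = vc)
  expect_equal(nrow(res), 40)
  expect_true(all(res$llr >= -1e-8))
  expect_equal(res$lod, res$llr / log(10))

  # dense oracle: explicit GLS residual quadratic forms with solve()
  Lambda <- model_covariance(vc, pop$K, pop$Z)
  Li <- solve(Lambda)
  gls_rss <- function(W) {
    # pseudo-inverse GLS: the residual quadratic form is well defined even
    # when founder columns are collinear in a small sample
    b <- MASS::ginv(t(W) %*% Li %*% W) %*% (t(W) %*% Li %*% Y)
    r <- Y - W %*% b
    as.numeric(t(r) %*% Li %*% r)
  }
  C <- contr.sum(8)
  for (v in c(1, 7, 23)) {
    A <- G$probs[, v, ] %*% C
    phi_oracle <- 0.5 * (gls_rss(pop$X) - gls_rss(cbind(pop$X, A)))
    expect_equal(res$llr[v], phi_oracle, tolerance = 1e-6)
  }

  # interaction statistic against the same oracle (dosage coding keeps the
  # focal design well conditioned in a 30-sample instance)
  D <- pop$sim$dosages
  res_i <- scan_interaction(Y, D, pop$X, pop$Z, diet_cols = 1:2, pop$K, vc = vc)
  for (v in c(2, 11)) {
    A <- D$dosages[, v, drop = FALSE]
    AI <- A * pop$Z[, 2]
    phi_oracle <- 0.5 * (gls_rss(cbind(pop$X, A)) - gls_rss(cbind(pop$X, A, AI)))
    expect_equal(res_i$llr[v], phi_oracle, tolerance = 1e-6)
  }

  # refit mode equals the difference of full profile-likelihood maxima
  res_r <- scan_additive(Y, G, pop$X, pop$Z, pop$K, vc = NULL, refit = TRUE,
                         n_starts = 1, seed = 1)
  v <- which.max(res$llr)
  A <- G$probs[, v, ] %*% C
  f1 <- fit_gxemm(Y, cbind(pop$X, A), pop$K, pop$Z, n_starts = 1, seed = 1)
  f0 <- fit_gxemm(Y, pop$X, pop$K, pop$Z, n_starts = 1, seed = 1)
  expect_equal(res_r$llr[v], max(f1$loglik - f0$loglik, 0), tolerance = 1e-6)
})

test_that("monomorphic variants get a zero statistic and a flag", {
  pop <- make_population(n = 25, n_markers = 10, seed = 77)
  vc <- variance_components(sigma2 = c(1, 1), rho2 = 0.2, omega = c(0, 0))
  set.seed(4)
  Y <- rnorm(25, 20, 2)
  D <- pop$sim$dosages
  D$dosages[, 3] <- 1.3          # constant dosage: no founder variance
  res <- scan_additive(Y, D, pop$X, pop$Z, pop$K, vc = vc)
  expect_true(res$monomorphic[3])
  expect_equal(res$llr[3], 0)
  # markers that vary across mice are not flagged
  poly <- which(apply(D$dosages, 2, sd) > 0)
  expect_false(any(res$monomorphic[poly]))
})

test_that("an injected additive QTL is localized near the causal marker", {
  pop <- make_population(n = 200, n_markers = 50, seed = 83)
  vc0 <- solve_components_for_pve(c(0.3, 0.3), c(1, 1), pop$K, pop$Z)
  causal <- 25   # middle of chromosome 1
  g <- pop$sim$dosages$dosages[, causal]
  sdY <- sqrt(mean(diag(model_covariance(vc0, pop$K, pop$Z))))
  mu <- g * (sdY / sd(g))
  Y <- simulate_phenotypes(vc0, pop$K, pop$Z, mu = mu, seed = 21)
  Kl <- loco_kinship(pop$sim$founder_probs)
  res <- scan_additive(Y, pop$sim$dosages, pop$X, pop$Z, Kl, n_starts = 1)
  top <- which.max(res$llr)
  expect_equal(res$chrom[top], "1")
  expect_lt(abs(top - causal), 10)
})

test_that("interaction and additive tests separate opposite-sign diet effects", {
  pop <- make_population(n = 200, n_markers = 30, seed = 91)
  vc0 <- solve_components_for_pve(c(0.2, 0.2), c(1, 1), pop$K, pop$Z)
  v <- 10
  g <- pop$sim$dosages$dosages[, v]
  gc <- g - mean(g)
  # opposite effects in the two diets, zero marginal effect
  mu <- gc * pop$Z[, 1] - gc * pop$Z[, 2]
  Y <- simulate_phenotypes(vc0, pop$K, pop$Z, mu = mu, seed = 31)
  vc <- fit_gxemm(Y, pop$X, pop$K, pop$Z, n_starts = 1, seed = 1)
  add <- scan_additive(Y, pop$sim$dosages, pop$X, pop$Z, pop$K, vc = vc)
  int <- scan_interaction(Y, pop$sim$dosages, pop$X, pop$Z, 1:2, pop$K, vc = vc)
  expect_gt(int$llr[v], 20)
  expect_lt(add$llr[v], 5)
  expect_gt(int$llr[v], 10 * max(add$llr[v], 0.5))
})

test_that("sequential permutation p-values follow the stopping rule arithmetic", {
  # observed statistic above all of M = 99 permutations: p = 1/100
  gen_low <- function(m) rep(0, m)
  r <- sequential_permutation_p(5, gen_low, C_stop = 10, M_max = 99, seed = 1)
  expect_equal(r$p_value, (0 + 1) / (99 + 1))
  expect_equal(r$C, 0); expect_equal(r$M, 99)

  # every 20th permutation exceeds: C hits 10 exactly at M = 200 and the
  # p-value is a draw from [10/200, 11/201]
  make_counter <- function() local({ i <- 0; function(m) {
    out <- numeric(m)
    for (j in seq_len(m)) { i <<- i + 1; out[j] <- if (i %% 20 == 0) 9 else 0 }
    out
  }})
  r2 <- sequential_permutation_p(5, make_counter(), C_stop = 10, M_max = 1e6,
                                 seed = 2)
  expect_equal(r2$C, 10); expect_equal(r2$M, 200)
  expect_gte(r2$p_value, 10 / 200)
  expect_lte(r2$p_value, 11 / 201)

  # ties count as exceedances
  r3 <- sequential_permutation_p(5, function(m) rep(5, m), C_stop = 10,
                                 M_max = 1e6, seed = 3)
  expect_equal(r3$C, 10); expect_equal(r3$M, 10)
  expect_error(sequential_permutation_p(1, gen_low, M_max = 0),
               class = "dietqtl_validation_error")
  # deterministic given seed
  r4 <- sequential_permutation_p(5, make_counter(), C_stop = 10, M_max = 500,
                                 seed = 9)
  r5 <- sequential_permutation_p(5, make_counter(), C_stop = 10, M_max = 500,
                                 seed = 9)
  expect_identical(r4, r5)
})

test_that("effective-test counts follow the LD eigenvalue spectrum", {
  # exactly orthogonal markers (Helmert columns): M_eff = ceil(f * V)
  V <- 12
  H <- contr.helmert(V + 1)   # columns are orthogonal with zero mean
  th <- effective_tests_threshold(H, rep("1", V))
  expect_equal(th$meff_90, ceiling(0.90 * V))
  expect_equal(th$meff_995, ceiling(0.995 * V))
  expect_gte(th$meff_995, th$meff_90)

  # perfectly correlated markers: a single effective test
  set.seed(2)
  base <- rnorm(50)
  Mc <- outer(base, c(1, 2, -1, 0.5))
  th1 <- effective_tests_threshold(Mc)
  expect_equal(th1$meff_90, 1)
  expect_equal(th1$meff_995, 1)

  # 10 LD blocks x 20 perfectly correlated markers: 9 eigenvalues reach 90%
  blocks <- do.call(cbind, lapply(1:10, function(b) {
    v <- rnorm(50)
    outer(v, rep(1, 20))
  }))
  thb <- effective_tests_threshold(blocks)
  expect_equal(thb$meff_90, 9)
  ord <- thb$thresholds
  expect_true(ord["stringent"] <= ord["significant"])
  expect_true(ord["significant"] <= ord["suggestive"])
})

test_that("significance labels follow the tiered cutoffs", {
  th <- structure(list(alpha = 0.05, meff_90 = 500, meff_995 = 4545,
                       thresholds = c(suggestive = 1e-3, significant = 1e-4,
                                      stringent = 1.1e-5)),
                  class = "significance_thresholds")
  expect_equal(classify_significance(1.0e-5, th, "additive"), "***")
  expect_equal(classify_significance(5e-4, th, "interaction"), "*")
  # the suggestive tier applies to interaction tests only
  expect_equal(classify_significance(5e-4, th, "additive"), "")
  expect_equal(classify_significance(9e-5, th, "additive"), "**")
})
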