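# Synthetic diversity-outbred data generator. Genomes are first-order
# Markov mosaics over the 8 founders with local linkage (low per-marker
# switch rate), founder probabilities are one-hot, dosages derive from
# simulated founder alleles, and phenotypes are drawn from the zero-mean
# multivariate normal implied by the GxEMM covariance with interaction
# variances solved in closed form to hit target per-environment PVE.
# Defaults reproduce the model-validation protocol: two environments,
# sigma2_e1 = sigma2_e2 = 1, samples assigned 1:1 or 4:1, target PVE_e
# swept over a grid.

#' Simulate DO-like founder mosaics
#'
#' Per mouse and chromosome, the founder-of-origin sequence along markers
#' is a first-order Markov chain over the 8 founders: with probability
#' `switch_rate` per marker step the founder is redrawn uniformly.
#' Founder probabilities are one-hot; each founder carries a random
#' biallelic allele (alternate-allele frequency 0.5) at every marker, and
#' the mouse dosage is the carried founder's allele count (0 or 2).
#'
#' @param n_mice Number of mice.
#' @param n_chrom Number of chromosomes (default 2).
#' @param n_markers Markers per chromosome (default 250).
#' @param switch_rate Per-marker founder switch probability in `[0, 1]`
#'   (default 0.05).
#' @param marker_spacing_bp Physical spacing between markers (default
#'   1e5).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List with `founder_probs` (a `founder_probs` object, one-hot),
#'   `dosages` (a `dosage_matrix`), and `founder_geno` (V x 8 matrix of
#'   founder alternate-allele counts, 0/2).
#' @export
simulate_mosaics <- function(n_mice, n_chrom = 2, n_markers = 250,
                             switch_rate = 0.05, marker_spacing_bp = 1e5,
                             seed = NULL) {
  if (switch_rate < 0 || switch_rate > 1) {
    stop_validation("switch_rate must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  V <- n_chrom * n_markers
  map <- data.frame(marker = paste0("m", seq_len(V)),
                    chrom = rep(as.character(seq_len(n_chrom)), each = n_markers),
                    pos_bp = rep(seq_len(n_markers) * marker_spacing_bp, n_chrom))
  # founder state per mouse x marker
  state <- matrix(0L, n_mice, V)
  for (cc in seq_len(n_chrom)) {
    cols <- (cc - 1) * n_markers + seq_len(n_markers)
    s <- sample.int(8, n_mice, replace = TRUE)
    state[, cols[1]] <- s
    if (n_markers > 1) {
      for (j in 2:n_markers) {
        flip <- stats::runif(n_mice) < switch_rate
        s[flip] <- sample.int(8, sum(flip), replace = TRUE)
        state[, cols[j]] <- s
      }
    }
  }
  probs <- array(0, dim = c(n_mice, V, 8),
                 dimnames = list(paste0("mouse", seq_len(n_mice)),
                                 map$marker, DO_FOUNDERS))
  idx <- cbind(rep(seq_len(n_mice), V), rep(seq_len(V), each = n_mice),
               as.vector(state))
  probs[idx] <- 1
  founder_geno <- matrix(2L * stats::rbinom(V * 8, 1, 0.5), V, 8,
                         dimnames = list(map$marker, DO_FOUNDERS))
  dos <- matrix(founder_geno[cbind(rep(seq_len(V), each = n_mice),
                                   as.vector(state))],
                n_mice, V)
  list(founder_probs = as_founder_probs(probs, map),
       dosages = dosage_matrix(dos, map),
       founder_geno = founder_geno)
}

#' Assign samples to environments at a given ratio
#'
#' @param n_mice Number of mice.
#' @param allocation Proportions per environment (normalized; e.g.
#'   `c(1, 1)` or `c(4, 1)`).
#' @param seed Integer seed.
#' @return N x E binary matrix Z with one environment per mouse.
#' @export
assign_environments <- function(n_mice, allocation = c(1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- allocation / sum(allocation)
  E <- length(p)
  sizes <- floor(n_mice * p)
  rem <- n_mice - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  lab <- sample(rep.int(seq_len(E), sizes))
  Z <- outer(lab, seq_len(E), `==`) * 1
  colnames(Z) <- paste0("env", seq_len(E))
  Z
}

#' Solve interaction variances for target per-environment PVE
#'
#' With the shared polygenic variance fixed at zero, the conditional
#' decomposition gives, for disjoint environments,
#' `PVE_e = Omega_ee g_e / (Omega_ee g_e + sigma2_e (Ne - 1) / Ne)` with
#' `g_e = tr(K o W_e)/Ne - sum(K o W_e)/Ne^2`, which inverts in closed
#' form to `Omega_ee = [PVE_e / (1 - PVE_e)] * sigma2_e (Ne-1)/Ne / g_e`.
#'
#' @param pve_e Target PVE per environment (each in `[0, 1)`).
#' @param sigma2_e Noise variance per environment.
#' @param K Kinship matrix.
#' @param Z Binary environment matrix (disjoint columns).
#' @return A `variance_components` object with `rho2 = 0` and the solved
#'   `omega`.
#' @export
solve_components_for_pve <- function(pve_e, sigma2_e, K, Z) {
  Z <- as.matrix(Z)
  E <- ncol(Z)
  pve_e <- rep_len(pve_e, E); sigma2_e <- rep_len(sigma2_e, E)
  if (any(pve_e < 0 | pve_e >= 1)) stop_validation("target PVE must lie in [0, 1)")
  if (any(rowSums(Z) != 1)) {
    stop_validation("closed-form inversion requires disjoint environments (one per mouse)")
  }
  K <- unclass(K)
  kd <- diag(K)
  omega <- vapply(seq_len(E), function(e) {
    ze <- Z[, e]; ne <- sum(ze)
    g_e <- sum(kd * ze) / ne - as.vector(crossprod(ze, K %*% ze)) / ne^2
    if (g_e <= 0) stop_validation("degenerate kinship: non-positive genetic coefficient in environment %d", e)
    resid <- sigma2_e[e] * (ne - 1) / ne
    (pve_e[e] / (1 - pve_e[e])) * resid / g_e
  }, numeric(1))
  vc <- variance_components(sigma2 = sigma2_e, rho2 = 0, omega = omega,
                            model = "gxemm", constrained = TRUE)
  names(vc$sigma2) <- names(vc$omega) <- colnames(Z)
  vc
}

#' Draw phenotypes from the model-implied multivariate normal
#'
#' `Y ~ N(mu, Lambda)` with `Lambda` from [model_covariance()], sampled
#' via the Cholesky factor. In the simulation protocol `mu = 0`; an
#' injected QTL enters through `mu` (e.g. `dosage * phi`).
#'
#' @param vc A `variance_components` object.
#' @param K Kinship matrix.
#' @param Z Environment matrix.
#' @param mu Mean vector (default 0).
#' @param n_draws Number of phenotype vectors.
#' @param seed Integer seed; fixed seed gives identical draws.
#' @return N x `n_draws` matrix (or a vector when `n_draws = 1`).
#' @export
simulate_phenotypes <- function(vc, K, Z, mu = 0, n_draws = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Lambda <- model_covariance(vc, K, Z)
  ch <- tryCatch(chol(Lambda), error = function(e) {
    ev <- min(eigen(Lambda, symmetric = TRUE, only.values = TRUE)$values)
    stop_validation("model covariance is not positive definite (smallest eigenvalue %.3e)", ev)
  })
  n <- nrow(Lambda)
  draws <- mu + crossprod(ch, matrix(stats::rnorm(n * n_draws), n, n_draws))
  if (n_draws == 1) as.vector(draws) else draws
}

#' Enumerate the simulation-protocol parameter grid
#'
#' Target PVE in environment 1 over `{0.2, 0.5, 0.8}`, target PVE in
#' environment 2 over `{0.05, 0.10, ..., 0.95}`, at allocation ratios 1:1
#' and 4:1 — 114 settings in total.
#'
#' @return Data frame `pve_e1`, `pve_e2`, `ratio`.
#' @export
enumerate_protocol_grid <- function() {
  expand.grid(pve_e1 = c(0.2, 0.5, 0.8),
              pve_e2 = seq(0.05, 0.95, by = 0.05),
              ratio = c("1:1", "4:1"),
              stringsAsFactors = FALSE)
}

#' Run the simulation-protocol recovery study
#'
#' For each grid setting and replicate: assign samples to the two
#' environments at the given ratio, solve the interaction variances for
#' the target PVE, draw a zero-mean phenotype, and fit the GxEMM (and
#' optionally EMMA) model, recording total and per-environment PVE
#' estimates.
#'
#' @param K Kinship matrix of the simulated population (e.g. from
#'   [simulate_mosaics()] + [compute_kinship()]).
#' @param settings Data frame with columns `pve_e1`, `pve_e2`, `ratio`
#'   (see [enumerate_protocol_grid()]); any subset may be supplied.
#' @param n_replicates Replicates per setting (protocol: 50).
#' @param sigma2_e Noise variances (protocol: both 1).
#' @param models Models to fit.
#' @param seed Integer seed controlling assignments, draws and fits.
#' @param n_starts Optimization starts per fit (default 1; the protocol
#'   likelihood surface is well behaved).
#' @return Data frame with one row per (setting, replicate, model):
#'   targets, `pve_tot`, `pve_e1_hat`, `pve_e2_hat` (NA for EMMA).
#' @export
run_simulation_study <- function(K, settings, n_replicates = 50,
                                 sigma2_e = c(1, 1),
                                 models = c("gxemm", "emma"),
                                 seed = 1, n_starts = 1) {
  n <- nrow(K)
  eig_K <- if ("emma" %in% models) eigen(unclass(K), symmetric = TRUE) else NULL
  out <- vector("list", nrow(settings) * n_replicates)
  k <- 0
  for (s in seq_len(nrow(settings))) {
    alloc <- if (settings$ratio[s] == "4:1") c(4, 1) else c(1, 1)
    targets <- c(settings$pve_e1[s], settings$pve_e2[s])
    for (r in seq_len(n_replicates)) {
      set.seed(seed + 7919L * s + r)
      Z <- assign_environments(n, alloc)
      vc_true <- solve_components_for_pve(targets, sigma2_e, K, Z)
      ptot_true <- pve_total(vc_true, K, Z, 0)$pve
      Y <- simulate_phenotypes(vc_true, K, Z)
      X <- fixed_effects_design(Z)
      for (mdl in models) {
        fit <- if (mdl == "gxemm") {
          fit_gxemm(Y, X, K, Z, n_starts = n_starts, seed = seed + r)
        } else {
          fit_emma(Y, X, K, n_starts = n_starts, seed = seed + r, eig = eig_K)
        }
        mu <- as.vector(X %*% fit$alpha)
        ptot <- if (mdl == "gxemm") pve_total(fit, K, Z, mu)$pve
                else pve_emma(fit, K, mu)$pve
        pe <- if (mdl == "gxemm") {
          c(pve_env(fit, K, Z, mu, 1)$pve, pve_env(fit, K, Z, mu, 2)$pve)
        } else c(NA_real_, NA_real_)
        k <- k + 1
        out[[k]] <- data.frame(setting = s, replicate = r, model = mdl,
                               pve_e1 = targets[1], pve_e2 = targets[2],
                               ratio = settings$ratio[s],
                               pve_tot_true = ptot_true,
                               pve_tot = ptot, pve_e1_hat = pe[1],
                               pve_e2_hat = pe[2],
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Summarize a simulation study as median and 95% interquantile band
#'
#' @param study Output of [run_simulation_study()].
#' @param value Column to summarize (default `pve_e2_hat`).
#' @return Data frame per (setting, model): `median`, `q2.5`, `q97.5`.
#' @export
summarize_simulation_study <- function(study, value = "pve_e2_hat") {
  sp <- split(study, interaction(study$setting, study$model, drop = TRUE))
  do.call(rbind, lapply(sp, function(g) {
    v <- g[[value]]
    data.frame(setting = g$setting[1], model = g$model[1],
               pve_e1 = g$pve_e1[1], pve_e2 = g$pve_e2[1], ratio = g$ratio[1],
               median = stats::median(v, na.rm = TRUE),
               q2.5 = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
               q97.5 = unname(stats::quantile(v, 0.975, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
}
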