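# Genome-wide association scans per age: additive founder-of-origin (or
# dosage) tests and genotype-diet interaction tests under the GxEMM
# covariance with LOCO kinship, sequential permutation p-values, and
# LD-eigenvalue effective-test Bonferroni thresholds.
#
# The test statistic is the log likelihood ratio (natural log)
#   Phi_a = log [ max L(phi_s, ...) / max L(phi_s = 0, ...) ]
# for the additive test, and for the interaction test the analogous ratio
# with the genotype-diet terms chi_se free versus zero (phi_s free in
# both). LOD = Phi / ln(10). By default the variance components are
# estimated once per (age, chromosome) under the no-focal-variant model
# and held fixed while the focal fixed effects are profiled across
# variants; `refit = TRUE` re-maximizes all parameters per variant.

# sum-to-zero contrast for the 8 founder columns, keeping the intercept
# identifiable (7 columns)
founder_contrast_cols <- function(G8) {
  C <- stats::contr.sum(8)
  A <- G8 %*% C
  colnames(A) <- paste0("f", seq_len(7))
  A
}

# focal-variant fixed-effect columns for one variant
focal_columns <- function(G, v) {
  if (inherits(G, "founder_probs")) {
    founder_contrast_cols(G$probs[, v, ])
  } else if (inherits(G, "dosage_matrix")) {
    matrix(G$dosages[, v], ncol = 1, dimnames = list(NULL, "dosage"))
  } else {
    matrix(as.matrix(G)[, v], ncol = 1, dimnames = list(NULL, "dosage"))
  }
}

scan_marker_map <- function(G) {
  if (!is.null(G$map)) G$map
  else data.frame(marker = paste0("v", seq_len(ncol(as.matrix(G)))),
                  chrom = "1", pos_bp = seq_len(ncol(as.matrix(G))))
}

# whitened projections for a fixed covariance: returns function computing
# Phi for extra columns on top of a base design
whiten <- function(Lambda) {
  R <- chol(Lambda)
  function(M) backsolve(R, M, transpose = TRUE)
}

# Phi for fixed variance components: half the drop in GLS residual sum of
# squares when `extra` columns join the whitened base design
phi_fixed_vc <- function(yw, Qbase, extraw, tol = 1e-8) {
  r <- extraw - Qbase %*% crossprod(Qbase, extraw)
  scale <- max(sqrt(colSums(extraw^2)), 1)
  keep <- sqrt(colSums(r^2)) > tol * scale
  if (!any(keep)) return(list(phi = 0, monomorphic = TRUE))
  qr_r <- qr(r[, keep, drop = FALSE])
  rank <- qr_r$rank
  if (rank == 0) return(list(phi = 0, monomorphic = TRUE))
  Q1 <- qr.Q(qr_r)[, seq_len(rank), drop = FALSE]
  phi <- 0.5 * sum(crossprod(Q1, yw)^2)
  list(phi = max(phi, 0), monomorphic = FALSE)
}

scan_engine <- function(Y, G, X, Z, K, vc, test, diet_cols = NULL,
                        refit = FALSE, ...) {
  map <- scan_marker_map(G)
  X <- as.matrix(X); Z <- as.matrix(Z)
  chroms <- unique(map$chrom)
  Klist <- if (is.list(K) && !inherits(K, "kinship")) K else
    stats::setNames(rep(list(K), length(chroms)), chroms)
  vclist <- if (inherits(vc, "variance_components")) {
    stats::setNames(rep(list(vc), length(chroms)), chroms)
  } else vc
  out <- vector("list", nrow(map))
  for (cc in chroms) {
    Kc <- Klist[[as.character(cc)]]
    if (is.null(Kc)) stop_validation("no kinship supplied for chromosome %s", cc)
    vcc <- if (!is.null(vclist)) vclist[[as.character(cc)]] else
      fit_gxemm(Y, X, Kc, Z, ...)
    Lambda <- model_covariance(vcc, Kc, Z)
    wh <- whiten(Lambda)
    yw <- wh(Y); Xw <- wh(X)
    vs <- which(map$chrom == cc)
    for (v in vs) {
      A <- focal_columns(G, v)
      if (test == "additive") {
        base_w <- Xw
        extra <- A
      } else {
        base_w <- cbind(Xw, wh(A))
        extra <- do.call(cbind, lapply(diet_cols[-1], function(e) A * Z[, e]))
      }
      Qb <- qr.Q(qr(base_w))
      res <- phi_fixed_vc(yw, Qb, wh(extra))
      phi <- res$phi
      if (refit && !res$monomorphic) {
        X1 <- if (test == "additive") cbind(X, A) else
          cbind(X, A, do.call(cbind, lapply(diet_cols[-1], function(e) A * Z[, e])))
        X0 <- if (test == "additive") X else cbind(X, A)
        # drop columns that make the design rank-deficient before refitting
        X1 <- X1[, qr(X1)$pivot[seq_len(qr(X1)$rank)], drop = FALSE]
        X0 <- X0[, qr(X0)$pivot[seq_len(qr(X0)$rank)], drop = FALSE]
        f1 <- fit_gxemm(Y, X1, Kc, Z, ...)
        f0 <- fit_gxemm(Y, X0, Kc, Z, ...)
        phi <- max(f1$loglik - f0$loglik, 0)
      }
      out[[v]] <- data.frame(marker = map$marker[v], chrom = map$chrom[v],
                             pos_bp = map$pos_bp[v], test = test,
                             llr = phi, lod = phi / log(10),
                             monomorphic = res$monomorphic,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Additive association scan
#'
#' Tests each variant for an additive effect on the phenotype at one age,
#' including the focal variant among the fixed effects (founder-of-origin
#' probabilities enter through a sum-to-zero contrast over the 8 founders;
#' dosages as a single column) while all other variants contribute through
#' the random effects via LOCO kinship.
#'
#' @param Y Phenotype vector at one age.
#' @param G A `founder_probs` or `dosage_matrix` object.
#' @param X Fixed-effect design (see [fixed_effects_design()]).
#' @param Z Environment matrix.
#' @param K A single kinship matrix, or a named list of LOCO kinships
#'   keyed by chromosome (see [loco_kinship()]).
#' @param vc Optional pre-fit `variance_components` (or named list per
#'   chromosome); when NULL the no-focal-variant model is fit per
#'   chromosome and its components held fixed across that chromosome's
#'   variants.
#' @param refit Re-maximize the variance components per variant (the exact
#'   likelihood-ratio; much slower).
#' @param ... Passed to [fit_gxemm()] for any internal fits.
#' @return Data frame per variant: `marker`, `chrom`, `pos_bp`, `test`,
#'   `llr` (natural-log likelihood ratio), `lod` (`llr / ln 10`),
#'   `monomorphic` flag.
#' @export
scan_additive <- function(Y, G, X, Z, K, vc = NULL, refit = FALSE, ...) {
  scan_engine(Y, G, X, Z, K, vc, test = "additive", refit = refit, ...)
}

#' Genotype-diet interaction scan
#'
#' Tests each variant for interaction with the diets of interest: the
#' alternative includes fixed effects for the focal variant and its
#' interaction with each diet column, the null keeps only the additive
#' focal effect. Interactions are coded against the first diet column as
#' reference, so the statistic detects any between-diet difference in the
#' variant effect.
#'
#' @inheritParams scan_additive
#' @param diet_cols Indices (or names) of the diet columns of `Z`; the
#'   first is the reference diet.
#' @export
scan_interaction <- function(Y, G, X, Z, diet_cols, K, vc = NULL,
                             refit = FALSE, ...) {
  Z <- as.matrix(Z)
  if (is.character(diet_cols)) diet_cols <- match(diet_cols, colnames(Z))
  scan_engine(Y, G, X, Z, K, vc, test = "interaction",
              diet_cols = diet_cols, refit = refit, ...)
}

#' Focal-variant effect estimates and standard errors
#'
#' Fits the focal variant's fixed effects by GLS under the fitted GxEMM
#' covariance and returns effect estimates with standard errors. At the
#' additive level these are the founder-contrast (or dosage) coefficients;
#' with `founder_effects = TRUE` founder-probability contrasts are mapped
#' back to the 8 per-founder allele effects (sum-to-zero). At the diet
#' level the per-diet effect of the variant is `phi_s + chi_se`
#' (interactions coded against the first diet column as reference, for
#' which `chi = 0`).
#'
#' @inheritParams scan_additive
#' @param v Variant index in `G`.
#' @param vc Fitted `variance_components` for this chromosome's LOCO
#'   kinship.
#' @param level `"additive"` for founder/dosage effects, `"diet"` for
#'   per-diet effects of the variant.
#' @param diet_cols Diet columns of `Z` (required for `level = "diet"`).
#' @param founder_effects Convert founder contrasts to per-founder
#'   effects (founder-probability mode only).
#' @return Data frame `term`, `estimate`, `se` (grams). For diet-level
#'   founder effects, terms are `diet:founder`.
#' @export
variant_effects <- function(Y, G, v, X, Z, K, vc, level = c("additive", "diet"),
                            diet_cols = NULL, founder_effects = FALSE) {
  level <- match.arg(level)
  X <- as.matrix(X); Z <- as.matrix(Z)
  A <- focal_columns(G, v)
  kA <- ncol(A)
  founder_mode <- kA == 7
  Cmat <- if (founder_mode) stats::contr.sum(8) else diag(1)
  Lambda <- model_covariance(vc, K, Z)
  wh <- whiten(Lambda)
  if (level == "additive") {
    W <- cbind(X, A)
  } else {
    if (is.null(diet_cols)) stop_validation("diet_cols required for diet-level effects")
    if (is.character(diet_cols)) diet_cols <- match(diet_cols, colnames(Z))
    inter <- do.call(cbind, lapply(diet_cols[-1], function(e) A * Z[, e]))
    W <- cbind(X, A, inter)
  }
  Ww <- wh(W); yw <- wh(Y)
  qrW <- qr(Ww)
  if (qrW$rank < ncol(Ww)) stop_validation("rank-deficient focal design")
  beta <- qr.coef(qrW, yw)
  cov <- chol2inv(qr.R(qrW))       # GLS covariance; Lambda is absolute scale
  iA <- ncol(X) + seq_len(kA)
  # linear maps from coefficients to reported effects
  to_effects <- function(cols_list, labels) {
    rows <- lapply(seq_along(cols_list), function(j) {
      Lm <- matrix(0, kA, ncol(W))
      for (q in seq_len(kA)) Lm[q, cols_list[[j]][[q]]] <- 1
      Out <- if (founder_effects && founder_mode) Cmat %*% Lm else Lm
      terms <- if (founder_effects && founder_mode) DO_FOUNDERS
               else colnames(A) %||% paste0("b", seq_len(kA))
      data.frame(term = if (is.null(labels)) terms
                        else paste0(labels[j], ":", terms),
                 estimate = as.vector(Out %*% beta),
                 se = sqrt(diag(Out %*% cov %*% t(Out))),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (level == "additive") {
    to_effects(list(as.list(iA)), NULL)
  } else {
    cols_list <- lapply(seq_along(diet_cols), function(j) {
      lapply(seq_len(kA), function(q) {
        if (j == 1) iA[q]
        else c(iA[q], ncol(X) + kA + (j - 2) * kA + q)
      })
    })
    to_effects(cols_list, colnames(Z)[diet_cols] %||% paste0("diet", diet_cols))
  }
}

#' Sequential permutation p-value
#'
#' Implements the sequential permutation rule: permuted statistics are
#' drawn until either `C_stop` of them reach the observed statistic or
#' `M_max` permutations have been used. With final exceedance count C
#' after M permutations, the p-value is `(C + 1) / (M + 1)` when the
#' permutation budget was exhausted, and a uniform draw from
#' `[C/M, (C+1)/(M+1)]` when stopping early at `C = C_stop` (ties
#' `Phi_m = Phi_obs` count as exceedances).
#'
#' @param phi_obs Observed statistic.
#' @param perm_stat Function of one argument `m` returning `m` permuted
#'   statistics (must consume the R RNG stream so that `seed` controls it).
#' @param C_stop Exceedance count at which to stop (default 10).
#' @param M_max Permutation budget.
#' @param seed Integer seed controlling permutations and the final draw.
#' @param batch Statistics generated per call to `perm_stat`.
#' @return List with `p_value`, `C` (exceedances), `M` (permutations used).
#' @export
sequential_permutation_p <- function(phi_obs, perm_stat, C_stop = 10,
                                     M_max = 1e8, seed = NULL, batch = 256) {
  if (M_max < 1) stop_validation("M_max must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  C <- 0L; M <- 0L
  while (M < M_max && C < C_stop) {
    m <- min(batch, M_max - M)
    stats <- perm_stat(m)
    exceed <- stats >= phi_obs
    cum <- cumsum(exceed)
    if (C + cum[m] >= C_stop) {
      # stop exactly at the permutation where the C_stop-th exceedance lands
      hit <- which(C + cum >= C_stop)[1]
      C <- C_stop
      M <- M + hit
      break
    }
    C <- C + cum[m]
    M <- M + m
  }
  p <- if (C >= C_stop && M < M_max) {
    stats::runif(1, C / M, (C + 1) / (M + 1))
  } else {
    (C + 1) / (M + 1)
  }
  list(p_value = p, C = C, M = M)
}

#' Permutation-statistic generator for a scan test
#'
#' Returns a closure suitable for [sequential_permutation_p()]: each call
#' permutes the phenotype rows (unrestricted by default, or within the
#' levels of `within`) and recomputes the scan statistic under the fixed
#' fitted covariance, in vectorized batches.
#'
#' @inheritParams scan_additive
#' @param v Variant index.
#' @param test `"additive"` or `"interaction"`.
#' @param diet_cols Diet columns (interaction test).
#' @param within Optional factor; permutations are restricted to shuffle
#'   phenotypes within its levels.
#' @return Function `f(m)` returning `m` permuted statistics.
#' @export
scan_perm_generator <- function(Y, G, v, X, Z, K, vc,
                                test = c("additive", "interaction"),
                                diet_cols = NULL, within = NULL) {
  test <- match.arg(test)
  X <- as.matrix(X); Z <- as.matrix(Z)
  A <- focal_columns(G, v)
  Lambda <- model_covariance(vc, K, Z)
  R <- chol(Lambda)
  wh <- function(M) backsolve(R, M, transpose = TRUE)
  if (test == "additive") {
    base_w <- wh(X)
    extra_w <- wh(A)
  } else {
    if (is.character(diet_cols)) diet_cols <- match(diet_cols, colnames(Z))
    base_w <- cbind(wh(X), wh(A))
    extra_w <- wh(do.call(cbind, lapply(diet_cols[-1], function(e) A * Z[, e])))
  }
  Q0 <- qr.Q(qr(base_w))
  r <- extra_w - Q0 %*% crossprod(Q0, extra_w)
  qr_r <- qr(r)
  Q1 <- qr.Q(qr_r)[, seq_len(max(qr_r$rank, 1)), drop = FALSE]
  n <- length(Y)
  lv <- if (is.null(within)) NULL else split(seq_len(n), within)
  function(m) {
    P <- vapply(seq_len(m), function(i) {
      if (is.null(lv)) sample.int(n) else {
        idx <- integer(n)
        for (g in lv) idx[g] <- g[sample.int(length(g))]
        idx
      }
    }, integer(n))
    Ym <- matrix(Y[P], nrow = n)
    Yw <- backsolve(R, Ym, transpose = TRUE)
    0.5 * colSums(crossprod(Q1, Yw)^2)
  }
}

#' Effective-test Bonferroni thresholds from LD eigenvalues
#'
#' Estimates the number of independent tests as the number of top
#' eigenvalues of the marker LD (correlation) matrix needed to explain a
#' given fraction of the variance across markers; eigenvalues are computed
#' per chromosome and pooled genome-wide. Two fractions give the two
#' tiers: 90% for the significant threshold and 99.5% for the stringent
#' one; the suggestive cutoff (applied to interaction tests) is ten times
#' the significant one.
#'
#' @param markers N x V matrix of marker values (e.g. dosages), or a
#'   `dosage_matrix`.
#' @param chrom Chromosome per marker (defaults to the object's map, or a
#'   single chromosome).
#' @param alpha Family-wise level (default 0.05).
#' @param fractions Variance fractions for the two tiers.
#' @return A `significance_thresholds` object: list with `alpha`,
#'   `meff_90`, `meff_995`, and `thresholds` (`suggestive`, `significant`,
#'   `stringent`).
#' @export
effective_tests_threshold <- function(markers, chrom = NULL, alpha = 0.05,
                                      fractions = c(0.90, 0.995)) {
  if (inherits(markers, "dosage_matrix")) {
    chrom <- chrom %||% markers$map$chrom
    markers <- markers$dosages
  }
  markers <- as.matrix(markers)
  if (ncol(markers) < 2) stop_validation("need at least 2 markers")
  chrom <- chrom %||% rep("1", ncol(markers))
  evs <- unlist(lapply(unique(chrom), function(cc) {
    M <- markers[, chrom == cc, drop = FALSE]
    sds <- apply(M, 2, stats::sd)
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) == 0) return(numeric(0))
    if (ncol(M) == 1) return(1)
    eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  }))
  evs <- sort(pmax(evs, 0), decreasing = TRUE)
  total <- sum(evs)
  meff <- vapply(fractions, function(f) {
    if (total <= 0) return(1L)
    as.integer(which(cumsum(evs) >= f * total - 1e-12)[1])
  }, integer(1))
  significant <- alpha / meff[1]
  stringent <- alpha / meff[2]
  structure(list(alpha = alpha,
                 meff_90 = meff[1], meff_995 = meff[2],
                 thresholds = c(suggestive = 10 * significant,
                                significant = significant,
                                stringent = stringent)),
            class = "significance_thresholds")
}

#' Label associations by significance tier
#'
#' `***` for p at or below the stringent cutoff, `**` for the significant
#' cutoff, and `*` (suggestive) for interaction tests only.
#'
#' @param results Scan data frame with columns `p_value` and `test`, or a
#'   numeric vector of p-values (then supply `test`).
#' @param thresholds A `significance_thresholds` object.
#' @param test Test type per p-value when `results` is a vector.
#' @return Character vector of labels (`"***"`, `"**"`, `"*"`, `""`).
#' @export
classify_significance <- function(results, thresholds, test = NULL) {
  if (is.data.frame(results)) {
    p <- results$p_value; test <- results$test
  } else {
    p <- as.numeric(results)
    test <- test %||% rep("additive", length(p))
  }
  th <- thresholds$thresholds
  out <- character(length(p))
  out[p <= th["suggestive"] & test == "interaction"] <- "*"
  out[p <= th["significant"]] <- "**"
  out[p <= th["stringent"]] <- "***"
  out
}
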