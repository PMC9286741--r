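# Tests for nonlinearity in effect-size trends with age. The per-age
# effect estimates phi-hat_st are modeled as normal around the true trend
# with known standard errors psi-hat_st; the null trend is linear in age
# and the alternative cubic, and the weighted likelihood-ratio statistic
# aleph = 2 ln [max L(cubic) / max L(linear)] is referred to a
# chi-squared distribution with 2 degrees of freedom.

#' Test an effect-size trend for nonlinearity in age
#'
#' Fits the linear (`phi = b0 + b1 t`) and cubic
#' (`phi = b0 + b1 t + b2 t^2 + b3 t^3`) trend models by weighted least
#' squares with per-age weights `1 / se^2` (maximum likelihood when the
#' standard errors are treated as known). The statistic is the drop in
#' weighted residual sum of squares, and the p-value comes from the
#' chi-squared upper tail with 2 degrees of freedom. Age is centered and
#' rescaled to `[-1, 1]` before fitting for numerical conditioning; the
#' statistic is invariant to this affine reparameterization.
#'
#' @param profile Data frame with columns `age`, `estimate`, `se` (one
#'   effect level; see [effect_profile()]).
#' @return A `nonlinearity_result` list: `aleph`, `p_value`, `df` (2),
#'   `coef_linear`, `coef_cubic` (on the rescaled age axis), `n_ages`.
#' @export
nonlinearity_test <- function(profile) {
  ok <- is.finite(profile$estimate) & is.finite(profile$se) & profile$se > 0
  d <- profile[ok, , drop = FALSE]
  if (nrow(d) < 5) {
    stop_validation("nonlinearity test needs at least 5 ages with finite estimates (got %d)",
                    nrow(d))
  }
  if (length(unique(d$age)) < 4) {
    stop_validation("cubic trend needs at least 4 distinct ages")
  }
  t_sc <- 2 * (d$age - min(d$age)) / (max(d$age) - min(d$age)) - 1
  w <- 1 / d$se^2
  fit_l <- stats::lm(d$estimate ~ t_sc, weights = w)
  fit_c <- stats::lm(d$estimate ~ t_sc + I(t_sc^2) + I(t_sc^3), weights = w)
  wrss <- function(f) sum(w * stats::residuals(f)^2)
  aleph <- max(wrss(fit_l) - wrss(fit_c), 0)
  structure(list(aleph = aleph,
                 p_value = stats::pchisq(aleph, df = 2, lower.tail = FALSE),
                 df = 2,
                 coef_linear = stats::coef(fit_l),
                 coef_cubic = stats::coef(fit_c),
                 n_ages = nrow(d)),
            class = "nonlinearity_result")
}

#' Enumerate the nonlinearity tests implied by a set of loci
#'
#' Diet-independent loci are tested once per founder allele of the lead
#' variant (8 tests per locus); diet-dependent loci once per
#' (founder, diet) pair (40 tests per locus with the five diets).
#'
#' @param loci Character/identifier vector of loci, or a count.
#' @param diets Diet labels for diet-dependent loci; NULL for
#'   diet-independent loci.
#' @param founders Founder labels (default the 8 canonical founders).
#' @return Data frame with one row per test: `locus`, `founder`, and
#'   `diet` (NA for diet-independent).
#' @export
nonlinearity_test_grid <- function(loci, diets = NULL, founders = DO_FOUNDERS) {
  if (length(loci) == 1 && is.numeric(loci)) loci <- paste0("locus", seq_len(loci))
  if (is.null(diets)) {
    expand.grid(locus = loci, founder = founders, diet = NA_character_,
                stringsAsFactors = FALSE)
  } else {
    expand.grid(locus = loci, founder = founders, diet = diets,
                stringsAsFactors = FALSE)
  }
}

#' Run nonlinearity tests across loci and apply tiered cutoffs
#'
#' Applies [nonlinearity_test()] to each supplied effect profile and flags
#' significance with the tier's fixed cutoff: `1e-4` for diet-independent
#' (founder-effect) trends and `1e-5` for diet-dependent
#' (founder-by-diet) trends, the Bonferroni-scale thresholds matching the
#' 112 and 760 tests implied by 14 diet-independent and 19 diet-dependent
#' loci.
#'
#' @param profiles Named list of profile data frames (`age`, `estimate`,
#'   `se`), one per test.
#' @param tier `"independent"` or `"dependent"`.
#' @return Data frame: `id`, `aleph`, `p_value`, `significant`, `tier`;
#'   attribute `n_tests` and `cutoff`.
#' @export
nonlinearity_sweep <- function(profiles, tier = c("independent", "dependent")) {
  tier <- match.arg(tier)
  cutoff <- if (tier == "independent") 1e-4 else 1e-5
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    res <- tryCatch(nonlinearity_test(profiles[[i]]), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(id = ids[i], aleph = NA_real_, p_value = NA_real_,
                        significant = NA, tier = tier))
    }
    data.frame(id = ids[i], aleph = res$aleph, p_value = res$p_value,
               significant = res$p_value < cutoff, tier = tier)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- nrow(out)
  attr(out, "cutoff") <- cutoff
  out
}
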