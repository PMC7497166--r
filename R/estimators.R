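#' @title Causal-effect estimators for two-sample MR
#' @description Constructors and methods around the `mr_estimate` container:
#'   a method-tagged causal estimate with standard error, 95% Wald interval,
#'   p-value, SNP count and dispersion diagnostics.
#' @name mr_estimate
NULL

new_mr_estimate <- function(method, beta, se, n_snp, dispersion = NA_real_,
                            cochran_q = NA_real_, df = NULL) {
  if (is.na(se)) {
    ci_low <- ci_high <- pvalue <- NA_real_
  } else {
    stopifnot(se > 0)
    ci_low <- beta - Z95 * se
    ci_high <- beta + Z95 * se
    pvalue <- if (is.null(df)) {
      2 * stats::pnorm(-abs(beta / se))
    } else {
      2 * stats::pt(-abs(beta / se), df = df)
    }
    pvalue <- max(pvalue, .Machine$double.xmin)
  }
  structure(list(method = method, beta = beta, se = se, ci_low = ci_low,
                 ci_high = ci_high, pvalue = pvalue, n_snp = n_snp,
                 dispersion = dispersion, cochran_q = cochran_q),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x)
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  OR = %.2f (%.2f-%.2f)", or$or, or$ci_low, or$ci_high))
  if (!is.na(x$dispersion)) cat(sprintf(", dispersion phi = %.3f", x$dispersion))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x)
  data.frame(risk_factor = attr(x, "risk_factor") %||% NA_character_,
             endpoint = attr(x, "endpoint") %||% NA_character_,
             method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, or = or$or,
             ci_low_or = or$ci_low, ci_high_or = or$ci_high,
             pvalue = x$pvalue, dispersion = x$dispersion,
             cochran_q = x$cochran_q, stringsAsFactors = FALSE)
}

#' Wald ratio estimator for a single-SNP instrument
#'
#' The causal estimate is `beta_outcome / beta_exposure`; its standard error
#' is the first-order delta-method approximation
#' `sqrt(se_out^2/bx^2 + by^2 se_exp^2/bx^4)` (no covariance term: the two
#' samples are independent).
#'
#' @param hset A `harmonised_set` with exactly one SNP.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
mr_wald_ratio <- function(hset) {
  stopifnot(nrow(hset) == 1)
  bx <- hset$beta_exposure
  by <- hset$beta_outcome
  if (bx == 0) stop("degenerate-instrument error: beta_exposure is zero")
  beta <- by / bx
  se <- sqrt(hset$se_outcome^2 / bx^2 +
               by^2 * hset$se_exposure^2 / bx^4)
  new_mr_estimate("wald", beta, se, n_snp = 1, dispersion = 1)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_outcome^2`. The fixed-effect standard error is
#' `1/sqrt(sum w bx^2)`. Under `"multiplicative_random"` effects it is
#' multiplied by `phi = max(1, sqrt(RSS_w/(k-1)))` — underdispersion is
#' floored at a residual standard error of 1. Cochran's Q (the weighted
#' residual sum of squares about the fitted slope) is reported. A
#' single-SNP set delegates to [mr_wald_ratio()].
#'
#' @param hset A `harmonised_set`.
#' @param effects `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw_re"` or `"ivw_fe"`; the
#'   `dispersion` field records phi.
#' @export
mr_ivw <- function(hset, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  k <- nrow(hset)
  if (k < 1) stop("input error: empty harmonised set")
  if (k == 1) return(mr_wald_ratio(hset))
  bx <- hset$beta_exposure
  by <- hset$beta_outcome
  w <- 1 / hset$se_outcome^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  phi <- if (effects == "multiplicative_random") {
    max(1, sqrt(q / (k - 1)))
  } else 1
  new_mr_estimate(if (effects == "fixed") "ivw_fe" else "ivw_re",
                  beta, phi * se_fixed, n_snp = k, dispersion = phi,
                  cochran_q = q)
}

#' Correlation-adjusted IVW estimator
#'
#' Generalised weighted regression through the origin with covariance
#' `Omega[i,j] = se_out[i] se_out[j] r[i,j]`, for instruments built from
#' correlated (e.g. weakly-correlated cis) variants. The same
#' multiplicative random-effects scaling with the underdispersion floor as
#' [mr_ivw()] applies. When `Omega` is not positive definite, a ridge of
#' `ridge * mean(diag(Omega))` is added (escalating tenfold as needed); a
#' condition number above `1e12` after the maximum ridge is an error.
#'
#' @param hset A `harmonised_set` whose `ld` attribute holds the signed
#'   correlation matrix of the instrument SNPs.
#' @param effects `"multiplicative_random"` or `"fixed"`.
#' @param ridge Initial relative ridge (default `1e-8`).
#' @return An `mr_estimate` with method `"ivw_corr"`.
#' @export
mr_ivw_correlated <- function(hset,
                              effects = c("multiplicative_random", "fixed"),
                              ridge = 1e-8) {
  effects <- match.arg(effects)
  k <- nrow(hset)
  if (k < 2) stop("input error: need >= 2 SNPs (use mr_wald_ratio for 1)")
  r <- attr(hset, "ld")
  if (is.null(r)) stop("input error: harmonised set carries no LD matrix")
  bx <- hset$beta_exposure
  by <- hset$beta_outcome
  omega <- outer(hset$se_outcome, hset$se_outcome) * r
  scale <- mean(diag(omega))
  ch <- NULL
  for (eps in c(0, ridge * 10^(0:7))) {
    ch <- tryCatch(chol(omega + diag(eps * scale, k)), error = function(e) NULL)
    if (!is.null(ch) && kappa(ch)^2 < 1e12) break
    ch <- NULL
  }
  if (is.null(ch)) {
    stop("conditioning error: Omega not positive definite within ridge budget")
  }
  oinv_x <- backsolve(ch, forwardsolve(t(ch), bx))
  oinv_y <- backsolve(ch, forwardsolve(t(ch), by))
  xox <- sum(bx * oinv_x)
  beta <- sum(bx * oinv_y) / xox
  se_fixed <- sqrt(1 / xox)
  resid <- by - beta * bx
  q <- sum(resid * backsolve(ch, forwardsolve(t(ch), resid)))
  phi <- if (effects == "multiplicative_random") {
    max(1, sqrt(q / (k - 1)))
  } else 1
  new_mr_estimate("ivw_corr", beta, phi * se_fixed, n_snp = k,
                  dispersion = phi, cochran_q = q)
}

#' MR-Egger regression with intercept test
#'
#' Each SNP is oriented so its exposure beta is non-negative, then outcome
#' betas are regressed on exposure betas with a free intercept and weights
#' `1/se_outcome^2`. The intercept is the formal test for directional
#' pleiotropy; the slope is the pleiotropy-corrected causal estimate (valid
#' under the InSIDE assumption). Standard errors use the multiplicative
#' scale `phi = max(1, sqrt(RSS_w/(k-2)))`; p-values use a t reference with
#' `k - 2` degrees of freedom.
#'
#' @param hset A `harmonised_set` with at least 3 independent SNPs.
#' @return An `mr_egger` object: `slope` (an `mr_estimate`, method
#'   `"egger_slope"`) and `intercept` (`estimate`, `se`, `pvalue`).
#' @export
mr_egger <- function(hset) {
  k <- nrow(hset)
  if (k < 3) stop("input error: MR-Egger needs >= 3 SNPs")
  s <- sign(hset$beta_exposure)
  s[s == 0] <- 1
  bx <- hset$beta_exposure * s
  by <- hset$beta_outcome * s
  w <- 1 / hset$se_outcome^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, X * w)
  xtwy <- crossprod(X, w * by)
  coefs <- drop(solve(xtwx, xtwy))
  resid <- by - drop(X %*% coefs)
  rss_w <- sum(w * resid^2)
  sigma <- sqrt(rss_w / (k - 2))
  phi <- max(1, sigma)
  se_u <- sqrt(diag(solve(xtwx)))
  slope <- new_mr_estimate("egger_slope", unname(coefs["slope"]),
                           unname(phi * se_u["slope"]), n_snp = k,
                           dispersion = phi, cochran_q = rss_w, df = k - 2)
  # the intercept is a pure significance test for directional pleiotropy:
  # it uses the standard weighted-regression t-test (residual scale sigma,
  # no underdispersion floor), which holds its nominal size exactly
  se_icpt <- unname(sigma * se_u["intercept"])
  icpt_p <- 2 * stats::pt(-abs(unname(coefs["intercept"]) / se_icpt),
                          df = k - 2)
  structure(list(slope = slope,
                 intercept = list(estimate = unname(coefs["intercept"]),
                                  se = se_icpt, pvalue = icpt_p)),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

# point estimate of the weighted median of per-SNP ratio estimates
weighted_median_point <- function(bx, by, sex, sey) {
  ratio <- by / bx
  var_r <- sey^2 / bx^2 + by^2 * sex^2 / bx^4
  w <- 1 / var_r
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(ratio[1])
  if (0.5 >= s[length(s)]) return(ratio[length(s)])
  stats::approx(s, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Orders per-SNP ratio estimates and interpolates the inverse-variance
#' weighted median: with normalised weights `w_i` sorted by ratio, the
#' estimate is the linear interpolation of the ratios at the point where
#' the cumulative midpoint weight `s_i = sum_(j<i) w_j + w_i/2` crosses
#' 0.5. Consistent when at least half of the instrument weight comes from
#' valid variants. The standard error is the standard deviation of the
#' estimator over `n_boot` parametric bootstrap resamples (normal
#' perturbation of both betas).
#'
#' @param hset A `harmonised_set` with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000); `0` skips the
#'   bootstrap and returns `NA` standard error/CI/p (point estimate only).
#' @param seed Seed for the bootstrap stream.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1) {
  k <- nrow(hset)
  if (k < 3) stop("input error: weighted median needs >= 3 SNPs")
  bx <- hset$beta_exposure
  by <- hset$beta_outcome
  sex <- hset$se_exposure
  sey <- hset$se_outcome
  est <- weighted_median_point(bx, by, sex, sey)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        weighted_median_point(stats::rnorm(k, bx, sex), stats::rnorm(k, by, sey),
                              sex, sey)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  new_mr_estimate("weighted_median", est, se, n_snp = k)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect by random-effects IVW on every
#' `(k-1)`-SNP subset, in input order, to expose single influential SNPs.
#'
#' @param hset A `harmonised_set` with at least 3 SNPs.
#' @return A data.frame with one row per left-out SNP:
#'   `(snp_left_out, beta, se, ci_low, ci_high, pvalue)`.
#' @export
mr_leave_one_out <- function(hset) {
  k <- nrow(hset)
  if (k < 3) stop("input error: leave-one-out needs >= 3 SNPs")
  rows <- lapply(seq_len(k), function(i) {
    e <- mr_ivw(hset_subset(hset, setdiff(seq_len(k), i)))
    data.frame(snp_left_out = hset$snp[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Instrument-strength statistics
#'
#' `F = R2 (n - k - 1) / (k (1 - R2))` for an instrument of `k` SNPs
#' explaining a proportion `R2` of exposure variance in a GWAS of `n`
#' participants. An F-statistic below ~10 conventionally signals weak
#' instruments.
#'
#' @param r2 Proportion of variance explained, in `[0, 1)`.
#' @param n Exposure GWAS sample size (`n > k + 1`).
#' @param k Number of SNPs in the instrument.
#' @return A `strength_stats` list `(r2, f_stat, n, k)`.
#' @export
#' @examples
#' instrument_strength(0.012, 3301, 1) # F ~ 40.1
instrument_strength <- function(r2, n, k) {
  if (r2 < 0 || r2 >= 1) stop("domain error: r2 must be in [0, 1)")
  if (k < 1) stop("domain error: k must be >= 1")
  if (n <= k + 1) stop("domain error: need n > k + 1")
  f <- r2 * (n - k - 1) / (k * (1 - r2))
  structure(list(r2 = r2, f_stat = f, n = n, k = k),
            class = "strength_stats")
}

#' Variance explained from summary statistics
#'
#' For independent SNPs instrumenting an exposure in SD units,
#' `R2 = sum 2 eaf_i (1 - eaf_i) beta_i^2`.
#'
#' @param records A `sumstats` data.frame (or `harmonised_set`, using the
#'   exposure side) with `eaf` present.
#' @return The proportion of variance explained.
#' @export
r2_from_sumstats <- function(records) {
  eaf <- records$eaf
  beta <- if (!is.null(records$beta)) records$beta else records$beta_exposure
  if (anyNA(eaf)) stop("cannot-compute error: eaf missing for some SNPs")
  if (is.null(beta) || anyNA(beta)) stop("cannot-compute error: beta missing")
  sum(2 * eaf * (1 - eaf) * beta^2)
}

#' Convert a log-odds estimate to an odds-ratio scale
#'
#' @param estimate An `mr_estimate` whose beta is on the log-odds scale.
#' @return A list `(or, ci_low, ci_high)` with `OR = exp(beta)` and the 95%
#'   CI `exp(beta +/- 1.96 se)`.
#' @export
to_odds_ratio <- function(estimate) {
  list(or = exp(estimate$beta), ci_low = exp(estimate$ci_low),
       ci_high = exp(estimate$ci_high))
}
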