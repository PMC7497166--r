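#' Priors for colocalisation
#'
#' Per-SNP prior probabilities that a variant is causal for trait 1 only
#' (`p1`), trait 2 only (`p2`), or both (`p12`). Defaults are the
#' field-standard `1e-4 / 1e-4 / 1e-5`.
#'
#' @param p1,p2,p12 Per-SNP priors.
#' @return A `coloc_priors` object.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0)
  if (p12 > min(p1, p2)) {
    stop("domain error: p12 must not exceed min(p1, p2)")
  }
  if (p1 + p2 + p12 >= 1) stop("domain error: priors must sum below 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a normal
#' effect prior of scale `prior_sd`: with `z = beta/se`, `V = se^2`,
#' `W = prior_sd^2` and shrinkage factor `W/(V+W)` (call it rho),
#' `log ABF = 0.5 log(1 - rho) + z^2 rho / 2`. This is the log Bayes factor for
#' association versus no association at a single variant.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), positive.
#' @param prior_sd Prior standard deviation of the true effect.
#' @return Log approximate Bayes factor(s), vectorised.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("domain error: se must be > 0")
  if (any(prior_sd <= 0)) stop("domain error: prior_sd must be > 0")
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

default_prior_sd <- function(trait_type) {
  if (identical(trait_type, "case_control")) 0.2 else 0.15
}

#' Posterior probabilities of colocalisation hypotheses
#'
#' Under the assumption of at most one causal variant per trait in the
#' region, computes posterior probabilities of the five configurations:
#' H0 neither trait associated; H1/H2 only trait 1/2 associated; H3 both
#' associated through distinct causal variants; H4 both associated sharing
#' a single causal variant. Per-SNP Wakefield log ABFs are combined in log
#' space (log-sum-exp throughout; raw Bayes factors are never exponentiated
#' unnormalised).
#'
#' @param region1,region2 `region_data` tables (see [extract_region()]);
#'   SNPs are intersected by id.
#' @param priors A [coloc_priors()] object.
#' @param prior_sd1,prior_sd2 Effect prior scales; default 0.15 for
#'   quantitative traits and 0.20 for case-control (log-odds) traits,
#'   resolved from each region's `trait_type` attribute.
#' @return A `coloc_result`: `pp` (named `pp0`..`pp4`, summing to 1 within
#'   1e-10), `n_snps`, `priors`, `prior_sd`, `window`, `snps`.
#' @export
coloc_posteriors <- function(region1, region2, priors = coloc_priors(),
                             prior_sd1 = NULL, prior_sd2 = NULL) {
  ids <- intersect(region1$snp, region2$snp)
  if (length(ids) == 0) {
    stop("no-overlap error: regions share no SNP ids")
  }
  i1 <- match(ids, region1$snp)
  i2 <- match(ids, region2$snp)
  sd1 <- prior_sd1 %||% default_prior_sd(attr(region1, "trait_type"))
  sd2 <- prior_sd2 %||% default_prior_sd(attr(region2, "trait_type"))
  l1 <- wakefield_log_abf(region1$beta[i1], region1$se[i1], sd1)
  l2 <- wakefield_log_abf(region2$beta[i2], region2$se[i2], sd2)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(priors$p1) + lsum1,
          h2 = log(priors$p2) + lsum2,
          h3 = log(priors$p1) + log(priors$p2) +
            logdiff(lsum1 + lsum2, lsum12),
          h4 = log(priors$p12) + lsum12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("pp", 0:4)
  structure(list(pp = pp, n_snps = length(ids), priors = priors,
                 prior_sd = c(trait1 = sd1, trait2 = sd2),
                 window = attr(region1, "window"), snps = ids),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation over %d shared SNPs\n", x$n_snps))
  cat(sprintf("  PP(H%d) = %.4f\n", 0:4, x$pp), sep = "")
  best <- which.max(x$pp) - 1
  if (max(x$pp) >= 0.80) {
    cat(sprintf("  H%d supported (PP >= 0.80)\n", best))
  } else {
    cat("  no hypothesis reaches PP >= 0.80\n")
  }
  invisible(x)
}

#' Regional association profile for Manhattan plotting
#'
#' One row per SNP, sorted by position, with `-log10(p)` taken from the
#' stored p-value or, when absent, derived from the normal z-statistic
#' `beta/se` (numerically stable for very large z).
#'
#' @param region A `region_data` table.
#' @return A data.frame `(snp, pos, neglog10_p)` sorted by position.
#' @export
regional_plot_data <- function(region) {
  nl <- ifelse(!is.na(region$pvalue), -log10(region$pvalue),
               neglog10p_from_z(region$beta / region$se))
  out <- data.frame(snp = region$snp, pos = region$pos, neglog10_p = nl,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag secondary association peaks in a region
#'
#' The single-causal-variant assumption behind [coloc_posteriors()] is
#' suspect when a region carries a second, weakly linked peak. Any SNP
#' whose `-log10(p)` is within 2 of the lead SNP's but whose r-squared with
#' the lead is below `r2_threshold` is reported.
#'
#' @param region A `region_data` table.
#' @param ld Optional signed LD matrix over the region's SNPs; without it
#'   the r-squared filter cannot be applied and an empty result is
#'   returned.
#' @param r2_threshold Linkage ceiling defining "independent" (default 0.1).
#' @return Character vector of suspect SNP ids (possibly empty).
#' @export
check_single_causal <- function(region, ld = NULL, r2_threshold = 0.1) {
  if (is.null(ld)) return(character(0))
  pd <- regional_plot_data(region)
  lead <- pd$snp[which.max(pd$neglog10_p)]
  near_top <- pd$snp[pd$neglog10_p >= max(pd$neglog10_p) - 2]
  near_top <- setdiff(near_top, lead)
  keep <- intersect(near_top, rownames(ld))
  keep[ld[keep, lead]^2 < r2_threshold]
}
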