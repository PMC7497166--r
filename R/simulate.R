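#' Configuration for the two-sample summary-statistics simulator
#'
#' Summary statistics are simulated directly from their asymptotic sampling
#' distributions: per-SNP marginal effect estimates are normal around the
#' LD-projected true effects with standard errors determined by allele
#' frequency and sample size. This is orders of magnitude faster than
#' genotype-level simulation and sufficient for validating summary-level
#' estimators.
#'
#' @param seed Master seed; every downstream draw is derived from it.
#' @param m_snps Number of SNPs.
#' @param maf Minor-allele frequencies in (0, 0.5]; scalar, vector of
#'   length `m_snps`, or `NULL` to draw uniformly on (0.1, 0.5).
#' @param ld_rho AR(1) correlation per grid step in `[0, 1)`; 0 gives
#'   independent SNPs.
#' @param n_exposure,n_outcome Sample sizes of the two (independent) GWAS.
#' @param causal_effect True effect of the exposure on the outcome.
#' @param pleiotropy `list(type = "none"|"balanced"|"directional",
#'   mean =, sd =)` for direct SNP-outcome effects on invalid SNPs.
#' @param invalid_fraction Proportion of SNPs given pleiotropic effects.
#' @param exposure_h2 Exposure variance explained by the instrument SNPs.
#' @param outcome_trait_type `"case_control"` (log-odds betas) or
#'   `"quantitative"`.
#' @param case_fraction Case fraction for a case-control outcome.
#' @param grid_bp Base-pair spacing of the SNP grid (default 5 kb).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1, m_snps = 20, maf = NULL, ld_rho = 0,
                       n_exposure = 1e5, n_outcome = 1e5, causal_effect = 0,
                       pleiotropy = list(type = "none", mean = 0, sd = 0),
                       invalid_fraction = 0, exposure_h2 = 0.05,
                       outcome_trait_type = c("case_control", "quantitative"),
                       case_fraction = 0.5, grid_bp = 5000) {
  outcome_trait_type <- match.arg(outcome_trait_type)
  stopifnot(m_snps >= 1, ld_rho >= 0, ld_rho < 1,
            n_exposure > 0, n_outcome > 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            exposure_h2 > 0, exposure_h2 < 1,
            case_fraction > 0, case_fraction < 1)
  if (!is.null(maf)) {
    stopifnot(all(maf > 0), all(maf <= 0.5),
              length(maf) %in% c(1, m_snps))
    if (length(maf) == 1) maf <- rep(maf, m_snps)
  }
  pleiotropy$type <- match.arg(pleiotropy$type %||% "none",
                               c("none", "balanced", "directional"))
  structure(list(seed = seed, m_snps = m_snps, maf = maf, ld_rho = ld_rho,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 causal_effect = causal_effect, pleiotropy = pleiotropy,
                 invalid_fraction = invalid_fraction,
                 exposure_h2 = exposure_h2,
                 outcome_trait_type = outcome_trait_type,
                 case_fraction = case_fraction, grid_bp = grid_bp),
            class = "sim_config")
}

# AR(1) correlation matrix rho^|i-j|
ar1_corr <- function(m, rho) {
  if (rho == 0) return(diag(m))
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

# analytic standard error of a marginal per-allele GWAS effect
marginal_se <- function(maf, n, trait_type = "quantitative",
                        case_fraction = 0.5) {
  phi <- if (trait_type == "case_control") {
    case_fraction * (1 - case_fraction)
  } else 1
  1 / sqrt(2 * maf * (1 - maf) * n * phi)
}

# non-palindromic ordered allele pairs
ALLELE_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)

# correlated effect-estimate noise: one draw from N(0, R) given chol(R)
corr_noise <- function(chol_r) {
  drop(crossprod(chol_r, stats::rnorm(nrow(chol_r))))
}

# shared core: one exposure GWAS plus one or more outcome GWAS over the
# same SNPs, with joint (per-SNP causal) effect vectors projected through LD
simulate_pair_core <- function(seed, chrom, positions, maf, R, bx_joint,
                               by_joint_list, n_exposure, outcome_specs,
                               trait_id_x, snp_prefix = "snp") {
  m <- length(positions)
  chol_r <- chol(R)
  with_seed(seed, {
    pair_idx <- sample(nrow(ALLELE_PAIRS), m, replace = TRUE)
    ea <- ALLELE_PAIRS[pair_idx, 1]
    oa <- ALLELE_PAIRS[pair_idx, 2]
    snp <- sprintf("%s_%s_%04d", snp_prefix, chrom, seq_len(m))
    se_x <- marginal_se(maf, n_exposure)
    bx_marg <- drop(R %*% bx_joint)
    bx_hat <- bx_marg + se_x * corr_noise(chol_r)
    zx <- bx_hat / se_x
    exposure <- sumstats(snp, chrom, positions, ea, oa, bx_hat, se_x,
                         pmax(2 * stats::pnorm(-abs(zx)), 1e-300),
                         n_exposure, eaf = maf, trait_id = trait_id_x,
                         trait_type = "quantitative", unit_note = "SD")
    outcomes <- lapply(outcome_specs, function(os) {
      by_joint <- by_joint_list[[os$name]]
      se_y <- marginal_se(maf, os$n, os$trait_type, os$case_fraction)
      by_marg <- drop(R %*% by_joint)
      by_hat <- by_marg + se_y * corr_noise(chol_r)
      zy <- by_hat / se_y
      sumstats(snp, chrom, positions, ea, oa, by_hat, se_y,
               pmax(2 * stats::pnorm(-abs(zy)), 1e-300), os$n,
               eaf = maf, trait_id = os$name,
               trait_type = os$trait_type,
               unit_note = if (os$trait_type == "case_control")
                 "natural-log odds" else "SD")
    })
    names(outcomes) <- vapply(outcome_specs, `[[`, "", "name")
    ld <- R
    dimnames(ld) <- list(snp, snp)
    list(exposure = exposure, outcomes = outcomes, ld = ld, snp = snp,
         se_x = se_x)
  })
}

#' Simulate a two-sample GWAS with known ground truth
#'
#' Draws per-SNP exposure effects scaled so the instrument explains
#' `exposure_h2` of exposure variance, generates marginal summary
#' statistics in two independent samples from the asymptotic sampling
#' distribution, and sets true outcome effects to
#' `causal_effect * beta_exposure + pleiotropy`. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list `exposure` (sumstats), `outcome` (sumstats), `ld`
#'   (signed correlation matrix) and `truth` (generating parameters:
#'   causal effect, per-SNP true effects and pleiotropy, maf).
#' @export
simulate_two_sample_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_snps
  pre <- with_seed(derive_seed(config$seed, "layout"), {
    maf <- config$maf %||% stats::runif(m, 0.1, 0.5)
    b_raw <- stats::rnorm(m)
    scale <- sqrt(config$exposure_h2 / sum(2 * maf * (1 - maf) * b_raw^2))
    bx <- b_raw * scale
    n_invalid <- round(config$invalid_fraction * m)
    invalid <- if (n_invalid > 0) sample(m, n_invalid) else integer(0)
    alpha <- numeric(m)
    pl <- config$pleiotropy
    if (length(invalid) > 0 && pl$type != "none") {
      if (pl$type == "directional") {
        # directional pleiotropy acts relative to the exposure-increasing
        # allele: its mean is carried by the orientation of each SNP's
        # exposure effect, so it does not cancel across effect signs
        alpha[invalid] <- sign(bx[invalid]) *
          stats::rnorm(length(invalid), pl$mean, pl$sd)
      } else {
        alpha[invalid] <- stats::rnorm(length(invalid), 0, pl$sd)
      }
    }
    list(maf = maf, bx = bx, alpha = alpha, invalid = invalid)
  })
  by <- config$causal_effect * pre$bx + pre$alpha
  R <- ar1_corr(m, config$ld_rho)
  core <- simulate_pair_core(
    seed = derive_seed(config$seed, "draw"),
    chrom = "1", positions = 1e6 + (seq_len(m) - 1) * config$grid_bp,
    maf = pre$maf, R = R, bx_joint = pre$bx,
    by_joint_list = list(outcome = by), n_exposure = config$n_exposure,
    outcome_specs = list(list(name = "outcome", n = config$n_outcome,
                              trait_type = config$outcome_trait_type,
                              case_fraction = config$case_fraction)),
    trait_id_x = "exposure")
  truth <- list(causal_effect = config$causal_effect, beta_exposure = pre$bx,
                pleiotropy = pre$alpha, invalid_snps = core$snp[pre$invalid],
                maf = pre$maf, snp = core$snp)
  list(exposure = core$exposure, outcome = core$outcomes$outcome,
       ld = core$ld, truth = truth)
}

#' Simulate a pair of regional association profiles for colocalisation
#'
#' Builds an AR(1) LD field over evenly spaced positions and plants one
#' causal variant per trait — the same variant iff `shared` — propagating
#' z-score profiles through LD. Both regions share all SNP ids.
#'
#' @param config A [sim_config()]; `m_snps`, `maf`, `ld_rho`, `grid_bp`,
#'   sample sizes and the outcome trait type are used.
#' @param shared Logical: do the two traits share the causal variant?
#' @param separation_bp Distance between the two causal variants when
#'   `shared = FALSE`; must be a multiple of `grid_bp` and fit in the region.
#' @param z1,z2 True z-statistics at each trait's causal variant (0 gives a
#'   null region for that trait).
#' @return A list `region1`, `region2` (`region_data`), `ld`, and `truth`
#'   (shared flag, causal positions, r-squared between the causal variants).
#' @export
simulate_coloc_region <- function(config, shared, separation_bp = 80000,
                                  z1 = 8, z2 = 8) {
  stopifnot(inherits(config, "sim_config"), config$m_snps >= 10)
  m <- config$m_snps
  steps <- separation_bp / config$grid_bp
  if (steps != round(steps)) {
    stop("config error: separation_bp must be a multiple of grid_bp")
  }
  c1 <- ceiling(m / 2)
  c2 <- if (shared) c1 else c1 + as.integer(steps)
  if (c2 > m) stop("config error: separation exceeds the region span")
  R <- ar1_corr(m, config$ld_rho)
  positions <- 5e7 + (seq_len(m) - 1) * config$grid_bp
  maf <- with_seed(derive_seed(config$seed, "coloc-maf"),
                   config$maf %||% stats::runif(m, 0.1, 0.5))
  se_x <- marginal_se(maf, config$n_exposure)
  se_y <- marginal_se(maf, config$n_outcome, config$outcome_trait_type,
                      config$case_fraction)
  # express the causal signals as joint effects so the core projects them
  bx_joint <- numeric(m)
  bx_joint[c1] <- z1 * se_x[c1]
  by_joint <- numeric(m)
  by_joint[c2] <- z2 * se_y[c2]
  core <- simulate_pair_core(
    seed = derive_seed(config$seed, "coloc-draw"),
    chrom = "1", positions = positions, maf = maf, R = R,
    bx_joint = bx_joint, by_joint_list = list(outcome = by_joint),
    n_exposure = config$n_exposure,
    outcome_specs = list(list(name = "outcome", n = config$n_outcome,
                              trait_type = config$outcome_trait_type,
                              case_fraction = config$case_fraction)),
    trait_id_x = "trait1", snp_prefix = "rsim")
  region1 <- extract_region(core$exposure, core$snp[c1],
                            window_bp = diff(range(positions)))
  region2 <- extract_region(core$outcomes$outcome, core$snp[c1],
                            window_bp = diff(range(positions)))
  truth <- list(shared = shared, causal_pos_trait1 = positions[c1],
                causal_pos_trait2 = positions[c2],
                causal_snp_trait1 = core$snp[c1],
                causal_snp_trait2 = core$snp[c2],
                r2_between = R[c1, c2]^2, z1 = z1, z2 = z2)
  list(region1 = region1, region2 = region2, ld = core$ld, truth = truth)
}
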