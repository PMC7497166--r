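# Synthetic seven-factor, three-endpoint study emulating a two-sample MR
# design: circulating biomarkers instrumented from their source GWAS
# against overall and receptor-stratified breast cancer endpoints.
#
# Defaults mirror the study conditions: instrument sizes and variance
# explained per the published instrument table (8 / 45 / 1 / 3 / 1 / 3 / 1
# SNPs; R2 from 0.002 to 0.54), exposure GWAS sample sizes per the source
# studies (3,301 to 204,402), endpoint case/control counts of the breast
# cancer consortium (122,977/105,974 overall; 69,501 ER+; 21,468 ER-).

STUDY_ENDPOINTS <- list(
  list(name = "overall",     n_cases = 122977, n_controls = 105974),
  list(name = "er_positive", n_cases = 69501,  n_controls = 105974),
  list(name = "er_negative", n_cases = 21468,  n_controls = 105974))

STUDY_FACTORS <- list(
  adiponectin = list(kind = "independent", k = 8,  h2 = 0.016,  n = 30708,
                     chrom = "12"),
  crp         = list(kind = "independent", k = 45, h2 = 0.035,  n = 204402,
                     chrom = "1"),
  hgf         = list(kind = "region", m = 81, h2 = 0.012,  n = 3301,
                     chrom = "7",
                     scenario = "confounded", confound_endpoint = "er_negative",
                     confound_steps = 9, confound_z = 14),
  il6         = list(kind = "corr_cis", k = 3, r_pair = 0.3, h2 = 0.002,
                     n = 133449, chrom = "6"),
  leptin_receptor = list(kind = "region", m = 81, h2 = 0.54, n = 3301,
                         chrom = "2"),
  pai1        = list(kind = "independent", k = 3, h2 = 0.0064, n = 30395,
                     chrom = "8"),
  resistin    = list(kind = "region", m = 81, h2 = 0.03, n = 3301,
                     chrom = "19",
                     scenario = "shared_causal", theta = 0.25))

#' Simulate the full seven-factor, three-endpoint study
#'
#' Generates summary statistics, LD matrices and instrument specifications
#' for seven biomarker exposures against three case-control endpoints,
#' with known ground truth. Five factors are null. One factor
#' (`resistin`) has a true causal effect acting through a variant shared
#' with the outcome (colocalisation should support H4). One factor
#' (`hgf`) is genomically confounded for the ER-negative endpoint: the
#' exposure and outcome signals come from distinct causal variants in LD
#' (r-squared ~0.15), producing a nominal MR hit whose colocalisation
#' favours H3 over H4.
#'
#' @param seed Master seed.
#' @param grid_bp Regional SNP spacing (default 5 kb).
#' @param ld_rho AR(1) correlation per grid step in regional factors
#'   (default 0.9).
#' @return A list: `study` (an [mr_study()] ready for [run_study()]) and
#'   `truth` (per-factor generating parameters).
#' @export
simulate_study <- function(seed = 1, grid_bp = 5000, ld_rho = 0.9) {
  endpoints_meta <- lapply(STUDY_ENDPOINTS, function(e) {
    n <- e$n_cases + e$n_controls
    list(name = e$name, n = n, trait_type = "case_control",
         case_fraction = e$n_cases / n)
  })
  names(endpoints_meta) <- vapply(endpoints_meta, `[[`, "", "name")
  endpoint_tables <- stats::setNames(
    vector("list", length(endpoints_meta)), names(endpoints_meta))
  factors <- list()
  truth <- list()
  for (fname in names(STUDY_FACTORS)) {
    fc <- STUDY_FACTORS[[fname]]
    fseed <- derive_seed(seed, paste0("factor-", fname))
    if (fc$kind == "independent") {
      m <- fc$k
      R <- diag(m)
      positions <- 1e7 + (seq_len(m) - 1) * 2e6
    } else if (fc$kind == "corr_cis") {
      m <- fc$k
      R <- matrix(fc$r_pair, m, m)
      diag(R) <- 1
      positions <- 5e7 + (seq_len(m) - 1) * 5e4
    } else {
      m <- fc$m
      R <- ar1_corr(m, ld_rho)
      positions <- 5e7 + (seq_len(m) - 1) * grid_bp
    }
    layout <- with_seed(derive_seed(fseed, "layout"), {
      maf <- stats::runif(m, 0.1, 0.5)
      signs <- sample(c(-1, 1), m, replace = TRUE)
      list(maf = maf, signs = signs)
    })
    maf <- layout$maf
    bx_joint <- numeric(m)
    if (fc$kind == "region") {
      c1 <- ceiling(m / 2)
      bx_joint[c1] <- sqrt(fc$h2 / (2 * maf[c1] * (1 - maf[c1])))
      causal_snp_idx <- c1
    } else {
      per_snp_h2 <- fc$h2 / m
      bx_joint <- layout$signs * sqrt(per_snp_h2 / (2 * maf * (1 - maf)))
      causal_snp_idx <- seq_len(m)
    }
    theta <- stats::setNames(rep(0, length(endpoints_meta)),
                             names(endpoints_meta))
    if (identical(fc$scenario, "shared_causal")) theta[] <- fc$theta
    by_joint_list <- lapply(endpoints_meta, function(em) {
      by <- theta[[em$name]] * bx_joint
      if (identical(fc$scenario, "confounded") &&
          em$name == fc$confound_endpoint) {
        c2 <- ceiling(m / 2) + fc$confound_steps
        se_y_c2 <- marginal_se(maf[c2], em$n, "case_control",
                               em$case_fraction)
        by[c2] <- by[c2] + fc$confound_z * se_y_c2
      }
      by
    })
    # condition on instrument discovery: each factor's source GWAS found a
    # genome-wide-significant instrument, so redraw the rare realisation
    # in which sampling noise pushes every SNP above the threshold
    for (attempt in 1:50) {
      core <- simulate_pair_core(
        seed = derive_seed(fseed, paste0("draw-", attempt)), chrom = fc$chrom,
        positions = positions, maf = maf, R = R, bx_joint = bx_joint,
        by_joint_list = by_joint_list, n_exposure = fc$n,
        outcome_specs = unname(endpoints_meta), trait_id_x = fname,
        snp_prefix = fname)
      if (any(core$exposure$pvalue < 5e-8)) break
    }
    for (en in names(endpoint_tables)) {
      endpoint_tables[[en]] <- rbind(endpoint_tables[[en]],
                                     core$outcomes[[en]])
    }
    spec <- if (fc$kind == "independent") {
      instrument_spec("polygenic")
    } else {
      c1 <- ceiling(m / 2)
      instrument_spec("monogenic_cis",
                      r2_threshold = if (fc$kind == "corr_cis") 0.15 else 0.01,
                      gene_tss = list(chrom = fc$chrom, pos = positions[c1]))
    }
    factors[[fname]] <- list(name = fname, sumstats = core$exposure,
                             ld = core$ld, spec = spec,
                             correlated = fc$kind == "corr_cis",
                             gwas_n = fc$n)
    truth[[fname]] <- list(
      kind = fc$kind, h2 = fc$h2, gwas_n = fc$n,
      causal_effect = as.list(theta),
      scenario = fc$scenario %||% "null",
      causal_snps = core$snp[causal_snp_idx],
      confounder_snp = if (identical(fc$scenario, "confounded")) {
        core$snp[ceiling(m / 2) + fc$confound_steps]
      } else NA_character_)
  }
  endpoints <- lapply(endpoints_meta, function(em) {
    ss <- endpoint_tables[[em$name]]
    rownames(ss) <- NULL
    class(ss) <- c("sumstats", "data.frame")
    list(name = em$name, sumstats = ss)
  })
  list(study = mr_study(factors, endpoints), truth = truth)
}

#' Write a self-contained toy study to disk
#'
#' Materialises [simulate_study()] as plain-text files: one exposure
#' summary-statistics TSV and one LD TSV per risk factor, one outcome TSV
#' per endpoint, the generating truth as YAML, and a `study.yaml`
#' configuration consumable by [read_study_config()]. Re-running with the
#' same seed reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, the named list of file paths.
#' @export
make_fixture_tables <- function(out_dir, seed = 1) {
  sim <- simulate_study(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  cfg_factors <- list()
  for (f in sim$study$factors) {
    sp <- file.path(out_dir, paste0("exposure_", f$name, ".tsv"))
    lp <- file.path(out_dir, paste0("ld_", f$name, ".tsv"))
    write_sumstats(f$sumstats, sp)
    write_ld_matrix(f$ld, lp)
    paths[[paste0("exposure_", f$name)]] <- sp
    paths[[paste0("ld_", f$name)]] <- lp
    spec <- f$spec
    cfg_factors[[length(cfg_factors) + 1]] <- list(
      name = f$name, sumstats = basename(sp), ld = basename(lp),
      gwas_n = f$gwas_n, correlated = f$correlated,
      instrument = list(mode = spec$mode, p_threshold = spec$p_threshold,
                        r2_threshold = spec$r2_threshold,
                        cis_window_bp = spec$cis_window_bp,
                        gene_tss = spec$gene_tss))
  }
  cfg_endpoints <- list()
  for (e in sim$study$endpoints) {
    op <- file.path(out_dir, paste0("outcome_", e$name, ".tsv"))
    write_sumstats(e$sumstats, op)
    paths[[paste0("outcome_", e$name)]] <- op
    cfg_endpoints[[length(cfg_endpoints) + 1]] <-
      list(name = e$name, sumstats = basename(op))
  }
  tp <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(sim$truth, tp)
  paths$truth <- tp
  cfg <- list(alpha = 0.05, coloc_trigger_p = 0.05, coloc_window_bp = 1e5,
              risk_factors = cfg_factors, endpoints = cfg_endpoints)
  cp <- file.path(out_dir, "study.yaml")
  yaml::write_yaml(cfg, cp)
  paths$study_config <- cp
  invisible(paths)
}

#' Read a study configuration from YAML
#'
#' The YAML lists `risk_factors` (name, sumstats path, optional ld path,
#' gwas_n, correlated flag, instrument block) and `endpoints` (name,
#' sumstats path), plus optional `alpha`, `coloc_trigger_p`,
#' `coloc_window_bp`. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path Path to the YAML file.
#' @return An [mr_study()].
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  factors <- lapply(cfg$risk_factors, function(rf) {
    inst <- rf$instrument %||% list()
    spec <- instrument_spec(
      mode = inst$mode %||% "polygenic",
      p_threshold = inst$p_threshold %||% 5e-8,
      r2_threshold = inst$r2_threshold %||% 0.01,
      cis_window_bp = inst$cis_window_bp %||% 1e6,
      gene_tss = inst$gene_tss)
    ss <- read_sumstats(resolve(rf$sumstats), trait_id = rf$name)
    ld <- if (!is.null(rf$ld)) read_ld_matrix(resolve(rf$ld), ss$snp) else NULL
    list(name = rf$name, sumstats = ss, ld = ld, spec = spec,
         correlated = isTRUE(rf$correlated), gwas_n = rf$gwas_n)
  })
  names(factors) <- vapply(factors, `[[`, "", "name")
  endpoints <- lapply(cfg$endpoints, function(ep) {
    list(name = ep$name,
         sumstats = read_sumstats(resolve(ep$sumstats), trait_id = ep$name,
                                  trait_type = "case_control"))
  })
  names(endpoints) <- vapply(endpoints, `[[`, "", "name")
  mr_study(factors, endpoints, alpha = cfg$alpha %||% 0.05,
           coloc_trigger_p = cfg$coloc_trigger_p %||% 0.05,
           coloc_window_bp = cfg$coloc_window_bp %||% 1e5)
}
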