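region_from <- function(beta, se, pos = seq_along(beta) * 1000,
                        trait_type = "quantitative", pvalue = NA_real_) {
  structure(data.frame(snp = paste0("rs", seq_along(beta)), pos = pos,
                       beta = beta, se = se, n = 1e4, eaf = 0.3,
                       pvalue = pvalue, stringsAsFactors = FALSE),
            class = c("region_data", "data.frame"),
            window = list(chrom = "1", start = min(pos), end = max(pos)),
            index_snp = "rs1", trait_id = "t", trait_type = trait_type)
}

test_that("Wakefield log ABF matches its closed form and limits", {
  # null z: evidence against association, equal to half log(1 - r)
  la <- wakefield_log_abf(0, 0.1, 0.15)
  r <- 0.15^2 / (0.1^2 + 0.15^2)
  expect_equal(la, 0.5 * log(1 - r))
  expect_lt(la, 0)

  # uninformative limit V >> W
  expect_equal(wakefield_log_abf(0.001, 10, 0.15), 0, tolerance = 1e-3)

  # quadrature oracle
  expect_equal(wakefield_log_abf(0.5, 0.05, 0.15),
               abf_quadrature_oracle(0.5, 0.05, 0.15), tolerance = 1e-6)

  expect_error(wakefield_log_abf(0.1, 0, 0.15), "domain error")
})

test_that("posteriors sum to one and respect ordering and priors", {
  set.seed(8)
  for (i in 1:10) {
    m <- sample(5:50, 1)
    r1 <- region_from(stats::rnorm(m, 0, 0.05), stats::runif(m, 0.01, 0.05))
    r2 <- region_from(stats::rnorm(m, 0, 0.05), stats::runif(m, 0.01, 0.05))
    cc <- coloc_posteriors(r1, r2)
    expect_equal(sum(cc$pp), 1, tolerance = 1e-10)
    expect_true(all(cc$pp >= 0 & cc$pp <= 1))
    # SNP-order invariance
    perm <- sample(m)
    cc2 <- coloc_posteriors(r1[perm, ], r2)
    expect_equal(unname(cc$pp), unname(cc2$pp), tolerance = 1e-12)
  }

  # pp4 -> 0 monotonically as p12 -> 0 (moderate shared signal, z = 3)
  r1 <- region_from(c(0.15, 0.01, 0.02), 0.05)
  r2 <- region_from(c(0.16, 0.02, 0.01), 0.05)
  pp4s <- vapply(c(1e-5, 1e-7, 1e-9, 1e-12), function(p12) {
    coloc_posteriors(r1, r2, coloc_priors(p12 = p12))$pp[["pp4"]]
  }, 0)
  expect_true(all(diff(pp4s) < 0))
  expect_lt(pp4s[4], 1e-6)

  other <- region_from(0.1, 0.05)
  other$snp <- "zz1"
  expect_error(coloc_posteriors(r1, other), "no-overlap")
})

test_that("posteriors equal the exhaustive configuration enumeration", {
  set.seed(17)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    b1 <- stats::rnorm(m, 0, 0.1)
    b2 <- stats::rnorm(m, 0, 0.1)
    s1 <- stats::runif(m, 0.05, 0.08)
    s2 <- stats::runif(m, 0.05, 0.08)
    r1 <- region_from(b1, s1)
    r2 <- region_from(b2, s2, trait_type = "case_control")
    pr <- coloc_priors()
    cc <- coloc_posteriors(r1, r2, pr)
    oracle <- coloc_enum_oracle(wakefield_log_abf(b1, s1, 0.15),
                                wakefield_log_abf(b2, s2, 0.20),
                                pr$p1, pr$p2, pr$p12)
    expect_equal(unname(cc$pp), oracle, tolerance = 1e-9)
  }
})

test_that("single-draw scenarios support the expected hypothesis", {
  cfg <- sim_config(seed = 3, m_snps = 81, ld_rho = 0.9)
  shared <- simulate_coloc_region(cfg, shared = TRUE)
  expect_gt(coloc_posteriors(shared$region1, shared$region2)$pp[["pp4"]], 0.8)

  distinct <- simulate_coloc_region(cfg, shared = FALSE, separation_bp = 8e4)
  expect_lt(distinct$truth$r2_between, 0.05)
  expect_gt(coloc_posteriors(distinct$region1, distinct$region2)$pp[["pp3"]],
            0.8)

  null <- simulate_coloc_region(cfg, shared = TRUE, z1 = 0, z2 = 0)
  expect_gt(coloc_posteriors(null$region1, null$region2)$pp[["pp0"]], 0.8)
})

test_that("regional plot data computes -log10 p and sorts by position", {
  r <- region_from(c(0.1, 0.2), 0.05, pos = c(2000, 1000),
                   pvalue = c(1, 1e-8))
  pd <- regional_plot_data(r)
  expect_equal(pd$pos, c(1000, 2000))
  expect_equal(pd$neglog10_p[pd$pos == 2000], 0)
  expect_equal(pd$neglog10_p[pd$pos == 1000], 8)
  expect_equal(nrow(pd), nrow(r))

  # derived from z when p is absent, stable at extreme z
  rz <- region_from(c(0.5, 5), c(0.05, 0.05))
  pdz <- regional_plot_data(rz)
  expect_equal(pdz$neglog10_p[1],
               -log10(2 * stats::pnorm(-10)), tolerance = 1e-9)
  expect_gt(pdz$neglog10_p[2], 300)  # z = 100 would underflow a naive p
})

test_that("secondary peaks violating the one-causal-variant assumption flag", {
  sim <- simulate_coloc_region(sim_config(seed = 13, m_snps = 81,
                                          ld_rho = 0.9),
                               shared = FALSE, separation_bp = 1e5)
  # craft a region with two equal, weakly linked peaks (noise-free)
  R <- unname(sim$ld)
  z <- 8 * R[, 41] + 8 * R[, 61]  # r2 between peaks = 0.9^40 < 0.1
  both <- sim$region1
  both$se <- 0.01
  both$beta <- 0.01 * z
  both$pvalue <- NA_real_
  flagged <- check_single_causal(both, sim$ld)
  expect_true(any(c(sim$region1$snp[41], sim$region1$snp[61]) %in% flagged))
  expect_identical(check_single_causal(both, NULL), character(0))
})
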