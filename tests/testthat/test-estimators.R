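test_that("Wald ratio and its delta-method standard error are correct", {
  h <- harmonised_set(0.5, 1e-12, 0.1, 0.05)
  e <- mr_wald_ratio(h)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1, tolerance = 1e-9)  # first term only

  h0 <- harmonised_set(0.5, 0.05, 0, 0.05)
  expect_equal(mr_wald_ratio(h0)$beta, 0)

  expect_error(mr_wald_ratio(harmonised_set(0, 0.01, 0.1, 0.05)),
               "degenerate-instrument")

  # delta-method se against a Monte-Carlo simulation of the ratio
  bx <- 0.3; sex <- 0.03; by <- 0.06; sey <- 0.02
  e2 <- mr_wald_ratio(harmonised_set(bx, sex, by, sey))
  set.seed(99)
  mc <- stats::rnorm(1e6, by, sey) / stats::rnorm(1e6, bx, sex)
  expect_equal(e2$se, stats::sd(mc), tolerance = 0.03)
})

test_that("IVW reduces, floors underdispersion and matches the GLS oracle", {
  h1 <- make_hset(1, k = 1)
  expect_equal(mr_ivw(h1)$beta, mr_wald_ratio(h1)$beta)

  # identical ratios with equal se: zero residuals, phi floored at 1
  hflat <- harmonised_set(c(0.1, 0.2, 0.3), 0.01,
                          0.5 * c(0.1, 0.2, 0.3), 0.02)
  ef <- mr_ivw(hflat)
  expect_equal(ef$beta, 0.5)
  expect_equal(ef$dispersion, 1)
  expect_equal(ef$cochran_q, 0, tolerance = 1e-20)

  for (s in 1:20) {
    h <- make_hset(s, k = sample(3:15, 1), theta = stats::runif(1, -0.5, 0.5),
                   pleio = stats::runif(1, 0, 0.01))
    o <- ivw_fixed_oracle(h$beta_exposure, h$beta_outcome, h$se_outcome)
    fe <- mr_ivw(h, effects = "fixed")
    expect_equal(fe$beta, o$beta, tolerance = 1e-10)
    expect_equal(fe$se, o$se, tolerance = 1e-10)
    re <- mr_ivw(h)
    expect_equal(re$beta, o$beta, tolerance = 1e-10)
    expect_gte(re$se, fe$se)  # floor never shrinks the fixed-effect se
  }
})

test_that("correlation-adjusted IVW matches a direct matrix-inverse oracle", {
  ids <- paste0("snp_", 1:3)
  r <- matrix(0.3, 3, 3); diag(r) <- 1; dimnames(r) <- list(ids, ids)
  for (s in 1:10) {
    h <- make_hset(s + 100, k = 3, theta = 0.2, ld = r)
    o <- ivw_corr_oracle(h$beta_exposure, h$beta_outcome, h$se_outcome, r)
    e <- mr_ivw_correlated(h, effects = "fixed")
    expect_equal(e$beta, o$beta, tolerance = 1e-10)
    expect_equal(e$se, o$se, tolerance = 1e-7)
  }

  # identity LD reduces exactly to the fixed-effect IVW
  id <- diag(4); dimnames(id) <- list(paste0("snp_", 1:4), paste0("snp_", 1:4))
  h4 <- make_hset(7, k = 4, ld = id)
  expect_equal(mr_ivw_correlated(h4)$beta, mr_ivw(h4)$beta, tolerance = 1e-12)

  # duplicated SNP (r = 1) with ridge regularisation approaches the
  # single-SNP Wald ratio
  ids2 <- c("a", "b")
  r1 <- matrix(1, 2, 2); dimnames(r1) <- list(ids2, ids2)
  hd <- harmonised_set(c(0.2, 0.2), 0.01, c(0.05, 0.05), 0.02,
                       snp = ids2, ld = r1)
  wald <- mr_wald_ratio(hset_subset(hd, 1))
  expect_equal(mr_ivw_correlated(hd)$beta, wald$beta, tolerance = 1e-3)
})

test_that("MR-Egger matches an lm oracle and is orientation-invariant", {
  for (s in 1:10) {
    h <- make_hset(s + 200, k = 10, theta = 0.3, pleio = 0.02)
    o <- egger_lm_oracle(h$beta_exposure, h$beta_outcome, h$se_outcome)
    e <- mr_egger(h)
    expect_equal(e$slope$beta, o$slope, tolerance = 1e-10)
    expect_equal(e$intercept$estimate, o$intercept, tolerance = 1e-10)
    expect_equal(unname(c(e$intercept$se, e$slope$se)), unname(o$se),
                 tolerance = 1e-10)
  }

  h <- make_hset(5, k = 8, theta = 0.3)
  flipped <- h
  flipped$beta_exposure[3] <- -flipped$beta_exposure[3]
  flipped$beta_outcome[3] <- -flipped$beta_outcome[3]
  e1 <- mr_egger(h)
  e2 <- mr_egger(flipped)
  expect_equal(e1$slope$beta, e2$slope$beta, tolerance = 1e-12)
  expect_equal(e1$intercept$estimate, e2$intercept$estimate, tolerance = 1e-12)

  # constant pleiotropy c on every SNP: intercept -> c, slope -> theta
  set.seed(77)
  k <- 200
  bx <- stats::runif(k, 0.05, 0.3)
  sey <- rep(0.001, k)
  by <- 0.3 * bx + 0.05 + stats::rnorm(k, 0, sey)
  hc <- harmonised_set(bx, 1e-6, by, sey)
  ec <- mr_egger(hc)
  expect_equal(ec$intercept$estimate, 0.05, tolerance = 0.005)
  expect_equal(ec$slope$beta, 0.3, tolerance = 0.02)

  expect_error(mr_egger(make_hset(1, k = 2)), ">= 3 SNPs")
})

test_that("Egger with its intercept constrained to zero is the fixed IVW", {
  h <- make_hset(9, k = 8, theta = 0.2)
  # augmented oracle: origin-constrained weighted regression
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = as.data.frame(h),
                   weights = 1 / h$se_outcome^2)
  expect_equal(mr_ivw(h, effects = "fixed")$beta,
               unname(stats::coef(fit)), tolerance = 1e-12)
})

test_that("weighted median interpolates cumulative midpoint weights", {
  hflat <- harmonised_set(rep(1, 3), 0.01, rep(0.4, 3), 0.02)
  expect_equal(mr_weighted_median(hflat, n_boot = 0)$beta, 0.4)

  # equal weights (tiny exposure se), ratios (0.1, 0.2, 0.9):
  # cumulative midpoint weights s = (1/6, 1/2, 5/6) hit 0.5 at the middle
  he2 <- harmonised_set(rep(1, 3), 1e-9, c(0.1, 0.2, 0.9), 0.02)
  wm <- mr_weighted_median(he2, n_boot = 0)
  expect_equal(wm$beta, 0.2, tolerance = 1e-9)

  # estimate always lies within the range of per-SNP ratios
  for (s in 1:15) {
    h <- make_hset(s + 300, k = sample(3:12, 1), theta = 0.1, pleio = 0.05)
    est <- mr_weighted_median(h, n_boot = 0)$beta
    ratios <- h$beta_outcome / h$beta_exposure
    expect_gte(est, min(ratios))
    expect_lte(est, max(ratios))
  }

  # bootstrap se is reproducible under a fixed seed and positive
  h <- make_hset(12, k = 6)
  a <- mr_weighted_median(h, n_boot = 200, seed = 5)
  b <- mr_weighted_median(h, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("leave-one-out flags the planted outlier", {
  hflat <- harmonised_set(c(0.1, 0.2, 0.3, 0.4), 0.01,
                          0.5 * c(0.1, 0.2, 0.3, 0.4), 0.02)
  lo <- mr_leave_one_out(hflat)
  expect_equal(nrow(lo), 4)
  expect_equal(lo$beta, rep(0.5, 4), tolerance = 1e-12)

  h <- make_hset(44, k = 8, theta = 0.3)
  h$beta_outcome[5] <- h$beta_outcome[5] + 0.2  # planted outlier
  full <- mr_ivw(h)$beta
  lo2 <- mr_leave_one_out(h)
  expect_equal(which.max(abs(lo2$beta - full)), 5)
})

test_that("instrument strength follows the F formula and is monotone", {
  expect_equal(instrument_strength(0.012, 3301, 1)$f_stat, 40.1,
               tolerance = 0.002)
  expect_equal(instrument_strength(0.54, 3301, 1)$f_stat, 3872.7,
               tolerance = 1e-4)
  expect_equal(instrument_strength(0, 100, 1)$f_stat, 0)
  # internal consistency to 1e-9: f = r2 (n-k-1) / (k (1-r2))
  s <- instrument_strength(0.035, 204402, 45)
  expect_equal(s$f_stat, s$r2 * (s$n - s$k - 1) / (s$k * (1 - s$r2)),
               tolerance = 1e-9)
  fs <- vapply(seq(0.01, 0.5, by = 0.01),
               function(r2) instrument_strength(r2, 5000, 3)$f_stat, 0)
  expect_true(all(diff(fs) > 0))
  expect_error(instrument_strength(1, 100, 1), "domain error")
  expect_error(instrument_strength(0.1, 3, 2), "domain error")
})

test_that("variance explained from summary statistics", {
  one <- sumstats("rs1", "1", 100, "A", "G", 0.2, 0.01, 1e-10, 1000,
                  eaf = 0.5)
  expect_equal(r2_from_sumstats(one), 0.02)
  two <- sumstats(c("rs1", "rs2"), "1", c(100, 200), "A", "G",
                  c(0.2, 0.1), 0.01, 1e-10, 1000, eaf = c(0.5, 0.2))
  expect_equal(r2_from_sumstats(two), 0.02 + 2 * 0.2 * 0.8 * 0.01)
  miss <- one; miss$eaf <- NA_real_
  expect_error(r2_from_sumstats(miss), "cannot-compute")

  # genotype-level simulation oracle: regression R2 at n = 5000
  set.seed(55)
  n <- 5000
  f <- c(0.3, 0.15)
  b <- c(0.15, 0.2)
  G <- cbind(stats::rbinom(n, 2, f[1]), stats::rbinom(n, 2, f[2]))
  y_g <- drop(G %*% b)
  y <- y_g + stats::rnorm(n, 0, sqrt(1 - var(y_g)))
  r2_emp <- summary(stats::lm(y ~ G))$r.squared
  # Monte-Carlo sd of R2 at n = 5000 is ~0.004; allow 3 sd
  expect_lt(abs(sum(2 * f * (1 - f) * b^2) - r2_emp), 0.012)
})

test_that("odds-ratio conversion reproduces printed-interval shapes", {
  e0 <- new_mr_estimate_for_test(0, 0.05)
  expect_equal(to_odds_ratio(e0)$or, 1)

  # abstract-style interval: OR 1.17 (1.01-1.35); the Wald interval is
  # symmetric in logs, so centre between the printed bounds
  beta <- log(sqrt(1.01 * 1.35))
  se <- (log(1.35) - log(1.01)) / (2 * stats::qnorm(0.975))
  e <- new_mr_estimate_for_test(beta, se)
  orr <- to_odds_ratio(e)
  expect_equal(round(orr$or, 2), 1.17)
  expect_equal(round(orr$ci_low, 2), 1.01)
  expect_equal(round(orr$ci_high, 2), 1.35)

  expect_equal(log(to_odds_ratio(e)$or), e$beta, tolerance = 1e-12)
})

test_that("all estimators are scale-equivariant in the exposure", {
  h <- make_hset(66, k = 8, theta = 0.25)
  c_ <- 3.7
  hs <- harmonised_set(h$beta_exposure * c_, h$se_exposure * c_,
                       h$beta_outcome, h$se_outcome)
  expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c_, tolerance = 1e-12)
  expect_equal(mr_egger(hs)$slope$beta, mr_egger(h)$slope$beta / c_,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, n_boot = 0)$beta,
               mr_weighted_median(h, n_boot = 0)$beta / c_,
               tolerance = 1e-12)
  h1 <- hset_subset(h, 1)
  h1s <- hset_subset(hs, 1)
  expect_equal(mr_wald_ratio(h1s)$beta, mr_wald_ratio(h1)$beta / c_,
               tolerance = 1e-12)
})
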