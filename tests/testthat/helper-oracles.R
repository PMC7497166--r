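# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (explicit loops, direct matrix inverses,
# stats::lm, numerical integration) so they stay independent of the
# package's own linear-algebra paths.

# random harmonised fixture with known causal effect
make_hset <- function(seed, k = 8, theta = 0.3, pleio = 0, ld = NULL) {
  set.seed(seed)
  bx <- stats::rnorm(k, 0, 0.15)
  bx[abs(bx) < 0.02] <- 0.05
  sex <- stats::runif(k, 0.005, 0.02)
  sey <- stats::runif(k, 0.01, 0.05)
  by <- theta * bx + stats::rnorm(k, 0, pleio) + stats::rnorm(k, 0, sey)
  harmonised_set(bx, sex, by, sey, ld = ld)
}

# naive weighted regression through the origin (closed form, explicit loop)
ivw_fixed_oracle <- function(bx, by, sey) {
  num <- 0
  den <- 0
  for (i in seq_along(bx)) {
    w <- 1 / sey[i]^2
    num <- num + w * bx[i] * by[i]
    den <- den + w * bx[i]^2
  }
  list(beta = num / den, se = sqrt(1 / den))
}

# generalised least squares via direct matrix inverse
ivw_corr_oracle <- function(bx, by, sey, r) {
  omega <- diag(sey) %*% r %*% diag(sey)
  oi <- solve(omega)
  v <- 1 / drop(t(bx) %*% oi %*% bx)
  list(beta = v * drop(t(bx) %*% oi %*% by), se = sqrt(v))
}

# MR-Egger through stats::lm on pre-oriented data; the slope se carries
# the underdispersion floor, the intercept se is the plain lm one
egger_lm_oracle <- function(bx, by, sey) {
  s <- sign(bx)
  s[s == 0] <- 1
  fit <- stats::lm(I(by * s) ~ I(bx * s), weights = 1 / sey^2)
  sm <- summary(fit)
  sigma <- sm$sigma
  se_lm <- sm$coefficients[, 2]
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se = unname(c(se_lm[1], se_lm[2] / sigma * max(1, sigma))))
}

# exhaustive enumeration of causal configurations for coloc (raw scale)
coloc_enum_oracle <- function(labf1, labf2, p1, p2, p12) {
  a1 <- exp(labf1)
  a2 <- exp(labf2)
  m <- length(a1)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + p1 * p2 * a1[i] * a2[j]
  }
  h4 <- p12 * sum(a1 * a2)
  u <- c(h0, h1, h2, h3, h4)
  u / sum(u)
}

# Wakefield ABF by numerical integration of the likelihood ratio
abf_quadrature_oracle <- function(beta, se, prior_sd) {
  marg <- stats::integrate(function(b) {
    stats::dnorm(beta, b, se) * stats::dnorm(b, 0, prior_sd)
  }, -Inf, Inf, rel.tol = 1e-10)$value
  log(marg / stats::dnorm(beta, 0, se))
}

# small sumstats table written to a temp file for IO tests
write_toy_sumstats <- function(path, rows, col_order = NULL) {
  header <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- header
  if (!is.null(col_order)) df <- df[col_order]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_rows <- function() {
  list(SNP = c("rs1", "rs2", "rs3"), CHR = c("1", "1", "2"),
       POS = c(100L, 200L, 300L), EA = c("A", "c", "G"),
       OA = c("G", "t", "A"), EAF = c(0.2, 0.5, NA),
       BETA = c(0.1, -0.2, 0.05), SE = c(0.01, 0.02, 0.01),
       P = c(1e-10, 1e-8, 0.5), N = c(1000, 1000, 1000))
}

# wald-based constructor for a bare estimate (exposure beta 1, tiny se)
new_mr_estimate_for_test <- function(beta, se) {
  mr_wald_ratio(harmonised_set(1, 1e-12, beta, se))
}
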