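# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiff <- function(a, b) {
  d <- b - a
  if (d >= 0) return(-Inf)
  a + log1p(-exp(d))
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# deterministic sub-seed for a named operation, derived from a master seed;
# keeps results below 2^31 so set.seed() accepts them
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

Z95 <- stats::qnorm(0.975)

# -log10(p) for a two-sided normal p-value at |z|, stable for very large z
neglog10p_from_z <- function(z) {
  -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
}
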