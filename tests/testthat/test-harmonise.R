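mk_records <- function(snp, chrom, pos, ea, oa, beta, se, pvalue,
                       eaf = NA_real_, n = 1000) {
  sumstats(snp, chrom, pos, ea, oa, beta, se, pvalue, n, eaf = eaf)
}

named_ld <- function(r, ids) {
  dimnames(r) <- list(ids, ids)
  r
}

test_that("instrument selection enforces significance and the cis window", {
  spec_cis <- instrument_spec("monogenic_cis",
                              gene_tss = list(chrom = "1", pos = 1e6))
  rec <- mk_records(paste0("rs", 1:10), "1", 1e6 + (1:10) * 1000,
                    "A", "G", 0.1, 0.01, rep(1e-6, 10))
  expect_equal(nrow(select_instrument(rec, instrument_spec("polygenic"))), 0)

  one <- mk_records("rs1", "1", 1e6 + 5e5, "A", "G", 0.2, 0.01, 1e-12)
  expect_equal(select_instrument(one, spec_cis)$snp, "rs1")

  far <- mk_records("rs1", "1", 1e6 + 1.5e6, "A", "G", 0.2, 0.01, 1e-12)
  expect_equal(nrow(select_instrument(far, spec_cis)), 0)

  # closed window: exactly 1 Mb from the TSS is cis
  edge <- mk_records("rs1", "1", 2e6, "A", "G", 0.2, 0.01, 1e-12)
  expect_equal(nrow(select_instrument(edge, spec_cis)), 1)

  expect_error(instrument_spec("monogenic_cis"), "gene_tss")
})

test_that("greedy clumping follows the p-value order and r2 ceiling", {
  rec <- mk_records(c("A", "B", "C"), "1", c(100, 200, 300), "A", "G",
                    0.1, 0.01, c(1e-10, 1e-9, 1e-8))
  # three mutually r2 = 1 SNPs -> only the smallest p survives
  expect_equal(clump(rec, named_ld(matrix(1, 3, 3), rec$snp), 0.01)$snp, "A")

  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.005)
  r[1, 3] <- r[3, 1] <- sqrt(0.5)
  r[2, 3] <- r[3, 2] <- 0
  expect_equal(clump(rec, named_ld(r, rec$snp), 0.01)$snp, c("A", "B"))

  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- sqrt(0.005)
  r2[1, 3] <- r2[3, 1] <- sqrt(0.12)
  r2[2, 3] <- r2[3, 2] <- sqrt(0.009)
  expect_equal(clump(rec, named_ld(r2, rec$snp), 0.15)$snp, c("A", "B", "C"))

  # invariant to input row order when p-values are distinct
  shuffled <- rec[c(3, 1, 2), ]
  expect_equal(clump(shuffled, named_ld(r2, rec$snp), 0.15)$snp,
               clump(rec, named_ld(r2, rec$snp), 0.15)$snp)

  expect_error(clump(rec, named_ld(diag(2), c("A", "B")), 0.01), "missing-LD")
})

test_that("harmonisation aligns alleles, flips swaps and strand flips", {
  ex <- mk_records(c("rs1", "rs2", "rs3", "rs4"), "1", 1:4 * 100,
                   c("A", "A", "A", "A"), c("G", "G", "G", "G"),
                   0.1, 0.01, 1e-10, eaf = 0.3)
  ou <- mk_records(c("rs1", "rs2", "rs3", "rs9"), "1", 1:4 * 100,
                   c("A", "G", "T", "A"), c("G", "A", "C", "G"),
                   c(0.5, 0.1, 0.2, 0.3), 0.02, 0.5, eaf = c(0.3, 0.7, 0.3, 0.3))
  h <- harmonise_pair(ex, ou)
  prov <- attr(h, "provenance")
  expect_equal(prov$flag,
               c("kept", "flipped", "kept", "dropped_missing_outcome"))
  expect_equal(h$beta_outcome, c(0.5, -0.1, 0.2))  # rs3 via strand complement
  expect_equal(nrow(h), 3)
})

test_that("palindromic SNPs are frequency-resolved or dropped", {
  pal <- function(eaf_x, ea_o, oa_o, eaf_o) {
    ex <- mk_records("rs1", "1", 100, "A", "T", 0.1, 0.01, 1e-10, eaf = eaf_x)
    ou <- mk_records("rs1", "1", 100, ea_o, oa_o, 0.2, 0.02, 0.5, eaf = eaf_o)
    tryCatch({
      h <- harmonise_pair(ex, ou)
      list(flag = attr(h, "provenance")$flag, beta = h$beta_outcome)
    }, error = function(e) list(flag = "error", beta = NA_real_))
  }
  # mid-band frequency cannot resolve strand -> dropped (and set empty)
  expect_equal(pal(0.50, "A", "T", 0.2)$flag, "error")
  # both frequencies on the same side of 0.5 -> consistent, keep
  r <- pal(0.2, "A", "T", 0.21)
  expect_equal(r$flag, "kept")
  expect_equal(r$beta, 0.2)
  # outcome frequency on the other side -> strand flip needed
  r2 <- pal(0.2, "A", "T", 0.8)
  expect_equal(r2$flag, "flipped")
  expect_equal(r2$beta, -0.2)
  # swapped labels, concordant after swap -> flip
  r3 <- pal(0.2, "T", "A", 0.79)
  expect_equal(r3$flag, "flipped")
  expect_equal(r3$beta, -0.2)
})

test_that("harmonisation is idempotent and orientation-invariant", {
  g <- simulate_two_sample_gwas(sim_config(seed = 21, m_snps = 10))
  h1 <- harmonise_pair(g$exposure, g$outcome)
  # re-expressing the harmonised outcome as records and re-harmonising
  # changes nothing
  out2 <- g$outcome
  h2 <- harmonise_pair(g$exposure, out2)
  expect_equal(as.data.frame(h1), as.data.frame(h2))

  # flipping every outcome record's alleles and beta sign leaves the
  # harmonised set invariant
  flipped <- g$outcome
  tmp <- flipped$ea
  flipped$ea <- flipped$oa
  flipped$oa <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h3 <- harmonise_pair(g$exposure, flipped)
  expect_equal(h1$beta_outcome, h3$beta_outcome, tolerance = 1e-12)
})

test_that("regional extraction uses a closed interval", {
  rec <- mk_records(paste0("rs", 1:5), "1", c(1e6 - 1e5, 1e6 - 1, 1e6,
                                              1e6 + 1e5, 1e6 + 1e5 + 1),
                    "A", "G", 0.1, 0.01, 0.5)
  r <- extract_region(rec, "rs3", 1e5)
  expect_equal(r$snp, c("rs1", "rs2", "rs3", "rs4"))  # boundary included
  expect_equal(attr(r, "index_snp"), "rs3")
  expect_equal(extract_region(rec, "rs3", 0)$snp, "rs3")
  expect_error(extract_region(rec, "rs99", 1e5), "lookup error")
})

test_that("regional extraction matches a brute-force position filter", {
  set.seed(31)
  m <- 500
  pos <- sort(sample(seq(1e6 - 2e5, 1e6 + 2e5), m))
  pos[250] <- 1e6
  rec <- mk_records(paste0("rs", seq_len(m)), "1", pos, "A", "G",
                    0.1, 0.01, 0.5)
  r <- extract_region(rec, "rs250", 1e5)
  brute <- rec$snp[abs(rec$pos - 1e6) <= 1e5]
  expect_identical(r$snp, brute)
  expect_gt(nrow(r), 200)  # ~half of a uniform +/-200 kb region
  expect_lt(nrow(r), 300)
})
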