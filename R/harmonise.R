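COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea] == oa)

#' Instrument-construction settings
#'
#' @param mode `"polygenic"` (cis + trans, genome-wide) or `"monogenic_cis"`
#'   (restricted to within `cis_window_bp` of the gene's transcription start
#'   site).
#' @param p_threshold Genome-wide significance cut-off (default `5e-8`).
#' @param r2_threshold LD-clumping ceiling on r-squared (default `0.01`;
#'   use `0.15` for weakly-correlated cis sets).
#' @param cis_window_bp Half-width of the cis window in base pairs
#'   (default 1 Mb), measured from the transcription start site.
#' @param gene_tss `list(chrom =, pos =)`; required iff `mode` is
#'   `"monogenic_cis"`.
#' @return An `instrument_spec` object.
#' @export
instrument_spec <- function(mode = c("polygenic", "monogenic_cis"),
                            p_threshold = 5e-8, r2_threshold = 0.01,
                            cis_window_bp = 1e6, gene_tss = NULL) {
  mode <- match.arg(mode)
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold > 0, r2_threshold <= 1, cis_window_bp > 0)
  if (mode == "monogenic_cis" && is.null(gene_tss)) {
    stop("spec error: gene_tss is required in monogenic_cis mode")
  }
  if (!is.null(gene_tss)) {
    stopifnot(!is.null(gene_tss$chrom), !is.null(gene_tss$pos))
  }
  structure(list(mode = mode, p_threshold = p_threshold,
                 r2_threshold = r2_threshold, cis_window_bp = cis_window_bp,
                 gene_tss = gene_tss),
            class = "instrument_spec")
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by chromosome,
#' position, then SNP id) and accepts a SNP iff its r-squared with every
#' already-accepted SNP is below `r2_threshold`. Output is therefore
#' invariant to input row order when p-values are distinct.
#'
#' @param records A `sumstats` data.frame.
#' @param ld Signed LD correlation matrix covering every candidate.
#' @param r2_threshold r-squared ceiling.
#' @return The retained rows, in acceptance order.
#' @export
clump <- function(records, ld, r2_threshold = 0.01) {
  if (nrow(records) == 0) return(records)
  missing_ids <- setdiff(records$snp, rownames(ld))
  if (length(missing_ids) > 0) {
    stop("missing-LD error: no LD entry for ",
         paste(missing_ids, collapse = ", "))
  }
  ord <- order(records$pvalue, records$chrom, records$pos, records$snp)
  x <- records[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(x))) {
    if (length(kept) == 0) {
      kept <- i
      next
    }
    r2 <- ld[x$snp[i], x$snp[kept]]^2
    if (all(r2 < r2_threshold)) kept <- c(kept, i)
  }
  out <- x[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select instrument SNPs for one exposure
#'
#' Keeps SNPs below the significance threshold, restricts to the cis window
#' in `monogenic_cis` mode, then LD-clumps. An empty result is legal and
#' signals that the trait is not instrumentable.
#'
#' @param records `sumstats` for one exposure trait.
#' @param spec An [instrument_spec()].
#' @param ld Signed LD matrix; may be `NULL` only when at most one SNP
#'   survives the significance/window filters.
#' @return The instrument rows (possibly zero rows).
#' @export
select_instrument <- function(records, spec, ld = NULL) {
  stopifnot(inherits(spec, "instrument_spec"))
  x <- records[records$pvalue < spec$p_threshold, , drop = FALSE]
  if (spec$mode == "monogenic_cis") {
    tss <- spec$gene_tss
    keep <- x$chrom == as.character(tss$chrom) &
      abs(x$pos - tss$pos) <= spec$cis_window_bp
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) <= 1) {
    rownames(x) <- NULL
    return(x)
  }
  if (is.null(ld)) {
    stop("missing-LD error: LD matrix required to clump ", nrow(x),
         " candidate SNPs")
  }
  clump(x, ld, spec$r2_threshold)
}

#' Construct a harmonised exposure/outcome set directly
#'
#' Low-level constructor for effect pairs already on a common effect-allele
#' orientation (e.g. simulated data); [harmonise_pair()] is the allele-aware
#' route for real tables.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Per-SNP effects
#'   and standard errors.
#' @param snp SNP ids (defaults to `snp_1 ...`).
#' @param eaf Effect-allele frequencies (optional).
#' @param ld Optional signed LD matrix over `snp`.
#' @return A `harmonised_set` object.
#' @export
harmonised_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, snp = NULL, eaf = NA_real_, ld = NULL) {
  k <- max(length(beta_exposure), length(beta_outcome))
  beta_exposure <- rep_len(beta_exposure, k)
  se_exposure <- rep_len(se_exposure, k)
  beta_outcome <- rep_len(beta_outcome, k)
  se_outcome <- rep_len(se_outcome, k)
  if (is.null(snp)) snp <- paste0("snp_", seq_len(k))
  stopifnot(length(snp) == k, all(se_exposure > 0), all(se_outcome > 0))
  x <- data.frame(snp = snp, beta_exposure = beta_exposure,
                  se_exposure = se_exposure, beta_outcome = beta_outcome,
                  se_outcome = se_outcome, eaf = eaf,
                  stringsAsFactors = FALSE)
  if (!is.null(ld)) {
    missing_ids <- setdiff(snp, rownames(ld))
    if (length(missing_ids) > 0) {
      stop("missing-LD error: ", paste(missing_ids, collapse = ", "))
    }
    ld <- ld[snp, snp, drop = FALSE]
  }
  structure(x, class = c("harmonised_set", "data.frame"), ld = ld,
            provenance = data.frame(snp = snp, flag = "kept",
                                    stringsAsFactors = FALSE))
}

#' Subset a harmonised set by SNP index
#'
#' Keeps the per-SNP rows and the matching LD sub-matrix.
#'
#' @param h A `harmonised_set`.
#' @param idx Integer or logical row index.
#' @return A `harmonised_set` over the selected SNPs.
#' @export
hset_subset <- function(h, idx) {
  ld <- attr(h, "ld")
  x <- as.data.frame(h)[idx, , drop = FALSE]
  harmonised_set(x$beta_exposure, x$se_exposure, x$beta_outcome,
                 x$se_outcome, snp = x$snp, eaf = x$eaf,
                 ld = if (is.null(ld)) NULL else ld[idx, idx, drop = FALSE])
}

#' Harmonise exposure and outcome records onto a common effect allele
#'
#' For each exposure SNP found in the outcome table: matching alleles are
#' kept as-is; swapped alleles flip the outcome beta sign and eaf; strand
#' complements are complemented first (non-palindromic SNPs only) and then
#' matched or swapped. Palindromic (A/T, C/G) SNPs are resolved by allele
#' frequency when both eafs lie outside `palindrome_eaf_band`, and dropped
#' otherwise. Exposure SNPs absent from the outcome are dropped and flagged.
#'
#' @param exposure Instrument rows (a `sumstats` data.frame).
#' @param outcome Outcome `sumstats` (may be genome-wide).
#' @param palindrome_eaf_band Frequency band around 0.5 inside which
#'   palindromic SNPs are considered unresolvable (default `c(0.42, 0.58)`).
#' @param ld Optional signed LD matrix; restricted to the kept SNPs.
#' @return A `harmonised_set`; attribute `"provenance"` flags every exposure
#'   SNP as `kept`, `flipped`, `dropped_palindromic`,
#'   `dropped_missing_outcome` or `dropped_allele_mismatch`.
#' @export
harmonise_pair <- function(exposure, outcome,
                           palindrome_eaf_band = c(0.42, 0.58), ld = NULL) {
  stopifnot(nrow(exposure) > 0)
  lo <- palindrome_eaf_band[1]
  hi <- palindrome_eaf_band[2]
  flags <- character(nrow(exposure))
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- match(ex$snp, outcome$snp)
    if (is.na(j)) {
      flags[i] <- "dropped_missing_outcome"
      next
    }
    ou <- outcome[j, ]
    ea_o <- ou$ea
    oa_o <- ou$oa
    pal <- is_palindromic(ex$ea, ex$oa)
    action <- NA_character_
    if (!pal) {
      if (ea_o == ex$ea && oa_o == ex$oa) {
        action <- "keep"
      } else if (ea_o == ex$oa && oa_o == ex$ea) {
        action <- "flip"
      } else {
        # try the opposite strand
        ea_c <- unname(COMPLEMENT[ea_o])
        oa_c <- unname(COMPLEMENT[oa_o])
        if (identical(ea_c, ex$ea) && identical(oa_c, ex$oa)) {
          action <- "keep"
        } else if (identical(ea_c, ex$oa) && identical(oa_c, ex$ea)) {
          action <- "flip"
        } else {
          flags[i] <- "dropped_allele_mismatch"
          next
        }
      }
    } else {
      same_pair <- (ea_o == ex$ea && oa_o == ex$oa) ||
        (ea_o == ex$oa && oa_o == ex$ea)
      if (!same_pair) {
        flags[i] <- "dropped_allele_mismatch"
        next
      }
      outside <- function(f) !is.na(f) && (f < lo || f > hi)
      if (!outside(ex$eaf) || !outside(ou$eaf)) {
        flags[i] <- "dropped_palindromic"
        next
      }
      # orient by which side of 0.5 each frequency falls
      f_o <- if (ea_o == ex$ea) ou$eaf else 1 - ou$eaf
      nominal_flip <- ea_o != ex$ea
      freq_agree <- (ex$eaf - 0.5) * (f_o - 0.5) > 0
      action <- if (freq_agree) {
        if (nominal_flip) "flip" else "keep"
      } else {
        if (nominal_flip) "keep" else "flip"
      }
    }
    flip <- action == "flip"
    flags[i] <- if (flip) "flipped" else "kept"
    rows[[i]] <- data.frame(
      snp = ex$snp,
      beta_exposure = ex$beta, se_exposure = ex$se,
      beta_outcome = if (flip) -ou$beta else ou$beta,
      se_outcome = ou$se,
      eaf = ex$eaf, stringsAsFactors = FALSE)
  }
  kept <- !vapply(rows, is.null, logical(1))
  if (!any(kept)) {
    stop("empty-harmonised error: no exposure SNP could be harmonised ",
         "with the outcome")
  }
  x <- do.call(rbind, rows[kept])
  h <- harmonised_set(x$beta_exposure, x$se_exposure, x$beta_outcome,
                      x$se_outcome, snp = x$snp, eaf = x$eaf, ld = ld)
  attr(h, "provenance") <- data.frame(snp = exposure$snp, flag = flags,
                                      stringsAsFactors = FALSE)
  h
}

#' Extract a regional window around an index SNP
#'
#' Returns the records on the index SNP's chromosome whose positions fall in
#' the closed interval `[pos - window_bp, pos + window_bp]`, packaged for
#' colocalisation.
#'
#' @param all_records A `sumstats` data.frame covering the region.
#' @param index_snp SNP id of the window centre.
#' @param window_bp Half-width of the window in base pairs (default 100 kb).
#' @return A `region_data` data.frame `(snp, pos, beta, se, n, eaf, pvalue)`
#'   with attributes `window` (chrom/start/end), `index_snp`, `trait_id`,
#'   `trait_type`.
#' @export
extract_region <- function(all_records, index_snp, window_bp = 1e5) {
  j <- match(index_snp, all_records$snp)
  if (is.na(j)) stop("lookup error: index SNP ", index_snp, " not found")
  chrom <- all_records$chrom[j]
  centre <- all_records$pos[j]
  keep <- all_records$chrom == chrom &
    all_records$pos >= centre - window_bp &
    all_records$pos <= centre + window_bp
  x <- all_records[keep, , drop = FALSE]
  if (anyDuplicated(x$snp)) stop("duplicate SNP ids within region")
  out <- data.frame(snp = x$snp, pos = x$pos, beta = x$beta, se = x$se,
                    n = x$n, eaf = x$eaf, pvalue = x$pvalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("region_data", "data.frame"),
            window = list(chrom = chrom, start = centre - window_bp,
                          end = centre + window_bp),
            index_snp = index_snp,
            trait_id = x$trait_id[1], trait_type = x$trait_type[1])
}
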