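#' Column schema for summary-statistics tables
#'
#' Maps the internal field names onto the column names of a tab-delimited
#' GWAS summary-statistics file. The defaults follow the common
#' `SNP/CHR/POS/EA/OA/EAF/BETA/SE/P/N` dialect.
#'
#' @param snp,chrom,pos,ea,oa,eaf,beta,se,pvalue,n Column names in the file.
#' @param na_tokens Character values treated as missing.
#' @return A `schema_config` object.
#' @export
#' @examples
#' default_schema(pvalue = "P_VALUE")
default_schema <- function(snp = "SNP", chrom = "CHR", pos = "POS",
                           ea = "EA", oa = "OA", eaf = "EAF",
                           beta = "BETA", se = "SE", pvalue = "P", n = "N",
                           na_tokens = c("NA", "", ".", "NaN")) {
  columns <- list(snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa,
                  eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
  if (anyNA(unlist(columns)) || any(!nzchar(unlist(columns)))) {
    stop("schema error: every field must map to a non-empty column name")
  }
  if (anyDuplicated(unlist(columns))) {
    stop("schema error: each required field must be mapped exactly once; ",
         "duplicated column name(s): ",
         paste(unique(unlist(columns)[duplicated(unlist(columns))]), collapse = ", "))
  }
  structure(list(columns = columns, na_tokens = na_tokens),
            class = "schema_config")
}

#' Read a column schema from a YAML file
#'
#' The YAML file holds `field: column` pairs (fields as in [default_schema()])
#' plus an optional `na_tokens` list.
#'
#' @param path Path to a YAML schema file.
#' @return A `schema_config` object.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_schema, raw)
}

SUMSTATS_COLS <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se",
                   "pvalue", "n", "trait_id", "trait_type", "unit_note")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table from vectors
#'
#' Internal-facing constructor used by the simulator and tests; applies the
#' same per-row invariants as [read_sumstats()] but stops on the first
#' violation rather than collecting row diagnostics.
#'
#' @param snp,chrom,pos,ea,oa,eaf,beta,se,pvalue,n Per-SNP fields.
#' @param trait_id Trait identifier.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param unit_note Free-text unit annotation.
#' @return A `sumstats` data.frame.
#' @export
sumstats <- function(snp, chrom, pos, ea, oa, beta, se, pvalue, n,
                     eaf = NA_real_, trait_id = NA_character_,
                     trait_type = c("quantitative", "case_control"),
                     unit_note = NA_character_) {
  trait_type <- match.arg(trait_type)
  x <- data.frame(snp = as.character(snp), chrom = as.character(chrom),
                  pos = as.integer(pos), ea = toupper(ea), oa = toupper(oa),
                  eaf = as.numeric(eaf), beta = as.numeric(beta),
                  se = as.numeric(se), pvalue = as.numeric(pvalue),
                  n = as.numeric(n), trait_id = trait_id,
                  trait_type = trait_type, unit_note = unit_note,
                  stringsAsFactors = FALSE)
  bad <- validate_sumstats_rows(x)
  if (any(bad != "")) {
    stop("invalid association record(s): row ", which(bad != "")[1], ": ",
         bad[bad != ""][1])
  }
  class(x) <- c("sumstats", "data.frame")
  x
}

# one reason string per row ("" when the row is valid)
validate_sumstats_rows <- function(x) {
  reason <- character(nrow(x))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[cond & reason == ""] <<- msg
  }
  flag(!nzchar(x$snp) | is.na(x$snp), "missing snp id")
  flag(is.na(x$pos) | x$pos < 1, "pos must be >= 1")
  flag(!(x$ea %in% VALID_ALLELES), "effect_allele not in {A,C,G,T}")
  flag(!(x$oa %in% VALID_ALLELES), "other_allele not in {A,C,G,T}")
  flag(x$ea == x$oa, "effect_allele equals other_allele")
  flag(is.na(x$beta), "non-numeric beta")
  flag(is.na(x$se) | x$se <= 0, "se must be > 0")
  flag(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1, "pvalue must be in (0,1]")
  flag(is.na(x$n) | x$n <= 0, "n must be > 0")
  ok_eaf <- is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)
  reason[!ok_eaf & reason == ""] <- "eaf must be in [0,1]"
  reason
}

#' Read a GWAS summary-statistics table
#'
#' Reads a headered tab-delimited file into the package's `sumstats`
#' data.frame. Alleles are upper-cased; rows violating the record invariants
#' (positive `se`, p in (0,1], alleles in \{A,C,G,T\}, distinct alleles,
#' `eaf` in \[0,1\] when present, `pos >= 1`, `n > 0`) are rejected with
#' row-indexed diagnostics attached as attribute `"rejected"` and reported
#' via a warning. Row ordering of accepted rows is preserved.
#'
#' @param path Path to the file.
#' @param schema A `schema_config` from [default_schema()] or [read_schema()].
#' @param trait_id Trait identifier attached to every record.
#' @param trait_type `"quantitative"` or `"case_control"` (log-odds betas).
#' @param unit_note Free-text unit annotation (e.g. `"SD"`, `"natural-log"`).
#' @return A `sumstats` data.frame; attribute `"rejected"` holds a data.frame
#'   of `(row, snp, reason)` for rejected rows.
#' @export
read_sumstats <- function(path, schema = default_schema(),
                          trait_id = NA_character_,
                          trait_type = c("quantitative", "case_control"),
                          unit_note = NA_character_) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(schema, "schema_config"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty-input error: no data rows in ", path)
  cols <- schema$columns
  missing_cols <- setdiff(unlist(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  nav <- function(v) {
    v[v %in% schema$na_tokens] <- NA_character_
    v
  }
  num <- function(field) suppressWarnings(as.numeric(nav(raw[[cols[[field]]]])))
  x <- data.frame(snp = nav(raw[[cols$snp]]),
                  chrom = nav(raw[[cols$chrom]]),
                  pos = suppressWarnings(as.integer(nav(raw[[cols$pos]]))),
                  ea = toupper(nav(raw[[cols$ea]])),
                  oa = toupper(nav(raw[[cols$oa]])),
                  eaf = num("eaf"), beta = num("beta"), se = num("se"),
                  pvalue = num("pvalue"), n = num("n"),
                  trait_id = trait_id, trait_type = trait_type,
                  unit_note = unit_note, stringsAsFactors = FALSE)
  reason <- validate_sumstats_rows(x)
  rejected <- data.frame(row = which(reason != ""),
                         snp = x$snp[reason != ""],
                         reason = reason[reason != ""],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " row(s) rejected while reading ", path, ": ",
            paste0("row ", utils::head(rejected$row, 5), " (",
                   utils::head(rejected$reason, 5), ")", collapse = "; "),
            if (nrow(rejected) > 5) " ..." else "")
  }
  x <- x[reason == "", , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("sumstats", "data.frame")
  attr(x, "rejected") <- rejected
  x
}

#' Write a summary-statistics table
#'
#' Inverse of [read_sumstats()] under the default schema; full numeric
#' precision is retained so a read/write/read round trip is lossless.
#'
#' @param x A `sumstats` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- data.frame(SNP = x$snp, CHR = x$chrom, POS = x$pos, EA = x$ea,
                    OA = x$oa, EAF = x$eaf, BETA = x$beta, SE = x$se,
                    P = x$pvalue, N = x$n, stringsAsFactors = FALSE)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD correlation matrix
#'
#' The file stores signed correlations `r` (not r-squared) as a square
#' tab-delimited matrix with SNP ids as the first row and first column.
#' The matrix is re-ordered to `expected_ids`, checked for symmetry within
#' `1e-8` then symmetrised, and its diagonal is set to exactly 1.
#'
#' @param path Path to the file.
#' @param expected_ids Optional character vector of SNP ids the matrix must
#'   cover; output rows/columns follow this ordering.
#' @return A numeric matrix with `dimnames` set to the SNP ids.
#' @export
read_ld_matrix <- function(path, expected_ids = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  r <- as.matrix(raw)
  if (nrow(r) != ncol(r)) stop("LD matrix is not square: ", path)
  if (!identical(rownames(r), colnames(r))) {
    stop("LD matrix row/column ids disagree: ", path)
  }
  if (any(!is.finite(r))) stop("non-numeric entries in LD matrix: ", path)
  if (any(abs(r) > 1 + 1e-12)) {
    stop("domain error: |r| > 1 in LD matrix: ", path)
  }
  if (max(abs(r - t(r))) > 1e-8) {
    stop("LD matrix asymmetric beyond tolerance 1e-8: ", path)
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (!is.null(expected_ids)) {
    missing_ids <- setdiff(expected_ids, rownames(r))
    if (length(missing_ids) > 0) {
      stop("missing-SNP error: LD matrix lacks ",
           paste(missing_ids, collapse = ", "))
    }
    r <- r[expected_ids, expected_ids, drop = FALSE]
  }
  r
}

#' Write an LD correlation matrix
#' @param r Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  stopifnot(is.matrix(r), !is.null(rownames(r)))
  out <- cbind(SNP = rownames(r),
               as.data.frame(format(r, digits = 17, trim = TRUE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' Writes one row per (risk factor, endpoint, method), mirroring the layout
#' of a primary MR results table: odds ratio and 95% CI to two decimals,
#' p-value to two significant figures, rows ordered by
#' (risk_factor, endpoint, method) so repeated writes are byte-identical.
#'
#' @param estimates Either the `primary` data.frame of a [run_study()] report
#'   or a list of `mr_estimate` objects carrying `risk_factor`/`endpoint`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(estimates, path) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, as.data.frame))
  }
  if (!is.data.frame(estimates) || nrow(estimates) == 0) {
    stop("empty-input error: no estimates to write")
  }
  need <- c("risk_factor", "endpoint", "method", "n_snp", "beta", "se",
            "or", "ci_low_or", "ci_high_or", "pvalue")
  missing_cols <- setdiff(need, names(estimates))
  if (length(missing_cols) > 0) {
    stop("results table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- estimates[order(estimates$risk_factor, estimates$endpoint,
                       estimates$method), , drop = FALSE]
  out <- data.frame(risk_factor = x$risk_factor, endpoint = x$endpoint,
                    method = x$method, n_snp = x$n_snp,
                    beta = sprintf("%.6g", x$beta),
                    se = sprintf("%.6g", x$se),
                    OR = sprintf("%.2f", x$or),
                    CI_low = sprintf("%.2f", x$ci_low_or),
                    CI_high = sprintf("%.2f", x$ci_high_or),
                    pvalue = signif(x$pvalue, 2), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
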