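#' Assemble a study configuration
#'
#' @param factors Named list; each element
#'   `list(name, sumstats, ld, spec, correlated, gwas_n)` — the exposure
#'   summary statistics (a `sumstats` data.frame, regional or genome-wide),
#'   an optional signed LD matrix over its SNPs, an [instrument_spec()],
#'   whether the instrument is a weakly-correlated cis set (routes to the
#'   correlation-adjusted IVW), and the exposure GWAS sample size.
#' @param endpoints Named list; each element `list(name, sumstats)`.
#' @param alpha Family-wise error level for the Bonferroni correction
#'   across risk factors (default 0.05, applied per endpoint).
#' @param coloc_trigger_p Nominal p-value below which colocalisation is run
#'   for a (factor, endpoint) pair (default 0.05).
#' @param coloc_window_bp Colocalisation window half-width (default 100 kb).
#' @param priors [coloc_priors()] used for triggered pairs.
#' @return An `mr_study` object.
#' @export
mr_study <- function(factors, endpoints, alpha = 0.05,
                     coloc_trigger_p = 0.05, coloc_window_bp = 1e5,
                     priors = coloc_priors()) {
  stopifnot(length(factors) >= 1, length(endpoints) >= 1,
            alpha > 0, alpha < 1)
  if (is.null(names(factors))) {
    names(factors) <- vapply(factors, `[[`, "", "name")
  }
  if (is.null(names(endpoints))) {
    names(endpoints) <- vapply(endpoints, `[[`, "", "name")
  }
  structure(list(factors = factors, endpoints = endpoints, alpha = alpha,
                 coloc_trigger_p = coloc_trigger_p,
                 coloc_window_bp = coloc_window_bp, priors = priors),
            class = "mr_study")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of risk factors tested per endpoint.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 7) # 0.00714..., reported as < 0.007
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("domain error: m must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}

# choose the primary estimator for one harmonised pair
route_estimator <- function(hset, correlated) {
  k <- nrow(hset)
  if (k == 1) return(mr_wald_ratio(hset))
  if (correlated) return(mr_ivw_correlated(hset))
  mr_ivw(hset, effects = "multiplicative_random")
}

na_primary_row <- function(factor_name, endpoint_name, status) {
  data.frame(risk_factor = factor_name, endpoint = endpoint_name,
             method = NA_character_, n_snp = NA_integer_, beta = NA_real_,
             se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             or = NA_real_, ci_low_or = NA_real_, ci_high_or = NA_real_,
             pvalue = NA_real_, dispersion = NA_real_, cochran_q = NA_real_,
             bonferroni = NA_character_, status = status,
             stringsAsFactors = FALSE)
}

#' Run the full MR + colocalisation study
#'
#' For every configured (risk factor, endpoint) pair: selects the
#' instrument, harmonises it against the endpoint, and routes to the
#' primary estimator by instrument structure — a single SNP uses the Wald
#' ratio; a weakly-correlated cis set uses the correlation-adjusted IVW;
#' otherwise the multiplicative random-effects IVW. MR-Egger, the weighted
#' median and leave-one-out run for every instrument of at least three
#' independent SNPs. Colocalisation (±`coloc_window_bp` around the top
#' instrument SNP) runs for every pair at nominal `p < coloc_trigger_p`.
#' Results are flagged against the Bonferroni threshold
#' `alpha / n_factors` (applied across risk factors, per endpoint). A
#' failure in one pair is recorded in its `status` and does not abort the
#' others.
#'
#' @param study An [mr_study()].
#' @param seed Seed controlling the weighted-median bootstrap streams.
#' @param log_path Optional path; per-stage events are appended as JSON
#'   lines.
#' @return A `study_report`: `primary` (one row per pair), `strength`
#'   (R2/F per factor), `sensitivity` (`egger`, `weighted_median`,
#'   `leave_one_out`), `coloc`, `bonferroni_p`, `log`.
#' @export
run_study <- function(study, seed = 1, log_path = NULL) {
  stopifnot(inherits(study, "mr_study"))
  m <- length(study$factors)
  thr <- bonferroni_threshold(study$alpha, m)
  log <- list()
  note <- function(...) {
    entry <- list(...)
    log[[length(log) + 1]] <<- entry
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
  }
  primary <- list()
  strength <- list()
  egger_rows <- list()
  wm_rows <- list()
  loo <- list()
  coloc_rows <- list()
  for (f in study$factors) {
    inst <- tryCatch(select_instrument(f$sumstats, f$spec, f$ld),
                     error = function(e) e)
    if (inherits(inst, "error") || nrow(inst) == 0) {
      status <- if (inherits(inst, "error")) {
        paste("instrument_error:", conditionMessage(inst))
      } else "not_instrumentable"
      note(stage = "instrument", factor = f$name, status = status)
      for (e in study$endpoints) {
        primary[[length(primary) + 1]] <- na_primary_row(f$name, e$name, status)
      }
      next
    }
    k <- nrow(inst)
    note(stage = "instrument", factor = f$name, n_snp = k,
         snps = inst$snp)
    r2 <- tryCatch(r2_from_sumstats(inst), error = function(e) NA_real_)
    fstat <- if (!is.na(r2) && f$gwas_n > k + 1) {
      instrument_strength(r2, f$gwas_n, k)$f_stat
    } else NA_real_
    strength[[length(strength) + 1]] <- data.frame(
      risk_factor = f$name, n_snp = k, r2 = r2, f_stat = fstat,
      n = f$gwas_n, stringsAsFactors = FALSE)
    top_snp <- inst$snp[which.min(inst$pvalue)]
    for (e in study$endpoints) {
      res <- tryCatch({
        h <- harmonise_pair(inst, e$sumstats, ld = f$ld)
        dropped <- attr(h, "provenance")
        dropped <- dropped[!(dropped$flag %in% c("kept", "flipped")), ]
        if (nrow(dropped) > 0) {
          note(stage = "harmonise", factor = f$name, endpoint = e$name,
               dropped = dropped$snp, reasons = dropped$flag)
        }
        est <- route_estimator(h, isTRUE(f$correlated))
        note(stage = "estimate", factor = f$name, endpoint = e$name,
             method = est$method, phi = est$dispersion)
        row <- cbind(as.data.frame(est)[-(1:2)],
                     data.frame(risk_factor = f$name, endpoint = e$name))
        row <- row[c("risk_factor", "endpoint",
                     setdiff(names(row), c("risk_factor", "endpoint")))]
        row$bonferroni <- if (est$pvalue < thr) "pass"
          else if (est$pvalue < 0.05) "nominal" else "null"
        row$status <- "ok"
        list(row = row, hset = h, est = est)
      }, error = function(err) err)
      if (inherits(res, "error")) {
        note(stage = "estimate", factor = f$name, endpoint = e$name,
             status = conditionMessage(res))
        primary[[length(primary) + 1]] <-
          na_primary_row(f$name, e$name,
                         paste("estimation_error:", conditionMessage(res)))
        next
      }
      primary[[length(primary) + 1]] <- res$row
      h <- res$hset
      if (nrow(h) >= 3 && !isTRUE(f$correlated)) {
        eg <- tryCatch(mr_egger(h), error = function(err) NULL)
        if (!is.null(eg)) {
          egger_rows[[length(egger_rows) + 1]] <- data.frame(
            risk_factor = f$name, endpoint = e$name,
            slope = eg$slope$beta, slope_se = eg$slope$se,
            slope_pvalue = eg$slope$pvalue,
            intercept = eg$intercept$estimate,
            intercept_se = eg$intercept$se,
            intercept_pvalue = eg$intercept$pvalue,
            stringsAsFactors = FALSE)
        }
        wm <- tryCatch(
          mr_weighted_median(h, n_boot = 1000,
                             seed = derive_seed(seed, paste(f$name, e$name))),
          error = function(err) NULL)
        if (!is.null(wm)) {
          wm_rows[[length(wm_rows) + 1]] <- data.frame(
            risk_factor = f$name, endpoint = e$name, beta = wm$beta,
            se = wm$se, pvalue = wm$pvalue, stringsAsFactors = FALSE)
        }
        lo <- tryCatch(mr_leave_one_out(h), error = function(err) NULL)
        if (!is.null(lo)) {
          loo[[paste(f$name, e$name, sep = ".")]] <- lo
        }
      }
      if (res$est$pvalue < study$coloc_trigger_p) {
        cres <- tryCatch({
          r1 <- extract_region(f$sumstats, top_snp, study$coloc_window_bp)
          r2g <- extract_region(e$sumstats, top_snp, study$coloc_window_bp)
          cc <- coloc_posteriors(r1, r2g, study$priors)
          secondary <- check_single_causal(r1, f$ld)
          if (length(secondary) > 0) {
            warning("possible secondary peak(s) near ", f$name,
                    " lead SNP; single-causal-variant assumption suspect: ",
                    paste(secondary, collapse = ", "), call. = FALSE)
            note(stage = "coloc", factor = f$name, endpoint = e$name,
                 secondary_peaks = secondary)
          }
          cc
        }, error = function(err) err)
        if (inherits(cres, "error")) {
          note(stage = "coloc", factor = f$name, endpoint = e$name,
               status = conditionMessage(cres))
        } else {
          pp <- as.list(cres$pp)
          coloc_rows[[length(coloc_rows) + 1]] <- data.frame(
            risk_factor = f$name, endpoint = e$name, index_snp = top_snp,
            n_snps = cres$n_snps, pp0 = pp$pp0, pp1 = pp$pp1, pp2 = pp$pp2,
            pp3 = pp$pp3, pp4 = pp$pp4, stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(x, proto) if (length(x) > 0) do.call(rbind, x) else proto
  report <- structure(list(
    primary = bind(primary, NULL),
    strength = bind(strength, NULL),
    sensitivity = list(egger = bind(egger_rows, NULL),
                       weighted_median = bind(wm_rows, NULL),
                       leave_one_out = loo),
    coloc = bind(coloc_rows, NULL),
    bonferroni_p = thr,
    log = log), class = "study_report")
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("MR study report: %d primary estimates, Bonferroni p < %.3f\n",
              nrow(x$primary), x$bonferroni_p))
  cols <- c("risk_factor", "endpoint", "method", "n_snp", "or",
            "ci_low_or", "ci_high_or", "pvalue", "bonferroni")
  print(format(x$primary[, cols], digits = 3), row.names = FALSE)
  if (!is.null(x$coloc) && nrow(x$coloc) > 0) {
    cat("\nColocalisation of nominal hits:\n")
    print(format(x$coloc, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Write scatter / forest / funnel diagnostic tables
#'
#' For a multi-SNP instrument, writes three tab-delimited data tables:
#' `scatter.tsv` (per-SNP exposure and outcome betas with their standard
#' errors), `forest.tsv` (per-SNP Wald ratios plus the combined IVW row),
#' `funnel.tsv` (per-SNP Wald ratio against its precision), and
#' `slopes.tsv` holding the fitted IVW (and, when available, MR-Egger and
#' weighted-median) slopes for overplotting. A single-SNP instrument is
#' skipped with a message.
#'
#' @param hset A `harmonised_set`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the weighted-median bootstrap.
#' @return Invisibly, a list of the tables and file paths, or `NULL` when
#'   skipped.
#' @export
diagnostics_bundle <- function(hset, out_dir, seed = 1) {
  k <- nrow(hset)
  if (k < 2) {
    message("diagnostics skipped: single-SNP instrument")
    return(invisible(NULL))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scatter <- data.frame(snp = hset$snp, beta_exposure = hset$beta_exposure,
                        se_exposure = hset$se_exposure,
                        beta_outcome = hset$beta_outcome,
                        se_outcome = hset$se_outcome,
                        stringsAsFactors = FALSE)
  per_snp <- lapply(seq_len(k), function(i) {
    e <- mr_wald_ratio(hset_subset(hset, i))
    data.frame(snp = hset$snp[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)
  })
  ivw <- mr_ivw(hset)
  forest <- rbind(do.call(rbind, per_snp),
                  data.frame(snp = "combined (IVW)", beta = ivw$beta,
                             se = ivw$se, ci_low = ivw$ci_low,
                             ci_high = ivw$ci_high, stringsAsFactors = FALSE))
  funnel <- data.frame(snp = forest$snp[seq_len(k)],
                       beta = forest$beta[seq_len(k)],
                       precision = 1 / forest$se[seq_len(k)],
                       stringsAsFactors = FALSE)
  slopes <- data.frame(method = "ivw_re", intercept = 0, slope = ivw$beta,
                       stringsAsFactors = FALSE)
  if (k >= 3) {
    eg <- mr_egger(hset)
    wm <- mr_weighted_median(hset, n_boot = 0, seed = seed)
    slopes <- rbind(slopes,
                    data.frame(method = "egger", intercept = eg$intercept$estimate,
                               slope = eg$slope$beta, stringsAsFactors = FALSE),
                    data.frame(method = "weighted_median", intercept = 0,
                               slope = wm$beta, stringsAsFactors = FALSE))
  }
  paths <- file.path(out_dir, c("scatter.tsv", "forest.tsv", "funnel.tsv",
                                "slopes.tsv"))
  tables <- list(scatter = scatter, forest = forest, funnel = funnel,
                 slopes = slopes)
  for (i in seq_along(tables)) {
    utils::write.table(tables[[i]], paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(tables = tables, paths = paths))
}
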