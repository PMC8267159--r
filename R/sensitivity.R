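#' Per-instrument Wald ratio estimates
#'
#' The "single SNP" analysis: each instrument's causal estimate on its own,
#' used to see whether one variant alone drives the combined result.
#'
#' @param h A [harmonized_set()].
#' @return Data frame with one row per instrument: `variant_id`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`.
#' @export
single_snp_analysis <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (any(h$gamma == 0)) {
    .mratlas_error("mratlas_undefined_ratio",
                   "zero variant-exposure effect among instruments")
  }
  beta <- h$Gamma / h$gamma
  se <- h$se_y / abs(h$gamma)
  data.frame(variant_id = h$variant_id, beta = beta, se = se,
             ci_low = beta - .z975 * se, ci_high = beta + .z975 * se,
             pval = 2 * pnorm(-abs(beta / se)), stringsAsFactors = FALSE)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect J times, omitting one instrument each time.
#' A row whose estimate departs sharply from the rest flags an instrument
#' that drives the combined effect single-handedly.
#'
#' @param h A [harmonized_set()] with at least three instruments (omitting
#'   one must leave a combinable set).
#' @param random Error model passed to [mr_ivw()].
#' @return Data frame with one row per omitted instrument: `omitted`,
#'   `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
leave_one_out <- function(h, random = "mult") {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 3L) {
    .mratlas_error("mratlas_dispatch_error",
                   "leave-one-out needs >= 3 instruments so each subset keeps >= 2")
  }
  rows <- lapply(seq_len(J), function(j) {
    e <- mr_ivw(.subset_h(h, -j), random = random)
    data.frame(omitted = h$variant_id[j], n_snp = e$n_snp, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.subset_h <- function(h, idx) {
  d <- as.data.frame(h)[idx, , drop = FALSE]
  harmonized_set(d$variant_id, d$gamma, d$se_x, d$Gamma, d$se_y,
                 effect_allele = d$effect_allele, other_allele = d$other_allele,
                 eaf = d$eaf, palindromic = d$palindromic, flipped = d$flipped,
                 exposure = attr(h, "exposure"), outcome = attr(h, "outcome"))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept of the MR-Egger regression with its SE and a
#' two-sided t test on J - 2 degrees of freedom. An intercept credibly
#' different from zero means the instruments' average pleiotropic effect is
#' directional, biasing IVW; the Egger slope is then the preferred estimate.
#'
#' @param h A [harmonized_set()] with at least three instruments.
#' @return A list with `intercept`, `se`, `pval`, `df`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)
  list(intercept = e$extras$egger_intercept,
       se = e$extras$egger_intercept_se,
       pval = e$extras$egger_intercept_p,
       df = e$extras$df)
}

#' Funnel-plot data
#'
#' Per-instrument ratio estimates against their precision (1/SE of the
#' ratio). Symmetric scatter about the combined estimate argues against
#' directional pleiotropy; the formal counterpart is
#' [egger_intercept_test()].
#'
#' @param h A [harmonized_set()].
#' @return Data frame with `variant_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(h) {
  s <- single_snp_analysis(h)
  data.frame(variant_id = s$variant_id, ratio = s$beta,
             precision = 1 / s$se, stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity statistic
#'
#' @param h A [harmonized_set()] with at least two instruments.
#' @return A list with `q_stat`, `q_df`, `pval` (upper-tail chi-squared).
#' @export
cochran_q <- function(h) {
  e <- mr_ivw(h)
  list(q_stat = e$extras$q_stat, q_df = e$extras$q_df,
       pval = stats::pchisq(e$extras$q_stat, e$extras$q_df, lower.tail = FALSE))
}

#' Assemble the full sensitivity report for one trait pair
#'
#' Runs every component the instrument count permits: single-SNP and
#' leave-one-out tables, Cochran's Q, the Egger intercept test, funnel data,
#' and the MR-PRESSO battery (which needs at least four instruments).
#' Components that cannot run are set to `NULL` with the reason recorded in
#' `$not_performed`.
#'
#' @param h A [harmonized_set()].
#' @param n_sim MR-PRESSO simulation count (default 1000).
#' @param seed Integer seed for the stochastic components.
#' @param presso_alpha Significance level for the PRESSO global test gate.
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1L, presso_alpha = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  rep_ <- list(single_snp = NULL, loo = NULL, q = NULL, egger = NULL,
               funnel = NULL, presso = NULL, not_performed = character(0))
  skip <- function(what, why) {
    rep_$not_performed[[what]] <<- why
  }
  rep_$single_snp <- single_snp_analysis(h)
  rep_$funnel <- funnel_data(h)
  if (J >= 2L) rep_$q <- cochran_q(h) else skip("q", "needs >= 2 instruments")
  if (J >= 3L) {
    rep_$loo <- leave_one_out(h)
    rep_$egger <- egger_intercept_test(h)
  } else {
    skip("loo", "needs >= 3 instruments")
    skip("egger", "needs >= 3 instruments")
  }
  if (J >= 4L) {
    rep_$presso <- mr_presso(h, n_sim = n_sim, seed = seed,
                             alpha_global = presso_alpha)
  } else {
    skip("presso", "needs >= 4 instruments")
  }
  class(rep_) <- "sensitivity_report"
  rep_
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df (p = %.3g)\n",
                x$q$q_stat, x$q$q_df, x$q$pval))
  }
  if (!is.null(x$egger)) {
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)\n",
                x$egger$intercept, x$egger$pval))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.3g; %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  }
  if (length(x$not_performed)) {
    cat("  not performed:",
        paste(names(x$not_performed), unlist(x$not_performed),
              sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Serialize a sensitivity report as a multi-section TSV bundle
#'
#' Writes one file per table (`single_snp.tsv`, `loo.tsv`, `funnel.tsv`,
#' `presso.tsv`) plus `summary.txt` into `dir`.
#'
#' @param report A [sensitivity_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sensitivity_bundle <- function(report, dir) {
  stopifnot(inherits(report, "sensitivity_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "NA")
    }
  }
  wt(report$single_snp, "single_snp.tsv")
  wt(report$loo, "loo.tsv")
  wt(report$funnel, "funnel.tsv")
  if (!is.null(report$presso)) {
    p <- report$presso
    wt(data.frame(variant_id = names(p$outlier_p),
                  outlier_p = unname(p$outlier_p),
                  flagged = names(p$outlier_p) %in% p$outliers),
       "presso.tsv")
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(report); sink(); close(con)
  invisible(dir)
}
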