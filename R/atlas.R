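#' Configuration for an atlas run
#'
#' Bundles the exposure panel, the outcome panel(s), and every threshold the
#' pipeline applies, so a run is fully described by one object plus a master
#' seed.
#'
#' @param exposures Named list of [summary_stats()] exposure panels.
#' @param outcomes Named list of [summary_stats()] outcome panels (binary,
#'   carrying case/control counts as attributes).
#' @param p_instrument Instrument-selection threshold (default 5e-8).
#' @param clump_r2,clump_kb LD-clumping parameters (defaults 0.001 and
#'   10,000 kb).
#' @param ld Optional [ld_matrix()] shared by all exposures; when `NULL`
#'   clumping is skipped (synthetic panels are generated independent).
#' @param n_tests Bonferroni denominator for tiering; default 60, the
#'   conventional trait-panel correction, regardless of panel size (set it
#'   to `length(exposures)` for a self-contained panel).
#' @param seed Master seed; per-pair streams are derived by stable hashing
#'   of `"exposure|outcome"`.
#' @param n_boot Weighted-median bootstrap draws per pair.
#' @param n_sim MR-PRESSO simulations per pair.
#' @param egger_substitution Replace the headline estimate with MR-Egger
#'   when its intercept test is significant at 0.05 (default `TRUE`).
#' @return An `atlas_config` list.
#' @export
atlas_config <- function(exposures, outcomes, p_instrument = 5e-8,
                         clump_r2 = 0.001, clump_kb = 10000, ld = NULL,
                         n_tests = 60L, seed = 1L, n_boot = 1000L,
                         n_sim = 1000L, egger_substitution = TRUE) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  .assert_prob(p_instrument, "p_instrument", open_right = TRUE)
  stopifnot(n_tests >= 1)
  structure(list(exposures = exposures, outcomes = outcomes,
                 p_instrument = p_instrument, clump_r2 = clump_r2,
                 clump_kb = clump_kb, ld = ld, n_tests = as.integer(n_tests),
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 n_sim = as.integer(n_sim),
                 egger_substitution = isTRUE(egger_substitution)),
            class = "atlas_config")
}

#' Classify a p-value into the Bonferroni evidence tiers
#'
#' `"significant"` below the Bonferroni threshold `0.05 / n_tests`,
#' `"suggestive"` between that threshold and 0.05 (strictly below 0.05),
#' `"null"` otherwise. With the conventional 60-trait panel the significant
#' cutoff is 8.33e-4, printed as 0.0008 in reports.
#'
#' @param pval P-value(s) in (0,1]; vectorized.
#' @param n_tests Number of tests corrected for (>= 1).
#' @return Character vector of tiers.
#' @export
classify_tier <- function(pval, n_tests) {
  stopifnot(all(pval > 0), all(pval <= 1), n_tests >= 1)
  cutoff <- 0.05 / n_tests
  ifelse(pval < cutoff, "significant",
         ifelse(pval < 0.05, "suggestive", "null"))
}

# headline rule: wald for J = 1, else IVW, with MR-Egger substituted when
# its intercept test flags directional pleiotropy
.headline <- function(estimates, egger_substitution = TRUE) {
  name <- attr(estimates, "headline")
  if (egger_substitution && !is.null(estimates$mr_egger)) {
    ip <- estimates$mr_egger$extras$egger_intercept_p
    if (!is.null(ip) && ip < 0.05) name <- "mr_egger"
  }
  list(method = name, estimate = estimates[[name]])
}

#' Run the full MR atlas over every exposure-outcome pair
#'
#' For each pair: select instruments at `p_instrument`, clump (when an LD
#' matrix is configured), harmonize, run every estimator the instrument
#' count permits, run the sensitivity battery and the power profile, and
#' tier the headline p-value. Failures are isolated per pair: a trait whose
#' instruments vanish (or that cannot be harmonized) is reported with
#' status `"not_analyzable"` and the pipeline continues. Given the same
#' config and master seed the result — including [atlas_table()] output —
#' is reproduced exactly.
#'
#' @param config An [atlas_config()].
#' @return An `atlas_result` list of per-pair records, each with `exposure`,
#'   `outcome`, `status`, `estimates`, `headline`, `headline_method`,
#'   `sensitivity`, `power`, `tier`. The Bonferroni cutoff is attached as
#'   attribute `"bonferroni"`.
#' @export
run_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  results <- list()
  for (ex_name in names(config$exposures)) {
    for (out_name in names(config$outcomes)) {
      key <- paste0(ex_name, "|", out_name)
      pair_seed <- derive_seed(config$seed, key)
      rec <- list(exposure = ex_name, outcome = out_name, status = "ok",
                  estimates = NULL, headline = NULL, headline_method = NA_character_,
                  sensitivity = NULL, power = NULL, tier = NA_character_,
                  message = NA_character_)
      res <- tryCatch({
        instruments <- select_instruments(config$exposures[[ex_name]],
                                          config$p_instrument)
        if (!is.null(config$ld)) {
          instruments <- ld_clump(instruments, config$ld,
                                  r2_max = config$clump_r2,
                                  window_kb = config$clump_kb)
        }
        h <- harmonize(instruments, config$outcomes[[out_name]])
        est <- mr_all(h, n_boot = config$n_boot,
                      seed = derive_seed(pair_seed, "wme"))
        head_ <- .headline(est, config$egger_substitution)
        rec$estimates <- est
        rec$headline <- head_$estimate
        rec$headline_method <- head_$method
        rec$sensitivity <- sensitivity_report(h, n_sim = config$n_sim,
                                              seed = derive_seed(pair_seed, "presso"))
        oc <- config$outcomes[[out_name]]
        rec$power <- tryCatch(
          power_profile(instruments, n_cases = attr(oc, "n_cases"),
                        n_controls = attr(oc, "n_controls")),
          error = function(e) NULL)  # e.g. missing EAF: diagnostics only
        rec$tier <- classify_tier(head_$estimate$pval, config$n_tests)
        rec
      }, mratlas_error = function(e) {
        rec$status <- "not_analyzable"
        rec$message <- conditionMessage(e)
        rec
      })
      results[[key]] <- res
    }
  }
  structure(results, class = "atlas_result",
            bonferroni = 0.05 / config$n_tests, n_tests = config$n_tests,
            seed = config$seed)
}

#' @export
print.atlas_result <- function(x, ...) {
  cat(sprintf("<atlas_result> %d pair(s); Bonferroni cutoff %.4f (0.05/%d)\n",
              length(x), attr(x, "bonferroni"), attr(x, "n_tests")))
  print(atlas_table(x))
  invisible(x)
}

#' Flatten an atlas result into the reporting table
#'
#' One row per analyzed (exposure, outcome, method); not-analyzable pairs
#' get a single row with `NA` estimates and the failure message. The
#' headline method is marked in `headline`, and `tier` repeats the pair's
#' tier on each of its rows.
#'
#' @param results An [run_atlas()] result.
#' @return A data frame.
#' @export
atlas_table <- function(results) {
  stopifnot(inherits(results, "atlas_result"))
  rows <- lapply(results, function(r) {
    if (r$status != "ok") {
      return(data.frame(exposure = r$exposure, outcome = r$outcome,
                        method = NA_character_, n_snp = NA_integer_,
                        beta = NA_real_, se = NA_real_, or = NA_real_,
                        or_low = NA_real_, or_high = NA_real_, pval = NA_real_,
                        q_stat = NA_real_, q_df = NA_integer_,
                        egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                        headline = FALSE, tier = "not_analyzable",
                        note = r$message, stringsAsFactors = FALSE))
    }
    tb <- estimates_table(r$estimates, r$exposure, r$outcome)
    tb$headline <- tb$method == r$headline_method
    tb$tier <- r$tier
    tb$note <- NA_character_
    tb
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write atlas results and run metadata to a directory
#'
#' Emits `results.tsv` (the [atlas_table()]), `run_log.txt` with the seeds
#' and thresholds, and one sensitivity bundle per analyzed pair under
#' `sensitivity/<exposure>__<outcome>/`.
#'
#' @param results An [run_atlas()] result.
#' @param dir Output directory.
#' @param config The [atlas_config()] used (for the log).
#' @return `dir`, invisibly.
#' @export
write_atlas_results <- function(results, dir, config = NULL) {
  stopifnot(inherits(results, "atlas_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tb <- atlas_table(results)
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], function(x) signif(x, 10))  # byte-stable formatting
  write.table(tb, file.path(dir, "results.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", eol = "\n")
  log_lines <- c(
    sprintf("pairs analyzed: %d", length(results)),
    sprintf("master seed: %d", attr(results, "seed")),
    sprintf("bonferroni threshold: %.4f (0.05/%d)",
            attr(results, "bonferroni"), attr(results, "n_tests")))
  if (!is.null(config)) {
    log_lines <- c(log_lines,
                   sprintf("instrument p threshold: %g", config$p_instrument),
                   sprintf("clump r2/window: %g / %g kb", config$clump_r2,
                           config$clump_kb),
                   sprintf("n_boot/n_sim: %d / %d", config$n_boot, config$n_sim))
  }
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  for (key in names(results)) {
    r <- results[[key]]
    if (r$status == "ok" && !is.null(r$sensitivity)) {
      write_sensitivity_bundle(r$sensitivity,
                               file.path(dir, "sensitivity",
                                         gsub("\\|", "__", key)))
    }
  }
  invisible(dir)
}
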