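#' Variance in the exposure explained by the instruments
#'
#' Standardized-trait approximation: each variant contributes
#' `2 * eaf * (1 - eaf) * beta^2` with `beta` in per-SD units, and the
#' contributions add (instruments are taken as independent after clumping).
#' Clipped to \[0,1\].
#'
#' @param stats A [summary_stats()] object whose records all carry `eaf`.
#' @return R-squared as a single number.
#' @export
variance_explained <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"))
  miss <- stats$variant_id[is.na(stats$eaf)]
  if (length(miss)) {
    stop(sprintf("missing eaf for %d variant(s): %s", length(miss),
                 paste(head(miss, 5L), collapse = ", ")), call. = FALSE)
  }
  min(1, max(0, sum(2 * stats$eaf * (1 - stats$eaf) * stats$beta^2)))
}

#' Instrument-strength F-statistic
#'
#' Default is the single-regressor convention
#' `F = R^2 * (n - 2) / (1 - R^2)`; with `k > 1` the k-regressor form
#' `F = (R^2 / k) * (n - k - 1) / (1 - R^2)` is used instead. Values below
#' about 10 signal weak-instrument bias.
#'
#' @param r_squared Variance explained, in \[0,1).
#' @param n Sample size of the study the R-squared refers to (> 2).
#' @param k Number of instruments for the k-regressor form (default 1).
#' @return The F-statistic (>= 0).
#' @export
f_statistic <- function(r_squared, n, k = 1L) {
  stopifnot(is.numeric(r_squared), r_squared >= 0, n > 2, k >= 1)
  if (r_squared >= 1) stop("`r_squared` must be < 1", call. = FALSE)
  if (k == 1L) {
    r_squared * (n - 2) / (1 - r_squared)
  } else {
    (r_squared / k) * (n - k - 1) / (1 - r_squared)
  }
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Normal-approximation power for detecting an assumed odds ratio per SD of
#' exposure:
#' `power = pnorm(sqrt(n * R2 * K(1-K)) * |log(OR)| - z_{1-alpha/2})`,
#' where `n` is the total outcome sample size and `K` the case fraction.
#' By default the balanced convention `K(1-K) = 0.25` is used; pass
#' `k_cases` with `balanced = FALSE` to use the observed case fraction.
#' Symmetric in `OR` and `1/OR`. At `OR = 1` the formula returns the
#' `alpha/2` tail mass (about 0.025 at the default alpha), not an error.
#'
#' @param r_squared Variance in the exposure explained by the instruments.
#' @param n_outcome Total outcome sample size (cases + controls).
#' @param or_assumed Assumed odds ratio(s) per SD; vectorized.
#' @param k_cases Case fraction in (0,1); only used when `balanced = FALSE`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param balanced Use `K(1-K) = 0.25` (default) instead of the observed
#'   case fraction.
#' @return Power value(s) in \[0,1\], same length as `or_assumed`.
#' @export
mr_power_binary <- function(r_squared, n_outcome, or_assumed,
                            k_cases = NULL, alpha = 0.05, balanced = TRUE) {
  stopifnot(r_squared >= 0, r_squared <= 1, n_outcome > 0, all(or_assumed > 0))
  .assert_prob(alpha, "alpha")
  kk <- if (balanced) 0.25 else {
    if (is.null(k_cases)) stop("`k_cases` needed when balanced = FALSE", call. = FALSE)
    .assert_prob(k_cases, "k_cases")
    k_cases * (1 - k_cases)
  }
  z <- qnorm(1 - alpha / 2)
  pnorm(sqrt(n_outcome * r_squared * kk) * abs(log(or_assumed)) - z)
}

#' Instrument-strength and power profile for one exposure-outcome pair
#'
#' Assembles the standard diagnostics row: variance explained, F-statistic,
#' power at the four conventional odds-ratio levels (1.10, 1.20, 1.33, 1.50
#' per SD, symmetric with 0.91, 0.83, 0.75, 0.67), and weak-instrument flags
#' at the conventional cutoffs (F below 10; best power below 80%).
#'
#' @param stats A [summary_stats()] exposure panel (instruments only), or
#'   `NULL` if `r_squared` is given directly.
#' @param n_cases,n_controls Outcome sample sizes.
#' @param r_squared Optional R-squared overriding [variance_explained()].
#' @param or_levels Odds-ratio grid (default `c(1.10, 1.20, 1.33, 1.50)`).
#' @param alpha Significance level for the power calculation.
#' @param balanced Passed to [mr_power_binary()].
#' @return A `power_profile` list: `trait_name`, `r_squared`, `f_stat`,
#'   `n_outcome`, `k_cases`, `power_at` (named by OR level), `weak_f`,
#'   `weak_power`.
#' @export
power_profile <- function(stats = NULL, n_cases, n_controls, r_squared = NULL,
                          or_levels = c(1.10, 1.20, 1.33, 1.50),
                          alpha = 0.05, balanced = TRUE) {
  if (is.null(r_squared)) {
    stopifnot(inherits(stats, "summary_stats"))
    r_squared <- variance_explained(stats)
  }
  n_outcome <- n_cases + n_controls
  k_cases <- n_cases / n_outcome
  pw <- mr_power_binary(r_squared, n_outcome, or_levels,
                        k_cases = k_cases, alpha = alpha, balanced = balanced)
  names(pw) <- format(or_levels, nsmall = 2)
  structure(list(trait_name = if (!is.null(stats)) trait_name(stats) else NA_character_,
                 r_squared = r_squared,
                 f_stat = f_statistic(r_squared, n_outcome),
                 n_outcome = n_outcome, k_cases = k_cases,
                 power_at = pw,
                 weak_f = f_statistic(r_squared, n_outcome) < 10,
                 weak_power = max(pw) < 0.80),
            class = "power_profile")
}

#' @export
print.power_profile <- function(x, ...) {
  cat(sprintf("<power_profile> %s: R2 = %.4f, F = %.2f (N = %d)\n",
              x$trait_name, x$r_squared, x$f_stat, x$n_outcome))
  cat("  power:", paste(sprintf("OR %s: %.2f", names(x$power_at), x$power_at),
                        collapse = " | "), "\n")
  if (x$weak_f) cat("  WARNING: F below 10 (weak instruments)\n")
  if (x$weak_power) cat("  WARNING: power below 80% at every OR level\n")
  invisible(x)
}

#' Tabulate power profiles in the diagnostics-table layout
#'
#' @param profiles A list of [power_profile()] objects.
#' @return A data frame with one row per trait: R-squared, power at each OR
#'   level (2 decimals), F (2 decimals).
#' @export
power_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    out <- data.frame(trait = p$trait_name, r_squared = p$r_squared,
                      stringsAsFactors = FALSE)
    for (nm in names(p$power_at)) {
      out[[paste0("power_or_", trimws(nm))]] <- round(p$power_at[[nm]], 2)
    }
    out$f_stat <- round(p$f_stat, 2)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
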