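#' Causal-effect estimate from one MR method
#'
#' Container for a single method's result: the causal effect `beta` on the
#' log-odds-per-SD scale, its standard error, normal (or t, for MR-Egger)
#' 95% confidence interval and two-sided p-value, the exponentiated
#' odds-ratio scale, the number of instruments, and method-specific extras
#' (Egger intercept triple, heterogeneity Q and its df, fixed-effect SE).
#'
#' @param method One of `"wald_ratio"`, `"ivw"`, `"mr_egger"`,
#'   `"weighted_median"`.
#' @param beta,se Point estimate and standard error.
#' @param ci_low,ci_high 95% confidence bounds.
#' @param pval Two-sided p-value.
#' @param n_snp Number of instruments used.
#' @param extras Named list of method-specific quantities.
#' @return An `mr_estimate` object.
#' @export
mr_estimate <- function(method, beta, se, ci_low, ci_high, pval, n_snp,
                        extras = list()) {
  stopifnot(ci_low <= beta + 1e-12, beta <= ci_high + 1e-12, se >= 0)
  pval <- min(max(pval, .Machine$double.xmin), 1)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
                 n_snp = as.integer(n_snp), extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (nSNP = %d)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$beta, x$se, x$or, x$or_low, x$or_high, x$pval))
  if (!is.null(x$extras$egger_intercept)) {
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$extras$egger_intercept, x$extras$egger_intercept_se,
                x$extras$egger_intercept_p))
  }
  if (!is.null(x$extras$q_stat)) {
    cat(sprintf("  Q = %.3f on %d df\n", x$extras$q_stat, x$extras$q_df))
  }
  invisible(x)
}

.z975 <- qnorm(0.975)

.norm_estimate <- function(method, beta, se, n_snp, extras = list()) {
  z <- if (se > 0) beta / se else sign(beta) * Inf
  mr_estimate(method, beta, se,
              ci_low = beta - .z975 * se, ci_high = beta + .z975 * se,
              pval = 2 * pnorm(-abs(z)), n_snp = n_snp, extras = extras)
}

#' Wald ratio estimate from a single instrument
#'
#' The variant-outcome effect divided by the variant-exposure effect,
#' with a first-order delta-method standard error `se_y / |gamma|` (the
#' exposure-side uncertainty is second order for the strong, genome-wide
#' significant instruments this design selects).
#'
#' @param h A [harmonized_set()] with exactly one instrument.
#' @return An [mr_estimate()] with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h) != 1L) {
    .mratlas_error("mratlas_dispatch_error",
                   sprintf("wald ratio requires exactly 1 instrument, got %d", nrow(h)))
  }
  if (h$gamma == 0) {
    .mratlas_error("mratlas_undefined_ratio",
                   "variant-exposure effect is zero; ratio undefined")
  }
  .norm_estimate("wald_ratio", h$Gamma / h$gamma, h$se_y / abs(h$gamma), 1L)
}

# closed-form IVW sums; also used by leave-one-out and MR-PRESSO
.ivw_sums <- function(gamma, Gamma, se_y) {
  w <- 1 / se_y^2
  s_xx <- sum(gamma^2 * w)
  s_xy <- sum(gamma * Gamma * w)
  beta <- s_xy / s_xx
  list(w = w, s_xx = s_xx, beta = beta,
       q = sum(w * (Gamma - beta * gamma)^2))
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted combination of per-variant Wald ratios, computed as the
#' slope of the zero-intercept regression of outcome effects on exposure
#' effects with weights `1/se_y^2`. Three error models are offered:
#' `"mult"` (default) inflates the fixed-effect SE by
#' `max(1, sqrt(Q/(J-1)))` — multiplicative random effects, the conventional
#' "adjusting for heterogeneity"; `"fixed"` reports the fixed-effect SE;
#' `"additive"` uses DerSimonian-Laird additive random effects on the
#' per-variant ratios. Cochran's Q and its df are returned in `extras`
#' along with the fixed-effect SE.
#'
#' @param h A [harmonized_set()] with at least two instruments.
#' @param random One of `"mult"`, `"fixed"`, `"additive"`.
#' @return An [mr_estimate()] with method `"ivw"`.
#' @export
mr_ivw <- function(h, random = c("mult", "fixed", "additive")) {
  stopifnot(inherits(h, "harmonized_set"))
  random <- match.arg(random)
  J <- nrow(h)
  if (J < 2L) {
    .mratlas_error("mratlas_dispatch_error",
                   sprintf("IVW requires >= 2 instruments, got %d", J))
  }
  if (any(h$gamma == 0)) {
    .mratlas_error("mratlas_undefined_ratio",
                   "zero variant-exposure effect among instruments")
  }
  s <- .ivw_sums(h$gamma, h$Gamma, h$se_y)
  se_fixed <- 1 / sqrt(s$s_xx)
  df <- J - 1L
  if (random == "mult") {
    beta <- s$beta
    se <- se_fixed * max(1, sqrt(s$q / df))
  } else if (random == "fixed") {
    beta <- s$beta
    se <- se_fixed
  } else {
    r <- h$Gamma / h$gamma
    v <- (h$se_y / h$gamma)^2
    wf <- 1 / v
    qr_ <- sum(wf * (r - sum(wf * r) / sum(wf))^2)
    tau2 <- max(0, (qr_ - df) / (sum(wf) - sum(wf^2) / sum(wf)))
    wr <- 1 / (v + tau2)
    beta <- sum(wr * r) / sum(wr)
    se <- 1 / sqrt(sum(wr))
  }
  .norm_estimate("ivw", beta, se, J,
                 extras = list(q_stat = s$q, q_df = df, se_fixed = se_fixed,
                               random = random))
}

# weighted two-parameter WLS used by MR-Egger; weights 1/se_y^2,
# instruments oriented to non-negative exposure effects first
.egger_fit <- function(gamma, Gamma, se_y) {
  flip <- sign(gamma) < 0
  g <- ifelse(flip, -gamma, gamma)
  G <- ifelse(flip, -Gamma, Gamma)
  w <- 1 / se_y^2
  sw <- sum(w); sx <- sum(w * g); sy <- sum(w * G)
  sxx <- sum(w * g^2); sxy <- sum(w * g * G)
  det <- sw * sxx - sx^2
  if (abs(det) < 1e-14 * sw * sxx || sxx == 0) {
    .mratlas_error("mratlas_collinear",
                   "degenerate design: exposure effects carry no spread")
  }
  slope <- (sw * sxy - sx * sy) / det
  inter <- (sxx * sy - sx * sxy) / det
  resid <- G - inter - slope * g
  df <- length(g) - 2L
  sigma2 <- sum(w * resid^2) / df
  disp <- max(1, sqrt(sigma2))  # floored multiplicative dispersion
  se_slope <- sqrt(sw / det) * disp
  se_inter <- sqrt(sxx / det) * disp
  list(slope = slope, intercept = inter, se_slope = se_slope,
       se_inter = se_inter, df = df, sigma = sqrt(sigma2))
}

#' MR-Egger regression estimate
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept, weights `1/se_y^2`, after orienting every instrument so its
#' exposure effect is non-negative. The slope is the pleiotropy-adjusted
#' causal estimate; a non-zero intercept indicates directional pleiotropy.
#' Standard errors carry a multiplicative dispersion floored at 1 (never
#' shrinking below the fixed-effect error) and inference is t-based with
#' J - 2 degrees of freedom. The intercept triple is stored in `extras` and
#' consumed by [egger_intercept_test()].
#'
#' @param h A [harmonized_set()] with at least three instruments.
#' @return An [mr_estimate()] with method `"mr_egger"`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 3L) {
    .mratlas_error("mratlas_dispatch_error",
                   sprintf("MR-Egger requires >= 3 instruments, got %d", J))
  }
  f <- .egger_fit(h$gamma, h$Gamma, h$se_y)
  tcrit <- stats::qt(0.975, f$df)
  mr_estimate("mr_egger", f$slope, f$se_slope,
              ci_low = f$slope - tcrit * f$se_slope,
              ci_high = f$slope + tcrit * f$se_slope,
              pval = 2 * pt(-abs(f$slope / f$se_slope), f$df),
              n_snp = J,
              extras = list(egger_intercept = f$intercept,
                            egger_intercept_se = f$se_inter,
                            egger_intercept_p = 2 * pt(-abs(f$intercept / f$se_inter), f$df),
                            df = f$df, sigma = f$sigma))
}

# weighted median of ratio estimates by cumulative-weight interpolation
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median of the per-variant ratio estimates, with
#' inverse-variance weights `gamma^2 / se_y^2`. Consistent as long as valid
#' instruments contribute more than half the total weight, which is what
#' makes it the standard robustness companion to IVW. The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' resampled from normal distributions centred at the observed values with
#' their reported SEs, the weighted median recomputed, and the SD of the
#' bootstrap estimates taken. The point estimate itself is deterministic;
#' only the SE is stochastic, hence the mandatory seed.
#'
#' @param h A [harmonized_set()] with at least three instruments.
#' @param n_boot Number of bootstrap draws (>= 100; default 1000).
#' @param seed Integer seed for the bootstrap (required).
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 3L) {
    .mratlas_error("mratlas_dispatch_error",
                   sprintf("weighted median requires >= 3 instruments, got %d", J))
  }
  if (missing(seed)) stop("`seed` is required for the bootstrap SE", call. = FALSE)
  stopifnot(n_boot >= 100)
  w <- h$gamma^2 / h$se_y^2
  est <- .weighted_median(h$Gamma / h$gamma, w)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gb <- matrix(rnorm(n_boot * J, h$gamma, h$se_x), n_boot, J, byrow = TRUE)
  Gb <- matrix(rnorm(n_boot * J, h$Gamma, h$se_y), n_boot, J, byrow = TRUE)
  boots <- vapply(seq_len(n_boot), function(b) {
    .weighted_median(Gb[b, ] / gb[b, ], gb[b, ]^2 / h$se_y^2)
  }, numeric(1))
  .norm_estimate("weighted_median", est, sd(boots), J,
                 extras = list(n_boot = n_boot, seed = seed))
}

#' Run every estimator the instrument count permits
#'
#' Dispatch follows the instrument count: one instrument gives the Wald
#' ratio alone; two give IVW alone; three or more give IVW, MR-Egger and the
#' weighted median. The headline estimate (attribute `"headline"`) is the
#' Wald ratio for a single instrument and IVW otherwise.
#'
#' @param h A [harmonized_set()].
#' @param n_boot,seed Passed to [mr_weighted_median()] when it runs.
#' @return A named list of [mr_estimate()] objects with attribute
#'   `"headline"` naming the headline method.
#' @export
mr_all <- function(h, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  out <- if (J == 1L) {
    list(wald_ratio = mr_wald_ratio(h))
  } else if (J == 2L) {
    list(ivw = mr_ivw(h))
  } else {
    list(ivw = mr_ivw(h),
         mr_egger = mr_egger(h),
         weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed))
  }
  attr(out, "headline") <- if (J == 1L) "wald_ratio" else "ivw"
  out
}

#' Tabulate MR estimates for reporting
#'
#' One row per method, with the column layout used by the atlas results TSV.
#'
#' @param estimates A list of [mr_estimate()] (e.g. from [mr_all()]).
#' @param exposure,outcome Trait labels for the first two columns.
#' @return A data frame.
#' @export
estimates_table <- function(estimates, exposure = "exposure", outcome = "outcome") {
  rows <- lapply(estimates, function(e) {
    data.frame(exposure = exposure, outcome = outcome, method = e$method,
               n_snp = e$n_snp, beta = e$beta, se = e$se, or = e$or,
               or_low = e$or_low, or_high = e$or_high, pval = e$pval,
               q_stat = e$extras$q_stat %||% NA_real_,
               q_df = e$extras$q_df %||% NA_integer_,
               egger_intercept = e$extras$egger_intercept %||% NA_real_,
               egger_intercept_p = e$extras$egger_intercept_p %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
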