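# MR-PRESSO: residual-sum-of-squares battery for horizontal pleiotropy.
# The observed statistic uses leave-one-out IVW predictions so a pleiotropic
# instrument cannot mask itself by dragging the slope; the null distribution
# comes from parametric simulation of both effect panels.

# leave-one-out IVW slopes from running sums; O(J)
.loo_betas <- function(gamma, Gamma, w) {
  s_xx <- sum(gamma^2 * w)
  s_xy <- sum(gamma * Gamma * w)
  (s_xy - gamma * Gamma * w) / (s_xx - gamma^2 * w)
}

# simulate n_sim replicate panels and return the per-SNP simulated squared
# weighted residuals (n_sim x J) under the no-pleiotropy null
.presso_sim <- function(h, n_sim) {
  J <- nrow(h)
  w <- 1 / h$se_y^2
  b_loo <- .loo_betas(h$gamma, h$Gamma, w)
  mu_y <- b_loo * h$gamma
  Gs <- matrix(rnorm(n_sim * J, rep(mu_y, each = n_sim), rep(h$se_y, each = n_sim)),
               n_sim, J)
  gs <- matrix(rnorm(n_sim * J, rep(h$gamma, each = n_sim), rep(h$se_x, each = n_sim)),
               n_sim, J)
  W <- matrix(w, n_sim, J, byrow = TRUE)
  s_xx <- rowSums(gs^2 * W)
  s_xy <- rowSums(gs * Gs * W)
  b_loo_sim <- (s_xy - gs * Gs * W) / (s_xx - gs^2 * W)
  W * (Gs - b_loo_sim * gs)^2
}

.presso_obs <- function(h) {
  w <- 1 / h$se_y^2
  b_loo <- .loo_betas(h$gamma, h$Gamma, w)
  w * (h$Gamma - b_loo * h$gamma)^2
}

#' MR-PRESSO global test for horizontal pleiotropy
#'
#' The observed statistic is the weighted residual sum of squares of each
#' instrument against its leave-one-out IVW prediction. Its null
#' distribution is built by `n_sim` parametric simulations (outcome effects
#' drawn about the leave-one-out predictions, exposure effects about their
#' observed values) and the p-value is the add-one tail frequency, so it is
#' bounded below by `1/(n_sim + 1)`.
#'
#' @param h A [harmonized_set()] with at least four instruments.
#' @param n_sim Number of simulations (>= 1000; default 1000).
#' @param seed Integer seed (required).
#' @return A list with `rss_obs` and `global_p`.
#' @export
presso_global <- function(h, n_sim = 1000, seed) {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h) < 4L) {
    .mratlas_error("mratlas_dispatch_error",
                   sprintf("MR-PRESSO requires >= 4 instruments, got %d", nrow(h)))
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_sim >= 1000)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rss_obs <- sum(.presso_obs(h))
  rss_sim <- rowSums(.presso_sim(h, n_sim))
  list(rss_obs = rss_obs,
       global_p = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1))
}

#' MR-PRESSO outlier test
#'
#' Run after a significant global test. Each instrument's observed squared
#' weighted residual is compared with its own simulated null distribution;
#' the add-one tail frequency is Bonferroni-adjusted across instruments and
#' variants with adjusted p < `alpha` are flagged. The corrected estimate is
#' IVW on the unflagged instruments.
#'
#' @inheritParams presso_global
#' @param alpha Flagging threshold on the Bonferroni-adjusted p (default
#'   0.05).
#' @return A list with `outlier_p` (named, adjusted), `outliers` (flagged
#'   variant IDs), and `beta_corrected` (an [mr_estimate()], or `NULL` when
#'   nothing is flagged).
#' @export
presso_outlier <- function(h, n_sim = 1000, seed, alpha = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  if (J < 4L) {
    .mratlas_error("mratlas_dispatch_error",
                   sprintf("MR-PRESSO requires >= 4 instruments, got %d", J))
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  obs <- .presso_obs(h)
  sim <- .presso_sim(h, n_sim)
  p_raw <- (1 + colSums(sim >= rep(obs, each = n_sim))) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * J)
  names(p_adj) <- h$variant_id
  outliers <- h$variant_id[p_adj < alpha]
  if (length(outliers) == J) {
    .mratlas_error("mratlas_presso_all_outliers",
                   "every instrument flagged; no corrected estimate possible")
  }
  beta_corrected <- if (length(outliers)) {
    mr_ivw(.subset_h(h, !h$variant_id %in% outliers))
  } else NULL
  list(outlier_p = p_adj, outliers = outliers, beta_corrected = beta_corrected)
}

#' MR-PRESSO distortion test
#'
#' Quantifies how much the flagged outliers distort the causal estimate:
#' the statistic is `100 * (beta_corrected - beta_raw) / |beta_corrected|`
#' (a percentage). Its null distribution is built by repeatedly removing the
#' same number of randomly chosen non-outlying instruments and recomputing
#' the shift; the p-value is the two-sided add-one tail frequency.
#'
#' @inheritParams presso_global
#' @param outliers Character vector of flagged variant IDs (non-empty,
#'   strictly fewer than J - 1).
#' @return A list with `distortion_pct` and `distortion_p`.
#' @export
presso_distortion <- function(h, outliers, n_sim = 1000, seed) {
  stopifnot(inherits(h, "harmonized_set"))
  J <- nrow(h)
  m <- length(outliers)
  if (m == 0L) stop("`outliers` must be non-empty", call. = FALSE)
  if (m >= J - 1L) stop("too many outliers to leave a combinable set", call. = FALSE)
  if (!all(outliers %in% h$variant_id)) {
    stop("`outliers` must be instrument variant IDs", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  is_out <- h$variant_id %in% outliers
  beta_raw <- mr_ivw(h)$beta
  beta_corr <- mr_ivw(.subset_h(h, !is_out))$beta
  d_obs <- 100 * (beta_corr - beta_raw) / abs(beta_corr)
  pool <- which(!is_out)
  # null shifts via running sums: removing a subset only subtracts its terms
  w <- 1 / h$se_y^2
  xx <- h$gamma^2 * w
  xy <- h$gamma * h$Gamma * w
  s_xx <- sum(xx); s_xy <- sum(xy)
  d_null <- vapply(seq_len(n_sim), function(s) {
    rm_idx <- sample(pool, m)
    b <- (s_xy - sum(xy[rm_idx])) / (s_xx - sum(xx[rm_idx]))
    100 * (b - beta_raw) / abs(b)
  }, numeric(1))
  # tolerance guards the degenerate homogeneous case, where both observed
  # and null shifts are zero up to floating-point noise
  list(distortion_pct = d_obs,
       distortion_p = (1 + sum(abs(d_null) >= abs(d_obs) - 1e-9)) / (n_sim + 1))
}

#' Full MR-PRESSO battery with its conditional logic
#'
#' Global test first; the outlier test runs only when the global test is
#' significant at `alpha_global`, and the distortion test only when outliers
#' are actually flagged — mirroring how the battery is applied in practice.
#'
#' @inheritParams presso_global
#' @param alpha_global Gate for running the outlier test (default 0.05).
#' @param alpha_outlier Flagging threshold passed to [presso_outlier()].
#' @return A `presso_result` list: `rss_obs`, `global_p`, `outlier_p`,
#'   `outliers`, `beta_raw`, `beta_corrected`, `distortion_pct`,
#'   `distortion_p`, and `performed` (which stages ran).
#' @export
mr_presso <- function(h, n_sim = 1000, seed, alpha_global = 0.05,
                      alpha_outlier = 0.05) {
  g <- presso_global(h, n_sim = n_sim, seed = seed)
  res <- list(rss_obs = g$rss_obs, global_p = g$global_p,
              outlier_p = NULL, outliers = character(0),
              beta_raw = mr_ivw(h), beta_corrected = NULL,
              distortion_pct = NA_real_, distortion_p = NA_real_,
              performed = "global")
  if (g$global_p < alpha_global) {
    o <- presso_outlier(h, n_sim = n_sim, seed = derive_seed(seed, "outlier"),
                        alpha = alpha_outlier)
    res$outlier_p <- o$outlier_p
    res$outliers <- o$outliers
    res$beta_corrected <- o$beta_corrected
    res$performed <- c(res$performed, "outlier")
    if (length(o$outliers) && length(o$outliers) < nrow(h) - 1L) {
      d <- presso_distortion(h, o$outliers, n_sim = n_sim,
                             seed = derive_seed(seed, "distortion"))
      res$distortion_pct <- d$distortion_pct
      res$distortion_p <- d$distortion_p
      res$performed <- c(res$performed, "distortion")
    }
  }
  class(res) <- "presso_result"
  res
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> RSS = %.3f, global p = %.3g\n",
              x$rss_obs, x$global_p))
  if ("outlier" %in% x$performed) {
    cat(sprintf("  outliers: %s\n",
                if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none"))
  }
  if ("distortion" %in% x$performed) {
    cat(sprintf("  distortion = %.1f%%, p = %.3g\n",
                x$distortion_pct, x$distortion_p))
  }
  invisible(x)
}
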