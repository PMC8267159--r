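#' Specification for a synthetic two-sample GWAS pair
#'
#' Describes the generating world for [simulate_gwas_pair()]: a linear causal
#' model on the log-odds scale, `Gamma_j = beta * gamma_j + alpha_j`, where
#' `alpha_j = 0` for valid instruments (the exclusion restriction) and is
#' drawn from `N(mu_alpha, tau_alpha^2)` for the invalid fraction. When
#' `inside = FALSE` the pleiotropic effects are additionally correlated with
#' instrument strength, violating the InSIDE condition MR-Egger relies on.
#' Instruments are oriented to the exposure-increasing allele (all
#' `gamma_j > 0`), the convention under which "directional" pleiotropy is
#' well defined.
#'
#' Default sample sizes mirror a large binary-outcome consortium panel
#' (11,348 cases / 15,861 controls) against a 100,000-strong continuous
#' exposure GWAS. Instrument strength is drawn so every instrument passes
#' the genome-wide threshold comfortably (true association z-scores uniform
#' on `z_range`).
#'
#' @param J Number of instruments (>= 1).
#' @param beta True causal effect, log-odds per SD of exposure.
#' @param maf_range Minor-allele-frequency interval instruments are drawn
#'   from.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param prop_invalid Fraction of instruments with pleiotropic effects, in
#'   \[0,1\].
#' @param mu_alpha,tau_alpha Mean and SD of the pleiotropic effects
#'   (`mu_alpha != 0` makes the pleiotropy directional).
#' @param inside If `FALSE`, pleiotropy is correlated with instrument
#'   strength (InSIDE violated).
#' @param outliers Data frame with columns `index`, `offset` planting
#'   outlier instruments; offsets are in multiples of the variant's outcome
#'   SE.
#' @param ld_blocks Optional list with `sizes` (integer vector) and `rho`
#'   (within-block adjacent correlation) controlling [simulate_ld_matrix()]
#'   and the physical layout of the variants.
#' @param z_range True exposure-association z-score range (default
#'   `c(10, 25)`).
#' @param variant_prefix Prefix for generated variant IDs.
#' @param seed Integer seed; every draw is derived from it.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(J = 30L, beta = 0, maf_range = c(0.1, 0.5),
                           n_exposure = 1e5, n_cases = 11348L,
                           n_controls = 15861L, prop_invalid = 0,
                           mu_alpha = 0, tau_alpha = 0, inside = TRUE,
                           outliers = NULL, ld_blocks = NULL,
                           z_range = c(10, 25), variant_prefix = "rs",
                           seed = 1L) {
  stopifnot(J >= 1, n_exposure > 0, n_cases > 0, n_controls > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5, tau_alpha >= 0,
            z_range[1] > 0, z_range[2] >= z_range[1])
  .assert_prob(prop_invalid, "prop_invalid", open_left = FALSE)
  if (!is.null(outliers)) {
    stopifnot(is.data.frame(outliers), all(c("index", "offset") %in% names(outliers)))
    if (any(outliers$index < 1 | outliers$index > J)) {
      stop("outlier index out of range 1..J", call. = FALSE)
    }
  }
  if (!is.null(ld_blocks)) {
    stopifnot(all(ld_blocks$sizes >= 1), ld_blocks$rho >= 0, ld_blocks$rho < 1)
    if (sum(ld_blocks$sizes) != J) stop("ld block sizes must sum to J", call. = FALSE)
  }
  structure(list(J = as.integer(J), beta = beta, maf_range = maf_range,
                 n_exposure = n_exposure, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 prop_invalid = prop_invalid, mu_alpha = mu_alpha,
                 tau_alpha = tau_alpha, inside = inside, outliers = outliers,
                 ld_blocks = ld_blocks, z_range = z_range,
                 variant_prefix = variant_prefix, seed = as.integer(seed)),
            class = "generator_spec")
}

# physical layout: within a block adjacent variants sit 10 kb apart, blocks
# are separated by 50,000 kb (outside any clumping window); without blocks
# every variant is 20,000 kb from its neighbours
.variant_layout <- function(spec) {
  if (is.null(spec$ld_blocks)) {
    pos <- seq_len(spec$J) * 2e7
  } else {
    pos <- numeric(spec$J)
    at <- 1e6
    i <- 1L
    for (size in spec$ld_blocks$sizes) {
      pos[i:(i + size - 1L)] <- at + (seq_len(size) - 1L) * 1e4
      at <- at + 5e7  # 50,000 kb gap between blocks
      i <- i + size
    }
  }
  list(chrom = rep("1", spec$J),
       pos = pos,
       id = paste0(spec$variant_prefix, seq_len(spec$J)))
}

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Draws exposure and outcome association panels under the generating model
#' described in [generator_spec()]. Exposure SEs follow the standard
#' summary-level form `1 / sqrt(2 f (1-f) n_exposure)`; outcome SEs are on
#' the log-odds scale, `1 / sqrt(2 f (1-f) N K (1-K))` with `K` the case
#' fraction. Estimated effects are the true effects plus seeded normal noise
#' at those SEs; planted outlier offsets are added to the outcome effects
#' last. All variants are A/G (non-palindromic) with identical allele
#' orientation in both panels, so the pair is harmonization-clean by
#' construction.
#'
#' @param spec A [generator_spec()].
#' @return A list with `exposure` and `outcome` ([summary_stats()] objects)
#'   and `truth` (a `synthetic_truth` list holding the spec, the realized
#'   `gamma`, `alpha`, `maf`, and outlier indices).
#' @export
simulate_gwas_pair <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  J <- spec$J
  lay <- .variant_layout(spec)

  maf <- runif(J, spec$maf_range[1], spec$maf_range[2])
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * spec$n_exposure)
  z_true <- runif(J, spec$z_range[1], spec$z_range[2])
  gamma_true <- z_true * se_x  # oriented to the exposure-increasing allele

  n_out <- spec$n_cases + spec$n_controls
  K <- spec$n_cases / n_out
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_out * K * (1 - K))

  n_invalid <- round(spec$prop_invalid * J)
  invalid <- sort(sample.int(J, n_invalid))
  alpha <- numeric(J)
  if (n_invalid > 0) {
    noise <- rnorm(n_invalid, 0, spec$tau_alpha)
    if (spec$inside) {
      alpha[invalid] <- spec$mu_alpha + noise
    } else {
      # tie pleiotropy to instrument strength: InSIDE broken
      g <- gamma_true[invalid]
      strength <- if (length(g) > 1L && sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, length(g))
      alpha[invalid] <- spec$mu_alpha + 0.7 * spec$tau_alpha * strength +
        sqrt(1 - 0.7^2) * noise
    }
  }

  gamma_hat <- gamma_true + rnorm(J, 0, se_x)
  Gamma_true <- spec$beta * gamma_true + alpha
  Gamma_hat <- Gamma_true + rnorm(J, 0, se_y)
  out_idx <- integer(0)
  if (!is.null(spec$outliers)) {
    out_idx <- as.integer(spec$outliers$index)
    Gamma_hat[out_idx] <- Gamma_hat[out_idx] + spec$outliers$offset * se_y[out_idx]
  }

  base <- data.frame(variant_id = lay$id, chrom = lay$chrom, pos = lay$pos,
                     effect_allele = "A", other_allele = "G", eaf = maf,
                     stringsAsFactors = FALSE)
  exposure <- base
  exposure$beta <- gamma_hat
  exposure$se <- se_x
  exposure$pval <- 2 * pnorm(-abs(gamma_hat / se_x))
  exposure$n <- spec$n_exposure
  outcome <- base
  outcome$beta <- Gamma_hat
  outcome$se <- se_y
  outcome$pval <- 2 * pnorm(-abs(Gamma_hat / se_y))
  outcome$n <- n_out

  truth <- structure(list(spec = spec, gamma = gamma_true, alpha = alpha,
                          maf = maf, invalid = invalid, outliers = out_idx),
                     class = "synthetic_truth")
  list(exposure = summary_stats(exposure, paste0(spec$variant_prefix, "exposure"),
                                "continuous"),
       outcome = summary_stats(outcome, paste0(spec$variant_prefix, "outcome"),
                               "binary", n_cases = spec$n_cases,
                               n_controls = spec$n_controls),
       truth = truth)
}

#' Simulate a block-diagonal LD matrix with AR(1) decay
#'
#' Within each block the correlation between variants `i` and `j` is
#' `rho^|i-j|` (so r^2 decays as `rho^2, rho^4, ...`); blocks are mutually
#' uncorrelated. AR(1) correlation matrices are positive semi-definite by
#' construction. Variant IDs and positions match the layout used by
#' [simulate_gwas_pair()] for the same spec.
#'
#' @param spec A [generator_spec()] with non-`NULL` `ld_blocks`.
#' @return An [ld_matrix()].
#' @export
simulate_ld_matrix <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(spec$ld_blocks)) stop("spec has no `ld_blocks`", call. = FALSE)
  lay <- .variant_layout(spec)
  r2 <- matrix(0, spec$J, spec$J)
  i <- 1L
  rho <- spec$ld_blocks$rho
  for (size in spec$ld_blocks$sizes) {
    idx <- i:(i + size - 1L)
    block <- rho^abs(outer(seq_len(size), seq_len(size), "-"))
    r2[idx, idx] <- block^2
    i <- i + size
  }
  diag(r2) <- 1
  ld_matrix(lay$id, r2, lay$pos, lay$chrom)
}

#' Build a miniature trait panel with known positives
#'
#' Generates `n_traits` independent exposure panels against one shared
#' binary outcome: the first `n_significant` traits carry a true causal
#' effect `beta_pos`, the rest are null. Each trait's variants get a
#' distinct ID prefix so the combined outcome panel is well-formed. The
#' generated instrument strength is checked to give power above 0.99 at the
#' Bonferroni threshold for every true positive; an infeasible request
#' errors with the limiting trait named.
#'
#' @param n_traits Number of traits in the panel.
#' @param n_significant Number of truth-positive traits (<= `n_traits`).
#' @param seed Master seed; per-trait streams are derived by stable hashing.
#' @param beta_pos True effect for the positive traits (default 0.3
#'   log-odds per SD).
#' @param J Instruments per trait (default 25).
#' @param n_tests Bonferroni denominator used for the feasibility check
#'   (default 60, the conventional trait-panel correction).
#' @return A list with `exposures` (named list of [summary_stats()]),
#'   `outcome` (one combined [summary_stats()]), and `truth` (data frame
#'   `trait`, `beta_true`, `is_positive`).
#' @export
make_atlas_fixture <- function(n_traits, n_significant, seed, beta_pos = 0.3,
                               J = 25L, n_tests = 60L) {
  stopifnot(n_significant <= n_traits, n_traits >= 1)
  traits <- sprintf("trait%02d", seq_len(n_traits))
  exposures <- list()
  outcome_records <- list()
  truth <- data.frame(trait = traits,
                      beta_true = c(rep(beta_pos, n_significant),
                                    rep(0, n_traits - n_significant)),
                      is_positive = seq_len(n_traits) <= n_significant,
                      stringsAsFactors = FALSE)
  alpha_bonf <- 0.05 / n_tests
  for (i in seq_len(n_traits)) {
    spec <- generator_spec(J = J, beta = truth$beta_true[i],
                           variant_prefix = paste0(traits[i], "_rs"),
                           seed = derive_seed(seed, traits[i]))
    pair <- simulate_gwas_pair(spec)
    attr(pair$exposure, "trait_name") <- traits[i]
    if (truth$is_positive[i]) {
      r2 <- variance_explained(pair$exposure)
      pw <- mr_power_binary(r2, spec$n_cases + spec$n_controls,
                            exp(abs(beta_pos)), alpha = alpha_bonf)
      if (pw < 0.99) {
        stop(sprintf(paste0("trait '%s': generated power %.3f < 0.99 at the ",
                            "Bonferroni threshold; increase J, z_range or ",
                            "beta_pos"), traits[i], pw), call. = FALSE)
      }
    }
    exposures[[traits[i]]] <- pair$exposure
    outcome_records[[i]] <- as.data.frame(pair$outcome)
  }
  outcome <- summary_stats(do.call(rbind, outcome_records), "lung_cancer",
                           "binary", n_cases = 11348L, n_controls = 15861L)
  list(exposures = exposures, outcome = outcome, truth = truth)
}
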