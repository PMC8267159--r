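test_that("Wald ratio matches the delta-method formula", {
  h <- make_h(gamma = 0.5, Gamma = 0.1, se_y = 0.02, se_x = 0.05)
  e <- mr_wald_ratio(h)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.04)
  expect_equal(e$ci_low, 0.2 - qnorm(0.975) * 0.04)
  expect_equal(e$or, exp(0.2))

  # null numerator and identity instrument
  expect_equal(mr_wald_ratio(make_h(0.5, 0, 0.02))$or, 1.0)
  e1 <- mr_wald_ratio(make_h(1, 0.3, 0.07))
  expect_equal(e1$beta, 0.3)
  expect_equal(e1$se, 0.07)

  expect_error(mr_wald_ratio(make_h(0, 0.1, 0.02)),
               class = "mratlas_undefined_ratio")
  expect_error(mr_wald_ratio(h3()), class = "mratlas_dispatch_error")
})

test_that("IVW equals a brute-force weighted regression through the origin", {
  h <- h3()
  e <- mr_ivw(h)
  expect_equal(e$beta, oracle_ivw_slope(h), tolerance = 1e-10)

  # identical ratios: zero heterogeneity, no inflation
  h0 <- make_h(gamma = c(1, 2), Gamma = c(0.2, 0.4), se_y = c(0.05, 0.05))
  e0 <- mr_ivw(h0)
  expect_equal(e0$beta, 0.2)
  expect_equal(e0$extras$q_stat, 0)
  expect_equal(e0$se, e0$extras$se_fixed)

  # scaling all outcome SEs by c leaves beta, scales the fixed-effect SE
  d <- as.data.frame(h)
  hc <- make_h(d$gamma, d$Gamma, d$se_y * 3)
  expect_equal(mr_ivw(hc)$beta, e$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(hc, random = "fixed")$se,
               3 * mr_ivw(h, random = "fixed")$se, tolerance = 1e-12)

  expect_error(mr_ivw(make_h(1, 0.1, 0.02)), class = "mratlas_dispatch_error")
})

test_that("IVW error models agree on homogeneous data and differ under heterogeneity", {
  h <- make_h(gamma = c(1, 1, 1, 1), Gamma = c(0.1, 0.3, -0.1, 0.5),
              se_y = rep(0.05, 4))
  e_f <- mr_ivw(h, random = "fixed")
  e_m <- mr_ivw(h, random = "mult")
  e_a <- mr_ivw(h, random = "additive")
  expect_equal(e_m$se, e_f$se * sqrt(e_f$extras$q_stat / 3), tolerance = 1e-12)
  expect_gt(e_m$se, e_f$se)
  expect_gt(e_a$se, e_f$se)
})

test_that("MR-Egger equals a brute-force two-parameter weighted regression", {
  h <- h4()
  e <- mr_egger(h)
  ora <- oracle_egger(h)
  expect_equal(e$extras$egger_intercept, ora[1], tolerance = 1e-10)
  expect_equal(e$beta, ora[2], tolerance = 1e-10)

  # exact line through the origin: slope recovered, intercept zero
  hl <- make_h(gamma = c(0.2, 0.4, 0.7, 1.1), Gamma = 0.3 * c(0.2, 0.4, 0.7, 1.1),
               se_y = rep(0.02, 4))
  el <- mr_egger(hl)
  expect_equal(el$beta, 0.3, tolerance = 1e-12)
  expect_equal(el$extras$egger_intercept, 0, tolerance = 1e-12)

  expect_error(mr_egger(make_h(c(1, 2), c(0.1, 0.2), c(0.02, 0.02))),
               class = "mratlas_dispatch_error")
  expect_error(mr_egger(make_h(c(1, 1, 1), c(0.1, 0.2, 0.3), rep(0.02, 3))),
               class = "mratlas_collinear")
})

test_that("Egger intercept recovers planted directional pleiotropy", {
  # all instruments pleiotropic with mean 0.05, InSIDE holding
  ints <- vapply(1:50, function(i) {
    pair <- simulate_gwas_pair(generator_spec(J = 50, beta = 0.2,
                                              prop_invalid = 1, mu_alpha = 0.05,
                                              tau_alpha = 0.02,
                                              seed = derive_seed(101, paste0("i", i))))
    egger_intercept_test(pair_to_h(pair))$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.05), 0.01)
})

test_that("weighted median interpolates the cumulative-weight midpoint", {
  # equal weights, symmetric ratios
  h <- make_h(gamma = c(1, 1, 1), Gamma = c(0.1, 0.2, 0.3), se_y = rep(1, 3))
  expect_equal(mr_weighted_median(h, seed = 1)$beta, 0.2)

  # one SNP holding 70% of the weight pins the estimate at its ratio:
  # cumulative midpoints are 0.075 / 0.5 / 0.925, so s = 0.5 is exact
  w <- c(0.15, 0.7, 0.15)
  r <- c(0.1, 0.2, 0.3)
  h70 <- make_h(gamma = sqrt(w), Gamma = r * sqrt(w), se_y = rep(1, 3))
  expect_equal(mr_weighted_median(h70, seed = 1)$beta, 0.2)

  # hand-computed interpolation: weights (.5,.3,.2) give s = (.25,.65,.9);
  # 0.5 sits 0.25/0.40 of the way from ratio 0.1 to 0.2 -> 0.1625
  w2 <- c(0.5, 0.3, 0.2)
  h2 <- make_h(gamma = sqrt(w2), Gamma = r * sqrt(w2), se_y = rep(1, 3))
  expect_equal(mr_weighted_median(h2, seed = 1)$beta, 0.1625)

  expect_error(mr_weighted_median(make_h(c(1, 2), c(0.1, 0.2), c(1, 1)), seed = 1),
               class = "mratlas_dispatch_error")
})

test_that("weighted median point estimate is seed-free; bootstrap SE is stable", {
  pair <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2, seed = 3))
  h <- pair_to_h(pair)
  e1 <- mr_weighted_median(h, n_boot = 1000, seed = 11)
  e2 <- mr_weighted_median(h, n_boot = 1000, seed = 99)
  expect_identical(e1$beta, e2$beta)
  expect_lt(abs(e1$se - e2$se) / e1$se, 0.05)
})

.subset_one <- function(h) {
  d <- as.data.frame(h)[1, ]
  harmonized_set(d$variant_id, d$gamma, d$se_x, d$Gamma, d$se_y)
}

test_that("estimators are equivariant under exposure-unit rescaling", {
  h <- h4()
  d <- as.data.frame(h)
  c_ <- 2.5
  hs <- harmonized_set(d$variant_id, d$gamma * c_, d$se_x * c_, d$Gamma, d$se_y)
  expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c_, tolerance = 1e-12)
  expect_equal(mr_egger(hs)$beta, mr_egger(h)$beta / c_, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, seed = 1)$beta,
               mr_weighted_median(h, seed = 1)$beta / c_, tolerance = 1e-12)
  expect_equal(mr_wald_ratio(.subset_one(hs))$beta,
               mr_wald_ratio(.subset_one(h))$beta / c_, tolerance = 1e-12)
})

test_that("the IVW combination rule reduces to the Wald ratio at J = 1", {
  # continuity of the closed-form sums (the public API dispatches instead)
  s <- mratlas:::.ivw_sums(0.5, 0.1, 0.02)
  expect_equal(s$beta, 0.2)
  expect_equal(1 / sqrt(s$s_xx), 0.02 / 0.5)
})

test_that("method dispatch follows the instrument count", {
  h1 <- make_h(0.5, 0.1, 0.02)
  expect_named(mr_all(h1), "wald_ratio")
  expect_equal(attr(mr_all(h1), "headline"), "wald_ratio")

  h2 <- make_h(c(0.5, 0.6), c(0.1, 0.12), c(0.02, 0.02))
  expect_named(mr_all(h2), "ivw")

  h5 <- make_h(seq(0.2, 1, length.out = 5), seq(0.05, 0.3, length.out = 5),
               rep(0.02, 5))
  est <- mr_all(h5, seed = 1)
  expect_named(est, c("ivw", "mr_egger", "weighted_median"))
  expect_true(all(vapply(est, function(e) e$n_snp, integer(1)) == 5L))
  expect_equal(attr(est, "headline"), "ivw")
})

test_that("estimates_table lays out the reporting columns", {
  est <- mr_all(h4(), seed = 1)
  tb <- estimates_table(est, "exp", "out")
  expect_equal(nrow(tb), 3L)
  expect_true(all(c("exposure", "outcome", "method", "n_snp", "beta", "se",
                    "or", "or_low", "or_high", "pval", "q_stat", "q_df",
                    "egger_intercept", "egger_intercept_p") %in% names(tb)))
  expect_false(is.na(tb$egger_intercept[tb$method == "mr_egger"]))
})
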