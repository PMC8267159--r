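test_that("leave-one-out is flat on homogeneous data and flags a driver", {
  # identical ratios: every omission gives the full-set estimate
  h <- make_h(gamma = c(0.5, 1, 2), Gamma = 0.2 * c(0.5, 1, 2),
              se_y = rep(0.02, 3))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 3L)
  expect_equal(loo$beta, rep(0.2, 3), tolerance = 1e-12)

  # one 5-SD-deviant instrument: omitting it moves the estimate most
  g <- rep(1, 8)
  G <- 0.2 * g
  se_y <- rep(0.02, 8)
  G[4] <- 0.2 + 5 * 0.02
  h_out <- make_h(g, G, se_y)
  loo2 <- leave_one_out(h_out)
  full <- mr_ivw(h_out)$beta
  shifts <- abs(loo2$beta - full)
  expect_equal(which.max(shifts), 4L)

  # cardinality at J = 10
  pair <- simulate_gwas_pair(generator_spec(J = 10, beta = 0.1, seed = 2))
  expect_equal(nrow(leave_one_out(pair_to_h(pair))), 10L)
  expect_error(leave_one_out(make_h(c(1, 2), c(0.1, 0.2), c(0.02, 0.02))),
               class = "mratlas_dispatch_error")
})

test_that("Egger intercept test is null on data through the origin", {
  h <- make_h(gamma = c(0.2, 0.5, 0.8, 1.2), Gamma = 0.25 * c(0.2, 0.5, 0.8, 1.2),
              se_y = rep(0.03, 4))
  et <- egger_intercept_test(h)
  expect_equal(et$intercept, 0, tolerance = 1e-12)
  expect_equal(et$pval, 1, tolerance = 1e-9)
  expect_equal(et$df, 2L)
})

test_that("Egger intercept test has power against directional pleiotropy", {
  rej <- vapply(1:500, function(i) {
    pair <- simulate_gwas_pair(generator_spec(J = 50, beta = 0.2,
                                              prop_invalid = 1, mu_alpha = 0.1,
                                              tau_alpha = 0.05,
                                              seed = derive_seed(201, paste0("p", i))))
    egger_intercept_test(pair_to_h(pair))$pval < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.80)
})

test_that("Egger intercept test is calibrated under balanced pleiotropy", {
  # spec scale is 2,000 replicates; run 1,000 with a 2-point Monte-Carlo band
  rej <- vapply(1:1000, function(i) {
    pair <- simulate_gwas_pair(generator_spec(J = 50, beta = 0.2,
                                              prop_invalid = 1, mu_alpha = 0,
                                              tau_alpha = 0.05,
                                              seed = derive_seed(202, paste0("t", i))))
    egger_intercept_test(pair_to_h(pair))$pval < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("funnel residuals reproduce Cochran's Q", {
  pair <- simulate_gwas_pair(generator_spec(J = 15, beta = 0.2, seed = 5))
  h <- pair_to_h(pair)
  q <- cochran_q(h)
  fd <- funnel_data(h)
  beta_ivw <- mr_ivw(h)$beta
  q_from_funnel <- sum(((fd$ratio - beta_ivw) * fd$precision)^2)
  expect_equal(q$q_stat, q_from_funnel, tolerance = 1e-10)
  expect_true(all(fd$precision > 0))
})

test_that("PRESSO global test: perfect fit, add-one bound, planted outlier", {
  # exact fit with tiny noise: p near 1
  g <- seq(0.2, 1.2, length.out = 6)
  h_fit <- make_h(g, 0.3 * g, se_y = rep(1e-4, 6))
  res <- presso_global(h_fit, n_sim = 1000, seed = 1)
  expect_gt(res$global_p, 0.5)
  expect_gte(res$global_p, 1 / 1001)

  # one instrument displaced by 5 SDs among 20
  pair <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2,
                                            outliers = data.frame(index = 7, offset = 5),
                                            seed = 17))
  res_out <- presso_global(pair_to_h(pair), n_sim = 1000, seed = 18)
  expect_lt(res_out$global_p, 0.05)

  expect_error(presso_global(h3(), n_sim = 1000, seed = 1),
               class = "mratlas_dispatch_error")
})

test_that("PRESSO outlier test flags planted outliers and only those", {
  pair <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2,
                                            outliers = data.frame(index = 7, offset = 6),
                                            seed = 23))
  h <- pair_to_h(pair)
  o <- presso_outlier(h, n_sim = 1000, seed = 29)
  expect_equal(o$outliers, "rs7")
  expect_s3_class(o$beta_corrected, "mr_estimate")
  expect_equal(o$beta_corrected$n_snp, 19L)

  # two planted outliers of opposite sign
  pair2 <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2,
                                             outliers = data.frame(index = c(3, 11),
                                                                   offset = c(6, -6)),
                                             seed = 31))
  o2 <- presso_outlier(pair_to_h(pair2), n_sim = 1000, seed = 37)
  expect_setequal(o2$outliers, c("rs3", "rs11"))
})

test_that("PRESSO outlier flags are invariant to instrument ordering", {
  pair <- simulate_gwas_pair(generator_spec(J = 16, beta = 0.2,
                                            outliers = data.frame(index = 5, offset = 6),
                                            seed = 41))
  h <- pair_to_h(pair)
  set.seed(1)
  perm <- sample(nrow(h))
  h_perm <- mratlas:::.subset_h(h, perm)
  o1 <- presso_outlier(h, n_sim = 2000, seed = 43)
  o2 <- presso_outlier(h_perm, n_sim = 2000, seed = 44)
  expect_setequal(o1$outliers, o2$outliers)
})

test_that("PRESSO distortion test is null when outliers do not move the estimate", {
  # all instruments share the ratio: removing any subset leaves beta alone
  g <- seq(0.3, 1.4, length.out = 8)
  h <- make_h(g, 0.2 * g, se_y = rep(0.02, 8))
  d <- presso_distortion(h, outliers = "rs2", n_sim = 1000, seed = 3)
  expect_equal(d$distortion_pct, 0, tolerance = 1e-9)
  expect_gt(d$distortion_p, 0.9)
  expect_gte(d$distortion_p, 1 / 1001)
  expect_lte(d$distortion_p, 1)

  # a dominant outlier produces a small distortion p
  pair <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2,
                                            outliers = data.frame(index = 7, offset = 8),
                                            seed = 47))
  hp <- pair_to_h(pair)
  dp <- presso_distortion(hp, outliers = "rs7", n_sim = 1000, seed = 53)
  expect_lt(dp$distortion_p, 0.05)

  expect_error(presso_distortion(h, outliers = character(0), n_sim = 1000, seed = 1))
  expect_error(presso_distortion(h, outliers = paste0("rs", 1:7), n_sim = 1000, seed = 1))
})

test_that("the PRESSO battery follows its conditional logic", {
  # clean data: global only
  pair <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2, seed = 59))
  res <- mr_presso(pair_to_h(pair), n_sim = 1000, seed = 61)
  expect_identical(res$performed, "global")
  expect_length(res$outliers, 0)
  expect_null(res$beta_corrected)

  # planted outlier: all three stages run
  pair2 <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.2,
                                             outliers = data.frame(index = 4, offset = 6),
                                             seed = 67))
  res2 <- mr_presso(pair_to_h(pair2), n_sim = 1000, seed = 71)
  expect_identical(res2$performed, c("global", "outlier", "distortion"))
  expect_true("rs4" %in% res2$outliers)
  expect_false(is.na(res2$distortion_p))
})

test_that("sensitivity_report gates components by instrument count", {
  pair <- simulate_gwas_pair(generator_spec(J = 3, beta = 0.2, seed = 73))
  rep3 <- sensitivity_report(pair_to_h(pair), seed = 1)
  expect_null(rep3$presso)
  expect_match(rep3$not_performed[["presso"]], ">= 4")
  expect_equal(nrow(rep3$loo), 3L)

  pair5 <- simulate_gwas_pair(generator_spec(J = 5, beta = 0.2, seed = 79))
  rep5 <- sensitivity_report(pair_to_h(pair5), n_sim = 1000, seed = 1)
  expect_s3_class(rep5$presso, "presso_result")
  expect_length(rep5$not_performed, 0)

  dir <- withr::local_tempdir()
  write_sensitivity_bundle(rep5, dir)
  expect_true(file.exists(file.path(dir, "single_snp.tsv")))
  expect_true(file.exists(file.path(dir, "summary.txt")))
})
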