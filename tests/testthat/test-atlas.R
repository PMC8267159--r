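test_that("tier classification follows the Bonferroni bands", {
  expect_equal(classify_tier(0.0005, 60), "significant")
  expect_equal(classify_tier(0.01, 60), "suggestive")
  expect_equal(classify_tier(0.05, 60), "null")        # strict upper bound
  expect_equal(classify_tier(0.05 / 60, 60), "suggestive")  # boundary is not significant
  expect_equal(classify_tier(1, 60), "null")
  expect_equal(classify_tier(c(1e-5, 0.02, 0.9), 60),
               c("significant", "suggestive", "null"))
  # tiering is a partition: exactly one tier per p-value
  p <- c(1e-6, 8e-4, 8.4e-4, 0.049, 0.05, 0.51, 1)
  expect_false(any(is.na(classify_tier(p, 60))))
})

test_that("run_atlas analyzes a small panel end to end and isolates failures", {
  fx <- make_atlas_fixture(3, 1, seed = 13)
  # add a trait whose instruments vanish at the selection threshold
  weak <- make_stats(paste0("weak_rs", 1:3), pval = c(1e-4, 1e-3, 0.02),
                     trait = "weak_trait")
  exposures <- c(fx$exposures, list(weak_trait = weak))
  cfg <- atlas_config(exposures, list(lung_cancer = fx$outcome),
                      n_tests = 60L, seed = 5, n_boot = 200L, n_sim = 1000L)
  res <- suppressMessages(run_atlas(cfg))
  expect_s3_class(res, "atlas_result")
  expect_length(res, 4L)
  expect_equal(attr(res, "bonferroni"), 0.05 / 60)

  wk <- res[["weak_trait|lung_cancer"]]
  expect_equal(wk$status, "not_analyzable")
  expect_match(wk$message, "no instruments")

  ok <- res[["trait01|lung_cancer"]]
  expect_equal(ok$status, "ok")
  expect_named(ok$estimates, c("ivw", "mr_egger", "weighted_median"))
  expect_s3_class(ok$power, "power_profile")
  expect_true(ok$tier %in% c("significant", "suggestive", "null"))

  tb <- atlas_table(res)
  expect_true(all(tb$tier[!is.na(tb$method) & tb$method == "ivw"] %in%
                    c("significant", "suggestive", "null")))
  expect_true("not_analyzable" %in% tb$tier)
})

test_that("a single-instrument trait gets the Wald ratio and no PRESSO", {
  pair <- simulate_gwas_pair(generator_spec(J = 1, beta = 0.3, seed = 19,
                                            variant_prefix = "cig_rs"))
  attr(pair$exposure, "trait_name") <- "cigarettes_per_day"
  cfg <- atlas_config(list(cigarettes_per_day = pair$exposure),
                      list(lung_cancer = pair$outcome), seed = 3)
  res <- suppressMessages(run_atlas(cfg))
  r <- res[["cigarettes_per_day|lung_cancer"]]
  expect_equal(r$status, "ok")
  expect_equal(r$headline_method, "wald_ratio")
  expect_named(r$estimates, "wald_ratio")
  expect_null(r$sensitivity$presso)
  expect_match(r$sensitivity$not_performed[["presso"]], ">= 4")
})

test_that("atlas runs are byte-identical under the same master seed", {
  fx <- make_atlas_fixture(2, 1, seed = 23)
  cfg <- atlas_config(fx$exposures, list(lung_cancer = fx$outcome),
                      seed = 7, n_boot = 200L, n_sim = 1000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_atlas_results(suppressMessages(run_atlas(cfg)), d1, cfg)
  write_atlas_results(suppressMessages(run_atlas(cfg)), d2, cfg)
  f1 <- file.path(d1, "results.tsv")
  f2 <- file.path(d2, "results.tsv")
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("bonferroni threshold: 0.0008",
                        readLines(file.path(d1, "run_log.txt")))))
})

test_that("build_network adds only supported directed edges", {
  # A -> B with effect 0.3; B -> A null
  ab <- simulate_gwas_pair(generator_spec(J = 20, beta = 0.3, seed = 29,
                                          variant_prefix = "a_rs"))
  ba <- simulate_gwas_pair(generator_spec(J = 20, beta = 0, seed = 31,
                                          variant_prefix = "b_rs"))
  attr(ab$exposure, "trait_name") <- "A"
  attr(ba$exposure, "trait_name") <- "B"
  attr(ab$outcome, "trait_name") <- "B"   # A's instruments scored in B
  attr(ba$outcome, "trait_name") <- "A"   # B's instruments scored in A
  traits <- list(A = list(instruments = ab$exposure, panel = ba$outcome),
                 B = list(instruments = ba$exposure, panel = ab$outcome))
  net <- build_network(traits, seed = 37, n_boot = 200L)
  expect_true(any(net$edges$source == "A" & net$edges$target == "B"))
  expect_false(any(net$edges$source == "B" & net$edges$target == "A"))
  expect_false(any(net$edges$source == net$edges$target))  # no self-edges

  path <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  expect_equal(read.delim(path)$source, net$edges$source)
})
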