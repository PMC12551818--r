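tt <- testretest_csa()
table_pairs <- test_retest_pairs(paste(tt$mouse, tt$side),
                                 tt$csa_test_mm2, tt$csa_retest_mm2)

test_that("pair construction rejects non-quantized areas", {
  expect_error(test_retest_pairs("u1", 0.4, 0.305), "integer pixel multiple")
  ok <- test_retest_pairs("u1", 50 * pixel_area(voxel_geometry()), 0.305)
  expect_identical(ok$test_px, 50L)
})

test_that("one-way random-effects ICC matches its definitional oracle and edge cases", {
  res <- icc_oneway(table_pairs)
  orc <- ss_icc_oracle(table_pairs$test_csa, table_pairs$retest_csa)
  expect_equal(res$icc, orc$icc, tolerance = 1e-12)
  expect_equal(res$ms_between, orc$ms_between, tolerance = 1e-12)
  expect_equal(res$ms_within, orc$ms_within, tolerance = 1e-12)
  expect_equal(round(res$icc, 2), 0.90)

  # perfect agreement with real between-unit variance
  perfect <- tibble::tibble(unit_id = letters[1:4],
                            test_csa = c(0.1, 0.2, 0.3, 0.4),
                            retest_csa = c(0.1, 0.2, 0.3, 0.4),
                            test_px = 1:4, retest_px = 1:4)
  expect_equal(icc_oneway(perfect)$icc, 1)

  # zero total variance: agreement is not estimable
  const <- tibble::tibble(unit_id = c("a", "b"), test_csa = c(0.2, 0.2),
                          retest_csa = c(0.2, 0.2), test_px = c(1L, 1L),
                          retest_px = c(1L, 1L))
  res0 <- icc_oneway(const)
  expect_true(res0$undefined)
  expect_true(is.na(res0$icc))
  expect_error(icc_oneway(perfect[1, ]), "at least 2")

  # affine rescaling of all measurements leaves the ICC unchanged
  scaled <- table_pairs
  scaled$test_csa <- 3.7 * scaled$test_csa + 0.5
  scaled$retest_csa <- 3.7 * scaled$retest_csa + 0.5
  expect_equal(icc_oneway(scaled)$icc, res$icc, tolerance = 1e-10)
})

test_that("Bland-Altman statistics reproduce the recorded summary and identities", {
  ba <- bland_altman(table_pairs)
  expect_equal(round(ba$bias, 3), 0.003)
  expect_equal(round(ba$sd_diff, 3), 0.032)
  expect_equal(round(ba$loa_low, 3), -0.060)
  expect_equal(round(ba$loa_high, 3), 0.066)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)

  # identical arms collapse to zero
  same <- table_pairs
  same$retest_csa <- same$test_csa; same$retest_px <- same$test_px
  ba0 <- bland_altman(same)
  expect_equal(c(ba0$bias, ba0$sd_diff, ba0$loa_low, ba0$loa_high),
               rep(0, 4))

  # swapping arms negates the bias, preserves spread
  swapped <- table_pairs[, c("unit_id", "retest_csa", "test_csa",
                             "retest_px", "test_px")]
  names(swapped) <- names(table_pairs)
  bas <- bland_altman(swapped)
  expect_equal(bas$bias, -ba$bias)
  expect_equal(bas$sd_diff, ba$sd_diff)
  expect_equal(bas$loa_high - bas$loa_low, ba$loa_high - ba$loa_low)
})

test_that("pixel-count relative differences reproduce every recorded unit", {
  expect_equal(round(relative_difference(51L, 42L), 3), 19.355)
  expect_equal(round(relative_difference(50L, 53L), 3), -5.825)
  expect_equal(relative_difference(34L, 34L), 0)
  expect_error(relative_difference(0L, 0L), "undefined")
  rd <- relative_difference(table_pairs$test_px, table_pairs$retest_px)
  expect_equal(round(rd, 3), tt$rel_diff_pct)
})

test_that("the reliability report aggregates all recorded summary cells", {
  rep <- reliability_report(table_pairs)
  expect_equal(round(rep$mean_test, 3), 0.258)
  expect_equal(round(rep$mean_retest, 3), 0.255)
  expect_equal(round(rep$mean_of_means, 3), 0.257)
  expect_equal(round(rep$bias, 3), 0.003)
  expect_equal(round(rep$mean_rel_diff, 3), 2.480)
  expect_equal(round(rep$sd_test, 3), 0.063)
  expect_equal(round(rep$sd_retest, 3), 0.076)
  expect_equal(round(rep$sd_of_means, 3), 0.068)
  expect_equal(round(rep$sd_diff, 3), 0.032)
  expect_equal(round(rep$sd_rel_diff, 3), 11.340)

  plots <- reliability_plots(rep)
  expect_s3_class(plots$scatter, "ggplot")
  expect_s3_class(plots$bland_altman, "ggplot")
})

test_that("estimated ICC recovers a known reliability on simulated pairs", {
  # sigma_between = 3 sigma_within gives an analytic ICC of 0.9
  set.seed(21)
  est <- replicate(200, {
    u <- rnorm(10, 0.25, 0.03)
    p <- tibble::tibble(unit_id = sprintf("u%02d", 1:10),
                        test_csa = u + rnorm(10, 0, 0.01),
                        retest_csa = u + rnorm(10, 0, 0.01),
                        test_px = 1L, retest_px = 1L)
    icc_oneway(p)$icc
  })
  expect_gte(median(est), 0.80)
  expect_lte(median(est), 0.96)
})

test_that("pipeline-measured test-retest variability matches the generator", {
  # 10 DRG pairs with 6% scan-to-scan size variation: Bland-Altman SD of
  # pipeline-measured differences inside the Monte-Carlo envelope
  for (rep_i in 1:2) {
    tst <- c(); rts <- c()
    for (u in 1:10) {
      pr <- render_test_retest(
        phantom_spec(noise_sigma = 40),
        jitter = list(dv_shift_px = c(-3L, 3L), intensity_scale = c(0.95, 1.05),
                      size_cv = 0.06),
        seed = rep_i * 100 + u)
      for (arm in c("test", "retest")) {
        r <- run_pipeline(pr[[arm]]$stack)
        v <- r$records$csa_mm2[r$records$side == "left"]
        if (arm == "test") tst <- c(tst, ifelse(length(v), v, NA))
        else rts <- c(rts, ifelse(length(v), v, NA))
      }
    }
    s <- sd(tst - rts, na.rm = TRUE)
    expect_gte(s, 0.015); expect_lte(s, 0.055)
  }
})
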