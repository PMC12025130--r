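test_that("the derived-parameter formula chain matches direct arithmetic", {
  expect_equal(direct_additive_variance(0.139), 0.556)
  expect_equal(direct_additive_variance(0), 0)
  expect_equal(direct_additive_variance(0.125), 0.5)
  expect_error(direct_additive_variance(-1), "negative")

  expect_equal(tbv_variance(0.5, 2 * 0.00246, 0.000187, 36), 1.073475,
               tolerance = 1e-6)  # printed sigma_TBV^2 is 1.072 (rounded inputs)
  expect_equal(tbv_variance(0.42, 0, 0, 36), 0.42)
  expect_error(tbv_variance(0.5, 0, 0, 1), "n")

  expect_equal(round(ige_total_variance(0.000136, 36), 3), 0.167)
  expect_equal(round(ige_total_variance(0.000187, 36), 3), 0.229)
  expect_equal(ige_total_variance(0, 12), 0)
  expect_equal(round(ige_share(ige_total_variance(0.000136, 36), 0.971), 2), 17.16)
  expect_error(ige_share(1, 0), "positive")

  expect_equal(round(phenotypic_variance(0.139, sigma_t_sq = 0.028,
                                         sigma_e_sq = 0.520), 3), 0.826)
  expect_equal(round(phenotypic_variance(0.119, 0.000136, 0.008, 0.517,
                                         n = 36, include_ige = TRUE), 3), 0.768)
  expect_equal(phenotypic_variance(0, 0, 0, 0), 0)

  expect_equal(round(heritability(0.556, 0.826), 3), 0.673)
  expect_equal(heritability(0, 1), 0)
  expect_equal(round(t_squared(0.971, 0.768), 3), 1.264)
  expect_error(heritability(0.5, 0), "positive")
})

test_that("uniformity conversions follow the exponential-scale formulas", {
  expect_equal(uniformity_additive_variance(0, 0.5), 0)
  expect_equal(uniformity_additive_variance(0.246, 0.4575),
               0.4575^2 * (exp(0.246) - 1), tolerance = 1e-12)
  expect_equal(round(uniformity_additive_variance(0.246, 0.4575), 4), 0.0584)
  # small-x limit: sigma_E^4 * x within 1%
  expect_equal(uniformity_additive_variance(0.01, 0.7), 0.7^4 * 0.01,
               tolerance = 0.01)
  expect_error(uniformity_additive_variance(0.1, 0), "positive")

  # hv2 = sigma_av^2 / (2 sigma_p^4 + 3 sigma_av^2), sigma_p^4 = (sigma_p^2)^2
  expect_equal(uniformity_heritability(0.019, 0.782),
               0.019 / (2 * 0.782^2 + 3 * 0.019), tolerance = 1e-12)
  expect_equal(round(uniformity_heritability(0.019, 0.782), 3), 0.015)
  expect_equal(round(uniformity_heritability(0.008, 0.826), 3), 0.006)
  expect_equal(uniformity_heritability(0, 0.8), 0)

  expect_equal(round(gcv_uniformity(0.246), 3), 0.528)
  expect_equal(round(gcv_uniformity(0.228), 3), 0.506)
  expect_equal(round(gcv_uniformity(0.137), 3), 0.383)
  expect_equal(gcv_uniformity(0), 0)
  expect_equal(gcv_uniformity(0.01), sqrt(0.01), tolerance = 0.01)  # Taylor limit
})

test_that("genetic correlations behave and reproduce the printed r_ads", {
  expect_equal(round(genetic_correlation(0.00246, 0.125, 0.000187), 3), 0.509)
  expect_equal(genetic_correlation(0, 1, 2), 0)
  expect_equal(genetic_correlation(sqrt(0.3 * 0.7), 0.3, 0.7), 1)
  expect_error(genetic_correlation(0.1, 0, 1), "positive")
  expect_warning(genetic_correlation(1, 0.5, 0.5), "outside")
})

test_that("pure ratios are scale invariant; hv2 deliberately is not", {
  for (c_ in c(0.5, 2, 10)) {
    expect_equal(heritability(0.556 * c_, 0.826 * c_), heritability(0.556, 0.826))
    expect_equal(t_squared(0.971 * c_, 0.768 * c_), t_squared(0.971, 0.768))
    expect_equal(genetic_correlation(0.002 * c_, 0.14 * c_, 0.00015 * c_),
                 genetic_correlation(0.002, 0.14, 0.00015))
  }
  expect_false(isTRUE(all.equal(uniformity_heritability(0.019 * 2, 0.782 * 2),
                                uniformity_heritability(0.019, 0.782))))
})

test_that("a report built from a fit is internally consistent", {
  fit <- fx_fit_small()
  rep_ <- genetic_parameter_report(fit, n = 12)
  expect_equal(rep_$sigma_ad_sq, 4 * rep_$sigma_au_sq)
  expect_equal(rep_$sigma_tbv_sq,
               tbv_variance(rep_$sigma_ad_sq, rep_$sigma_ad_as,
                            rep_$sigma_as_sq, rep_$n))
  expect_equal(rep_$h2, rep_$sigma_ad_sq / rep_$sigma_p_sq)
  expect_equal(rep_$T2, rep_$sigma_tbv_sq / rep_$sigma_p_sq)
  expect_equal(rep_$ige_share_percent,
               100 * rep_$ige_total_variance / rep_$sigma_tbv_sq)
  expect_equal(rep_$gcv_v, sqrt(expm1(rep_$sigma_av_exp_sq)))
  expect_true(abs(rep_$r_g) <= 1 + 1e-8)
  expect_output(print(rep_), "Genetic parameters")
})
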