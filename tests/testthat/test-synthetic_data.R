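test_that("pedigree simulation yields the requested family structure", {
  ped <- quiet(simulate_pedigree(40, 40, 40, 36, seed = 1))
  off <- ped[!is.na(ped$sire_id), ]
  expect_equal(nrow(off), 1440)
  expect_equal(sum(is.na(ped$sire_id)), 80)  # founder slots
  pairs <- unique(paste(off$sire_id, off$dam_id))
  expect_length(pairs, 40)                   # distinct parent pairs
  tiny <- quiet(simulate_pedigree(2, 2, 1, 2, seed = 2))
  sibs <- tiny[!is.na(tiny$sire_id), ]
  expect_equal(sibs$sire_id[1], sibs$sire_id[2])
  expect_equal(sibs$dam_id[1], sibs$dam_id[2])
  again <- quiet(simulate_pedigree(40, 40, 40, 36, seed = 1))
  expect_identical(ped, again)
})

test_that("gene drop obeys Mendelian certainty and Hardy-Weinberg frequencies", {
  ped <- quiet(simulate_pedigree(6, 6, 6, 20, seed = 4))
  gen <- gene_drop_genotypes(ped, 400, maf_low = 0.5, maf_high = 0.5, seed = 4)
  codes <- gen$codes
  off <- ped[!is.na(ped$sire_id), ]
  # both parents homozygous alt at a SNP -> every child homozygous alt
  for (f in unique(off$family_id)) {
    kids <- off$individual_id[off$family_id == f]
    s <- off$sire_id[off$family_id == f][1]
    d <- off$dam_id[off$family_id == f][1]
    fixed <- which(codes[s, ] == 2 & codes[d, ] == 2)
    if (length(fixed)) {
      expect_true(all(codes[kids, fixed] == 2))
    }
  }
  # founders at p = 0.5: genotype frequencies ~ (0.25, 0.5, 0.25)
  founder_codes <- codes[ped$individual_id[is.na(ped$sire_id)], ]
  freq <- table(factor(founder_codes, levels = 0:2)) / length(founder_codes)
  se <- 3 * sqrt(0.25 * 0.75 / length(founder_codes))
  expect_lt(abs(freq[["0"]] - 0.25), se)
  expect_lt(abs(freq[["1"]] - 0.50), 3 * sqrt(0.5 * 0.5 / length(founder_codes)))
  expect_lt(abs(freq[["2"]] - 0.25), se)
})

test_that("degenerate truth collapses the phenotype to its fixed part", {
  fx <- fx_small()
  tr <- truth_params(sigma_au_sq = 0, sigma_au_as = 0, sigma_as_sq = 0,
                     sigma_t_sq = 0, sigma_av_exp_sq = 0, r_ad_av = 0,
                     beta0v = -60, sex_diff = 2, slope_male = 0,
                     slope_female = 0, mu = 16)
  sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, tr, seed = 5))
  y <- sim$phenotypes$harvest_weight
  expected <- 16 + (as.numeric(sim$phenotypes$sex == "female") - 0.5) * 2
  expect_equal(y, expected, tolerance = 1e-4)
})

test_that("generated effects reproduce the target covariance structure", {
  # pool draws over replicates; individual-level scale
  fx <- fx_trial()
  tr <- truth_params()
  Sig <- tr$Sigma_additive
  reps <- 6
  vt <- vads <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, tr, seed = 600 + r))
    ids <- sim$phenotypes$individual_id
    ad <- sim$truth$ad[ids]; as_ <- sim$truth$as[ids]
    vt[r] <- var(ad + 35 * as_)
    vads[r] <- cov(ad, as_)
  }
  target_tbv <- tbv_variance(Sig["ad", "ad"], Sig["ad", "as"], Sig["as", "as"], 36)
  se_tbv <- sd(vt) / sqrt(reps)
  expect_lt(abs(mean(vt) - target_tbv), 3 * se_tbv)
  expect_lt(abs(mean(vads) - Sig["ad", "as"]), 3 * sd(vads) / sqrt(reps) + 1e-4)
})

test_that("sire-dam generating scale gives identical effects to full sibs", {
  fx <- fx_small()
  sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, truth_params(), seed = 6,
                                   generating_scale = "sire_dam"))
  off <- fx$ped[!is.na(fx$ped$sire_id), ]
  f1 <- off$individual_id[off$family_id == off$family_id[1]]
  expect_equal(var(sim$truth$ad[f1]), 0, tolerance = 1e-20)
  expect_equal(var(sim$truth$av[f1]), 0, tolerance = 1e-20)
})

test_that("dispersion effects drive the squared residuals", {
  fx <- fx_small()
  tr <- truth_params(sigma_av_exp_sq = 1.0, r_ad_av = 0, beta0v = log(0.4))
  sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, tr, seed = 7))
  ids <- sim$phenotypes$individual_id
  e <- sim$truth$residual[ids]
  slope <- coef(lm(log(e^2 + 1e-12) ~ sim$truth$av[ids]))[2]
  expect_gt(slope, 0.5)
})

test_that("survival thinning behaves and is seed-stable", {
  fx <- fx_small()
  expect_identical(apply_survival(fx$pheno, 1), fx$pheno)
  a <- apply_survival(fx$pheno, 0.9271, seed = 8)
  b <- apply_survival(fx$pheno, 0.9271, seed = 8)
  expect_identical(a$alive, b$alive)
  expect_true(all(is.na(a$harvest_weight[!a$alive])))
  expect_true(all(a$initial_weight == fx$pheno$initial_weight))  # covariates kept
  n <- nrow(fx$pheno)
  expect_lt(abs(sum(a$alive) - 0.9271 * n), 4 * sqrt(n * 0.9271 * 0.0729))
})

test_that("the full simulation pipeline is deterministic under fixed seeds", {
  fx <- fx_small()
  s1 <- quiet(simulate_phenotypes(fx$ped, fx$lay, truth_params(), seed = 12))
  s2 <- quiet(simulate_phenotypes(fx$ped, fx$lay, truth_params(), seed = 12))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$ad, s2$truth$ad)
})

test_that("simulation files round-trip", {
  fx <- fx_small()
  gen <- gene_drop_genotypes(fx$ped, 50, seed = 13)
  sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, truth_params(), seed = 13))
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, fx$ped, dir, genotypes = gen)
  back <- read_phenotypes(files[["phenotypes"]])
  expect_equal(back$harvest_weight, sim$phenotypes$harvest_weight, tolerance = 1e-10)
  gback <- read_genotypes(files[["genotypes"]])
  expect_equal(unname(gback$codes), unname(gen$codes))
})
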