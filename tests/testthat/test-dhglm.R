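test_that("design assembly counts cage mates' parents correctly", {
  # cage of three singleton-family individuals with distinct parents
  lay <- structure(list(
    cages = list(list(cage_id = "C01", families = c("F01", "F02", "F03"),
                      members = c("F01_01", "F02_01", "F03_01"))),
    group_size = 3L, families_per_cage = 3L, cages_per_family = 1L,
    family_ids = c("F01", "F02", "F03")), class = "design_layout")
  ped <- data.frame(
    individual_id = c("s1", "d1", "s2", "d2", "s3", "d3",
                      "F01_01", "F02_01", "F03_01"),
    sire_id = c(rep(NA, 6), "s1", "s2", "s3"),
    dam_id = c(rep(NA, 6), "d1", "d2", "d3"),
    generation = c(rep(0L, 6), 1L, 1L, 1L),
    family_id = c(rep(NA, 6), "F01", "F02", "F03"))
  ph <- data.frame(individual_id = c("F01_01", "F02_01", "F03_01"),
                   family_id = c("F01", "F02", "F03"), cage_id = "C01",
                   sex = c("male", "female", "male"), initial_weight = 4.8,
                   harvest_weight = c(15, 16, 17), alive = TRUE)
  db <- assemble_designs(ph, lay, ped, include_ige = TRUE, include_cage = TRUE)
  Zs <- as.matrix(db$Zs)
  expect_true(all(rowSums(Zs) == 4))         # 2 parents x 2 cage mates
  expect_true(all(Zs %in% c(0, 1)))          # unit entries
  expect_equal(unname(rowSums(as.matrix(db$Z_par))), rep(2, 3))
  # no IGE -> no Zs
  db0 <- assemble_designs(ph, lay, ped, include_ige = FALSE)
  expect_null(db0$Zs)
})

test_that("a full 3FAM cage gives Zs counts of 11 on own and 12 on other families", {
  fx <- fx_trial()
  ped <- fx$ped
  ph <- data.frame(individual_id = layout_ids <- unlist(lapply(fx$lay$cages, `[[`, "members")),
                   family_id = sub("_[0-9]+$", "", layout_ids),
                   cage_id = rep(vapply(fx$lay$cages, `[[`, "", "cage_id"), each = 36),
                   sex = "male", initial_weight = 4.8, harvest_weight = 10,
                   alive = TRUE)
  db <- assemble_designs(ph, fx$lay, ped, include_ige = TRUE)
  i <- 1  # first member of the first cage
  row <- as.matrix(db$Zs)[i, ]
  own_s <- ped$sire_id[ped$individual_id == db$record_ids[i]]
  own_d <- ped$dam_id[ped$individual_id == db$record_ids[i]]
  expect_equal(unname(row[own_s]), 11)
  expect_equal(unname(row[own_d]), 11)
  expect_equal(sort(unique(row[row > 0])), c(11, 12))
  expect_equal(sum(row), 2 * 35)  # 2(n-1) entries aggregated by parent
})

test_that("the psi linearization follows its closed form", {
  expect_equal(update_psi(1, 0, 1), 0)
  expect_equal(update_psi(4, 0.5, 2), log(2) + (8 - 2) / 2, tolerance = 1e-12)
  expect_equal(round(update_psi(4, 0.5, 2), 4), 3.6931)
  expect_error(update_psi(1, 1, 1), "leverage")
  expect_error(update_psi(1, 0.2, 0), "residual variance")
  # homoscedastic expectation: mean psi ~ log sigma_e^2
  set.seed(42)
  e <- rnorm(20000, 0, sqrt(2.5))
  psi <- update_psi(e^2, rep(0, 20000), rep(2.5, 20000))
  expect_lt(abs(mean(psi) - log(2.5)), 3 * sd(psi) / sqrt(20000))
})

test_that("leverages match closed forms and the dense projection oracle", {
  n <- 25
  h <- compute_leverages(matrix(1, n, 1), components = list(sigma_e_sq = 3))
  expect_equal(h, rep(1 / n, n), tolerance = 1e-10)

  # 30-observation toy with one random effect: dense oracle
  set.seed(106)
  g <- gl(6, 5)
  Z <- model.matrix(~ g - 1)
  X <- cbind(1, rnorm(30))
  w <- runif(30, 0.5, 2)
  comp <- list(sigma_au_sq = 0.7, sigma_e_sq = 1.3)
  bundle <- list(X = X, Z_par = Z)
  h2 <- compute_leverages(bundle, weights = w, components = comp)
  Wm <- cbind(X, Z)
  Rinv <- diag(1 / (w * comp$sigma_e_sq))
  Ginv <- diag(c(rep(0, 2), rep(1 / comp$sigma_au_sq, 6)))
  C <- t(Wm) %*% Rinv %*% Wm + Ginv
  Hmat <- Wm %*% solve(C) %*% t(Wm) %*% Rinv
  expect_equal(h2, unname(diag(Hmat)), tolerance = 1e-8)
  expect_true(all(h2 > 0 & h2 < 1))
  # trace identity: sum of leverages = effective number of parameters
  expect_equal(sum(h2), sum(diag(Hmat)), tolerance = 1e-8)
})

test_that("the DHGLM fit recovers structure on a small well-specified simulation", {
  fit <- fx_fit_small()
  expect_true(fit$converged)
  expect_s3_class(fit, "dhglm_fit")
  # scaled residual variances should sit near 1 on well-specified data
  expect_gt(fit$components$scale_params[[1]], 0.7)
  expect_lt(fit$components$scale_params[[1]], 1.3)
  # outer-loop likelihood changes shrink
  dl <- abs(diff(fit$outer_trace))
  expect_lt(dl[length(dl)], 1e-4)
  expect_true(all(fit$leverage >= 0 & fit$leverage < 1))
  expect_equal(length(fit$psi), length(fit$e))
  # fitted per-observation variances track the exponential predictor (the
  # damped update leaves a sub-percent gap at the outer tolerance)
  eta <- as.numeric(fit$bundle$Xv %*% fit$bv + fit$bundle$Z_par %*% fit$auv)
  expect_equal(unname(fit$sigma_e_i), exp(eta), tolerance = 0.02)
})

test_that("with a homoscedastic dispersion side the mean model matches plain REML", {
  fx <- fx_small()
  tr <- truth_params(sigma_av_exp_sq = 0, r_ad_av = 0, sigma_as_sq = 0,
                     sigma_au_as = 0, beta0v = log(0.5))
  sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, tr, seed = 41,
                                   generating_scale = "sire_dam"))
  fit <- quiet(fit_dhglm(sim$phenotypes, fx$lay, fx$ped, fx$A))
  db <- assemble_designs(sim$phenotypes, fx$lay, fx$ped)
  Kp <- fx$A$matrix[db$parents, db$parents]
  ref <- reml_fit(db$y, db$X,
                  random = list(par = list(Z = db$Z_par, K = Kp),
                                cage = list(Z = db$Zt, K = NULL)))
  expect_equal(fit$components$sigma_au_sq, unname(ref$varcomp["par"]),
               tolerance = 0.25)
  expect_equal(fit$components$sigma_e_sq,
               unname(ref$varcomp["residual"]), tolerance = 0.15)
})

test_that("breeding values follow their definitions", {
  fit <- fx_fit_small()
  bv <- predict_breeding_values(fit, n = 12)
  i <- 5
  id <- bv$individual_id[i]
  s <- fit$bundle$sire[match(id, fit$bundle$record_ids)]
  d <- fit$bundle$dam[match(id, fit$bundle$record_ids)]
  expect_equal(bv$ebv_direct[i], unname(fit$au[s] + fit$au[d]))
  expect_equal(bv$tbv[i], bv$ebv_direct[i] + 11 * bv$ebv_indirect[i])
  expect_equal(bv$ebv_dispersion[i], unname(fit$auv[s] + fit$auv[d]))
  # au_sire = 0.1, au_dam = 0.3 -> ad = 0.4 (definition)
  fit2 <- fit
  fit2$au[s] <- 0.1; fit2$au[d] <- 0.3
  expect_equal(predict_breeding_values(fit2, n = 12)$ebv_direct[i], 0.4)
  # all indirect effects zero -> TBV = direct EBV
  fit3 <- fit
  fit3$as_eff[] <- 0
  bv3 <- predict_breeding_values(fit3, n = 12)
  expect_equal(bv3$tbv, bv3$ebv_direct)
})

test_that("A- and H-matrix fits agree when G carries only pedigree information", {
  fx <- fx_small()
  A <- fx$A
  off <- fx$ped$individual_id[!is.na(fx$ped$sire_id)]
  Gped <- structure(list(matrix = A$matrix[off, off], ids = off, kind = "G"),
                    class = "relationship_matrix")
  H <- build_H(A, Gped, genotyped_ids = off, blend_weight = 0.95, tune = TRUE)
  ph <- apply_survival(fx$pheno, 0.95, seed = 33)
  fa <- quiet(fit_dhglm(ph, fx$lay, fx$ped, A))
  fh <- quiet(fit_dhglm(ph, fx$lay, fx$ped, H))
  expect_lt(abs(fh$components$sigma_au_sq - fa$components$sigma_au_sq) /
              fa$components$sigma_au_sq, 0.10)
  expect_lt(abs(fh$components$sigma_e_sq - fa$components$sigma_e_sq) /
              fa$components$sigma_e_sq, 0.10)
})
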