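toy_ped <- function(df) {
  df$generation <- 0L
  df$family_id <- NA_character_
  class(df) <- c("pedigree", "data.frame")
  df
}

test_that("A matrix reproduces textbook relationships", {
  founders <- toy_ped(data.frame(individual_id = c("s", "d"),
                                 sire_id = NA_character_, dam_id = NA_character_))
  expect_equal(unname(build_A(founders)$matrix), diag(2))
  ped <- toy_ped(data.frame(individual_id = c("s", "d", "k1", "k2"),
                            sire_id = c(NA, NA, "s", "s"),
                            dam_id = c(NA, NA, "d", "d")))
  A <- build_A(ped)$matrix
  expect_equal(A["k1", "k2"], 0.5)  # full sibs
  expect_equal(A["s", "k1"], 0.5)   # parent-offspring
  expect_equal(A["k1", "k1"], 1)    # non-inbred
})

test_that("A matrix matches the recursive oracle on an inbred pedigree", {
  # three generations with a full-sib mating -> inbred final individual
  ped <- toy_ped(data.frame(
    individual_id = c("a", "b", "c", "d", "e", "f", "g"),
    sire_id = c(NA, NA, "a", "a", "c", "c", "e"),
    dam_id = c(NA, NA, "b", "b", "d", "d", "f")))
  A <- build_A(ped)$matrix
  O <- relationship_oracle(ped)
  expect_equal(A, O, tolerance = 1e-12)
  expect_gt(A["g", "g"], 1)  # inbreeding from the full-sib mating shows up
  # PSD: Cholesky succeeds with tiny jitter
  expect_silent(chol(A + diag(1e-8, nrow(A))))
})

test_that("pedigree sorting rejects cycles and unknown parents", {
  cyc <- toy_ped(data.frame(individual_id = c("x", "y"),
                            sire_id = c("y", "x"), dam_id = c(NA, NA)))
  expect_error(build_A(cyc), "cycle")
  orphan <- toy_ped(data.frame(individual_id = "x", sire_id = "ghost",
                               dam_id = NA_character_))
  expect_error(build_A(orphan), "absent")
})

test_that("QC filters match hand enumeration on a planted toy", {
  # 6 individuals x 5 SNPs
  codes <- rbind(c(0, 1, 2, 1, 0),
                 c(1, 1, 2, NA, 0),
                 c(0, 2, 2, NA, 1),
                 c(NA, 1, 2, NA, 0),
                 c(NA, 0, 2, NA, 1),
                 c(NA, 1, 2, NA, 0))
  dimnames(codes) <- list(paste0("i", 1:6), paste0("s", 1:5))
  gm <- structure(list(codes = codes, founder_freq = setNames(rep(0.3, 5), colnames(codes)),
                       snp_ids = colnames(codes)), class = "genotype_matrix")
  # by hand: s1 missing 3/6 = 0.5 -> drop; s4 missing 4/6 -> drop;
  # s3 all code 2 -> MAF 0 -> drop; s2 MAF = 1-6/12... freq 6/12=0.5 keep;
  # s5 freq 2/12 = 1/6 -> MAF 0.167 keep. Survivors s2, s5 complete, so all
  # individuals have call rate 1 -> 6 kept.
  out <- qc_genotypes(gm)
  expect_equal(colnames(out$genotypes$codes), c("s2", "s5"))
  expect_equal(out$report$removed_snp_missing, 2)
  expect_equal(out$report$removed_snp_maf, 1)
  expect_equal(out$report$n_individuals_out, 6)

  # strict thresholds: MAF exactly 0.05 removed, call rate 0.76 removed
  codes2 <- matrix(rep(c(0, 1), length.out = 20 * 25), 20, 25,
                   dimnames = list(paste0("i", 1:20), paste0("s", 1:25)))
  codes2[, 1] <- c(rep(1, 2), rep(0, 18))   # freq 2/40 = 0.05, not > 0.05: drop
  codes2[, 2] <- c(rep(1, 3), rep(0, 17))   # freq 3/40 = 0.075: keep
  codes2[1, 10:15] <- NA   # those SNPs: missing 1/20 = 5% < 10%, kept;
                           # i1 call rate 18/24 = 0.75 <= 0.8 -> removed
  gm2 <- structure(list(codes = codes2, founder_freq = setNames(rep(0.3, 25), colnames(codes2)),
                        snp_ids = colnames(codes2)), class = "genotype_matrix")
  out2 <- qc_genotypes(gm2)
  expect_false("s1" %in% colnames(out2$genotypes$codes))
  expect_true("s2" %in% colnames(out2$genotypes$codes))
  expect_false("i1" %in% rownames(out2$genotypes$codes))
  expect_equal(out2$report$n_individuals_out, 19)
})

test_that("VanRaden G matches its closed form and pedigree expectations", {
  gm <- structure(list(codes = matrix(2, 2, 1, dimnames = list(c("x", "y"), "s1")),
                       founder_freq = c(s1 = 0.5), snp_ids = "s1"),
                  class = "genotype_matrix")
  G <- build_G(gm, freq = 0.5)
  expect_equal(unname(G$matrix), matrix(2, 2, 2))  # denom 0.5, centered 1

  expect_error(build_G(gm), "monomorphic")  # observed freq 1 -> zero denominator

  ped <- quiet(simulate_pedigree(4, 4, 4, 6, seed = 21))
  gen <- gene_drop_genotypes(ped, 10000, seed = 21)
  # centering with the known founder frequencies isolates the pedigree
  # expectation; observed-frequency centering is checked separately below
  Gm <- build_G(gen, freq = gen$founder_freq)$matrix
  off <- ped[!is.na(ped$sire_id), ]
  po <- mapply(function(k, s) Gm[k, s], off$individual_id, off$sire_id)
  expect_lt(abs(mean(po) - 0.5), 0.05)          # parent-offspring ~ 0.5
  founders <- ped$individual_id[is.na(ped$sire_id)]
  expect_lt(abs(mean(diag(Gm)[founders]) - 1), 0.05)  # 1 + F ~ 1 under HWE
  # centering with observed frequencies: mean off-diagonal ~ 0
  Gobs <- build_G(gen)$matrix
  n <- nrow(Gobs)
  expect_lt(abs((sum(Gobs) - sum(diag(Gobs))) / (n^2 - n)), 0.05)
})

test_that("H matrix limits and block formula hold", {
  fx <- fx_small()
  A <- fx$A
  expect_equal(build_H(A)$matrix, A$matrix)  # no genotyped individuals

  ped <- quiet(simulate_pedigree(3, 3, 3, 4, seed = 22))
  gen <- gene_drop_genotypes(ped, 2000, seed = 22)
  A2 <- build_A(ped)
  G2 <- build_G(gen)
  Hall <- build_H(A2, G2, genotyped_ids = A2$ids, blend_weight = 1, tune = FALSE)
  expect_equal(Hall$matrix, G2$matrix[A2$ids, A2$ids], tolerance = 1e-12)

  # 4-individual pedigree, 2 genotyped: dense block-formula oracle
  ped4 <- toy_ped(data.frame(individual_id = c("s", "d", "k1", "k2"),
                             sire_id = c(NA, NA, "s", "s"),
                             dam_id = c(NA, NA, "d", "d")))
  A4 <- build_A(ped4)
  gen4 <- gene_drop_genotypes(ped4, 500, seed = 23)
  g_ids <- c("k1", "k2")
  G4 <- build_G(structure(list(codes = gen4$codes[g_ids, ],
                               founder_freq = gen4$founder_freq,
                               snp_ids = gen4$snp_ids), class = "genotype_matrix"))
  H4 <- build_H(A4, G4, g_ids, blend_weight = 0.95, tune = FALSE)
  Am <- A4$matrix; Gb <- 0.95 * G4$matrix + 0.05 * Am[g_ids, g_ids]
  i1 <- c("s", "d")
  A22i <- solve(Am[g_ids, g_ids])
  oracle11 <- Am[i1, i1] + Am[i1, g_ids] %*% A22i %*% (Gb - Am[g_ids, g_ids]) %*%
    A22i %*% Am[g_ids, i1]
  oracle12 <- Am[i1, g_ids] %*% A22i %*% Gb
  expect_equal(H4$matrix[i1, i1], oracle11, tolerance = 1e-10)
  expect_equal(H4$matrix[i1, g_ids], oracle12, tolerance = 1e-10)
  expect_equal(H4$matrix[g_ids, g_ids], Gb, tolerance = 1e-10)
  expect_equal(H4$matrix, t(H4$matrix))
})

test_that("H approaches A as the genomic blend weight vanishes (with tuning)", {
  ped <- quiet(simulate_pedigree(4, 4, 4, 5, seed = 24))
  gen <- gene_drop_genotypes(ped, 1500, seed = 24)
  A <- build_A(ped)
  G <- build_G(gen)
  off <- ped$individual_id[!is.na(ped$sire_id)]
  for (w in c(0.2, 0.05, 0.01)) {
    H <- build_H(A, G, off, blend_weight = w, tune = TRUE)
    dmax <- max(abs(H$matrix - A$matrix))
    expect_lt(dmax, w * 2 + 0.02)
  }
})

test_that("relationship matrices round-trip through sparse text", {
  fx <- fx_small()
  path <- withr::local_tempfile(fileext = ".txt")
  write_relmat(fx$A, path)
  back <- read_relmat(path)
  expect_equal(back$matrix, fx$A$matrix, tolerance = 1e-12)
  expect_equal(back$kind, "A")
})
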