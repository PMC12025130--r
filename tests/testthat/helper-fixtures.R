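# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# small geometry for unit tests: 12 families x 12 (3 cages of 4 each)
fx_small <- function() fixture("small", function() {
  lay <- build_layout(12, 3, 4, seed = 3)
  ped <- quiet(simulate_pedigree(12, 12, 12, 12, seed = 3))
  A <- build_A(ped)
  sim <- quiet(simulate_phenotypes(ped, lay, truth_params(beta0v = log(0.5)),
                                   seed = 31, generating_scale = "sire_dam"))
  list(lay = lay, ped = ped, A = A, sim = sim, pheno = sim$phenotypes)
})

# the trial geometry: 40 families x 36 in 40 cages of 3 x 12
fx_trial <- function() fixture("trial", function() {
  lay <- build_layout(40, 3, 12, seed = 1)
  ped <- quiet(simulate_pedigree(40, 40, 40, 36, seed = 1))
  A <- build_A(ped)
  list(lay = lay, ped = ped, A = A)
})

# ten replicate DHGLM fits (IGE and NoIGE) at the trial geometry under the
# study-condition truth; consumed by the parameter-recovery, null-calibration
# and directional-IGE acceptance tests
fx_recovery <- function() fixture("recovery", function() {
  fx <- fx_trial()
  tr <- truth_params(beta0v = log(0.52))
  reps <- lapply(1:10, function(s) {
    sim <- quiet(simulate_phenotypes(fx$ped, fx$lay, tr, seed = 1000 + s,
                                     generating_scale = "sire_dam"))
    ph <- apply_survival(sim$phenotypes, 0.9271, seed = 2000 + s)
    list(ige = quiet(fit_dhglm(ph, fx$lay, fx$ped, fx$A, include_ige = TRUE)),
         noige = quiet(fit_dhglm(ph, fx$lay, fx$ped, fx$A, include_ige = FALSE)))
  })
  list(truth = tr, reps = reps)
})

# one converged small DHGLM fit for structure-level tests
fx_fit_small <- function() fixture("fit_small", function() {
  fx <- fx_small()
  ph <- apply_survival(fx$pheno, 0.95, seed = 32)
  quiet(fit_dhglm(ph, fx$lay, fx$ped, fx$A, include_ige = TRUE))
})

# genomic CV fixture: cryptic founder relatedness + marker-based effects
fx_genomic <- function() fixture("genomic", function() {
  nf <- 24
  ped_full <- quiet(simulate_pedigree(nf, nf, nf, 24, base_pop_size = 12, seed = 5))
  lay <- build_layout(nf, 3, 8, seed = 5)
  gen <- gene_drop_genotypes(ped_full, 3000, seed = 6)
  tr <- truth_params(sigma_as_sq = 0, sigma_au_as = 0, beta0v = log(0.30))
  sim <- quiet(simulate_phenotypes(ped_full, lay, tr, seed = 7,
                                   genetic_basis = "markers", genotypes = gen))
  ph <- apply_survival(sim$phenotypes, 0.9271, seed = 8)
  ped <- truncate_pedigree(ped_full)
  A <- build_A(ped)
  offspring <- ped$individual_id[!is.na(ped$sire_id)]
  gsub <- gen
  gsub$codes <- gen$codes[offspring, , drop = FALSE]
  G <- build_G(gsub)
  H <- build_H(A, G, genotyped_ids = offspring)
  list(ped_full = ped_full, ped = ped, lay = lay, gen = gen, sim = sim,
       pheno = ph, A = A, G = G, H = H, offspring = offspring)
})

# brute-force 3FAM structure checker, independent of validate_layout:
# one count per malformed cage, per family with the wrong cage count, and per
# distinct family pair appearing in more than one cage
brute_force_layout_violations <- function(cages, cages_per_family,
                                          family_ids = NULL) {
  nviol <- 0L
  fams <- lapply(cages, `[[`, "families")
  if (is.null(family_ids)) family_ids <- sort(unique(unlist(fams)))
  for (f in fams) if (length(unique(f)) != 3) nviol <- nviol + 1L
  tab <- table(factor(unlist(fams), levels = family_ids))
  nviol <- nviol + sum(tab != cages_per_family)
  pairs <- unlist(lapply(fams, function(f) {
    out <- character(0)
    for (i in 1:2) for (j in (i + 1):3) {
      out <- c(out, paste(sort(c(f[i], f[j])), collapse = "|"))
    }
    out
  }))
  nviol + sum(table(pairs) > 1)
}

# additive relationship by memoised recursion (independent of build_A)
relationship_oracle <- function(ped) {
  sire <- setNames(ped$sire_id, ped$individual_id)
  dam <- setNames(ped$dam_id, ped$individual_id)
  pos <- setNames(seq_len(nrow(ped)), ped$individual_id)
  memo <- new.env(parent = emptyenv())
  a <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "~")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + 0.5 * a(sire[[i]], dam[[i]])
    } else {
      if (pos[[i]] < pos[[j]]) { tmp <- i; i <- j; j <- tmp }
      0.5 * (a(sire[[i]], j) + a(dam[[i]], j))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  out <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  for (i in ped$individual_id) for (j in ped$individual_id) out[i, j] <- a(i, j)
  out
}

# dense restricted log-likelihood for a one-random-effect model (grid oracle)
dense_restricted_loglik <- function(y, X, Z, K, s2u, s2e) {
  V <- s2u * (Z %*% K %*% t(Z)) + diag(s2e, length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            as.numeric(t(y) %*% P %*% y))
}
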