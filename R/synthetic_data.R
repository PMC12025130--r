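#' Simulate a full-sib family pedigree
#'
#' Founder sires and dams, then `n_families` full-sib families of
#' `family_size` offspring from distinct sire x dam pairs (one pair per
#' family). Offspring ids are `<family>_<nn>` so that they align with the
#' member ids generated by [build_layout()].
#'
#' With `base_pop_size > 0` an additional unrecorded base generation is
#' simulated and the sires/dams are drawn as offspring of random base-pair
#' matings, creating cryptic relatedness among the nominal founders (the
#' situation of a nucleus population with incomplete pedigree depth).
#' [truncate_pedigree()] removes the base generation again for analyses that
#' should be blind to it.
#'
#' @param n_sires,n_dams numbers of founder parents available.
#' @param n_families number of full-sib families (<= n_sires * n_dams).
#' @param family_size offspring per family.
#' @param family_ids optional family ids (default `F01`, ...).
#' @param base_pop_size unrecorded base individuals (0 = unrelated founders).
#' @param seed integer seed.
#' @return data.frame of class `pedigree`: `individual_id`, `sire_id`,
#'   `dam_id` (`NA` for founders), `generation` (-1 base, 0 founders,
#'   1 offspring), `family_id` (`NA` for founders). Parents precede
#'   offspring.
#' @export
simulate_pedigree <- function(n_sires = 40, n_dams = 40, n_families = 40,
                              family_size = 36, family_ids = NULL,
                              base_pop_size = 0, seed = 1L) {
  if (n_families > n_sires * n_dams) stop("insufficient parents: n_families > n_sires*n_dams")
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  if (is.null(family_ids)) family_ids <- sprintf("F%02d", seq_len(n_families))
  sires <- sprintf("S%02d", seq_len(n_sires))
  dams <- sprintf("D%02d", seq_len(n_dams))
  pair_idx <- sample.int(n_sires * n_dams, n_families)
  pair_s <- sires[(pair_idx - 1L) %% n_sires + 1L]
  pair_d <- dams[(pair_idx - 1L) %/% n_sires + 1L]
  base <- NULL
  founder_sire <- founder_dam <- NA_character_
  if (base_pop_size > 0) {
    stopifnot(base_pop_size >= 4)
    bids <- sprintf("B%02d", seq_len(base_pop_size))
    base <- data.frame(individual_id = bids,
                       sire_id = NA_character_, dam_id = NA_character_,
                       generation = -1L, family_id = NA_character_,
                       stringsAsFactors = FALSE)
    half <- base_pop_size %/% 2
    founder_sire <- bids[sample.int(half, n_sires + n_dams, replace = TRUE)]
    founder_dam <- bids[half + sample.int(base_pop_size - half, n_sires + n_dams,
                                          replace = TRUE)]
  }
  founders <- data.frame(individual_id = c(sires, dams),
                         sire_id = founder_sire, dam_id = founder_dam,
                         generation = 0L, family_id = NA_character_,
                         stringsAsFactors = FALSE)
  offspring <- do.call(rbind, lapply(seq_len(n_families), function(f) {
    data.frame(individual_id = sprintf("%s_%02d", family_ids[f], seq_len(family_size)),
               sire_id = pair_s[f], dam_id = pair_d[f],
               generation = 1L, family_id = family_ids[f],
               stringsAsFactors = FALSE)
  }))
  ped <- rbind(base, founders, offspring)
  class(ped) <- c("pedigree", "data.frame")
  log_stage("simulate_pedigree", seed = seed,
            n_families = n_families, family_size = family_size)
  ped
}

#' Drop unrecorded pedigree depth
#'
#' Removes generations below `keep_from` and blanks the parent links of the
#' oldest retained generation, yielding the pedigree an analyst without the
#' deeper records would use.
#'
#' @param pedigree a `pedigree` with a `generation` column.
#' @param keep_from oldest generation to retain.
#' @return truncated `pedigree`.
#' @export
truncate_pedigree <- function(pedigree, keep_from = 0L) {
  ped <- pedigree[pedigree$generation >= keep_from, , drop = FALSE]
  oldest <- ped$generation == min(ped$generation)
  ped$sire_id[oldest] <- NA_character_
  ped$dam_id[oldest] <- NA_character_
  rownames(ped) <- NULL
  ped
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn independently per locus at a per-SNP allele
#' frequency uniform on (`maf_low`, `maf_high`); offspring inherit one allele
#' from each parent by fair Mendelian sampling. Loci are unlinked.
#'
#' @param pedigree a `pedigree` (parents before offspring).
#' @param n_snps number of biallelic loci.
#' @param maf_low,maf_high founder allele-frequency bounds, in (0, 0.5].
#' @param missing_rate fraction of genotype calls set to missing at random.
#' @param seed integer seed.
#' @return list of class `genotype_matrix`: `codes` (individuals x SNPs,
#'   additive 0/1/2 with `NA` missing, dimnames set), `founder_freq` (the
#'   frequencies alleles were dropped at), `snp_ids`.
#' @export
gene_drop_genotypes <- function(pedigree, n_snps, maf_low = 0.05,
                                maf_high = 0.5, missing_rate = 0, seed = 1L) {
  stopifnot(maf_low > 0, maf_high <= 0.5, maf_low <= maf_high)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  ped <- sort_pedigree(pedigree)
  n <- nrow(ped)
  p <- runif(n_snps, maf_low, maf_high)
  h1 <- matrix(0L, n, n_snps)
  h2 <- matrix(0L, n, n_snps)
  row_of <- setNames(seq_len(n), ped$individual_id)
  for (i in seq_len(n)) {
    s <- ped$sire_id[i]; d <- ped$dam_id[i]
    h1[i, ] <- if (is.na(s)) as.integer(runif(n_snps) < p) else {
      si <- row_of[[s]]
      ifelse(runif(n_snps) < 0.5, h1[si, ], h2[si, ])
    }
    h2[i, ] <- if (is.na(d)) as.integer(runif(n_snps) < p) else {
      di <- row_of[[d]]
      ifelse(runif(n_snps) < 0.5, h1[di, ], h2[di, ])
    }
  }
  codes <- h1 + h2
  if (missing_rate > 0) {
    codes[runif(length(codes)) < missing_rate] <- NA_integer_
  }
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  dimnames(codes) <- list(ped$individual_id, snp_ids)
  structure(list(codes = codes, founder_freq = setNames(p, snp_ids),
                 snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' Generating parameters for the phenotype simulator
#'
#' Defaults emulate the study conditions of the shrimp trial the package is
#' designed around: parent-level direct variance 0.14, direct-indirect
#' covariance 0.002, indirect variance 0.00015, cage variance 0.03,
#' exponential-scale dispersion genetic variance 0.25, tagging weight
#' Normal(4.8, 0.5^2) g truncated positive, overall mean near 16.6 g with
#' females about 0.9 g heavier than males. Scales follow the sire-dam
#' reporting convention (see [fit_dhglm()]): the generator converts them to
#' individual additive scale internally (direct 4*sigma_au_sq, covariance
#' 2*sigma_au_as, indirect and dispersion used as given).
#'
#' @param sigma_au_sq parent-level direct genetic variance for harvest weight.
#' @param sigma_au_as parent-level direct-indirect covariance (reported scale).
#' @param sigma_as_sq indirect genetic variance (reported/additive scale);
#'   0 disables indirect effects.
#' @param sigma_t_sq random cage variance.
#' @param sigma_av_exp_sq additive genetic variance of log residual variance
#'   (exponential scale).
#' @param r_ad_av genetic correlation between direct mean and dispersion
#'   effects.
#' @param beta0v intercept of log residual variance (environmental part).
#' @param sexv_female additive shift of log residual variance for females.
#' @param mu overall mean harvest weight (g).
#' @param sex_diff female minus male mean difference (g).
#' @param slope_male,slope_female sex-specific regressions of harvest weight
#'   on tagging weight (g per g).
#' @param m1bw_mean,m1bw_sd tagging body-weight distribution (g).
#' @return list of class `truth_params`.
#' @export
truth_params <- function(sigma_au_sq = 0.14, sigma_au_as = 0.002,
                         sigma_as_sq = 0.00015, sigma_t_sq = 0.03,
                         sigma_av_exp_sq = 0.25, r_ad_av = 0.2,
                         beta0v = log(0.24), sexv_female = 0.1,
                         mu = 16.6, sex_diff = 0.9,
                         slope_male = 2.5, slope_female = 2.7,
                         m1bw_mean = 4.8, m1bw_sd = 0.5) {
  sigma_ad_sq <- 4 * sigma_au_sq
  sigma_ad_av <- r_ad_av * sqrt(sigma_ad_sq * sigma_av_exp_sq)
  Sigma <- matrix(c(sigma_ad_sq, 2 * sigma_au_as, sigma_ad_av,
                    2 * sigma_au_as, sigma_as_sq, 0,
                    sigma_ad_av, 0, sigma_av_exp_sq), 3, 3,
                  dimnames = list(c("ad", "as", "av"), c("ad", "as", "av")))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    stop("generating covariance matrix is not positive semi-definite")
  }
  structure(list(sigma_au_sq = sigma_au_sq, sigma_au_as = sigma_au_as,
                 sigma_as_sq = sigma_as_sq, sigma_t_sq = sigma_t_sq,
                 sigma_av_exp_sq = sigma_av_exp_sq, r_ad_av = r_ad_av,
                 beta0v = beta0v, sexv_female = sexv_female,
                 mu = mu, sex_diff = sex_diff,
                 slope_male = slope_male, slope_female = slope_female,
                 m1bw_mean = m1bw_mean, m1bw_sd = m1bw_sd,
                 Sigma_additive = Sigma),
            class = "truth_params")
}

# individual_id -> (cage_id, family_id) table for a layout
layout_members <- function(layout) {
  do.call(rbind, lapply(layout$cages, function(cg) {
    data.frame(individual_id = cg$members, cage_id = cg$cage_id,
               family_id = sub("_[0-9]+$", "", cg$members),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate phenotypes under the DHGLM-IGE generative model
#'
#' Draws correlated individual-level direct (`ad`), indirect (`as`) and
#' dispersion (`av`) genetic effects, iid cage effects, and phenotypes
#' \deqn{y_i = \mu + sex_i + \beta_{sex}\,M1BW_i + ad_i +
#'       \sum_{j \in cage(i), j \ne i} as_j + t_{cage(i)} + e_i,\qquad
#'       e_i \sim N(0, \exp(\beta_{0v} + sexv_i + av_i)).}
#' With `genetic_basis = "pedigree"` the effects are multivariate normal with
#' covariance `Sigma (x) A` over the pedigree (Mendelian sampling included).
#' With `genetic_basis = "markers"` the effects are sums of per-SNP effects on
#' the supplied gene-dropped genotypes, covariance-matched to the same `Sigma`
#' (so realized genomic relationships, not just expected ones, structure the
#' effects - the regime in which single-step genomic evaluation can genuinely
#' outperform pedigree BLUP).
#'
#' The `generating_scale` argument controls where the genetic effects live.
#' `"individual"` draws `(ad, as, av)` per individual (Mendelian sampling
#' included) -- the scale on which total-breeding-value and phenotypic
#' variance identities hold exactly. `"sire_dam"` draws effects at the parent
#' level and gives each offspring the sum of its parents' effects, which is
#' exactly the process the sire-dam DHGLM fits; use it to calibrate parameter
#' recovery of the fitting machinery. (Under `"individual"` the
#' within-family half of the direct variance is homoscedastic residual from
#' the model's viewpoint, so the model's dispersion component estimates the
#' genetic variance of the log *total* residual variance -- systematically
#' smaller than the generating `sigma_av_exp_sq`.)
#'
#' @param pedigree a `pedigree` covering all layout members.
#' @param layout a `design_layout`; its members define cage co-membership.
#' @param truth a [truth_params()] list.
#' @param seed integer seed.
#' @param genetic_basis `"pedigree"` or `"markers"`.
#' @param genotypes `genotype_matrix` (required for `"markers"`).
#' @param generating_scale `"individual"` (default) or `"sire_dam"`.
#' @return list with `phenotypes` (phenotype table, all alive) and `truth`
#'   (`simulation_truth`: effect vectors `ad`, `as`, `av` indexed by
#'   individual, cage effects `t`, the additive-scale covariance actually
#'   used, the input parameters and seed).
#' @export
simulate_phenotypes <- function(pedigree, layout, truth = truth_params(),
                                seed = 1L,
                                genetic_basis = c("pedigree", "markers"),
                                genotypes = NULL,
                                generating_scale = c("individual", "sire_dam")) {
  genetic_basis <- match.arg(genetic_basis)
  generating_scale <- match.arg(generating_scale)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  ped <- sort_pedigree(pedigree)
  members <- layout_members(layout)
  if (!all(members$individual_id %in% ped$individual_id)) {
    stop("layout members missing from pedigree")
  }
  Sigma <- truth$Sigma_additive
  n_ped <- nrow(ped)
  if (generating_scale == "sire_dam") {
    # parent-level effects; each offspring receives the sum of its parents'
    sire_of <- setNames(ped$sire_id, ped$individual_id)
    dam_of <- setNames(ped$dam_id, ped$individual_id)
    off <- ped$individual_id[!is.na(sire_of) & !is.na(dam_of)]
    parents <- sort(unique(c(sire_of[off], dam_of[off])))
    A <- build_A(ped)
    Ap <- A$matrix[parents, parents]
    # per-parent covariance implied by the reporting conventions
    Sp <- Sigma
    Sp["ad", "ad"] <- Sigma["ad", "ad"] / 4      # v_au
    Sp["as", "as"] <- Sigma["as", "as"] / 4
    Sp["av", "av"] <- Sigma["av", "av"] / 4
    Sp["ad", "as"] <- Sp["as", "ad"] <- Sigma["ad", "as"] / 4
    Sp["ad", "av"] <- Sp["av", "ad"] <- Sigma["ad", "av"] / 4
    LA <- t(chol(Ap + diag(1e-10, nrow(Ap))))
    LS <- t(chol(Sp + diag(1e-12, 3)))
    Ep <- LA %*% matrix(rnorm(nrow(Ap) * 3), nrow(Ap), 3) %*% t(LS)
    rownames(Ep) <- parents
    E <- matrix(0, n_ped, 3, dimnames = list(ped$individual_id, c("ad", "as", "av")))
    E[parents, ] <- Ep
    E[off, ] <- Ep[sire_of[off], ] + Ep[dam_of[off], ]
  } else if (genetic_basis == "pedigree") {
    A <- build_A(ped)
    LA <- t(chol(A$matrix + diag(1e-10, n_ped)))
    LS <- t(chol(Sigma + diag(1e-12, 3)))
    E <- LA %*% matrix(rnorm(n_ped * 3), n_ped, 3) %*% t(LS)
  } else {
    if (is.null(genotypes)) stop("genetic_basis='markers' requires genotypes")
    Z <- genotypes$codes[ped$individual_id, , drop = FALSE]
    p <- genotypes$founder_freq
    Zc <- sweep(Z, 2, 2 * p)
    denom <- sum(2 * p * (1 - p))
    LS <- t(chol(Sigma + diag(1e-12, 3)))
    B <- matrix(rnorm(ncol(Zc) * 3), ncol(Zc), 3) %*% t(LS) / sqrt(denom)
    E <- Zc %*% B
  }
  rownames(E) <- ped$individual_id
  colnames(E) <- c("ad", "as", "av")

  cages <- vapply(layout$cages, `[[`, "", "cage_id")
  t_eff <- setNames(rnorm(length(cages), 0, sqrt(truth$sigma_t_sq)), cages)

  ids <- members$individual_id
  n <- length(ids)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  m1bw <- rnorm(n, truth$m1bw_mean, truth$m1bw_sd)
  while (any(m1bw <= 0)) m1bw[m1bw <= 0] <- rnorm(sum(m1bw <= 0), truth$m1bw_mean, truth$m1bw_sd)
  as_all <- E[ids, "as"]
  cage_as_total <- tapply(as_all, members$cage_id, sum)[members$cage_id]
  ige_in <- if (truth$sigma_as_sq > 0) cage_as_total - as_all else rep(0, n)
  sexf <- as.numeric(sex == "female")
  slope <- ifelse(sex == "female", truth$slope_female, truth$slope_male)
  log_var <- truth$beta0v + truth$sexv_female * sexf + E[ids, "av"]
  e <- rnorm(n, 0, sqrt(exp(log_var)))
  y <- truth$mu + (sexf - 0.5) * truth$sex_diff +
    slope * (m1bw - truth$m1bw_mean) +
    E[ids, "ad"] + ige_in + t_eff[members$cage_id] + e
  pheno <- data.frame(individual_id = ids,
                      family_id = members$family_id,
                      cage_id = members$cage_id,
                      sex = sex, initial_weight = m1bw,
                      harvest_weight = y, alive = TRUE,
                      stringsAsFactors = FALSE)
  # degenerate all-variance-zero draws can graze 0; keep validity meaningful
  truth_out <- structure(list(ad = E[, "ad"], as = E[, "as"], av = E[, "av"],
                              t = t_eff, Sigma_additive = Sigma,
                              params = truth, residual = setNames(e, ids),
                              genetic_basis = genetic_basis,
                              generating_scale = generating_scale, seed = seed),
                         class = "simulation_truth")
  log_stage("simulate_phenotypes", seed = seed, n = n, basis = genetic_basis,
            scale = generating_scale)
  list(phenotypes = pheno, truth = truth_out)
}

#' Thin a phenotype table by random survival
#'
#' Non-informative iid Bernoulli survival: dead individuals keep their
#' covariates but lose the harvest-weight record.
#'
#' @param pheno phenotype table.
#' @param survival_rate probability of surviving to harvest, in (0, 1].
#' @param seed integer seed.
#' @return phenotype table with updated `alive` and `harvest_weight`.
#' @export
apply_survival <- function(pheno, survival_rate = 0.9271, seed = 1L) {
  stopifnot(survival_rate > 0, survival_rate <= 1)
  if (survival_rate == 1) return(pheno)
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  alive <- runif(nrow(pheno)) < survival_rate
  pheno$alive <- pheno$alive & alive
  pheno$harvest_weight[!pheno$alive] <- NA_real_
  pheno
}

#' Write simulated data to plain-text files
#'
#' Phenotypes and pedigree as CSV, genotypes as a tab-separated additive-coded
#' table (PLINK `.raw`-like: IID column then one column per SNP), truth as
#' JSON.
#'
#' @param sim output of [simulate_phenotypes()].
#' @param pedigree the pedigree used.
#' @param dir output directory (created if needed).
#' @param genotypes optional `genotype_matrix`.
#' @return invisible character vector of the files written.
#' @export
write_simulation <- function(sim, pedigree, dir, genotypes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(phenotypes = file.path(dir, "phenotypes.csv"),
             pedigree = file.path(dir, "pedigree.csv"),
             truth = file.path(dir, "truth.json"))
  write_phenotypes(sim$phenotypes, files[["phenotypes"]])
  write.csv(as.data.frame(pedigree), files[["pedigree"]], row.names = FALSE, na = "")
  tr <- sim$truth
  jsonlite::write_json(list(ad = as.list(tr$ad), as = as.list(tr$as),
                            av = as.list(tr$av), t = as.list(tr$t),
                            params = unclass(tr$params)[setdiff(names(tr$params), "Sigma_additive")],
                            seed = tr$seed),
                       files[["truth"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(genotypes)) {
    gf <- file.path(dir, "genotypes.raw")
    df <- data.frame(IID = rownames(genotypes$codes), genotypes$codes,
                     check.names = FALSE)
    write.table(df, gf, sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
    files <- c(files, genotypes = gf)
  }
  invisible(files)
}

#' Read an additive-coded genotype table
#'
#' Tab-separated, `IID` column then one column per SNP with 0/1/2/NA codes
#' (the layout written by [write_simulation()], compatible with the numeric
#' part of PLINK `.raw` exports).
#'
#' @param path file path.
#' @return a `genotype_matrix` (founder frequencies recomputed as observed
#'   frequencies).
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$IID
  codes <- as.matrix(df[, setdiff(names(df), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")), drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- ids
  bad <- !(codes %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("genotype codes must be 0/1/2/NA")
  p <- colMeans(codes, na.rm = TRUE) / 2
  structure(list(codes = codes, founder_freq = p, snp_ids = colnames(codes)),
            class = "genotype_matrix")
}
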