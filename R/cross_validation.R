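#' Adjusted phenotypes from a reference DHGLM fit
#'
#' Phenotypes with fixed-effect estimates removed: `y* = y - X b-hat`, which
#' by the fit decomposition equals `ad-hat + t-hat + e-hat`, and the
#' dispersion analogue `psi* = psi - Xv bv-hat = av-hat + ev-hat`. These are
#' the validation targets of cross-validation.
#'
#' @param fit a converged `dhglm_fit` (conventionally a no-IGE reference
#'   model).
#' @return list `y_star`, `psi_star`, named by record id.
#' @export
adjust_phenotypes <- function(fit) {
  if (!fit$converged) stop("reference fit did not converge")
  bundle <- fit$bundle
  y_star <- bundle$y - as.numeric(bundle$X %*% fit$b)
  psi_star <- fit$psi - as.numeric(bundle$Xv %*% fit$bv)
  list(y_star = setNames(y_star, bundle$record_ids),
       psi_star = setNames(psi_star, bundle$record_ids))
}

#' Balanced random folds
#'
#' Partition ids into `k` folds whose sizes differ by at most one;
#' deterministic given the seed.
#'
#' @param ids character or integer vector.
#' @param k number of folds (<= length(ids)).
#' @param seed integer seed.
#' @return integer fold assignment (1..k) named by id.
#' @export
make_folds <- function(ids, k, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("k > number of ids")
  old <- set_local_seed(seed); on.exit(restore_seed(old))
  setNames(sample(rep_len(seq_len(k), n)), ids)
}

#' Prediction accuracy and bias
#'
#' Pearson correlation between adjusted phenotypes and predicted (G)EBVs, and
#' the regression coefficient of the adjusted phenotype on the prediction
#' (1 = unbiased; > 1 indicates EBV underdispersion/underestimation,
#' < 1 overestimation).
#'
#' @param adjusted adjusted phenotypes of the validation animals.
#' @param predicted their (G)EBVs.
#' @return named numeric `c(r, b)`.
#' @export
accuracy_bias <- function(adjusted, predicted) {
  if (length(adjusted) < 3 || length(adjusted) != length(predicted)) {
    stop("need >= 3 paired values")
  }
  if (var(adjusted) == 0 || var(predicted) == 0) stop("zero-variance input")
  c(r = cor(adjusted, predicted),
    b = as.numeric(cov(adjusted, predicted) / var(predicted)))
}

# refit the bivariate MME of `fit` with the given record ids masked (both the
# mean and dispersion rows), at fixed variance components, weights and psi
refit_masked <- function(fit, masked_ids) {
  bundle <- fit$bundle
  n <- length(bundle$y)
  keep <- !(bundle$record_ids %in% masked_ids)
  h <- fit$leverage
  th_g <- rbind(c(fit$components$raw$v_au, fit$components$raw$c_au_auv),
                c(fit$components$raw$c_au_auv, fit$components$raw$v_auv))
  sc <- stack_model(bundle, fit$K_par, th_g,
                    if (fit$include_cage) fit$components$sigma_t_sq else NA_real_,
                    fit$sigma_e_i, h, include_ige = FALSE,
                    include_cage = fit$include_cage)
  rows <- c(which(keep), n + which(keep))
  groups <- lapply(sc$groups, function(g) {
    g$Z <- lapply(g$Z, function(z) z[rows, , drop = FALSE]); g
  })
  # keep the full-fit residual scales fixed
  rpart <- list(part = sc$rpart$part[rows], d = sc$rpart$d[rows],
                sigma2 = as.numeric(fit$components$scale_params),
                est = c(FALSE, FALSE))
  out <- solve_mme(c(bundle$y, fit$psi)[rows], sc$Xs[rows, , drop = FALSE],
                   groups, rpart)
  list(au = setNames(out$u[[1]][[1]], bundle$parents),
       auv = setNames(out$u[[1]][[2]], bundle$parents))
}

#' k-fold cross-validated prediction accuracy: pBLUP vs ssGBLUP
#'
#' Compares pedigree-based (A) and single-step genomic (H) prediction of
#' harvest weight (HW) and its uniformity (HWU) by replicated k-fold
#' cross-validation. Adjusted phenotypes come from the pedigree no-IGE
#' reference fit; in every replicate both methods are evaluated on identical
#' folds (paired design). Within each fold the masked animals' records (mean
#' and dispersion rows) are removed, the mixed-model equations are re-solved
#' at the variance components, weights and linearized responses of the
#' corresponding full-data fit, and the masked animals are predicted by their
#' parental sums (`au_s + au_d` for HW, `auv_s + auv_d` for HWU).
#'
#' @param pheno phenotype table.
#' @param layout `design_layout`.
#' @param pedigree pedigree.
#' @param A pedigree `relationship_matrix`.
#' @param H single-step `relationship_matrix` (same parent coverage).
#' @param k folds.
#' @param replicates number of replicate fold randomizations.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param include_ige opt-in: also fit the IGE models (default FALSE,
#'   matching the convention of excluding them from CV).
#' @param control [dhglm_control()] for the full-data fits.
#' @return list of class `cv_report`: `folds` (data.frame method, trait,
#'   replicate, fold, r, b), `summary` (mean accuracy/bias per method x
#'   trait), `k`, `replicates`, `seed`, plus the reference fits.
#' @export
run_cv <- function(pheno, layout, pedigree, A, H, k = 10L, replicates = 20L,
                   seed = 1L, include_ige = FALSE,
                   control = dhglm_control()) {
  fitA <- fit_dhglm(pheno, layout, pedigree, A, include_ige = include_ige,
                    control = control)
  fitH <- fit_dhglm(pheno, layout, pedigree, H, include_ige = include_ige,
                    control = control)
  adj <- adjust_phenotypes(fitA)
  ids <- fitA$bundle$record_ids
  fits <- list(pBLUP = fitA, ssGBLUP = fitH)
  sire <- fitA$bundle$sire; dam <- fitA$bundle$dam
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    folds <- make_folds(ids, k, seed = seed + rep_i)
    for (fold_i in seq_len(k)) {
      test_ids <- ids[folds == fold_i]
      ti <- match(test_ids, ids)
      for (method in names(fits)) {
        sol <- refit_masked(fits[[method]], test_ids)
        ebv_hw <- sol$au[sire[ti]] + sol$au[dam[ti]]
        ebv_hwu <- sol$auv[sire[ti]] + sol$auv[dam[ti]]
        ab_hw <- accuracy_bias(adj$y_star[test_ids], ebv_hw)
        ab_hwu <- accuracy_bias(adj$psi_star[test_ids], ebv_hwu)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, trait = c("HW", "HWU"), replicate = rep_i,
          fold = fold_i, r = c(ab_hw[["r"]], ab_hwu[["r"]]),
          b = c(ab_hw[["b"]], ab_hwu[["b"]]), stringsAsFactors = FALSE)
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  summary_df <- aggregate(cbind(r, b) ~ method + trait, data = folds_df, FUN = mean)
  log_stage("run_cv", seed = seed, k = k, replicates = replicates)
  structure(list(folds = folds_df, summary = summary_df, k = k,
                 replicates = replicates, seed = seed,
                 reference_fit = fitA, genomic_fit = fitH),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation:", x$k, "folds x", x$replicates, "replicates\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-replicate paired accuracy differences
#'
#' Mean accuracy per replicate for each method and the ssGBLUP - pBLUP
#' difference on identical folds, per trait.
#'
#' @param cv a `cv_report`.
#' @return data.frame `trait`, `replicate`, `r_pBLUP`, `r_ssGBLUP`, `diff`.
#' @export
cv_paired_differences <- function(cv) {
  agg <- aggregate(r ~ method + trait + replicate, data = cv$folds, FUN = mean)
  wide <- merge(agg[agg$method == "pBLUP", c("trait", "replicate", "r")],
                agg[agg$method == "ssGBLUP", c("trait", "replicate", "r")],
                by = c("trait", "replicate"), suffixes = c("_pBLUP", "_ssGBLUP"))
  wide$diff <- wide$r_ssGBLUP - wide$r_pBLUP
  wide[order(wide$trait, wide$replicate), ]
}
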