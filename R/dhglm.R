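#' Assemble DHGLM design matrices
#'
#' Builds, over the alive records only, the fixed-effect matrices of the mean
#' model (intercept, sex, sex x initial-weight interaction) and the dispersion
#' model (intercept, sex), the sire+dam incidence for direct genetic effects,
#' the indirect-genetic-effect incidence `Zs` (row i counts, for every parent,
#' how many of i's cage mates are that parent's offspring -- in a full 3FAM
#' cage of 3 x 12 that is 11 on own-family parents and 12 on each other
#' family's parents), and the cage incidence. Cage mates are taken from the
#' layout (the full stocked cage), so animals that died before harvest still
#' appear as interaction partners of the survivors.
#'
#' @param pheno phenotype table (dead rows allowed; they contribute no rows).
#' @param layout `design_layout` enumerating cage membership.
#' @param pedigree pedigree giving each individual's sire and dam.
#' @param include_ige build `Zs`.
#' @param include_cage build `Zt`.
#' @return list of class `design_bundle`: `X`, `Xv`, `Z_par` (sire+dam
#'   incidence), `Zs` (or NULL), `Zt` (or NULL), `parents`, `cage_ids`,
#'   `record_ids`, `sire`, `dam`, `y`.
#' @export
assemble_designs <- function(pheno, layout, pedigree, include_ige = FALSE,
                             include_cage = TRUE) {
  pheno <- validate_phenotypes(pheno, layout)
  ped <- as.data.frame(sort_pedigree(pedigree))
  sire_of <- setNames(ped$sire_id, ped$individual_id)
  dam_of <- setNames(ped$dam_id, ped$individual_id)
  members <- layout_members(layout)
  rec <- pheno[pheno$alive, , drop = FALSE]
  if (!all(rec$individual_id %in% members$individual_id)) {
    stop("records not present in layout membership")
  }
  all_ids <- members$individual_id
  if (anyNA(sire_of[all_ids]) || anyNA(dam_of[all_ids])) {
    stop("individual with unknown parents cannot enter the parental design")
  }
  parents <- sort(unique(c(sire_of[all_ids], dam_of[all_ids])))
  np <- length(parents)
  pidx <- setNames(seq_len(np), parents)
  n <- nrow(rec)

  rec$sex <- factor(rec$sex, levels = c("male", "female"))
  X <- stats::model.matrix(~ sex + sex:initial_weight, data = rec)
  Xv <- stats::model.matrix(~ sex, data = rec)

  ri <- seq_len(n)
  Z_par <- sparseMatrix(i = c(ri, ri),
                        j = c(pidx[sire_of[rec$individual_id]],
                              pidx[dam_of[rec$individual_id]]),
                        x = 1, dims = c(n, np),
                        dimnames = list(rec$individual_id, parents))

  Zs <- NULL
  if (include_ige) {
    # per cage: total parent counts over all members; row i = total - own
    mem_cage <- setNames(members$cage_id, members$individual_id)
    cage_ids_all <- sort(unique(members$cage_id))
    cage_tot <- matrix(0, length(cage_ids_all), np,
                       dimnames = list(cage_ids_all, parents))
    for (id in all_ids) {
      cg <- mem_cage[[id]]
      cage_tot[cg, pidx[[sire_of[[id]]]]] <- cage_tot[cg, pidx[[sire_of[[id]]]]] + 1
      cage_tot[cg, pidx[[dam_of[[id]]]]] <- cage_tot[cg, pidx[[dam_of[[id]]]]] + 1
    }
    Zs <- cage_tot[mem_cage[rec$individual_id], , drop = FALSE]
    own <- cbind(seq_len(n), pidx[sire_of[rec$individual_id]])
    Zs[own] <- Zs[own] - 1
    own <- cbind(seq_len(n), pidx[dam_of[rec$individual_id]])
    Zs[own] <- Zs[own] - 1
    Zs <- Matrix(Zs, sparse = TRUE)
    rownames(Zs) <- rec$individual_id
  }

  Zt <- NULL
  cage_ids <- sort(unique(rec$cage_id))
  if (include_cage) {
    Zt <- sparseMatrix(i = ri, j = match(rec$cage_id, cage_ids), x = 1,
                       dims = c(n, length(cage_ids)),
                       dimnames = list(rec$individual_id, cage_ids))
  }
  structure(list(X = X, Xv = Xv, Z_par = Z_par, Zs = Zs, Zt = Zt,
                 parents = parents, cage_ids = cage_ids,
                 record_ids = rec$individual_id,
                 sire = sire_of[rec$individual_id],
                 dam = dam_of[rec$individual_id],
                 y = rec$harvest_weight),
            class = "design_bundle")
}

#' Linearized dispersion response
#'
#' The working response of the residual-variance model,
#' `psi_i = log(sigma_ei^2) + (e_i^2/(1 - h_i) - sigma_ei^2) / sigma_ei^2`,
#' a first-order expansion of the log squared residual around the current
#' per-observation residual variance.
#'
#' @param e_sq squared residuals of the mean model.
#' @param h leverages (diagonal of the hat matrix of the mean model), `< 1`.
#' @param sigma_e_i per-observation residual variances from the previous
#'   iteration, `> 0`.
#' @return numeric vector psi.
#' @export
update_psi <- function(e_sq, h, sigma_e_i) {
  if (any(h >= 1)) stop("leverage >= 1")
  if (any(sigma_e_i <= 0)) stop("non-positive residual variance")
  log(sigma_e_i) + (e_sq / (1 - h) - sigma_e_i) / sigma_e_i
}

#' Leverages of a weighted mixed model
#'
#' Diagonal of the hat matrix mapping observations to fitted values of
#' Henderson's mixed-model equations at fixed variance components:
#' `h_i = w_i' C^{-1} w_i / Var(e_i)` with `w_i` the i-th row of `[X Z]`.
#'
#' @param bundle a `design_bundle` (its `X`, `Z_par`, `Zs`, `Zt` are used) or
#'   a plain fixed-effect matrix `X`.
#' @param weights known residual variance multipliers per observation.
#' @param components list with `sigma_au_sq` (parent-level direct variance),
#'   optional `sigma_as_raw` and `sigma_au_as_raw` (per-parent indirect
#'   variance/covariance), optional `sigma_t_sq`, and `sigma_e_sq` (residual
#'   scale); `K` optional parent kernel (identity default).
#' @return numeric leverages, each in `[0, 1)`.
#' @export
compute_leverages <- function(bundle, weights = NULL, components = list(sigma_e_sq = 1)) {
  if (is.matrix(bundle)) bundle <- list(X = bundle)
  X <- bundle$X
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  groups <- list()
  if (!is.null(bundle$Z_par)) {
    K <- components$K
    if (is.null(K)) K <- diag(ncol(bundle$Z_par))
    if (inherits(K, "relationship_matrix")) K <- K$matrix
    if (!is.null(bundle$Zs) && !is.null(components$sigma_as_raw)) {
      th <- matrix(c(components$sigma_au_sq, components$sigma_au_as_raw %||% 0,
                     components$sigma_au_as_raw %||% 0, components$sigma_as_raw), 2, 2)
      groups <- c(groups, list(list(Z = list(bundle$Z_par, bundle$Zs), K = K, theta = th)))
    } else {
      groups <- c(groups, list(list(Z = list(bundle$Z_par), K = K,
                                    theta = matrix(components$sigma_au_sq, 1, 1))))
    }
  }
  if (!is.null(bundle$Zt) && !is.null(components$sigma_t_sq)) {
    groups <- c(groups, list(list(Z = list(bundle$Zt), K = diag(ncol(bundle$Zt)),
                                  theta = matrix(components$sigma_t_sq, 1, 1))))
  }
  rpart <- list(part = rep(1L, n), d = weights,
                sigma2 = components$sigma_e_sq %||% 1)
  fit <- solve_mme(rep(0, n), X, groups, rpart)
  fit$leverage
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Control settings for [fit_dhglm()]
#'
#' @param tol_outer convergence tolerance on the outer-loop change in
#'   restricted log-likelihood.
#' @param tol_inner inner AI-REML tolerance.
#' @param max_outer,max_inner iteration caps.
#' @param bound lower bound for variances.
#' @param damping initial relaxation factor in (0, 1] for the update of the
#'   per-observation log residual variances; reduced automatically when the
#'   outer log-likelihood oscillates.
#' @param trace print progress.
#' @export
dhglm_control <- function(tol_outer = 1e-4, tol_inner = 1e-6, max_outer = 50L,
                          max_inner = 100L, bound = 1e-8, damping = 1,
                          trace = FALSE) {
  stopifnot(tol_outer > 0, tol_inner > 0, damping > 0, damping <= 1)
  list(tol_outer = tol_outer, tol_inner = tol_inner,
       max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
       bound = bound, damping = damping, trace = isTRUE(trace))
}

# stacked bivariate model pieces shared by the fitter and the CV refits
stack_model <- function(bundle, K_par, theta_g, theta_t, sigma_ei2, h,
                        include_ige, include_cage) {
  n <- length(bundle$y)
  zero_par <- Matrix(0, n, ncol(bundle$Z_par), sparse = TRUE)
  Zau <- rbind(bundle$Z_par, zero_par)
  Zauv <- rbind(zero_par, bundle$Z_par)
  Zlist <- list(Zau, Zauv)
  free <- matrix(TRUE, 2, 2)
  if (include_ige) {
    Zas <- rbind(bundle$Zs, Matrix(0, n, ncol(bundle$Zs), sparse = TRUE))
    Zlist <- c(Zlist, list(Zas))
    free <- matrix(TRUE, 3, 3)
    free[2, 3] <- free[3, 2] <- FALSE  # dispersion-indirect covariance pinned at 0
  }
  groups <- list(list(Z = Zlist, K = K_par, theta = theta_g, free = free))
  if (include_cage) {
    Zt2 <- rbind(bundle$Zt, Matrix(0, n, ncol(bundle$Zt), sparse = TRUE))
    groups <- c(groups, list(list(Z = list(Zt2), K = diag(ncol(bundle$Zt)),
                                  theta = matrix(theta_t, 1, 1))))
  }
  Xs <- rbind(cbind(Matrix(bundle$X, sparse = TRUE),
                    Matrix(0, n, ncol(bundle$Xv), sparse = TRUE)),
              cbind(Matrix(0, n, ncol(bundle$X), sparse = TRUE),
                    Matrix(bundle$Xv, sparse = TRUE)))
  rpart <- list(part = rep(1:2, each = n),
                d = c(sigma_ei2, 2 / (1 - h)),
                sigma2 = c(1, 1))
  list(groups = groups, Xs = Xs, rpart = rpart, n = n)
}

#' Fit the sire-dam DHGLM
#'
#' Iteratively reweighted REML fit of the coupled harvest-weight mean model
#' and residual-variance (uniformity) model. The outer loop alternates
#' (1) a bivariate weighted AI-REML fit of the stacked responses `(y, psi)`
#' with correlated parental effects `(au, auv)` over the relationship kernel
#' (plus indirect effects `as` correlated with `au`, and an iid cage effect),
#' and (2) recomputation of residuals, leverages, the per-observation residual
#' variances `sigma_ei^2 = exp(Xv bv + Z auv)`, the linearized response `psi`,
#' and the weights `W = diag(1/sigma_ei^2)`, `Wv = diag((1-h_i)/2)`, until the
#' restricted log-likelihood stabilizes. A common full-sib environmental
#' effect is not modeled.
#'
#' Variance components are reported on three explicit scales: `raw` per-parent
#' components as fitted; the conventional sire-dam reporting scale
#' (`sigma_au_sq` as fitted, indirect variance x4, covariances x2 -- the scale
#' of the package's derived-parameter formulas); and the individual additive
#' scale (`sigma_ad_sq = 4 sigma_au_sq`, ...).
#'
#' @param pheno phenotype table.
#' @param layout `design_layout`.
#' @param pedigree pedigree covering all layout members and their parents.
#' @param relmat `relationship_matrix` (kind A or H) covering all parents.
#' @param include_ige model indirect genetic effects.
#' @param include_cage model a random cage effect; default (`NULL`) follows
#'   the convention of dropping the cage effect only for H-matrix models with
#'   indirect effects.
#' @param control [dhglm_control()].
#' @return object of class `dhglm_fit`; see Details and
#'   [genetic_parameter_report()].
#' @export
fit_dhglm <- function(pheno, layout, pedigree, relmat, include_ige = FALSE,
                      include_cage = NULL, control = dhglm_control()) {
  if (is.null(include_cage)) {
    include_cage <- !(identical(relmat$kind, "H") && include_ige)
  }
  bundle <- assemble_designs(pheno, layout, pedigree,
                             include_ige = include_ige,
                             include_cage = include_cage)
  if (length(unique(sub("_[0-9]+$", "", bundle$record_ids))) < 2) {
    stop("need at least 2 families")
  }
  if (!all(bundle$parents %in% relmat$ids)) {
    stop("relationship matrix does not cover all parents")
  }
  K_par <- relmat$matrix[bundle$parents, bundle$parents]
  y <- bundle$y
  n <- length(y)
  vy <- var(y)

  # Stage 0: homoscedastic REML on the mean model for starting values
  groups0 <- if (include_ige) {
    th0 <- matrix(c(vy / 8, 0, 0, vy / 1e4), 2, 2)
    list(list(Z = list(bundle$Z_par, bundle$Zs), K = K_par, theta = th0))
  } else {
    list(list(Z = list(bundle$Z_par), K = K_par, theta = matrix(vy / 8, 1, 1)))
  }
  if (include_cage) {
    groups0 <- c(groups0, list(list(Z = list(bundle$Zt),
                                    K = diag(length(bundle$cage_ids)),
                                    theta = matrix(vy / 20, 1, 1))))
  }
  st0 <- reml_engine(y, bundle$X, groups0,
                     rpart = list(part = rep(1L, n), d = rep(1, n),
                                  sigma2 = vy / 2),
                     tol = control$tol_inner, max_iter = control$max_inner,
                     bound = control$bound)
  sigma_e0 <- st0$sigma2[1]
  h <- pmin(pmax(st0$leverage, 0), 1 - 1e-8)
  sigma_ei2 <- rep(sigma_e0, n)
  psi <- update_psi(st0$ehat^2, h, sigma_ei2)

  # starting covariance for (au, auv[, as])
  v_au <- st0$theta[[1]][1, 1]
  th_g <- if (include_ige) {
    m <- diag(c(v_au, 0.02, max(st0$theta[[1]][2, 2], control$bound)))
    m[1, 3] <- m[3, 1] <- st0$theta[[1]][1, 2]
    m
  } else {
    diag(c(v_au, 0.02))
  }
  th_t <- if (include_cage) st0$theta[[2]][1, 1] else NA_real_

  logL_prev <- -Inf
  converged <- FALSE
  outer_trace <- numeric(0)
  fit_in <- NULL
  damp <- control$damping
  dl_prev <- Inf
  smooth_run <- 0L
  # warm starts must sit strictly inside the PSD cone or the AI machinery
  # stalls on the boundary
  sc <- stack_model(bundle, K_par, psd_interior(th_g), th_t, sigma_ei2, h,
                    include_ige, include_cage)
  for (outer in seq_len(control$max_outer)) {
    fit_in <- reml_engine(c(y, psi), sc$Xs, sc$groups, sc$rpart,
                          tol = control$tol_inner,
                          max_iter = control$max_inner,
                          bound = control$bound)
    th_g <- fit_in$theta[[1]]
    if (include_cage) th_t <- fit_in$theta[[2]][1, 1]
    pX <- ncol(bundle$X)
    b <- fit_in$b[seq_len(pX)]
    bv <- fit_in$b[pX + seq_len(ncol(bundle$Xv))]
    au <- fit_in$u[[1]][[1]]
    auv <- fit_in$u[[1]][[2]]
    as_eff <- if (include_ige) fit_in$u[[1]][[3]] else NULL
    e <- fit_in$ehat[seq_len(n)]
    ev <- fit_in$ehat[n + seq_len(n)]
    h <- pmin(pmax(fit_in$leverage[seq_len(n)], 0), 1 - 1e-8)
    eta_v <- pmin(pmax(as.numeric(bundle$Xv %*% bv + bundle$Z_par %*% auv), -30), 30)
    outer_trace <- c(outer_trace, fit_in$logL)
    dl <- abs(fit_in$logL - logL_prev)
    if (outer >= 3 && dl > 2 * dl_prev && dl > 5 * control$tol_outer) {
      damp <- max(0.15, damp * 0.6)   # genuine oscillation: relax harder
      smooth_run <- 0L
    } else if (dl <= dl_prev) {
      smooth_run <- smooth_run + 1L
      if (smooth_run >= 2L) damp <- min(1, damp / 0.6)  # recover once stable
    }
    sigma_ei2 <- exp((1 - damp) * log(sigma_ei2) + damp * eta_v)
    psi <- update_psi(e^2, h, sigma_ei2)
    if (control$trace) {
      message(sprintf("outer %d: logL=%.4f dlogL=%.3g damp=%.2f inner_iter=%d",
                      outer, fit_in$logL, dl, damp, fit_in$iterations))
    }
    if (outer >= 2 && dl < control$tol_outer) {
      converged <- TRUE
      break
    }
    dl_prev <- dl
    logL_prev <- fit_in$logL
    sc <- stack_model(bundle, K_par, psd_interior(th_g), th_t, sigma_ei2, h,
                      include_ige, include_cage)
  }
  if (!converged) {
    warning("DHGLM outer loop did not converge in ", control$max_outer,
            " iterations (partial fit returned)")
  }

  raw <- list(v_au = th_g[1, 1], v_auv = th_g[2, 2], c_au_auv = th_g[1, 2],
              v_as = if (include_ige) th_g[3, 3] else NA_real_,
              c_au_as = if (include_ige) th_g[1, 3] else NA_real_)
  vc <- list(
    sigma_au_sq = raw$v_au,
    sigma_au_as = if (include_ige) 2 * raw$c_au_as else NA_real_,
    sigma_as_sq = if (include_ige) 4 * raw$v_as else NA_real_,
    sigma_auv_exp_sq = raw$v_auv,
    sigma_au_auv = raw$c_au_auv,
    sigma_av_exp_sq = 4 * raw$v_auv,
    sigma_ad_av_exp = 4 * raw$c_au_auv,
    sigma_ad_sq = 4 * raw$v_au,
    sigma_ad_as = if (include_ige) 4 * raw$c_au_as else NA_real_,
    sigma_t_sq = if (include_cage) th_t else NA_real_,
    sigma_e_sq = mean(sigma_ei2) * fit_in$sigma2[1],
    sigma_e_exp_sq = fit_in$sigma2[2],
    scale_params = c(sigma_eps_sq = fit_in$sigma2[1],
                     sigma_epsv_sq = fit_in$sigma2[2]),
    raw = raw)

  structure(list(
    components = vc,
    b = setNames(as.numeric(fit_in$b[seq_len(ncol(bundle$X))]), colnames(bundle$X)),
    bv = setNames(as.numeric(fit_in$b[ncol(bundle$X) + seq_len(ncol(bundle$Xv))]),
                  colnames(bundle$Xv)),
    au = setNames(au, bundle$parents),
    auv = setNames(auv, bundle$parents),
    as_eff = if (include_ige) setNames(as_eff, bundle$parents),
    t_eff = if (include_cage) setNames(fit_in$u[[2]][[1]], bundle$cage_ids),
    e = setNames(e, bundle$record_ids),
    ev = setNames(ev, bundle$record_ids),
    psi = setNames(psi, bundle$record_ids),
    leverage = setNames(h, bundle$record_ids),
    sigma_e_i = setNames(sigma_ei2, bundle$record_ids),
    weights = list(W = 1 / sigma_ei2, Wv = (1 - h) / 2),
    logL = fit_in$logL, outer_trace = outer_trace,
    converged = converged, outer_iterations = length(outer_trace),
    include_ige = include_ige, include_cage = include_cage,
    matrix_kind = relmat$kind, group_size = layout$group_size,
    bundle = bundle, K_par = K_par),
    class = "dhglm_fit")
}

#' @export
print.dhglm_fit <- function(x, ...) {
  cat("sire-dam DHGLM fit (", x$matrix_kind, " matrix, ",
      if (x$include_ige) "with" else "no", " IGE, ",
      if (x$include_cage) "with" else "no", " cage effect): ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$outer_iterations, " outer iterations, logL = ",
      format(x$logL, digits = 7), "\n", sep = "")
  vc <- x$components
  cat(sprintf("  sigma_au^2 = %.4f  sigma_av,exp^2 = %.4f  sigma_t^2 = %s\n",
              vc$sigma_au_sq, vc$sigma_av_exp_sq,
              if (is.na(vc$sigma_t_sq)) "-" else sprintf("%.4f", vc$sigma_t_sq)))
  if (x$include_ige) {
    cat(sprintf("  sigma_ads = %.5f  sigma_as^2 = %.6f\n",
                vc$sigma_au_as, vc$sigma_as_sq))
  }
  cat(sprintf("  sigma_e^2 = %.4f  scale (eps, eps_v) = (%.3f, %.3f)\n",
              vc$sigma_e_sq, vc$scale_params[1], vc$scale_params[2]))
  invisible(x)
}

#' Breeding values from a DHGLM fit
#'
#' Per-individual direct EBV (`ad = au_sire + au_dam`), indirect EBV
#' (parental sum of indirect effects), total breeding value
#' `TBV = ad + (n-1) * indirect`, and dispersion EBV (parental sum of
#' dispersion effects, exponential scale).
#'
#' @param fit a converged `dhglm_fit`.
#' @param n group size (animals per cage); default from the fit's layout.
#' @param ids individuals to evaluate (default: all fitted records).
#' @return data.frame `individual_id`, `ebv_direct`, `ebv_indirect`, `tbv`,
#'   `ebv_dispersion`.
#' @export
predict_breeding_values <- function(fit, n = NULL, ids = NULL) {
  if (!fit$converged) warning("fit did not converge; breeding values are provisional")
  bundle <- fit$bundle
  if (is.null(ids)) ids <- bundle$record_ids
  sire <- bundle$sire[match(ids, bundle$record_ids)]
  dam <- bundle$dam[match(ids, bundle$record_ids)]
  if (anyNA(sire) || anyNA(dam)) stop("unknown parents for some ids")
  if (is.null(n)) n <- fit$group_size %||% 36
  ad <- fit$au[sire] + fit$au[dam]
  ind <- if (fit$include_ige) fit$as_eff[sire] + fit$as_eff[dam] else rep(0, length(ids))
  data.frame(individual_id = ids,
             ebv_direct = as.numeric(ad),
             ebv_indirect = as.numeric(ind),
             tbv = as.numeric(ad + (n - 1) * ind),
             ebv_dispersion = as.numeric(fit$auv[sire] + fit$auv[dam]),
             row.names = NULL)
}
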