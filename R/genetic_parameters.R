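# Derived genetic parameters for harvest weight (HW) and its uniformity
# (HWU). All functions take explicitly labeled scale inputs: "sire-dam
# reported" quantities are the components as conventionally printed for
# sire-dam models (direct variance per parent, indirect variance and
# covariances already on the total scale), "additive" quantities are
# individual additive-scale (direct variance x4).

#' Direct additive genetic variance from the sire-dam component
#'
#' `sigma_ad^2 = 4 sigma_au^2`.
#' @param sigma_au_sq parent-level direct variance (>= 0).
#' @return additive direct variance.
#' @export
direct_additive_variance <- function(sigma_au_sq) {
  if (any(sigma_au_sq < 0)) stop("negative variance")
  4 * sigma_au_sq
}

#' Variance of the total breeding value
#'
#' `sigma_TBV^2 = sigma_ad^2 + 2 (n-1) sigma_ad,as + (n-1)^2 sigma_as^2`
#' with additive-scale inputs and group size `n`.
#'
#' @param sigma_ad_sq additive direct variance.
#' @param sigma_ad_as additive direct-indirect covariance.
#' @param sigma_as_sq indirect genetic variance.
#' @param n group size (>= 2).
#' @export
tbv_variance <- function(sigma_ad_sq, sigma_ad_as, sigma_as_sq, n) {
  if (n < 2) stop("group size n must be >= 2")
  sigma_ad_sq + 2 * (n - 1) * sigma_ad_as + (n - 1)^2 * sigma_as_sq
}

#' Total variance produced by indirect genetic effects
#'
#' `(n-1)^2 sigma_as^2`: each animal's indirect effect is expressed in its
#' n-1 cage mates.
#' @inheritParams tbv_variance
#' @export
ige_total_variance <- function(sigma_as_sq, n) {
  if (n < 2) stop("group size n must be >= 2")
  (n - 1)^2 * sigma_as_sq
}

#' @rdname ige_total_variance
#' @param ige_variance output of `ige_total_variance`.
#' @param sigma_tbv_sq total-breeding-value variance (> 0).
#' @return percentage of `sigma_tbv_sq` attributable to indirect effects.
#' @export
ige_share <- function(ige_variance, sigma_tbv_sq) {
  if (sigma_tbv_sq <= 0) stop("sigma_tbv_sq must be positive")
  100 * ige_variance / sigma_tbv_sq
}

#' Phenotypic variance composition of the sire-dam model
#'
#' `sigma_p^2 = 2 sigma_au^2 + [ige] (n-1) sigma_as^2 + sigma_t^2 +
#' sigma_e^2`: the between-family direct part carried by the two parental
#' effects, the indirect variance expressed in each record when indirect
#' effects are modeled, cage variance (0 when absent), and residual.
#'
#' @param sigma_au_sq parent-level direct variance.
#' @param sigma_as_sq indirect variance (reported scale); ignored unless
#'   `include_ige`.
#' @param sigma_t_sq cage variance (0 when the model has no cage effect).
#' @param sigma_e_sq residual variance.
#' @param n group size.
#' @param include_ige whether the model carried indirect effects.
#' @export
phenotypic_variance <- function(sigma_au_sq, sigma_as_sq = 0, sigma_t_sq = 0,
                                sigma_e_sq, n = NULL, include_ige = FALSE) {
  if (is.na(sigma_t_sq)) sigma_t_sq <- 0
  out <- 2 * sigma_au_sq + sigma_t_sq + sigma_e_sq
  if (include_ige) {
    if (is.null(n)) stop("n required when include_ige")
    out <- out + (n - 1) * sigma_as_sq
  }
  out
}

#' Heritability and heritable total variance ratio
#'
#' `h2 = sigma_ad^2 / sigma_p^2`; `T2 = sigma_TBV^2 / sigma_p^2` (may exceed
#' 1: total breeding values are expressed across cage mates, not within one
#' phenotype).
#'
#' @param sigma_ad_sq additive direct variance.
#' @param sigma_p_sq phenotypic variance (> 0).
#' @export
heritability <- function(sigma_ad_sq, sigma_p_sq) {
  if (sigma_p_sq <= 0) stop("sigma_p_sq must be positive")
  sigma_ad_sq / sigma_p_sq
}

#' @rdname heritability
#' @param sigma_tbv_sq total-breeding-value variance.
#' @export
t_squared <- function(sigma_tbv_sq, sigma_p_sq) {
  if (sigma_p_sq <= 0) stop("sigma_p_sq must be positive")
  sigma_tbv_sq / sigma_p_sq
}

#' Additive-scale genetic variance of residual variance
#'
#' Converts the exponential-scale dispersion genetic variance to the additive
#' scale: `sigma_av^2 = sigma_E^4 (exp(sigma_av,exp^2) - 1)` with
#' `sigma_E^2 = sigma_e^2 - 2 sigma_au^2` the residual variance net of the
#' parental direct part. Printed literature values of `sigma_av^2` often come
#' from unrounded internals and need not be recoverable from the rounded
#' `sigma_av,exp^2`.
#'
#' @param sigma_av_exp_sq exponential-scale dispersion genetic variance.
#' @param sigma_E_sq `sigma_e^2 - 2 sigma_au^2` (> 0).
#' @export
uniformity_additive_variance <- function(sigma_av_exp_sq, sigma_E_sq) {
  if (any(sigma_av_exp_sq < 0)) stop("negative variance")
  if (sigma_E_sq <= 0) stop("sigma_E_sq must be positive")
  sigma_E_sq^2 * expm1(sigma_av_exp_sq)
}

#' Heritability of uniformity on the additive scale
#'
#' `hv2 = sigma_av^2 / (2 sigma_p^4 + 3 sigma_av^2)`.
#' @param sigma_av_sq additive-scale dispersion genetic variance.
#' @param sigma_p_sq phenotypic variance (> 0).
#' @export
uniformity_heritability <- function(sigma_av_sq, sigma_p_sq) {
  if (sigma_p_sq <= 0) stop("sigma_p_sq must be positive")
  sigma_av_sq / (2 * sigma_p_sq^2 + 3 * sigma_av_sq)
}

#' Genetic coefficient of variation of residual variance
#'
#' `GCV_v = sigma_av / sigma_E^2 = sqrt(exp(sigma_av,exp^2) - 1)` under the
#' exponential-scale conversion (the `sigma_E` factors cancel).
#' @param sigma_av_exp_sq exponential-scale dispersion genetic variance
#'   (>= 0).
#' @export
gcv_uniformity <- function(sigma_av_exp_sq) {
  if (any(sigma_av_exp_sq < 0)) stop("negative variance")
  sqrt(expm1(sigma_av_exp_sq))
}

#' Genetic correlation from a covariance and two variances
#'
#' `cov / sqrt(var1 * var2)`; values outside the unit interval (possible with
#' REML components estimated near boundaries) are reported as-is with a
#' warning.
#' @param cov covariance.
#' @param var1,var2 variances (> 0).
#' @export
genetic_correlation <- function(cov, var1, var2) {
  if (var1 <= 0 || var2 <= 0) stop("variances must be positive")
  r <- cov / sqrt(var1 * var2)
  if (abs(r) > 1) warning("correlation outside [-1, 1]: ", format(r, digits = 4))
  r
}

#' Full derived-parameter report from a DHGLM fit
#'
#' Collects every derived quantity -- additive variances, total-breeding-value
#' variance and the share of it produced by indirect effects, phenotypic
#' variance, h2, T2, dispersion variances on both scales, hv2, GCVv and the
#' genetic correlations -- with explicit scale labels.
#'
#' @param fit a `dhglm_fit`.
#' @param n group size; default from the fit.
#' @return list of class `genetic_parameter_report`.
#' @export
genetic_parameter_report <- function(fit, n = NULL) {
  vc <- fit$components
  if (is.null(n)) n <- fit$group_size %||% 36
  ige <- fit$include_ige
  sigma_ad_sq <- direct_additive_variance(vc$sigma_au_sq)
  sigma_p_sq <- phenotypic_variance(vc$sigma_au_sq,
                                    if (ige) vc$sigma_as_sq else 0,
                                    vc$sigma_t_sq %||% 0,
                                    vc$sigma_e_sq, n = n, include_ige = ige)
  sigma_tbv_sq <- if (ige) {
    tbv_variance(sigma_ad_sq, vc$sigma_ad_as, vc$sigma_as_sq, n)
  } else NA_real_
  ige_var <- if (ige) ige_total_variance(vc$sigma_as_sq, n) else NA_real_
  sigma_E_sq <- vc$sigma_e_sq - 2 * vc$sigma_au_sq
  sigma_av_sq <- if (sigma_E_sq > 0) {
    uniformity_additive_variance(vc$sigma_av_exp_sq, sigma_E_sq)
  } else NA_real_
  structure(list(
    n = n,
    sigma_au_sq = vc$sigma_au_sq,
    sigma_ad_sq = sigma_ad_sq,
    sigma_ads = if (ige) vc$sigma_au_as else NA_real_,
    sigma_ad_as = if (ige) vc$sigma_ad_as else NA_real_,
    sigma_as_sq = if (ige) vc$sigma_as_sq else NA_real_,
    sigma_t_sq = vc$sigma_t_sq,
    sigma_e_sq = vc$sigma_e_sq,
    sigma_e_exp_sq = vc$sigma_e_exp_sq,
    sigma_p_sq = sigma_p_sq,
    sigma_tbv_sq = sigma_tbv_sq,
    ige_total_variance = ige_var,
    ige_share_percent = if (ige) ige_share(ige_var, sigma_tbv_sq) else NA_real_,
    h2 = heritability(sigma_ad_sq, sigma_p_sq),
    T2 = if (ige) t_squared(sigma_tbv_sq, sigma_p_sq) else NA_real_,
    sigma_av_exp_sq = vc$sigma_av_exp_sq,
    sigma_E_sq = sigma_E_sq,
    sigma_av_sq = sigma_av_sq,
    hv2 = if (!is.na(sigma_av_sq)) uniformity_heritability(sigma_av_sq, sigma_p_sq) else NA_real_,
    gcv_v = gcv_uniformity(vc$sigma_av_exp_sq),
    r_ad_as = if (ige) genetic_correlation(vc$raw$c_au_as, vc$raw$v_au, vc$raw$v_as) else NA_real_,
    r_g = genetic_correlation(vc$raw$c_au_auv, vc$raw$v_au, vc$raw$v_auv),
    scale_convention = paste(
      "sigma_au_sq is the per-parent (sire-dam) direct variance;",
      "sigma_ads, sigma_as_sq, sigma_av_exp_sq are on the conventional",
      "reported scale (covariance x2, variances x4 of the per-parent fit);",
      "sigma_ad_sq, sigma_ad_as are individual additive scale.")),
    class = "genetic_parameter_report")
}

#' @export
print.genetic_parameter_report <- function(x, ...) {
  fmt <- function(v, d = 3) if (is.na(v)) "   -" else formatC(v, digits = d, format = "f")
  rows <- c(sigma_ad_sq_sire_dam = fmt(x$sigma_au_sq),
            sigma_ads = fmt(x$sigma_ads, 5),
            sigma_as_sq = fmt(x$sigma_as_sq, 6),
            sigma_av_sq = fmt(x$sigma_av_sq),
            sigma_av_exp_sq = fmt(x$sigma_av_exp_sq),
            sigma_e_sq = fmt(x$sigma_e_sq),
            sigma_e_exp_sq = fmt(x$sigma_e_exp_sq),
            sigma_t_sq = fmt(x$sigma_t_sq),
            sigma_p_sq = fmt(x$sigma_p_sq),
            sigma_TBV_sq = fmt(x$sigma_tbv_sq),
            h2 = fmt(x$h2), T2 = fmt(x$T2), hv2 = fmt(x$hv2),
            GCVv = fmt(x$gcv_v), r_ads = fmt(x$r_ad_as), r_g = fmt(x$r_g))
  cat("Genetic parameters (group size n =", x$n, ")\n")
  for (nm in names(rows)) cat(sprintf("  %-22s %s\n", nm, rows[[nm]]))
  invisible(x)
}
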