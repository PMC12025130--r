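#' @import Matrix
NULL

# ---------------------------------------------------------------------------
# Generic average-information REML engine on the mixed-model equations.
#
# Model: y = X b + sum_g sum_a Z_{g,a} u_{g,a} + e, where within group g the
# effect vectors u_{g,1..m} (each of length q_g) share a kernel K_g and have a
# free m x m covariance Theta_g: Var(vec(U_g)) = Theta_g (x) K_g. The residual
# is independent with Var(e_i) = d_i * sigma2_{part(i)} for known weights d
# and one free scale per partition.
#
# All trace and quadratic forms are evaluated through the coefficient matrix C
# of Henderson's mixed-model equations, so the cost per iteration is governed
# by the number of equations (fixed + random levels), not the number of
# records. AI steps are guarded by step-halving against the restricted
# log-likelihood; an EM step on the Theta blocks is the fallback. Variances
# are kept >= `bound`.
# ---------------------------------------------------------------------------

# groups: list of list(Z = list of n x q (Matrix or matrix), K, Kinv, logdetK,
#         theta = m x m start, free = m x m logical (FALSE entries frozen))
# rpart:  list(part = integer n-vector, d = known variance weights,
#              sigma2 = starting scales, est = logical per partition)
reml_engine <- function(y, X, groups, rpart, tol = 1e-6, max_iter = 100L,
                        bound = 1e-8, verbose = FALSE) {
  n <- length(y)
  X <- Matrix(X, sparse = TRUE)
  p <- ncol(X)
  for (g in seq_along(groups)) {
    groups[[g]]$Z <- lapply(groups[[g]]$Z, function(z) Matrix(z, sparse = TRUE))
    if (is.null(groups[[g]]$free)) {
      groups[[g]]$free <- matrix(TRUE, nrow(groups[[g]]$theta), nrow(groups[[g]]$theta))
    }
    if (is.null(groups[[g]]$Kinv)) {
      K <- groups[[g]]$K
      ch <- chol(K)
      groups[[g]]$Kinv <- chol2inv(ch)
      groups[[g]]$logdetK <- 2 * sum(log(diag(ch)))
    } else if (is.null(groups[[g]]$logdetK)) {
      groups[[g]]$logdetK <- -determinant(groups[[g]]$Kinv, logarithm = TRUE)$modulus
    }
  }
  if (is.null(rpart$est)) rpart$est <- rep(TRUE, length(rpart$sigma2))
  n_part <- length(rpart$sigma2)
  part_idx <- lapply(seq_len(n_part), function(k) which(rpart$part == k))

  # column bookkeeping: fixed cols 1..p, then group g trait a levels
  cols <- list()
  off <- p
  for (g in seq_along(groups)) {
    m <- length(groups[[g]]$Z)
    q <- ncol(groups[[g]]$Z[[1]])
    cols[[g]] <- lapply(seq_len(m), function(a) off + (a - 1L) * q + seq_len(q))
    off <- off + m * q
  }
  n_eq <- off
  W <- do.call(cbind, c(list(X), unlist(lapply(groups, `[[`, "Z"),
                                        recursive = FALSE)))

  # free-parameter map (rebuilt when a component is frozen at the boundary)
  build_par_map <- function() {
    pm <- list()
    for (g in seq_along(groups)) {
      m <- nrow(groups[[g]]$theta)
      for (a in seq_len(m)) for (b in a:m) {
        if (groups[[g]]$free[a, b]) {
          pm[[length(pm) + 1L]] <- list(type = "theta", g = g, a = a, b = b)
        }
      }
    }
    for (k in seq_len(n_part)) {
      if (rpart$est[k]) pm[[length(pm) + 1L]] <- list(type = "resid", k = k)
    }
    pm
  }
  par_map <- build_par_map()
  n_par <- length(par_map)
  pin_count <- new.env(parent = emptyenv())

  get_par <- function() {
    vapply(par_map, function(pm) {
      if (pm$type == "theta") groups[[pm$g]]$theta[pm$a, pm$b] else rpart$sigma2[pm$k]
    }, numeric(1))
  }
  set_par <- function(v) {
    for (l in seq_len(n_par)) {
      pm <- par_map[[l]]
      if (pm$type == "theta") {
        groups[[pm$g]]$theta[pm$a, pm$b] <<- v[l]
        groups[[pm$g]]$theta[pm$b, pm$a] <<- v[l]
      } else rpart$sigma2[pm$k] <<- v[l]
    }
  }
  valid_par <- function(v) {
    for (l in seq_len(n_par)) {
      pm <- par_map[[l]]
      if (pm$type == "theta" && pm$a == pm$b && v[l] < bound) return(FALSE)
      if (pm$type == "resid" && v[l] < bound) return(FALSE)
    }
    # PSD of each theta under candidate values
    gl <- groups
    for (l in seq_len(n_par)) {
      pm <- par_map[[l]]
      if (pm$type == "theta") {
        gl[[pm$g]]$theta[pm$a, pm$b] <- v[l]
        gl[[pm$g]]$theta[pm$b, pm$a] <- v[l]
      }
    }
    for (g in seq_along(gl)) {
      ev <- eigen(gl[[g]]$theta, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 0) return(FALSE)
    }
    TRUE
  }
  clamp_par <- function(v) {
    for (l in seq_len(n_par)) {
      pm <- par_map[[l]]
      if ((pm$type == "resid") || (pm$a == pm$b)) v[l] <- max(v[l], bound)
    }
    v
  }

  # Evaluate the restricted log-likelihood and the state needed for derivatives
  evaluate <- function() {
    dvar <- rpart$d * rpart$sigma2[rpart$part]
    rinv <- 1 / dvar
    Wr <- W * sqrt(rinv)
    C0 <- as.matrix(crossprod(Wr))
    rhs <- as.numeric(crossprod(W, rinv * y))
    C <- C0
    logdetG <- 0
    for (g in seq_along(groups)) {
      th <- groups[[g]]$theta
      m <- nrow(th); q <- length(cols[[g]][[1]])
      thinv <- tryCatch(solve(th), error = function(e) NULL)
      if (is.null(thinv)) {
        thinv <- solve(th + diag(1e-10 * max(diag(th), bound), m))
      }
      for (a in seq_len(m)) for (b in seq_len(m)) {
        C[cols[[g]][[a]], cols[[g]][[b]]] <-
          C[cols[[g]][[a]], cols[[g]][[b]]] + thinv[a, b] * groups[[g]]$Kinv
      }
      ldt <- determinant(th, logarithm = TRUE)
      logdetG <- logdetG + q * as.numeric(ldt$modulus) + m * groups[[g]]$logdetK
    }
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Cinv <- chol2inv(ch)
    s <- as.numeric(Cinv %*% rhs)
    yPy <- sum(rinv * y^2) - sum(s * rhs)
    logdetC <- 2 * sum(log(diag(ch)))
    logdetR <- sum(log(dvar))
    logL <- -0.5 * (logdetR + logdetG + logdetC + yPy)
    ehat <- as.numeric(y - W %*% s)
    Py <- rinv * ehat
    list(logL = logL, C0 = C0, Cinv = Cinv, s = s, rinv = rinv, dvar = dvar,
         ehat = ehat, Py = Py, rhs = rhs)
  }

  apply_P <- function(st, f) {
    st$rinv * f - st$rinv * as.numeric(W %*% (st$Cinv %*% as.numeric(crossprod(W, st$rinv * f))))
  }

  em_step <- function(st, hdiag) {
    for (g in seq_along(groups)) {
      m <- nrow(groups[[g]]$theta)
      q <- length(cols[[g]][[1]])
      newth <- groups[[g]]$theta
      for (a in seq_len(m)) for (b in a:m) {
        if (!groups[[g]]$free[a, b]) next
        ua <- st$s[cols[[g]][[a]]]; ub <- st$s[cols[[g]][[b]]]
        val <- (sum(ua * (groups[[g]]$Kinv %*% ub)) +
                  sum(groups[[g]]$Kinv * st$Cinv[cols[[g]][[a]], cols[[g]][[b]]])) / q
        newth[a, b] <- newth[b, a] <- val
      }
      groups[[g]]$theta <<- newth
    }
    for (k in seq_len(n_part)) {
      if (!rpart$est[k]) next
      ii <- part_idx[[k]]
      s2 <- rpart$sigma2[k]
      Pii <- st$rinv[ii] - st$rinv[ii]^2 * hdiag[ii]
      rpart$sigma2[k] <<- max(bound,
        (sum(st$ehat[ii]^2 / rpart$d[ii]) + s2 * length(ii) -
           s2^2 * sum(rpart$d[ii] * Pii)) / length(ii))
    }
  }

  st <- evaluate()
  if (is.null(st)) stop("singular mixed-model coefficient matrix at start values")
  trace <- st$logL
  converged <- FALSE
  grad <- rep(NA_real_, n_par)
  for (iter in seq_len(if (n_par) max_iter else 0L)) {
    WCinv <- as.matrix(W %*% st$Cinv)
    hdiag <- Matrix::rowSums(W * WCinv)  # w_i' C^{-1} w_i

    Fmat <- matrix(0, n, n_par)
    trP <- numeric(n_par)
    for (l in seq_len(n_par)) {
      pm <- par_map[[l]]
      if (pm$type == "theta") {
        g <- pm$g; a <- pm$a; b <- pm$b
        Za <- groups[[g]]$Z[[a]]; Zb <- groups[[g]]$Z[[b]]
        K <- groups[[g]]$K
        ca <- cols[[g]][[a]]; cb <- cols[[g]][[b]]
        Q <- st$C0[ca, cb, drop = FALSE]           # Za' R^-1 Zb
        tr1 <- sum(K * t(Q))                       # tr(R^-1 Za K Zb')
        Ma <- st$C0[, ca, drop = FALSE]            # W' R^-1 Za
        Mb <- st$C0[, cb, drop = FALSE]
        tr2 <- sum((st$Cinv %*% Ma) * (Mb %*% K))  # tr(Cinv Ma K Mb')
        f <- as.numeric(Za %*% (K %*% as.numeric(crossprod(Zb, st$Py))))
        if (a != b) {
          tr1 <- 2 * tr1; tr2 <- 2 * tr2
          f <- f + as.numeric(Zb %*% (K %*% as.numeric(crossprod(Za, st$Py))))
        }
        trP[l] <- tr1 - tr2
        Fmat[, l] <- f
      } else {
        k <- pm$k; ii <- part_idx[[k]]
        Pii <- st$rinv[ii] - st$rinv[ii]^2 * hdiag[ii]
        trP[l] <- sum(rpart$d[ii] * Pii)
        f <- numeric(n)
        f[ii] <- rpart$d[ii] * st$Py[ii]
        Fmat[, l] <- f
      }
    }
    grad <- -0.5 * (trP - as.numeric(crossprod(Fmat, st$Py)))
    PF <- apply(Fmat, 2, function(f) apply_P(st, f))
    AI <- 0.5 * crossprod(Fmat, PF)
    AI <- (AI + t(AI)) / 2

    cur <- get_par()
    step <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI), 1), n_par), grad),
                     error = function(e) grad / max(abs(diag(AI)), 1))
    accepted <- FALSE
    new_st <- NULL
    for (h in 0:12) {
      cand <- clamp_par(cur + step / 2^h)
      if (!valid_par(cand)) next
      set_par(cand)
      new_st <- evaluate()
      if (!is.null(new_st) && is.finite(new_st$logL) &&
          new_st$logL >= st$logL - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      set_par(cur)
      em_step(st, hdiag)
      # the EM update with frozen covariance entries can leave the boundary of
      # the PSD cone; clip eigenvalues, then shrink covariances toward the
      # diagonal until the likelihood is evaluable again
      fix_frozen <- function(g, th) {
        th[!groups[[g]]$free] <- groups[[g]]$theta[!groups[[g]]$free]
        th
      }
      for (g in seq_along(groups)) {
        groups[[g]]$theta <- fix_frozen(g, psd_clip(groups[[g]]$theta, bound))
      }
      newv <- clamp_par(get_par())
      set_par(newv)
      new_st <- evaluate()
      shrink <- 0L
      while ((is.null(new_st) || !is.finite(new_st$logL)) && shrink < 6L) {
        shrink <- shrink + 1L
        for (g in seq_along(groups)) {
          th <- groups[[g]]$theta
          th <- psd_clip(0.7 * th + 0.3 * diag(diag(th), nrow(th)), bound)
          groups[[g]]$theta <- fix_frozen(g, th)
        }
        set_par(clamp_par(get_par()))
        new_st <- evaluate()
      }
      if (is.null(new_st) || !is.finite(new_st$logL)) {
        set_par(cur)
        converged <- FALSE
        break
      }
    }
    dlogL <- new_st$logL - st$logL
    st <- new_st
    trace <- c(trace, st$logL)
    # freeze variance components stuck at the lower bound (and their
    # covariances, pinned to 0) so the AI machinery stops thrashing on them
    refrozen <- FALSE
    for (g in seq_along(groups)) {
      m <- nrow(groups[[g]]$theta)
      if (m < 1) next
      for (a in seq_len(m)) {
        if (!groups[[g]]$free[a, a]) next
        key <- paste(g, a)
        if (groups[[g]]$theta[a, a] <= 10 * bound) {
          pin_count[[key]] <- (pin_count[[key]] %||% 0L) + 1L
          if (pin_count[[key]] >= 3L) {
            groups[[g]]$theta[a, a] <- bound
            groups[[g]]$theta[a, -a] <- groups[[g]]$theta[-a, a] <- 0
            groups[[g]]$free[a, ] <- groups[[g]]$free[, a] <- FALSE
            refrozen <- TRUE
          }
        } else pin_count[[key]] <- 0L
      }
    }
    if (refrozen) {
      par_map <- build_par_map()
      n_par <- length(par_map)
      st <- evaluate()
      if (!n_par) break
    }
    if (verbose) message(sprintf("  REML iter %d logL=%.6f dlogL=%.2e", iter, st$logL, dlogL))
    if (abs(dlogL) < tol && iter >= 2) {
      converged <- TRUE
      break
    }
  }
  WCinv <- as.matrix(W %*% st$Cinv)
  hdiag <- Matrix::rowSums(W * WCinv)
  leverage <- as.numeric(hdiag * st$rinv)
  u <- lapply(seq_along(groups), function(g)
    lapply(cols[[g]], function(cc) st$s[cc]))
  if (!n_par) converged <- TRUE
  list(b = st$s[seq_len(p)],
       u = u,
       theta = lapply(groups, `[[`, "theta"),
       sigma2 = rpart$sigma2,
       logL = st$logL, trace = trace, converged = converged,
       iterations = length(trace) - 1L, grad = grad,
       leverage = leverage, ehat = st$ehat, rinv = st$rinv,
       cols = cols, n_fixed = p, Cinv = st$Cinv)
}

# clip a symmetric matrix to the PSD cone (eigenvalues >= floor)
psd_clip <- function(th, floor = 1e-8) {
  if (nrow(th) == 1) return(pmax(th, floor))
  es <- eigen((th + t(th)) / 2, symmetric = TRUE)
  if (min(es$values) >= floor) return(th)
  es$vectors %*% diag(pmax(es$values, floor), nrow(th)) %*% t(es$vectors)
}

# pull a covariance matrix strictly inside the PSD cone by shrinking
# off-diagonals (used for warm starts: a boundary-singular start stalls the
# AI machinery)
psd_interior <- function(th, rel_margin = 1e-3) {
  if (nrow(th) == 1) return(th)
  margin <- rel_margin * mean(diag(th))
  for (lam in seq(1, 0, by = -0.05)) {
    cand <- lam * th + (1 - lam) * diag(diag(th), nrow(th))
    ev <- eigen((cand + t(cand)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= margin) return(cand)
  }
  diag(diag(th), nrow(th))
}

# solve the MME once at fixed variance parameters (used for CV refits)
solve_mme <- function(y, X, groups, rpart) {
  out <- reml_engine(y, X, groups = lapply(groups, function(g) {
    g$free <- matrix(FALSE, nrow(g$theta), nrow(g$theta)); g
  }), rpart = modifyList(rpart, list(est = rep(FALSE, length(rpart$sigma2)))),
  max_iter = 1L, tol = Inf)
  out
}

#' Variance-component estimation by average-information REML
#'
#' Single-response linear mixed model with independent random effect blocks,
#' each with an optional relationship kernel, and a diagonal residual with
#' known weights:
#' `y = X b + sum_k Z_k u_k + e`, `u_k ~ N(0, sigma2_k K_k)`,
#' `Var(e_i) = sigma2_e * w_i`. Estimated by AI-REML with step-halving against
#' the restricted likelihood and an EM fallback; variances are constrained to
#' at least `bound`.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param random list of random blocks, each `list(Z = incidence matrix,
#'   K = relationship/kernel matrix or NULL for identity)`.
#' @param weights known residual variance multipliers (default 1).
#' @param start optional numeric vector of starting variances
#'   (`length(random) + 1`, residual last).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param max_iter maximum AI iterations.
#' @param bound lower bound for variances.
#' @return list of class `reml_fit`: `varcomp` (named vector, residual last),
#'   `b`, `u` (list per block), `logL`, `trace`, `converged`, `iterations`,
#'   `leverage`, `grad`.
#' @export
reml_fit <- function(y, X, random, weights = NULL, start = NULL,
                     tol = 1e-6, max_iter = 100L, bound = 1e-8) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0), nrow(X) == n)
  vy <- var(y)
  k <- length(random)
  if (is.null(start)) start <- rep(vy / (k + 1), k + 1)
  groups <- lapply(seq_len(k), function(j) {
    Z <- random[[j]]$Z
    K <- random[[j]]$K
    if (is.null(K)) K <- diag(ncol(Z))
    if (inherits(K, "relationship_matrix")) K <- K$matrix
    list(Z = list(Z), K = as.matrix(K), theta = matrix(start[j], 1, 1))
  })
  rpart <- list(part = rep(1L, n), d = weights, sigma2 = start[k + 1])
  fit <- reml_engine(y, X, groups, rpart, tol = tol, max_iter = max_iter,
                     bound = bound)
  names_vc <- c(if (!is.null(names(random))) names(random)
                else if (k) paste0("u", seq_len(k)) else character(0),
                "residual")
  vc <- setNames(c(vapply(fit$theta, function(t) t[1, 1], numeric(1)),
                   fit$sigma2), names_vc)
  structure(list(varcomp = vc, b = fit$b,
                 u = lapply(fit$u, `[[`, 1),
                 logL = fit$logL, trace = fit$trace,
                 converged = fit$converged, iterations = fit$iterations,
                 leverage = fit$leverage, grad = fit$grad),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; logL =", format(x$logL, digits = 6), "\n")
  print(round(x$varcomp, 6))
  invisible(x)
}
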