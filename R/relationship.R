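#' Topologically sort a pedigree
#'
#' Orders records so every parent precedes its offspring; errors on cycles or
#' parents that never appear as individuals.
#'
#' @param pedigree data.frame with `individual_id`, `sire_id`, `dam_id`
#'   (`NA`/`""`/`"0"` for unknown).
#' @return the pedigree, sorted, with unknown parents normalized to `NA`.
#' @export
sort_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  for (col in c("sire_id", "dam_id")) {
    v <- as.character(ped[[col]])
    v[v %in% c("", "0", "NA")] <- NA_character_
    ped[[col]] <- v
  }
  ped$individual_id <- as.character(ped$individual_id)
  if (anyDuplicated(ped$individual_id)) stop("duplicate individual_id in pedigree")
  parents <- setdiff(stats::na.omit(c(ped$sire_id, ped$dam_id)), ped$individual_id)
  if (length(parents)) stop("parents absent from pedigree: ", paste(parents, collapse = ", "))
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$individual_id)
  placed <- logical(n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      s <- ped$sire_id[i]; d <- ped$dam_id[i]
      (is.na(s) || placed[idx[[s]]]) && (is.na(d) || placed[idx[[d]]])
    }, logical(1))]
    if (!length(ready)) {
      if (length(remaining)) stop("pedigree contains a cycle")
      break
    }
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pedigree)
  out
}

#' Pedigree additive relationship matrix (A)
#'
#' Tabular (recursive) method: for individual i with parents s, d,
#' `a_ij = (a_sj + a_dj)/2` for earlier j and `a_ii = 1 + a_sd/2`, so the
#' diagonal is 1 plus the inbreeding coefficient.
#'
#' @param pedigree a pedigree (any order; sorted internally).
#' @return list of class `relationship_matrix`: `matrix` (dense, symmetric,
#'   dimnames = individual ids), `ids`, `kind = "A"`.
#' @export
build_A <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  n <- nrow(ped)
  ids <- ped$individual_id
  idx <- setNames(seq_len(n), ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  si <- ifelse(is.na(ped$sire_id), 0L, idx[ped$sire_id])
  di <- ifelse(is.na(ped$dam_id), 0L, idx[ped$dam_id])
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (si[i] > 0) row <- row + A[si[i], prev] / 2
    if (di[i] > 0) row <- row + A[di[i], prev] / 2
    A[i, prev] <- row
    A[prev, i] <- row
    A[i, i] <- 1 + if (si[i] > 0 && di[i] > 0) A[si[i], di[i]] / 2 else 0
  }
  structure(list(matrix = A, ids = ids, kind = "A"),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(x$kind, "relationship matrix over", length(x$ids), "individuals;",
      "mean diagonal", format(mean(diag(x$matrix)), digits = 4), "\n")
  invisible(x)
}

#' SNP and individual quality control
#'
#' Filters in the fixed order SNP missingness, then minor allele frequency,
#' then individual call rate, with strict thresholds: a SNP is retained when
#' its missing rate is `< snp_missing_max` and its MAF is `> maf_min`; an
#' individual is removed when its call rate is `<= ind_call_min`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param snp_missing_max maximum tolerated SNP missing rate (exclusive).
#' @param maf_min minimum MAF (exclusive).
#' @param ind_call_min individual call-rate threshold (removal at or below).
#' @return list `genotypes` (filtered `genotype_matrix`) and `report`
#'   (`qc_report`: in/out counts and per-filter removals).
#' @export
qc_genotypes <- function(genotypes, snp_missing_max = 0.10, maf_min = 0.05,
                         ind_call_min = 0.80) {
  codes <- genotypes$codes
  n_ind_in <- nrow(codes); n_snp_in <- ncol(codes)
  miss <- colMeans(is.na(codes))
  keep1 <- miss < snp_missing_max
  codes <- codes[, keep1, drop = FALSE]
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- maf > maf_min
  codes <- codes[, keep2, drop = FALSE]
  if (ncol(codes) == 0) stop("all SNPs removed by QC")
  call_rate <- rowMeans(!is.na(codes))
  keep3 <- call_rate > ind_call_min
  codes <- codes[keep3, , drop = FALSE]
  report <- structure(list(n_snps_in = n_snp_in, n_snps_out = ncol(codes),
                           n_individuals_in = n_ind_in,
                           n_individuals_out = nrow(codes),
                           removed_snp_missing = sum(!keep1),
                           removed_snp_maf = sum(!keep2),
                           removed_ind_call = sum(!keep3),
                           thresholds = c(snp_missing_max = snp_missing_max,
                                          maf_min = maf_min,
                                          ind_call_min = ind_call_min),
                           filter_order = c("snp_missingness", "maf", "individual_call_rate")),
                      class = "qc_report")
  stopifnot(report$n_snps_in - report$removed_snp_missing - report$removed_snp_maf
            == report$n_snps_out,
            report$n_individuals_in - report$removed_ind_call
            == report$n_individuals_out)
  out <- genotypes
  out$codes <- codes
  out$founder_freq <- genotypes$founder_freq[colnames(codes)]
  out$snp_ids <- colnames(codes)
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("genotype QC:", x$n_snps_in, "->", x$n_snps_out, "SNPs (",
      x$removed_snp_missing, "missingness,", x$removed_snp_maf, "MAF );",
      x$n_individuals_in, "->", x$n_individuals_out, "individuals (",
      x$removed_ind_call, "call rate )\n")
  invisible(x)
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = ZZ' / sum(2 p_k (1 - p_k))` with `Z` the genotype codes centered by
#' twice the observed allele frequencies; missing codes are mean-imputed per
#' SNP beforehand.
#'
#' @param genotypes a (post-QC) `genotype_matrix`.
#' @param freq optional per-SNP allele frequencies to center/scale with
#'   (default: observed frequencies).
#' @return `relationship_matrix` of kind `"G"`.
#' @export
build_G <- function(genotypes, freq = NULL) {
  codes <- genotypes$codes
  storage.mode(codes) <- "double"
  p <- if (is.null(freq)) colMeans(codes, na.rm = TRUE) / 2 else freq
  if (any(is.na(codes))) {
    for (k in which(colSums(is.na(codes)) > 0)) {
      codes[is.na(codes[, k]), k] <- 2 * p[k]
    }
  }
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero VanRaden denominator")
  Z <- sweep(codes, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  structure(list(matrix = G, ids = rownames(codes), kind = "G"),
            class = "relationship_matrix")
}

#' Single-step (H) relationship matrix
#'
#' Combines pedigree and genomic information: the genomic matrix is rescaled so
#' that the means of its diagonal and off-diagonal match the pedigree
#' relationships among genotyped individuals (`tune = TRUE`), blended with
#' `blend_weight` on the genomic side to keep it invertible, and propagated to
#' ungenotyped individuals with the standard block formulas
#' `H22 = Gb`, `H12 = A12 A22^{-1} Gb`,
#' `H11 = A11 + A12 A22^{-1} (Gb - A22) A22^{-1} A21`.
#'
#' @param A pedigree `relationship_matrix`.
#' @param G genomic `relationship_matrix` over `genotyped_ids`.
#' @param genotyped_ids ids (subset of A's ids) that are genotyped.
#' @param blend_weight weight on the (tuned) genomic matrix; the remainder is
#'   A22.
#' @param tune match mean diagonal/off-diagonal of G to A22 before blending.
#' @return `relationship_matrix` of kind `"H"` in A's id order.
#' @export
build_H <- function(A, G = NULL, genotyped_ids = character(),
                    blend_weight = 0.95, tune = TRUE) {
  if (!length(genotyped_ids)) {
    out <- A; out$kind <- "H"
    return(out)
  }
  stopifnot(all(genotyped_ids %in% A$ids))
  Gm <- G$matrix[genotyped_ids, genotyped_ids]
  ids <- A$ids
  g2 <- match(genotyped_ids, ids)
  g1 <- setdiff(seq_along(ids), g2)
  Am <- A$matrix
  A22 <- Am[g2, g2, drop = FALSE]
  if (tune) {
    nd <- length(genotyped_ids)
    md_a <- mean(diag(A22)); mo_a <- (sum(A22) - sum(diag(A22))) / (nd^2 - nd)
    md_g <- mean(diag(Gm)); mo_g <- (sum(Gm) - sum(diag(Gm))) / (nd^2 - nd)
    # solve a + b*md_g = md_a ; a + b*mo_g = mo_a
    b <- (md_a - mo_a) / (md_g - mo_g)
    a <- md_a - b * md_g
    Gm <- a + b * Gm
  }
  Gb <- blend_weight * Gm + (1 - blend_weight) * A22
  H <- Am
  A22inv <- tryCatch(solve(A22), error = function(e) stop("singular A22 block"))
  Delta <- Gb - A22
  if (length(g1)) {
    B <- Am[g1, g2, drop = FALSE] %*% A22inv
    H[g1, g1] <- Am[g1, g1] + B %*% Delta %*% t(B)
    H12 <- B %*% Gb
    H[g1, g2] <- H12
    H[g2, g1] <- t(H12)
  }
  H[g2, g2] <- Gb
  structure(list(matrix = H, ids = ids, kind = "H",
                 genotyped_ids = genotyped_ids,
                 blend_weight = blend_weight, tuned = tune),
            class = "relationship_matrix")
}

#' Write / read a relationship matrix
#'
#' Sparse three-column text (`i`, `j`, `value` over the upper triangle,
#' entries below `tol` dropped) with a header line carrying the id order and
#' kind.
#'
#' @param relmat a `relationship_matrix`.
#' @param path output path.
#' @param tol magnitude below which entries are not written.
#' @export
write_relmat <- function(relmat, path, tol = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind=", relmat$kind), con)
  writeLines(paste0("#ids=", paste(relmat$ids, collapse = ",")), con)
  m <- relmat$matrix
  ut <- which(upper.tri(m, diag = TRUE) & abs(m) > tol, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], value = m[ut])
  write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  hdr <- readLines(path, n = 2)
  kind <- sub("^#kind=", "", hdr[1])
  ids <- strsplit(sub("^#ids=", "", hdr[2]), ",", fixed = TRUE)[[1]]
  df <- read.delim(path, skip = 2)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[cbind(df$i, df$j)] <- df$value
  m[cbind(df$j, df$i)] <- df$value
  structure(list(matrix = m, ids = ids, kind = kind),
            class = "relationship_matrix")
}
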