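#' Construct a three-families-per-cage (3FAM) test layout
#'
#' Builds a cage layout in which every cage holds exactly three families, every
#' family is tested in exactly `cages_per_family` cages and no unordered pair of
#' families co-occurs in more than one cage (a partial Steiner triple system).
#' Optional kinship and body-weight-variation constraints restrict which family
#' triples are acceptable: the predicted within-cage coefficient of variation of
#' tagging weight must not exceed `global_cv` and the mean pairwise kinship of
#' the three families must not exceed `global_mean_kinship`.
#'
#' For `cages_per_family = 3` and seven or more families the structural part is
#' built from the cyclic starter triple \{i, i+1, i+3\} (mod n), which yields n
#' cages with every family in three of them and every pair at most once (the
#' Fano plane when n = 7). Kinship/CV constraints are then satisfied by seeded
#' stochastic swap repair; for other `cages_per_family` a randomized greedy
#' pair-respecting assembly with restarts is used. The search is deterministic
#' given `seed`.
#'
#' @param n_families number of families.
#' @param cages_per_family number of cages each family is tested in.
#' @param members_per_family_per_cage individuals contributed by a family to
#'   each of its cages.
#' @param family_ids optional character ids (default `F01`, `F02`, ...).
#' @param family_kinship optional symmetric matrix of pairwise family kinship
#'   coefficients (dimnames = family ids).
#' @param family_weight_stats optional data.frame `family_id`, `mean`, `sd` of
#'   tagging body weight, used to predict per-cage CV before phenotyping.
#' @param global_cv,global_mean_kinship constraint ceilings (fractions); `NULL`
#'   disables the corresponding check.
#' @param seed integer seed for the stochastic search.
#' @param max_swaps iteration budget for constraint repair.
#' @return object of class `design_layout`: list with `cages` (each a list
#'   `cage_id`, `families`, `members`), `group_size`, `cages_per_family`,
#'   `families_per_cage = 3`, `family_ids` and a `violations` attribute (empty
#'   data.frame when all constraints hold; constraint repair failure is
#'   reported there and by a warning, never silently).
#' @export
build_layout <- function(n_families, cages_per_family = 3,
                         members_per_family_per_cage = 12,
                         family_ids = NULL,
                         family_kinship = NULL, family_weight_stats = NULL,
                         global_cv = NULL, global_mean_kinship = NULL,
                         seed = 1L, max_swaps = 2000L) {
  stopifnot(n_families >= 3, cages_per_family >= 1, members_per_family_per_cage >= 1)
  if ((n_families * cages_per_family) %% 3L != 0L) {
    stop("n_families * cages_per_family must be divisible by 3")
  }
  if (n_families < 2 * cages_per_family + 1) {
    stop("infeasible: pair-uniqueness needs n_families >= 2*cages_per_family + 1 (",
         n_families, " < ", 2 * cages_per_family + 1, ")")
  }
  if (is.null(family_ids)) {
    family_ids <- sprintf("F%02d", seq_len(n_families))
  }
  stopifnot(length(family_ids) == n_families, !anyDuplicated(family_ids))
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))

  triples <- if (cages_per_family == 3 && n_families >= 7) {
    cyclic_triples(n_families)
  } else {
    greedy_triples(n_families, cages_per_family)
  }
  triples <- repair_constraints(triples, family_ids, family_kinship,
                                family_weight_stats,
                                members_per_family_per_cage,
                                global_cv, global_mean_kinship, max_swaps)

  # deterministic member assignment: consecutive blocks per family in cage order
  next_member <- setNames(rep(1L, n_families), family_ids)
  m <- members_per_family_per_cage
  cages <- vector("list", nrow(triples))
  for (ci in seq_len(nrow(triples))) {
    fams <- sort(family_ids[triples[ci, ]])  # lexicographic tie-break
    members <- unlist(lapply(fams, function(f) {
      idx <- next_member[[f]] + seq_len(m) - 1L
      next_member[[f]] <<- next_member[[f]] + m
      sprintf("%s_%02d", f, idx)
    }))
    cages[[ci]] <- list(cage_id = sprintf("C%02d", ci),
                        families = fams, members = members)
  }
  layout <- structure(list(cages = cages,
                           group_size = 3L * m,
                           families_per_cage = 3L,
                           cages_per_family = as.integer(cages_per_family),
                           family_ids = family_ids),
                      class = "design_layout")
  viol <- validate_layout(layout, family_kinship, family_weight_stats,
                          global_cv, global_mean_kinship)
  attr(layout, "violations") <- viol
  if (nrow(viol)) {
    warning("layout constraint repair incomplete: ", nrow(viol),
            " violation(s) remain (see validate_layout)")
  }
  layout
}

cyclic_triples <- function(n) {
  t(vapply(seq_len(n) - 1L,
           function(i) as.integer(c(i, (i + 1L) %% n, (i + 3L) %% n) + 1L),
           integer(3)))
}

greedy_triples <- function(n, c_per, max_restarts = 200L) {
  n_cages <- n * c_per / 3L
  for (r in seq_len(max_restarts)) {
    remaining <- rep(c_per, n)
    used <- matrix(FALSE, n, n)
    triples <- matrix(NA_integer_, n_cages, 3)
    ok <- TRUE
    for (ci in seq_len(n_cages)) {
      cand <- which(remaining > 0)
      found <- FALSE
      for (try in seq_len(50L)) {
        if (length(cand) < 3) break
        tri <- sort(sample(cand, 3))
        if (!used[tri[1], tri[2]] && !used[tri[1], tri[3]] && !used[tri[2], tri[3]]) {
          triples[ci, ] <- tri
          remaining[tri] <- remaining[tri] - 1L
          used[tri[1], tri[2]] <- used[tri[2], tri[1]] <- TRUE
          used[tri[1], tri[3]] <- used[tri[3], tri[1]] <- TRUE
          used[tri[2], tri[3]] <- used[tri[3], tri[2]] <- TRUE
          found <- TRUE
          break
        }
      }
      if (!found) { ok <- FALSE; break }
    }
    if (ok) return(triples)
  }
  stop("constraint satisfaction not found within iteration budget (",
       max_restarts, " restarts) for n_families=", n,
       ", cages_per_family=", c_per)
}

# Predicted CV of a 3-family mixture with equal member counts.
mixture_cv <- function(means, sds) {
  mu <- mean(means)
  v <- mean(sds^2 + means^2) - mu^2
  sqrt(max(v, 0)) / mu
}

cage_content_violations <- function(tri_ids, cage_id, family_kinship,
                                    family_weight_stats, global_cv,
                                    global_mean_kinship) {
  out <- list()
  if (!is.null(family_kinship) && !is.null(global_mean_kinship)) {
    k <- family_kinship[tri_ids, tri_ids]
    mk <- mean(k[upper.tri(k)])
    if (mk > global_mean_kinship + 1e-12) {
      out <- c(out, list(data.frame(cage = cage_id, constraint = "kinship",
                                    value = mk, limit = global_mean_kinship)))
    }
  }
  if (!is.null(family_weight_stats) && !is.null(global_cv)) {
    i <- match(tri_ids, family_weight_stats$family_id)
    cv <- mixture_cv(family_weight_stats$mean[i], family_weight_stats$sd[i])
    if (cv > global_cv + 1e-12) {
      out <- c(out, list(data.frame(cage = cage_id, constraint = "cv",
                                    value = cv, limit = global_cv)))
    }
  }
  out
}

repair_constraints <- function(triples, family_ids, family_kinship,
                               family_weight_stats, m, global_cv,
                               global_mean_kinship, max_swaps) {
  if (is.null(family_kinship) && is.null(family_weight_stats)) return(triples)
  score <- function(tr) {
    sum(vapply(seq_len(nrow(tr)), function(ci) {
      length(cage_content_violations(family_ids[tr[ci, ]], ci, family_kinship,
                                     family_weight_stats, global_cv,
                                     global_mean_kinship))
    }, numeric(1)))
  }
  cur <- score(triples)
  n_cages <- nrow(triples)
  pair_used <- function(tr) {
    p <- apply(tr, 1, function(x) {
      cb <- utils::combn(sort(x), 2); paste(cb[1, ], cb[2, ], sep = "-")
    })
    as.vector(p)
  }
  it <- 0L
  while (cur > 0 && it < max_swaps) {
    it <- it + 1L
    ci <- sample.int(n_cages, 1)
    cj <- sample.int(n_cages, 1)
    if (ci == cj) next
    si <- sample.int(3, 1); sj <- sample.int(3, 1)
    cand <- triples
    tmp <- cand[ci, si]
    cand[ci, si] <- cand[cj, sj]
    cand[cj, sj] <- tmp
    if (anyDuplicated(cand[ci, ]) || anyDuplicated(cand[cj, ])) next
    if (anyDuplicated(pair_used(cand))) next
    new <- score(cand)
    if (new <= cur) {
      triples <- cand
      cur <- new
    }
  }
  triples
}

#' Validate a 3FAM layout
#'
#' Structural checks (three families per cage, equal per-family cage counts,
#' pair-uniqueness, equal member contributions, no individual in two cages) and
#' the kinship/CV content constraints. Never throws on content: every failed
#' check becomes a row of the returned table.
#'
#' @inheritParams build_layout
#' @param layout a `design_layout`.
#' @return data.frame with columns `cage`, `constraint`, `value`, `limit`;
#'   zero rows iff the layout satisfies every check.
#' @export
validate_layout <- function(layout, family_kinship = NULL,
                            family_weight_stats = NULL, global_cv = NULL,
                            global_mean_kinship = NULL) {
  empty <- data.frame(cage = character(), constraint = character(),
                      value = numeric(), limit = numeric())
  viol <- list()
  fams_per_cage <- lapply(layout$cages, `[[`, "families")
  ids <- vapply(layout$cages, `[[`, "", "cage_id")
  for (i in seq_along(layout$cages)) {
    if (length(fams_per_cage[[i]]) != 3 || anyDuplicated(fams_per_cage[[i]])) {
      viol <- c(viol, list(data.frame(cage = ids[i], constraint = "families_per_cage",
                                      value = length(unique(fams_per_cage[[i]])), limit = 3)))
    }
  }
  counts <- table(factor(unlist(fams_per_cage), levels = layout$family_ids))
  off <- names(counts)[counts != layout$cages_per_family]
  for (f in off) {
    viol <- c(viol, list(data.frame(cage = NA_character_, constraint = "cages_per_family",
                                    value = as.numeric(counts[[f]]),
                                    limit = layout$cages_per_family)))
  }
  pairs <- unlist(lapply(fams_per_cage, function(f) {
    cb <- utils::combn(sort(f), 2); paste(cb[1, ], cb[2, ], sep = "|")
  }))
  dup_pairs <- unique(pairs[duplicated(pairs)])
  for (p in dup_pairs) {
    viol <- c(viol, list(data.frame(cage = NA_character_, constraint = "pair_uniqueness",
                                    value = sum(pairs == p), limit = 1)))
  }
  members <- unlist(lapply(layout$cages, `[[`, "members"))
  if (anyDuplicated(members)) {
    viol <- c(viol, list(data.frame(cage = NA_character_, constraint = "member_uniqueness",
                                    value = sum(duplicated(members)), limit = 0)))
  }
  m_expect <- layout$group_size / 3
  for (i in seq_along(layout$cages)) {
    fam_of <- sub("_[0-9]+$", "", layout$cages[[i]]$members)
    tab <- table(fam_of)
    if (length(layout$cages[[i]]$members) != layout$group_size ||
        any(tab != m_expect)) {
      viol <- c(viol, list(data.frame(cage = ids[i], constraint = "members_per_family",
                                      value = max(abs(as.numeric(tab) - m_expect)),
                                      limit = 0)))
    }
    viol <- c(viol, cage_content_violations(layout$cages[[i]]$families, ids[i],
                                            family_kinship, family_weight_stats,
                                            global_cv, global_mean_kinship))
  }
  if (!length(viol)) return(empty)
  do.call(rbind, viol)
}

#' @export
print.design_layout <- function(x, ...) {
  cat("3FAM design layout: ", length(x$cages), " cages, ",
      length(x$family_ids), " families, ", x$cages_per_family,
      " cages/family, group size ", x$group_size, "\n", sep = "")
  v <- attr(x, "violations")
  cat(if (!is.null(v) && nrow(v)) paste0(nrow(v), " constraint violation(s)")
      else "all constraints satisfied", "\n")
  invisible(x)
}

#' Write / read a layout as CSV
#'
#' One row per cage: `cage_id`, `family_1..3`, and the member ids separated by
#' semicolons.
#'
#' @param layout a `design_layout`.
#' @param path CSV path.
#' @export
write_layout <- function(layout, path) {
  rows <- lapply(layout$cages, function(cg) {
    data.frame(cage_id = cg$cage_id, family_1 = cg$families[1],
               family_2 = cg$families[2], family_3 = cg$families[3],
               members = paste(cg$members, collapse = ";"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cages <- lapply(seq_len(nrow(df)), function(i) {
    list(cage_id = df$cage_id[i],
         families = sort(c(df$family_1[i], df$family_2[i], df$family_3[i])),
         members = strsplit(df$members[i], ";", fixed = TRUE)[[1]])
  })
  fam <- sort(unique(unlist(lapply(cages, `[[`, "families"))))
  cpf <- as.integer(round(length(cages) * 3 / length(fam)))
  structure(list(cages = cages,
                 group_size = length(cages[[1]]$members),
                 families_per_cage = 3L, cages_per_family = cpf,
                 family_ids = fam),
            class = "design_layout")
}

# Seed helpers: deterministic local RNG without clobbering the caller's stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
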