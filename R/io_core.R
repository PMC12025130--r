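#' @importFrom stats cor rnorm rbinom runif sd var setNames lm coef
#' @importFrom utils read.csv write.csv
NULL

PHENO_COLS <- c("individual_id", "family_id", "cage_id", "sex",
                "initial_weight", "harvest_weight", "alive")

#' Validate a phenotype table
#'
#' Checks the invariants of the per-individual phenotype table: one row per
#' individual, sex restricted to male/female, positive harvest weight for every
#' live animal, and (optionally) that every cage id is part of a known design
#' layout.
#'
#' @param pheno data.frame with columns `individual_id`, `family_id`,
#'   `cage_id`, `sex`, `initial_weight` (g, at tagging), `harvest_weight`
#'   (g, `NA` when dead) and `alive` (logical).
#' @param layout optional `design_layout` (see [build_layout()]); when given,
#'   `cage_id`s must occur in it.
#' @return the table, invisibly, with normalized column types.
#' @export
validate_phenotypes <- function(pheno, layout = NULL) {
  missing_cols <- setdiff(PHENO_COLS, names(pheno))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  pheno$individual_id <- as.character(pheno$individual_id)
  pheno$family_id <- as.character(pheno$family_id)
  pheno$cage_id <- as.character(pheno$cage_id)
  sex <- tolower(as.character(pheno$sex))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be male/female (got: ",
         paste(unique(sex[!sex %in% c("male", "female")]), collapse = ", "), ")")
  }
  pheno$sex <- sex
  if (is.character(pheno$alive)) pheno$alive <- tolower(pheno$alive) %in% c("true", "t", "1", "yes")
  if (is.numeric(pheno$alive)) pheno$alive <- pheno$alive != 0
  pheno$initial_weight <- as.numeric(pheno$initial_weight)
  hw <- pheno$harvest_weight
  if (is.character(hw)) hw[hw %in% c("", "NA")] <- NA
  hw <- as.numeric(hw)
  hw[!is.na(hw) & hw == 0 & !pheno$alive] <- NA  # 0 accepted as missing for dead
  pheno$harvest_weight <- hw
  dup <- duplicated(pheno$individual_id)
  if (any(dup)) stop("duplicate individual_id: ",
                     paste(unique(pheno$individual_id[dup]), collapse = ", "))
  bad <- pheno$alive & (is.na(pheno$harvest_weight) | pheno$harvest_weight <= 0)
  if (any(bad)) {
    stop("alive individuals must have positive harvest_weight: ",
         paste(pheno$individual_id[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  if (!is.null(layout)) {
    known <- vapply(layout$cages, `[[`, "", "cage_id")
    unknown <- setdiff(unique(pheno$cage_id), known)
    if (length(unknown)) stop("cage_id not in layout: ", paste(unknown, collapse = ", "))
  }
  invisible(pheno)
}

#' Read a phenotype CSV
#'
#' Missing harvest weights may be encoded as an empty field, `NA` or `0`
#' (dead animals only). Row order and count are preserved.
#'
#' @inheritParams validate_phenotypes
#' @param path CSV file with a header row and the columns listed in
#'   [validate_phenotypes()].
#' @return validated phenotype data.frame.
#' @export
read_phenotypes <- function(path, layout = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_phenotypes(raw, layout = layout)
}

#' Write a phenotype CSV
#'
#' Inverse of [read_phenotypes()]; missing weights are written as empty fields.
#'
#' @param pheno phenotype table.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  pheno <- validate_phenotypes(pheno)
  write.csv(pheno[, PHENO_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Descriptive statistics of harvest weight
#'
#' Per-group stocking and harvest counts, harvest-weight mean, range, sample
#' standard deviation (n-1 denominator), coefficient of variation and survival
#' percentage.
#'
#' @param pheno phenotype table.
#' @param group_by one of `"all"`, `"sex"`, `"family"`, `"cage"`.
#' @return data.frame with one row per group: `group`, `n_stocked`,
#'   `n_harvested`, `mean`, `min`, `max`, `sd`, `cv_percent`,
#'   `survival_percent`.
#' @export
descriptive_stats <- function(pheno, group_by = c("all", "sex", "family", "cage")) {
  group_by <- match.arg(group_by)
  pheno <- validate_phenotypes(pheno)
  key <- switch(group_by,
                all = rep("All", nrow(pheno)),
                sex = pheno$sex,
                family = pheno$family_id,
                cage = pheno$cage_id)
  groups <- sort(unique(key))
  rows <- lapply(groups, function(g) {
    sub <- pheno[key == g, ]
    w <- sub$harvest_weight[sub$alive]
    if (!length(w)) stop("group '", g, "' has no harvested individuals")
    m <- mean(w)
    s <- if (length(w) > 1) sd(w) else 0
    data.frame(group = g,
               n_stocked = nrow(sub),
               n_harvested = sum(sub$alive),
               mean = m, min = min(w), max = max(w), sd = s,
               cv_percent = if (m != 0) 100 * s / m else NA_real_,
               survival_percent = 100 * sum(sub$alive) / nrow(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run configuration
#'
#' Plumbing for scripted analyses: which relationship matrix to use, whether to
#' model indirect genetic and cage effects, convergence tolerances, seeds and
#' cross-validation settings. Stored as YAML.
#'
#' @param matrix_kind "A" (pedigree) or "H" (single-step genomic).
#' @param include_ige model indirect genetic effects of cage mates.
#' @param include_cage model a random cage effect (`NA` = decide by convention,
#'   see [fit_dhglm()]).
#' @param seed integer master seed.
#' @param tol_outer,tol_inner DHGLM outer-loop and REML inner-loop convergence
#'   tolerances on the change in restricted log-likelihood.
#' @param cv_k,cv_replicates cross-validation folds (>= 2) and replicates.
#' @return list of class `run_config`.
#' @export
run_config <- function(matrix_kind = c("A", "H"), include_ige = FALSE,
                       include_cage = NA, seed = 1L,
                       tol_outer = 1e-4, tol_inner = 1e-6,
                       cv_k = 10L, cv_replicates = 20L) {
  matrix_kind <- match.arg(matrix_kind)
  stopifnot(cv_k >= 2, tol_outer > 0, tol_inner > 0, cv_replicates >= 1)
  structure(list(matrix_kind = matrix_kind, include_ige = isTRUE(include_ige),
                 include_cage = include_cage, seed = as.integer(seed),
                 tol_outer = tol_outer, tol_inner = tol_inner,
                 cv_k = as.integer(cv_k), cv_replicates = as.integer(cv_replicates)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stage logging: seed, an order-insensitive input fingerprint and free-form
# details go to stderr and, when option hwuni.log_file is set, to that file.
log_stage <- function(stage, seed = NULL, input = NULL, ...) {
  details <- c(...)
  fp <- if (!is.null(input)) {
    format(sum(as.numeric(utf8ToInt(paste(format(input), collapse = ""))) *
               rep_len(c(1, 3, 7, 31), length(utf8ToInt(paste(format(input), collapse = ""))))) %% 1e9,
           scientific = FALSE)
  }
  msg <- paste0("[hwuni] ", stage,
                if (!is.null(seed)) paste0(" seed=", seed),
                if (!is.null(fp)) paste0(" input_fp=", fp),
                if (length(details)) paste0(" ", paste(names(details), details,
                                                       sep = "=", collapse = " ")))
  message(msg)
  lf <- getOption("hwuni.log_file")
  if (!is.null(lf)) cat(msg, "\n", file = lf, append = TRUE)
  invisible(msg)
}
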