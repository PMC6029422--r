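#' Tiered variable set
#'
#' Bundles variable names with their visit (tier) index and role.  Tiers
#' encode the chronological order of repeated measurements: a biomarker
#' measured at visit 2 has tier 2.  At most one variable may carry the
#' `"outcome"` role and, if present, it must occupy a tier strictly greater
#' than every covariate tier (the endpoint is observed after all
#' measurements).
#'
#' @param names character vector of unique variable names.
#' @param tier named (or positionally matched) non-negative integer vector of
#'   visit indices, one per variable.
#' @param outcome optional name of the binary outcome variable.
#' @return an object of class `tiered_vars` with elements `names`, `tier`
#'   (named integer) and `role` (named character, `"covariate"`/`"outcome"`).
#' @examples
#' tiered_vars(c("bm1@V1", "bm1@V2", "y"), tier = c(1, 2, 3), outcome = "y")
#' @export
tiered_vars <- function(names, tier, outcome = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names))
    stop("duplicated variable names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (is.null(base::names(tier))) {
    if (length(tier) != length(names))
      stop("`tier` must have one entry per variable")
    tier <- stats::setNames(as.integer(tier), names)
  } else {
    missing <- setdiff(names, base::names(tier))
    if (length(missing))
      stop("no tier for variable(s): ", paste(missing, collapse = ", "))
    tier <- stats::setNames(as.integer(tier[names]), names)
  }
  if (any(is.na(tier)) || any(tier < 0))
    stop("tiers must be non-negative integers")
  role <- stats::setNames(rep("covariate", length(names)), names)
  if (!is.null(outcome)) {
    if (length(outcome) != 1L || !outcome %in% names)
      stop("`outcome` must name exactly one variable present in `names`")
    role[outcome] <- "outcome"
    cov_tiers <- tier[role == "covariate"]
    if (length(cov_tiers) && tier[outcome] <= max(cov_tiers))
      stop("the outcome tier must be strictly greater than every covariate tier")
  }
  structure(list(names = names, tier = tier, role = role),
            class = "tiered_vars")
}

#' @export
print.tiered_vars <- function(x, ...) {
  n_out <- sum(x$role == "outcome")
  cat(sprintf("tiered_vars: %d variables over tiers {%s}%s\n",
              length(x$names),
              paste(sort(unique(x$tier)), collapse = ", "),
              if (n_out) sprintf(", outcome: %s", outcome_of(x)) else ""))
  invisible(x)
}

#' Name of the outcome variable, or NULL
#' @param vars a `tiered_vars` object.
#' @export
outcome_of <- function(vars) {
  out <- vars$names[vars$role == "outcome"]
  if (length(out)) out else NULL
}

#' Covariate names of a tiered variable set
#' @param vars a `tiered_vars` object.
#' @export
covariates_of <- function(vars) {
  vars$names[vars$role == "covariate"]
}

#' Build a tiered variable set from `name@V<k>` column labels
#'
#' Columns following the `<biomarker>@V<k>` convention are assigned tier `k`;
#' the outcome column gets tier `max(k) + 1`.
#'
#' @param columns character vector of column names.
#' @param outcome name of the outcome column (not `name@V<k>`-tagged).
#' @param tier_map optional named list/vector mapping column name to tier,
#'   overriding the suffix convention.
#' @export
tiers_from_names <- function(columns, outcome = NULL, tier_map = NULL) {
  covs <- setdiff(columns, outcome)
  if (is.null(tier_map)) {
    m <- regmatches(covs, regexec("@[Vv]([0-9]+)$", covs))
    bad <- covs[vapply(m, length, 1L) == 0L]
    if (length(bad))
      stop("cannot infer a tier for column(s) without an `@V<k>` suffix: ",
           paste(bad, collapse = ", "), "; supply a tier map")
    tier <- vapply(m, function(g) as.integer(g[2]), 1L)
    names(tier) <- covs
  } else {
    tier_map <- unlist(tier_map)
    missing <- setdiff(covs, names(tier_map))
    if (length(missing))
      stop("tier map is missing column(s): ", paste(missing, collapse = ", "))
    tier <- stats::setNames(as.integer(tier_map[covs]), covs)
  }
  if (!is.null(outcome))
    tier[outcome] <- max(tier[covs], 0L) + 1L
  tiered_vars(columns, tier[columns], outcome = outcome)
}
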