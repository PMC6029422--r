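#' Locally valid parent sets of a covariate in a CPDAG
#'
#' The local IDA step: with `pa(x)` the directed parents of `x` and `sib`
#' its undirected neighbours, a subset `S` of `sib` gives the candidate
#' adjustment set `pa(x) + S`.  Orienting every `s in S` into `x` is
#' locally valid iff it creates no new collider at `x`, i.e. every member
#' of `S` is adjacent to every other member of `S + pa(x)`.
#'
#' @param cpdag a `mixed_graph` (output of the PC variants).
#' @param x covariate node name.
#' @return list of character vectors (deduplicated, deterministic order;
#'   always contains at least `pa(x)`).
#' @export
locally_valid_parent_sets <- function(cpdag, x) {
  if (!x %in% cpdag$nodes) stop("node not in graph: ", x)
  pa <- sort(parents_of(cpdag, x))
  sib <- sort(siblings_of(cpdag, x))
  adj <- adjacency_matrix(cpdag)
  valid <- list()
  for (k in 0:length(sib)) {
    for (S in subsets_of_size(seq_along(sib), k)) {
      Sn <- sib[S]
      others <- c(Sn, pa)
      ok <- TRUE
      for (s in Sn) {
        if (!all(adj[s, setdiff(others, s)] == 1L)) { ok <- FALSE; break }
      }
      if (ok) valid[[length(valid) + 1L]] <- sort(c(pa, Sn))
    }
  }
  unique(valid)
}

#' Adjusted effect of a continuous covariate on the binary outcome
#'
#' Firth-penalised logistic regression of the outcome on the covariate and
#' an adjustment set.  `scale = "log-odds"` returns the covariate's
#' coefficient (conditional log odds ratio per unit).
#' `scale = "risk-difference"` standardises over the observed adjustment
#' rows (g-formula): the mean difference in fitted risk between setting
#' the covariate to `mean(x) + 1` and to `mean(x)`.
#'
#' @param data numeric matrix / data.frame.
#' @param x covariate column name.
#' @param outcome binary outcome column name.
#' @param adjust character vector of adjustment columns (no `x`/outcome).
#' @param scale `"log-odds"` (default) or `"risk-difference"`.
#' @return a single numeric effect.
#' @export
estimate_effect <- function(data, x, outcome, adjust = character(),
                            scale = c("log-odds", "risk-difference")) {
  scale <- match.arg(scale)
  data <- as.matrix(data)
  adjust <- setdiff(adjust, c(x, outcome))
  X <- cbind(`(Intercept)` = 1, data[, c(x, adjust), drop = FALSE])
  fit <- firth_logistic_fit(X, data[, outcome])
  if (scale == "log-odds") return(unname(fit$coefficients[x]))
  xbar <- mean(data[, x])
  Z <- data[, adjust, drop = FALSE]
  eta0 <- fit$coefficients["(Intercept)"] + fit$coefficients[x] * xbar +
    if (length(adjust)) drop(Z %*% fit$coefficients[adjust]) else 0
  mean(stats::plogis(eta0 + fit$coefficients[x]) - stats::plogis(eta0))
}

#' IDA effect multiset for one covariate
#'
#' One adjusted effect per locally valid parent set; the lower bound of
#' the covariate's absolute total causal effect on the outcome is the
#' minimum absolute entry, and the ambiguity is the number of distinct
#' effect values (tolerance 1e-8).
#'
#' @inheritParams estimate_effect
#' @param cpdag a `mixed_graph` from the structure-learning step.
#' @return object of class `effect_multiset`: `covariate`, `entries`
#'   (data.frame `adjustment_set` (list-column), `theta`), `lower_bound`,
#'   `ambiguity`.
#' @export
ida_multiset <- function(cpdag, data, x, outcome,
                         scale = c("log-odds", "risk-difference")) {
  scale <- match.arg(scale)
  sets <- locally_valid_parent_sets(cpdag, x)
  sets <- lapply(sets, setdiff, y = outcome)
  theta <- vapply(sets, function(S)
    estimate_effect(data, x, outcome, S, scale), numeric(1))
  structure(list(
    covariate = x,
    entries = data.frame(adjustment_set = I(sets), theta = theta),
    lower_bound = min(abs(theta)),
    ambiguity = n_distinct_tol(theta)),
    class = "effect_multiset")
}

n_distinct_tol <- function(x, tol = 1e-8) {
  x <- sort(x)
  if (!length(x)) return(0L)
  sum(c(TRUE, diff(x) > tol))
}

#' @export
print.effect_multiset <- function(x, ...) {
  cat(sprintf("IDA multiset for %s: %d adjustment set(s), lower bound %.4f, ambiguity %d\n",
              x$covariate, nrow(x$entries), x$lower_bound, x$ambiguity))
  invisible(x)
}

#' IDA lower bounds for every covariate
#'
#' @param cpdag a `mixed_graph`.
#' @param data numeric matrix / data.frame.
#' @param vars a [tiered_vars] with an outcome, or NULL (then `outcome`
#'   must be given).
#' @param outcome outcome column name (defaults to the one in `vars`).
#' @param scale effect scale, see [estimate_effect()].
#' @return data.frame `covariate`, `lower_bound`, `ambiguity`, `thetas`
#'   (semicolon-joined multiset values), ordered as [rank_effects()].
#' @export
ida_all_effects <- function(cpdag, data, vars = NULL,
                            outcome = outcome_of(vars),
                            scale = "log-odds") {
  if (is.null(outcome)) stop("no outcome variable given")
  covs <- setdiff(cpdag$nodes, outcome)
  ms <- lapply(covs, function(x)
    ida_multiset(cpdag, data, x, outcome, scale))
  bounds <- stats::setNames(vapply(ms, `[[`, numeric(1), "lower_bound"), covs)
  ord <- rank_effects(bounds)
  sel <- match(ord, covs)
  data.frame(covariate = ord,
             lower_bound = unname(bounds[ord]),
             ambiguity = vapply(ms, `[[`, integer(1), "ambiguity")[sel],
             thetas = vapply(ms, function(m)
               paste(signif(m$entries$theta, 8), collapse = ";"),
               character(1))[sel],
             stringsAsFactors = FALSE)
}

#' Rank covariates by their causal-effect lower bound
#'
#' Descending lower bound; ties broken alphabetically for determinism.
#'
#' @param bounds named numeric vector `covariate -> lower bound`.
#' @return character vector of covariate names, best first.
#' @export
rank_effects <- function(bounds) {
  nm <- names(bounds)
  nm[order(-bounds, nm)]
}
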