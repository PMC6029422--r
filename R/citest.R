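#' Partial correlation from a correlation matrix
#'
#' Correlation of variables `i` and `j` given the conditioning set `S`,
#' obtained from the inverse of the `(i, j, S)` submatrix of the
#' correlation matrix.  This is the estimator the Gaussian CI test builds
#' on (covariates assumed jointly normal).
#'
#' @param corr correlation matrix (names or indices must cover `i`, `j`,
#'   `S`).
#' @param i,j variable names or indices, distinct, not in `S`.
#' @param S conditioning set (possibly empty).
#' @return partial correlation in \[-1, 1\].
#' @export
partial_correlation <- function(corr, i, j, S = integer()) {
  if (length(S) == 0L) return(corr[i, j])
  sub <- corr[c(i, j, S), c(i, j, S), drop = FALSE]
  pm <- tryCatch(solve(sub), error = function(e)
    stop("singular correlation submatrix for {",
         paste(c(i, j, S), collapse = ", "),
         "}: collinear variables", call. = FALSE))
  r <- -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
  max(-1, min(1, r))
}

#' Fisher z test of (partial) correlation
#'
#' Tests `r = 0` via the variance-stabilising transform
#' `z = atanh(r)`; the statistic `sqrt(n - |S| - 3) * |z|` is standard
#' normal under independence.
#'
#' @param r (partial) correlation.
#' @param n sample size.
#' @param s_size size of the conditioning set.
#' @param alpha significance cut-off; dependencies with p-value below
#'   `alpha` are kept as edges (default 0.02, the application setting).
#' @return list with `partial_corr`, `statistic`, `p_value`, `independent`
#'   (`p_value > alpha`).
#' @export
fisher_z_test <- function(r, n, s_size = 0L, alpha = 0.02) {
  df <- n - s_size - 3
  if (df < 1) stop("sample too small for conditioning set of size ", s_size)
  if (abs(r) > 1) stop("|r| > 1")
  if (abs(r) >= 1) {
    warning("|r| = 1: degenerate correlation, treated as dependent")
    return(list(partial_corr = r, statistic = Inf, p_value = 0,
                independent = FALSE))
  }
  z <- atanh(r)
  stat <- sqrt(df) * abs(z)
  p <- 2 * stats::pnorm(-stat)
  list(partial_corr = r, statistic = stat, p_value = p,
       independent = p > alpha)
}

#' Gaussian conditional-independence tester for a dataset
#'
#' Computes the correlation matrix once and returns a closure
#' `function(i, j, S)` yielding the Fisher-z p-value — the test backend of
#' [pc_stable()] and [copc_stable()].  The binary outcome column, when
#' present, enters the correlation matrix as a 0/1 numeric by default
#' (pragmatic Gaussian approximation); with
#' `outcome_test = "logistic-lrt"` pairs involving the outcome are instead
#' tested by a likelihood-ratio test from a logistic regression.
#'
#' @param data numeric matrix or data.frame (no missing values).
#' @param outcome optional name of the binary outcome column.
#' @param outcome_test `"gaussian"` (default) or `"logistic-lrt"`.
#' @param log record every test (pair, conditioning set, p-value) for
#'   audit; retrieve with [ci_test_log()].
#' @return function `(i, j, S) -> p-value` with attributes `n` (sample
#'   size) and an environment counter readable via [ci_test_count()].
#' @export
gauss_ci_test <- function(data, outcome = NULL,
                          outcome_test = c("gaussian", "logistic-lrt"),
                          log = FALSE) {
  outcome_test <- match.arg(outcome_test)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (any(!is.finite(data)))
    stop("data contain missing or non-finite cells; impute upstream ",
         "(e.g. MICE) before structure learning")
  n <- nrow(data)
  corr <- stats::cor(data)
  nm <- colnames(data)
  out_idx <- if (!is.null(outcome)) match(outcome, nm) else 0L
  count <- new.env(parent = emptyenv())
  count$n_tests <- 0L
  count$log <- if (log) list() else NULL
  # hot path: accepts node names or integer indices into the data columns
  f <- function(i, j, S = integer()) {
    count$n_tests <- count$n_tests + 1L
    if (is.character(i)) i <- match(i, nm)
    if (is.character(j)) j <- match(j, nm)
    if (is.character(S)) S <- match(S, nm)
    if (outcome_test == "logistic-lrt" && out_idx > 0L &&
        (out_idx == i || out_idx == j)) {
      p <- logistic_lrt_p(data, nm[i], nm[j], nm[S], outcome)
      if (log)
        count$log[[count$n_tests]] <- list(i = nm[i], j = nm[j],
                                           S = paste(nm[S], collapse = "|"),
                                           r = NA_real_, p = p)
      return(p)
    }
    ns <- length(S)
    r <- if (ns == 0L) {
      corr[i, j]
    } else if (ns == 1L) {
      rij <- corr[i, j]; rik <- corr[i, S]; rjk <- corr[j, S]
      den <- (1 - rik^2) * (1 - rjk^2)
      if (den <= 0)
        stop("singular correlation submatrix for {", nm[i], ", ", nm[j],
             ", ", nm[S], "}: collinear variables", call. = FALSE)
      (rij - rik * rjk) / sqrt(den)
    } else {
      idx <- c(i, j, S)
      pm <- tryCatch(solve(corr[idx, idx]), error = function(e)
        stop("singular correlation submatrix for {",
             paste(nm[idx], collapse = ", "), "}: collinear variables",
             call. = FALSE))
      -pm[1L, 2L] / sqrt(pm[1L, 1L] * pm[2L, 2L])
    }
    df <- n - ns - 3
    if (df < 1) stop("sample too small for conditioning set of size ", ns)
    r <- max(-1 + 1e-12, min(1 - 1e-12, r))
    p <- 2 * stats::pnorm(-sqrt(df) * abs(atanh(r)))
    if (log)
      count$log[[count$n_tests]] <- list(i = nm[i], j = nm[j],
                                         S = paste(nm[S], collapse = "|"),
                                         r = r, p = p)
    p
  }
  attr(f, "n") <- n
  attr(f, "nodes") <- nm
  attr(f, "counter") <- count
  attr(f, "max_level") <- n - 4L
  f
}

logistic_lrt_p <- function(data, i, j, S, outcome) {
  x <- setdiff(c(i, j), outcome)
  y <- data[, outcome]
  Z <- data[, S, drop = FALSE]
  f0 <- stats::glm.fit(cbind(1, Z), y, family = stats::binomial())
  f1 <- stats::glm.fit(cbind(1, Z, data[, x]), y, family = stats::binomial())
  lr <- max(0, f0$deviance - f1$deviance)
  stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Number of CI tests performed by a tester closure
#' @param test a closure from [gauss_ci_test()] or [dsep_ci_test()].
#' @export
ci_test_count <- function(test) attr(test, "counter")$n_tests

#' Audit log of a tester built with `log = TRUE`
#' @param test a closure from [gauss_ci_test()].
#' @return data.frame with columns `i`, `j`, `S` (pipe-joined), `r`, `p`.
#' @export
ci_test_log <- function(test) {
  lg <- attr(test, "counter")$log
  if (is.null(lg)) stop("tester was not built with log = TRUE")
  do.call(rbind, lapply(lg, as.data.frame))
}

#' d-separation in a DAG
#'
#' Moralised-ancestral-graph criterion: `i` and `j` are d-separated by `S`
#' iff they are disconnected in the moralisation of the subgraph induced by
#' the ancestors of `{i, j} + S`, after removing `S`.
#'
#' @param dag a `mixed_graph` with only directed edges.
#' @param i,j node names.
#' @param S conditioning node names.
#' @export
dsep <- function(dag, i, j, S = character()) {
  d <- directed_part(dag)
  nm <- dag$nodes
  idx <- function(x) match(x, nm)
  # ancestors of the query nodes (including themselves)
  anc <- rep(FALSE, length(nm))
  frontier <- idx(c(i, j, S))
  anc[frontier] <- TRUE
  while (length(frontier)) {
    pa <- which(rowSums(d[, frontier, drop = FALSE]) > 0L & !anc)
    anc[pa] <- TRUE
    frontier <- pa
  }
  keep <- which(anc)
  sub <- d[keep, keep, drop = FALSE]
  # moralise: marry parents of a common child, drop directions
  m <- sub + t(sub)
  for (ch in seq_along(keep)) {
    pa <- which(sub[, ch] == 1L)
    if (length(pa) > 1L) m[pa, pa] <- 1L
  }
  m <- (m > 0L); diag(m) <- FALSE
  # connectivity avoiding S
  blocked <- keep %in% idx(S)
  src <- match(idx(i), keep); dst <- match(idx(j), keep)
  reach <- rep(FALSE, length(keep)); reach[src] <- TRUE
  frontier <- src
  while (length(frontier)) {
    nxt <- which(colSums(m[frontier, , drop = FALSE]) > 0L & !reach & !blocked)
    if (dst %in% nxt) return(FALSE)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

#' Oracle CI tester backed by d-separation in a known DAG
#'
#' Returns p-value 1 for d-separated queries and 0 otherwise; substituting
#' it for the data-driven test turns the PC variants into their population
#' versions (used for consistency checks).
#'
#' @param dag the true DAG (`mixed_graph`, directed edges only).
#' @return closure compatible with [gauss_ci_test()] output.
#' @export
dsep_ci_test <- function(dag) {
  count <- new.env(parent = emptyenv())
  count$n_tests <- 0L
  nm <- dag$nodes
  f <- function(i, j, S = character()) {
    count$n_tests <- count$n_tests + 1L
    if (is.numeric(i)) i <- nm[i]
    if (is.numeric(j)) j <- nm[j]
    if (is.numeric(S)) S <- nm[S]
    if (dsep(dag, i, j, S)) 1 else 0
  }
  attr(f, "n") <- Inf
  attr(f, "counter") <- count
  attr(f, "max_level") <- Inf
  attr(f, "nodes") <- dag$nodes
  f
}
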