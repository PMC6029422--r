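#' Learning configuration
#'
#' @param alpha significance cut-off for the CI tests, in (0, 1).  Smaller
#'   values give sparser graphs; 0.02 is the application default.
#' @param max_cond_size cap on the conditioning-set size (default
#'   unbounded; the sample size imposes `n - 4` regardless).
#' @param tiered whether chronological (tier) background knowledge is used.
#' @param outcome_test how CI tests involving the binary outcome are run,
#'   see [gauss_ci_test()].
#' @export
learn_config <- function(alpha = 0.02, max_cond_size = Inf, tiered = FALSE,
                         outcome_test = "gaussian") {
  stopifnot(alpha > 0, alpha < 1, max_cond_size >= 0)
  structure(list(alpha = alpha, max_cond_size = max_cond_size,
                 tiered = tiered, outcome_test = outcome_test),
            class = "learn_config")
}

#' Order-independent (stable) skeleton search
#'
#' Level-wise edge deletion: at level `l` the candidate separating sets for
#' a pair are the size-`l` subsets of its endpoints' adjacency sets
#' *frozen at the start of the level*, so deletions within a level cannot
#' influence which tests other pairs see — the output is invariant to the
#' variable order.  With tiers, candidates for a pair measured at times
#' `t, t*` are restricted to variables measured no later than
#' `max(t, t*)`: the future is never conditioned on.  Pre-directed edges of
#' the initial graph count as adjacencies for candidacy and keep their
#' direction if they survive (partially directed skeleton).
#'
#' @param test CI tester closure (`function(i, j, S) -> p`), e.g. from
#'   [gauss_ci_test()] or [dsep_ci_test()].
#' @param cfg a [learn_config].
#' @param initial starting `mixed_graph` (complete undirected by default in
#'   [pc_stable()]; the chronologically pre-directed graph in
#'   [copc_stable()]).
#' @return list `graph` (the surviving edges, marks preserved), `sepsets`
#'   (named list keyed `"a|b"`, `a < b`), `n_tests`.
#' @export
pc_stable_skeleton <- function(test, cfg, initial) {
  g <- initial
  nm <- g$nodes
  p <- length(nm)
  tiers <- if (cfg$tiered) g$vars$tier[nm] else NULL
  amat <- g$amat
  sepsets <- list()
  alpha <- cfg$alpha
  max_l <- min(cfg$max_cond_size, attr(test, "max_level") %||% Inf)
  n0 <- ci_test_count_safe(test)
  # testers accept integer indices when their node order matches the graph
  use_idx <- identical(attr(test, "nodes"), nm)
  q_test <- if (use_idx) test else function(i, j, S) test(nm[i], nm[j], nm[S])

  # level 0: unordered pairs, S = {}
  adj <- (amat + t(amat)) > 0L
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (q_test(i, j, integer()) > alpha) {
      amat[i, j] <- amat[j, i] <- 0L
      sepsets[[pair_key(nm[i], nm[j])]] <- character()
    }
  }

  # canonical node order by name: sepset search is enumerated in this
  # order on both endpoint sides, so the result is invariant to the
  # column order of the data (full order independence, not only the
  # frozen-adjacency kind)
  canon <- order(nm)
  l <- 0L
  repeat {
    l <- l + 1L
    if (l > max_l) break
    adj <- (amat + t(amat)) > 0L
    frozen <- lapply(seq_len(p), function(i) {
      nb <- which(adj[i, ])
      nb[order(nm[nb])]
    })
    any_left <- FALSE
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(pairs)) {
      a <- pmin(pairs[, 1], pairs[, 2]); b <- pmax(pairs[, 1], pairs[, 2])
      ord <- order(pmin(nm[a], nm[b]), pmax(nm[a], nm[b]))
      pairs <- pairs[ord, , drop = FALSE]
    }
    for (r in seq_len(nrow(pairs))) {
      ab <- pairs[r, ]
      if (nm[ab[2]] < nm[ab[1]]) ab <- rev(ab)
      removed <- FALSE
      for (side in list(ab, rev(ab))) {
        i <- side[1]; j <- side[2]
        cand <- setdiff(frozen[[i]], j)
        if (!is.null(tiers))
          cand <- cand[tiers[cand] <= max(tiers[i], tiers[j])]
        if (length(cand) < l) next
        any_left <- TRUE
        for (S in subsets_of_size(cand, l)) {
          if (q_test(i, j, S) > alpha) {
            amat[i, j] <- amat[j, i] <- 0L
            sepsets[[pair_key(nm[i], nm[j])]] <- nm[S]
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    if (!any_left) break
  }
  list(graph = new_mixed_graph(amat, g$vars),
       sepsets = sepsets,
       n_tests = ci_test_count_safe(test) - n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ci_test_count_safe <- function(test) {
  cnt <- attr(test, "counter")
  if (is.null(cnt)) 0L else cnt$n_tests
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

# all size-l subsets of a vector, lexicographic order
subsets_of_size <- function(x, l) {
  if (l == 0L) return(list(integer()))
  if (length(x) < l) return(list())
  if (length(x) == l) return(list(x))  # combn(scalar, l) would expand 1:x
  m <- utils::combn(x, l)
  lapply(seq_len(ncol(m)), function(c) m[, c])
}

#' Orient v-structures in a (partially directed) skeleton
#'
#' For every unshielded triple `a - b - c` (a, c non-adjacent) whose
#' separating set does not contain `b`, the triple is oriented into the
#' collider `a -> b <- c`.  Pre-directed edges are never reversed: when a
#' collider would require flipping a background arrow, that arrowhead is
#' skipped with a warning.  When two colliders demand opposite directions
#' of one undirected edge, it is left undirected with a warning.
#'
#' @param skeleton `mixed_graph` from [pc_stable_skeleton()].
#' @param sepsets the separating-set store from the same call.
#' @return the oriented `mixed_graph`.
#' @export
orient_v_structures <- function(skeleton, sepsets) {
  amat <- skeleton$amat
  nm <- skeleton$nodes
  d0 <- amat * (1L - t(amat))       # background (pre-directed) edges
  adj <- (amat + t(amat)) > 0L
  want <- matrix(0L, nrow(amat), ncol(amat))  # demanded arrowheads x -> b
  for (b in seq_along(nm)) {
    nb <- which(adj[b, ])
    if (length(nb) < 2L) next
    for (ii in seq_along(nb)) {
      for (jj in seq_len(ii - 1L)) {
        a <- nb[jj]; c <- nb[ii]
        if (adj[a, c]) next
        S <- sepsets[[pair_key(nm[a], nm[c])]]
        if (!is.null(S) && nm[b] %in% S) next
        want[a, b] <- 1L
        want[c, b] <- 1L
      }
    }
  }
  idx <- which(want == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    x <- idx[r, 1]; b <- idx[r, 2]
    if (d0[b, x] == 1L) {
      warning(sprintf("v-structure arrowhead %s -> %s conflicts with background edge %s -> %s; kept background",
                      nm[x], nm[b], nm[b], nm[x]))
      next
    }
    if (want[b, x] == 1L && d0[x, b] == 0L) {
      if (x < b)
        warning(sprintf("conflicting v-structures on edge %s - %s; left undirected",
                        nm[x], nm[b]))
      next
    }
    amat[b, x] <- 0L
  }
  new_mixed_graph(amat, skeleton$vars)
}

#' PC-stable: order-independent constraint-based CPDAG estimation
#'
#' Skeleton search from the complete undirected graph, v-structure
#' orientation from the separating sets, and Meek-rule closure.  The
#' output approximates the CPDAG of the Markov equivalence class of the
#' data-generating DAG (exact under oracle CI tests).
#'
#' @param data numeric matrix / data.frame, or NULL when `test` is given.
#' @param cfg a [learn_config] with `tiered = FALSE`.
#' @param test optional CI tester closure overriding the default Gaussian
#'   test on `data` (e.g. a [dsep_ci_test()] oracle).
#' @param vars optional [tiered_vars] carried through to the output.
#' @return a `mixed_graph` CPDAG with attributes `sepsets` and `n_tests`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); z <- x + rnorm(200); y <- z + rnorm(200)
#' g <- pc_stable(cbind(x = x, z = z, y = y), learn_config(alpha = 0.01))
#' graph_edges(g)  # chain skeleton x - z - y
#' @export
pc_stable <- function(data = NULL, cfg = learn_config(), test = NULL,
                      vars = NULL) {
  if (isTRUE(cfg$tiered))
    stop("use copc_stable() for tiered learning")
  if (is.null(test)) {
    data <- as.matrix(data)
    if (!is.null(vars)) data <- data[, vars$names, drop = FALSE]
    test <- gauss_ci_test(data,
                          outcome = if (!is.null(vars)) outcome_of(vars),
                          outcome_test = cfg$outcome_test)
    nm <- colnames(data)
  } else {
    nm <- attr(test, "nodes") %||% colnames(data)
  }
  initial <- complete_undirected_graph(vars %||% nm)
  sk <- pc_stable_skeleton(test, cfg, initial)
  g <- orient_v_structures(sk$graph, sk$sepsets)
  g <- meek_closure(g)
  attr(g, "sepsets") <- sk$sepsets
  attr(g, "n_tests") <- sk$n_tests
  g
}

#' Complete undirected graph over a node set
#' @param nodes character vector or [tiered_vars].
#' @export
complete_undirected_graph <- function(nodes) {
  vars <- NULL
  if (inherits(nodes, "tiered_vars")) { vars <- nodes; nodes <- nodes$names }
  p <- length(nodes)
  amat <- matrix(1L, p, p, dimnames = list(nodes, nodes))
  diag(amat) <- 0L
  new_mixed_graph(amat, vars)
}

#' Chronologically informed initial graph
#'
#' The complete graph in which every edge between variables measured at
#' different visits is pre-directed from the earlier visit to the later
#' one, edges within a visit stay undirected, and all edges into the
#' outcome (maximal tier) point at it.
#'
#' @param vars a [tiered_vars] object.
#' @return a `mixed_graph`.
#' @export
copc_initial_graph <- function(vars) {
  nodes <- vars$names
  tr <- vars$tier[nodes]
  p <- length(nodes)
  amat <- matrix(1L, p, p, dimnames = list(nodes, nodes))
  diag(amat) <- 0L
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (tr[i] > tr[j]) amat[i, j] <- 0L   # keep only earlier -> later
    }
  }
  new_mixed_graph(amat, vars)
}

#' COPC-stable: chronologically ordered PC-stable
#'
#' PC-stable augmented with the chronological order of repeated
#' measurements: (i) the skeleton search starts from
#' [copc_initial_graph()] and never conditions on variables measured after
#' both members of the tested pair; (ii) cross-visit edges that survive
#' keep their chronological direction (partially directed skeleton);
#' (iii) v-structures only orient within-visit undirected edges; (iv) the
#' Meek closure treats the chronological arrows as fixed background.  The
#' output therefore contains no non-chronologically ordered edge.
#'
#' @param data numeric matrix / data.frame whose columns match
#'   `vars$names`, or NULL when `test` is given.
#' @param vars a [tiered_vars] with the visit map (and optionally the
#'   outcome).
#' @param cfg a [learn_config]; `tiered` is forced to TRUE.
#' @param test optional CI tester closure (oracle use).
#' @return a `mixed_graph` CPDAG with attributes `sepsets` and `n_tests`.
#' @export
copc_stable <- function(data = NULL, vars, cfg = learn_config(tiered = TRUE),
                        test = NULL) {
  cfg$tiered <- TRUE
  if (is.null(test)) {
    data <- as.matrix(data)
    miss <- setdiff(vars$names, colnames(data))
    if (length(miss))
      stop("data lack column(s): ", paste(miss, collapse = ", "))
    data <- data[, vars$names, drop = FALSE]
    test <- gauss_ci_test(data, outcome = outcome_of(vars),
                          outcome_test = cfg$outcome_test)
  }
  initial <- copc_initial_graph(vars)
  sk <- pc_stable_skeleton(test, cfg, initial)
  g <- orient_v_structures(sk$graph, sk$sepsets)
  g <- meek_closure(g)
  stopifnot(classify_edges(g, vars)[["n_nonchronological"]] == 0L)
  attr(g, "sepsets") <- sk$sepsets
  attr(g, "n_tests") <- sk$n_tests
  g
}
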