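#' Mixed graph over a set of variables
#'
#' A graph whose edges are each either directed (`a -> b`) or undirected
#' (`a - b`).  The same container serves as initial graph, skeleton,
#' partially directed skeleton, PDAG, CPDAG and DAG.  Internally the graph
#' is an adjacency matrix `amat` with `amat[a, b] == 1 && amat[b, a] == 0`
#' meaning `a -> b`, and both entries 1 meaning `a - b`.
#'
#' @param nodes character vector of node names, or a [tiered_vars] object.
#' @param directed two-column matrix / data.frame of directed edges
#'   (from, to), or NULL.
#' @param undirected two-column matrix / data.frame of undirected edges,
#'   or NULL.
#' @return object of class `mixed_graph` with elements `nodes` (character),
#'   `amat` (0/1 integer matrix) and `vars` (the `tiered_vars`, or NULL).
#' @examples
#' g <- mixed_graph(c("a", "b", "c"),
#'                  directed = rbind(c("a", "b")),
#'                  undirected = rbind(c("b", "c")))
#' graph_edges(g)
#' @export
mixed_graph <- function(nodes, directed = NULL, undirected = NULL) {
  vars <- NULL
  if (inherits(nodes, "tiered_vars")) {
    vars <- nodes
    nodes <- vars$names
  }
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  add <- function(m, pairs, sym) {
    if (is.null(pairs) || NROW(pairs) == 0L) return(m)
    pairs <- as.matrix(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (!a %in% nodes || !b %in% nodes)
        stop("edge endpoint not a node: ", a, " / ", b)
      if (a == b) stop("self-loop on node ", a)
      m[a, b] <- 1L
      if (sym) m[b, a] <- 1L
    }
    m
  }
  amat <- add(amat, directed, sym = FALSE)
  amat <- add(amat, undirected, sym = TRUE)
  new_mixed_graph(amat, vars)
}

new_mixed_graph <- function(amat, vars = NULL) {
  diag(amat) <- 0L
  structure(list(nodes = rownames(amat), amat = amat, vars = vars),
            class = "mixed_graph")
}

#' @export
print.mixed_graph <- function(x, ...) {
  e <- edge_counts(x)
  cat(sprintf("mixed_graph: %d nodes, %d directed + %d undirected edges\n",
              length(x$nodes), e[["directed"]], e[["undirected"]]))
  invisible(x)
}

# directed part: amat[i,j]==1, amat[j,i]==0
directed_part <- function(g) g$amat * (1L - t(g$amat))
# undirected part (symmetric 0/1)
undirected_part <- function(g) g$amat * t(g$amat)
# symmetric adjacency
adjacency_matrix <- function(g) 1L * ((g$amat + t(g$amat)) > 0L)

edge_counts <- function(g) {
  c(directed = sum(directed_part(g)),
    undirected = sum(undirected_part(g)) / 2L)
}

#' Edge list of a mixed graph
#'
#' @param g a `mixed_graph`.
#' @return data.frame with columns `from`, `to`, `mark`
#'   (`"directed"`/`"undirected"`); undirected edges are listed once with
#'   `from < to` lexicographically.
#' @export
graph_edges <- function(g) {
  d <- which(directed_part(g) == 1L, arr.ind = TRUE)
  u <- which(undirected_part(g) == 1L, arr.ind = TRUE)
  u <- u[u[, 1] < u[, 2], , drop = FALSE]
  nm <- g$nodes
  out <- data.frame(
    from = c(nm[d[, 1]], nm[u[, 1]]),
    to   = c(nm[d[, 2]], nm[u[, 2]]),
    mark = rep(c("directed", "undirected"), c(nrow(d), nrow(u))),
    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Test whether the directed part of a graph is acyclic
#' @param g a `mixed_graph`.
#' @export
is_acyclic <- function(g) {
  d <- directed_part(g)
  # iterative leaf removal (Kahn)
  repeat {
    indeg <- colSums(d)
    keep <- rowSums(d) + indeg > 0L
    if (!any(keep)) return(TRUE)
    src <- keep & indeg == 0L
    if (!any(src)) return(FALSE)
    d[src, ] <- 0L
  }
}

# is there a directed path a ~> b (following directed edges only)?
has_directed_path <- function(dmat, a, b) {
  reached <- logical(nrow(dmat))
  frontier <- a
  while (length(frontier)) {
    nxt <- which(colSums(dmat[frontier, , drop = FALSE]) > 0L & !reached)
    if (b %in% nxt) return(TRUE)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Parents of a node (tails of directed edges into it)
#' @param g a `mixed_graph`.
#' @param x node name.
#' @export
parents_of <- function(g, x) {
  stopifnot(x %in% g$nodes)
  g$nodes[directed_part(g)[, x] == 1L]
}

#' Undirected neighbours (siblings) of a node
#' @param g a `mixed_graph`.
#' @param x node name.
#' @export
siblings_of <- function(g, x) {
  stopifnot(x %in% g$nodes)
  g$nodes[undirected_part(g)[, x] == 1L]
}

#' Relabel / permute the nodes of a mixed graph
#' @param g a `mixed_graph`.
#' @param perm character permutation of `g$nodes`.
#' @export
permute_graph <- function(g, perm) {
  stopifnot(setequal(perm, g$nodes))
  new_mixed_graph(g$amat[perm, perm], g$vars)
}

#' Random tier-free DAG (testing and simulation helper)
#'
#' Directed edges are drawn independently over the upper triangle of a
#' random node ordering, guaranteeing acyclicity.
#'
#' @param p number of nodes.
#' @param edge_prob inclusion probability per ordered candidate pair.
#' @param nodes optional node names (default `x1..xp`).
#' @return a `mixed_graph` containing only directed edges.
#' @export
random_dag <- function(p, edge_prob = 0.3, nodes = paste0("x", seq_len(p))) {
  ord <- sample(p)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (stats::runif(1) < edge_prob)
        amat[ord[i], ord[j]] <- 1L
    }
  }
  new_mixed_graph(amat)
}
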