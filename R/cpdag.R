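#' Meek orientation rules to closure
#'
#' Repeatedly applies the three orientation rules used after v-structure
#' detection until no undirected edge can be oriented:
#' R1: a -> b, b - c, a and c non-adjacent  =>  b -> c;
#' R2: a -> c -> b with a - b               =>  a -> b;
#' R3: a - b, a - c, a - d, c -> b, d -> b, c and d non-adjacent => a -> b.
#' Directed edges already present (v-structures, chronological background
#' knowledge) are never reversed.  An orientation whose addition would
#' create a directed cycle is skipped with a warning: on finite data the
#' learned constraint set can be inconsistent, and a partially oriented
#' graph is preferable to a failure.
#'
#' @param pdag a `mixed_graph` whose directed part is acyclic.
#' @param fixed ignored placeholder kept for explicitness: directed edges of
#'   `pdag` are always treated as fixed background knowledge.
#' @return the closed `mixed_graph`.
#' @export
meek_closure <- function(pdag, fixed = NULL) {
  amat <- pdag$amat
  p <- nrow(amat)
  orient <- function(i, j) {
    # orient i - j into i -> j unless it would close a directed cycle
    d <- amat * (1L - t(amat))
    if (has_directed_path(d, j, i)) {
      warning(sprintf("skipping orientation %s -> %s: would create a cycle",
                      rownames(amat)[i], rownames(amat)[j]))
      return(FALSE)
    }
    amat[j, i] <<- 0L
    TRUE
  }
  repeat {
    changed <- FALSE
    d <- amat * (1L - t(amat))
    u <- amat * t(amat)
    adj <- (amat + t(amat)) > 0L
    und <- which(u == 1L, arr.ind = TRUE)
    und <- und[und[, 1] < und[, 2], , drop = FALSE]
    for (r in seq_len(nrow(und))) {
      a <- und[r, 1]; b <- und[r, 2]
      if (amat[a, b] * amat[b, a] == 0L) next  # oriented earlier this sweep
      # R1: some k -> a with k not adjacent to b  =>  a -> b (and symmetric)
      if (any(d[, a] == 1L & !adj[, b])) { changed <- orient(a, b) || changed; next }
      if (any(d[, b] == 1L & !adj[, a])) { changed <- orient(b, a) || changed; next }
      # R2: directed path a -> k -> b of length 2  =>  a -> b
      if (any(d[a, ] == 1L & d[, b] == 1L)) { changed <- orient(a, b) || changed; next }
      if (any(d[b, ] == 1L & d[, a] == 1L)) { changed <- orient(b, a) || changed; next }
      # R3: a - c, a - k, c -> b, k -> b, c and k non-adjacent  =>  a -> b
      r3 <- function(x, y) {
        cand <- which(u[x, ] == 1L & d[, y] == 1L)
        if (length(cand) < 2L) return(FALSE)
        for (ci in seq_along(cand)) {
          for (ki in seq_len(ci - 1L)) {
            if (!adj[cand[ci], cand[ki]]) return(TRUE)
          }
        }
        FALSE
      }
      if (r3(a, b)) { changed <- orient(a, b) || changed; next }
      if (r3(b, a)) { changed <- orient(b, a) || changed; next }
    }
    if (!changed) break
  }
  new_mixed_graph(amat, pdag$vars)
}

#' v-structures of a graph
#'
#' Unshielded colliders: ordered triples (a, b, c) with a -> b <- c and a, c
#' non-adjacent.
#'
#' @param g a `mixed_graph`.
#' @return data.frame with columns `a`, `b`, `c` (a < c lexicographically).
#' @export
v_structures <- function(g) {
  d <- directed_part(g)
  adj <- adjacency_matrix(g)
  nm <- g$nodes
  out <- list()
  for (b in seq_along(nm)) {
    pa <- which(d[, b] == 1L)
    if (length(pa) < 2L) next
    for (i in seq_along(pa)) {
      for (j in seq_len(i - 1L)) {
        a <- pa[j]; c <- pa[i]
        if (!adj[a, c])
          out[[length(out) + 1L]] <- c(nm[min(a, c)], nm[b], nm[max(a, c)])
      }
    }
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), c = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], c = m[, 3], stringsAsFactors = FALSE)
}

#' CPDAG of a DAG
#'
#' Maps a DAG to the completed partially directed acyclic graph representing
#' its Markov equivalence class: same skeleton, v-structures kept directed,
#' all other compelled edges oriented by the Meek rules, reversible edges
#' undirected.
#'
#' @param dag a `mixed_graph` with only directed edges, acyclic.
#' @return a `mixed_graph` (the CPDAG).
#' @examples
#' chain <- mixed_graph(c("a", "b", "c"),
#'                      directed = rbind(c("a", "b"), c("b", "c")))
#' graph_edges(dag_to_cpdag(chain))  # fully undirected: a - b - c
#' @export
dag_to_cpdag <- function(dag) {
  if (sum(undirected_part(dag)) > 0L)
    stop("input must contain only directed edges")
  if (!is_acyclic(dag))
    stop("input graph is cyclic")
  vs <- v_structures(dag)
  # pattern: skeleton undirected + v-structure arrows
  amat <- adjacency_matrix(dag)
  dimnames(amat) <- dimnames(dag$amat)
  for (r in seq_len(nrow(vs))) {
    amat[vs$b[r], vs$a[r]] <- 0L
    amat[vs$b[r], vs$c[r]] <- 0L
  }
  meek_closure(new_mixed_graph(amat, dag$vars))
}

#' All DAGs of a Markov equivalence class by exhaustive orientation
#'
#' Enumerates every acyclic orientation of the undirected edges of a PDAG
#' that creates no new v-structure and destroys none, i.e. the consistent
#' DAG extensions.  Exponential in the number of undirected edges; intended
#' for small graphs (test oracles, local-vs-global IDA checks).
#'
#' @param cpdag a `mixed_graph`.
#' @return list of `mixed_graph` DAGs (possibly empty if the input admits
#'   no consistent extension).
#' @export
equivalence_class_dags <- function(cpdag) {
  u <- undirected_part(cpdag)
  und <- which(u == 1L, arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  k <- nrow(und)
  if (k > 20L) stop("too many undirected edges for exhaustive enumeration")
  # the CPDAG's directed colliders are exactly the class's v-structures
  target_vs <- vs_key(v_structures(cpdag))
  out <- list()
  for (mask in seq_len(2^k) - 1L) {
    amat <- cpdag$amat
    for (e in seq_len(k)) {
      i <- und[e, 1]; j <- und[e, 2]
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0L) amat[i, j] <- 0L else amat[j, i] <- 0L
    }
    g <- new_mixed_graph(amat, cpdag$vars)
    if (!is_acyclic(g)) next
    if (!identical(vs_key(v_structures(g)), target_vs)) next
    out[[length(out) + 1L]] <- g
  }
  out
}

# canonical string key of a v-structure table
vs_key <- function(vs) {
  if (!nrow(vs)) return(character())
  sort(paste(vs$a, vs$b, vs$c, sep = "|"))
}
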