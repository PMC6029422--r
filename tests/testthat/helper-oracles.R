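# Independent oracles for the graph machinery.  These deliberately avoid
# the package's Meek-closure path: acyclicity via DFS, colliders found by
# direct triple scanning, CPDAGs by brute-force orientation enumeration.

oracle_is_acyclic <- function(amat) {
  p <- nrow(amat)
  state <- integer(p)  # 0 unvisited, 1 on stack, 2 done
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return()
    state[v] <<- 1L
    for (w in which(amat[v, ] == 1L)) {
      if (state[w] == 1L) { ok <<- FALSE; return() }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
  }
  for (v in seq_len(p)) if (state[v] == 0L) visit(v)
  ok
}

oracle_colliders <- function(amat) {
  # sorted strings "a|b|c" for unshielded a -> b <- c, a < c
  p <- nrow(amat)
  adj <- (amat + t(amat)) > 0L
  out <- character()
  for (b in seq_len(p)) {
    pa <- which(amat[, b] == 1L & amat[b, ] == 0L)
    if (length(pa) < 2) next
    for (a in pa) for (c in pa) {
      if (a < c && !adj[a, c])
        out <- c(out, paste(a, b, c, sep = "|"))
    }
  }
  sort(out)
}

# brute-force CPDAG: enumerate every orientation of the skeleton, keep the
# acyclic ones with the DAG's colliders, mark an edge undirected iff its
# orientation differs across the kept DAGs
oracle_cpdag_amat <- function(dag_amat) {
  adj <- (dag_amat + t(dag_amat)) > 0L
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  k <- nrow(edges)
  stopifnot(k <= 14)
  target <- oracle_colliders(dag_amat)
  agg <- NULL
  for (mask in seq_len(2^k) - 1L) {
    m <- matrix(0L, nrow(dag_amat), ncol(dag_amat))
    for (e in seq_len(k)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0L) m[j, i] <- 1L else m[i, j] <- 1L
    }
    if (!oracle_is_acyclic(m)) next
    if (!identical(oracle_colliders(m), target)) next
    agg <- if (is.null(agg)) m else agg + m
  }
  stopifnot(!is.null(agg))
  out <- 1L * (agg > 0L)
  dimnames(out) <- dimnames(dag_amat)
  out
}

# random tiered weighted DAG directly (independent of generate_tiered_dag)
random_tiered_dag <- function(p_per_tier, n_tiers, edge_prob = 0.3,
                              outcome = FALSE) {
  covs <- as.vector(outer(seq_len(p_per_tier), seq_len(n_tiers),
                          function(i, v) sprintf("v%d_%d", v, i)))
  tier <- rep(seq_len(n_tiers), each = p_per_tier)
  nodes <- covs
  tiers <- stats::setNames(tier, covs)
  out_name <- NULL
  if (outcome) {
    out_name <- "yy"
    nodes <- c(covs, out_name)
    tiers[out_name] <- n_tiers + 1L
  }
  vars <- tiered_vars(nodes, tiers[nodes], outcome = out_name)
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  tr <- vars$tier[nodes]
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    if (tr[i] < tr[j] || (tr[i] == tr[j] && i < j)) {
      if (stats::runif(1) < edge_prob) amat[i, j] <- 1L
    }
  }
  mixed_graph(vars, directed = which_edges(amat, nodes))
}

which_edges <- function(amat, nodes) {
  idx <- which(amat == 1L, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(nodes[idx[, 1]], nodes[idx[, 2]])
}

# pattern of a DAG: skeleton undirected + oracle-found colliders directed
orient_v_structures_pattern <- function(dag) {
  adj <- 1L * ((dag$amat + t(dag$amat)) > 0L)
  dimnames(adj) <- list(dag$nodes, dag$nodes)
  for (key in oracle_colliders(dag$amat)) {
    t3 <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    adj[t3[2], t3[1]] <- 0L
    adj[t3[2], t3[3]] <- 0L
  }
  mixed_graph(dag$nodes,
              directed = which_edges(adj * (1L - t(adj)), dag$nodes),
              undirected = which_edges_upper(adj * t(adj), dag$nodes))
}

which_edges_upper <- function(amat, nodes) {
  idx <- which(amat == 1L & upper.tri(amat), arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(nodes[idx[, 1]], nodes[idx[, 2]])
}

edge_freqs_for_test <- function(g) {
  e <- graph_edges(g)
  mapply(function(a, b) g$freq[a, b], e$from, e$to, USE.NAMES = FALSE)
}

vs_key_for_test <- function(vs) {
  if (!nrow(vs)) return(character())
  sort(paste(vs$a, vs$b, vs$c, sep = "|"))
}

# translate index-based "a|b|c" collider keys to name-based ones
sapply_names <- function(keys, nodes) {
  sort(vapply(keys, function(k) {
    t3 <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    paste(nodes[t3[1]], nodes[t3[2]], nodes[t3[3]], sep = "|")
  }, character(1), USE.NAMES = FALSE))
}

# simple topological order via repeated source removal
topo_order_for_test <- function(amat) {
  p <- nrow(amat); out <- integer(0); left <- seq_len(p)
  m <- amat
  while (length(left)) {
    src <- left[colSums(m[left, left, drop = FALSE]) == 0L]
    stopifnot(length(src) > 0)
    out <- c(out, src)
    left <- setdiff(left, src)
  }
  out
}
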