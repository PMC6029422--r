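#' Structural Hamming distance
#'
#' `variant = "paper"` counts one point per adjacency present in one graph
#' and absent in the other (extra or missing connection), ignoring
#' orientation.  `variant = "full"` (Tsamardinos) additionally counts one
#' point per shared adjacency whose mark (direction or undirectedness)
#' differs.
#'
#' @param estimated,truth `mixed_graph`s over the same node set.
#' @param variant `"paper"` or `"full"`.
#' @return non-negative integer.
#' @export
shd <- function(estimated, truth, variant = c("paper", "full")) {
  variant <- match.arg(variant)
  check_same_nodes(estimated, truth)
  truth <- align_nodes(truth, estimated)
  a1 <- adjacency_matrix(estimated)
  a2 <- adjacency_matrix(truth)
  ut <- upper.tri(a1)
  d <- sum(a1[ut] != a2[ut])
  if (variant == "full") {
    both <- a1 == 1L & a2 == 1L
    mism <- (estimated$amat != truth$amat) | (t(estimated$amat) != t(truth$amat))
    d <- d + sum(both[ut] & mism[ut])
  }
  as.integer(d)
}

check_same_nodes <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes))
    stop("graphs are defined over different node sets")
}

align_nodes <- function(g, ref) {
  if (identical(g$nodes, ref$nodes)) g else permute_graph(g, ref$nodes)
}

#' Edge classification by chronology
#'
#' Counts directed and undirected edges, and the number of
#' non-chronologically ordered edges: directed edges pointing from a
#' strictly later tier to a strictly earlier one, plus undirected edges
#' between two distinct tiers (which chronological background knowledge
#' should have pre-directed).
#'
#' @param g a `mixed_graph`.
#' @param tiers a [tiered_vars] object (defaults to `g$vars`).
#' @return named integer vector `n_directed`, `n_undirected`,
#'   `n_nonchronological`.
#' @export
classify_edges <- function(g, tiers = g$vars) {
  if (is.null(tiers)) stop("no tier information available")
  tr <- tiers$tier[g$nodes]
  d <- directed_part(g)
  u <- undirected_part(g)
  de <- which(d == 1L, arr.ind = TRUE)
  ue <- which(u == 1L, arr.ind = TRUE)
  ue <- ue[ue[, 1] < ue[, 2], , drop = FALSE]
  n_dir <- nrow(de)
  n_und <- nrow(ue)
  bad_dir <- if (n_dir) sum(tr[de[, 1]] > tr[de[, 2]]) else 0L
  bad_und <- if (n_und) sum(tr[ue[, 1]] != tr[ue[, 2]]) else 0L
  c(n_directed = as.integer(n_dir),
    n_undirected = as.integer(n_und),
    n_nonchronological = as.integer(bad_dir + bad_und))
}

#' Skeleton-recovery confusion metrics
#'
#' Sensitivity and specificity over unordered node pairs (presence/absence
#' of an adjacency in the estimated graph against the truth), the
#' structural Hamming distance, and — when tier information is available —
#' the chronological edge classification of the estimated graph.
#'
#' @param estimated,truth `mixed_graph`s over the same node set.
#' @param tiers optional [tiered_vars]; defaults to those stored in
#'   `estimated`.
#' @return object of class `structure_metrics`: a list with `sensitivity`,
#'   `specificity`, `shd`, `tp`, `fp`, `tn`, `fn` and (if tiered)
#'   `n_directed`, `n_undirected`, `n_nonchronological`.
#' @export
structure_metrics <- function(estimated, truth, tiers = estimated$vars) {
  check_same_nodes(estimated, truth)
  truth <- align_nodes(truth, estimated)
  a1 <- adjacency_matrix(estimated)
  a2 <- adjacency_matrix(truth)
  ut <- upper.tri(a1)
  tp <- sum(a1[ut] & a2[ut]); fn <- sum(!a1[ut] & a2[ut])
  fp <- sum(a1[ut] & !a2[ut]); tn <- sum(!a1[ut] & !a2[ut])
  out <- list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    shd = shd(estimated, truth, "paper"),
    tp = tp, fp = fp, tn = tn, fn = fn)
  if (!is.null(tiers)) out <- c(out, as.list(classify_edges(estimated, tiers)))
  structure(out, class = "structure_metrics")
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("Se = %.3f, Sp = %.3f, SHD = %d\n",
              x$sensitivity, x$specificity, x$shd))
  if (!is.null(x$n_nonchronological))
    cat(sprintf("edges: %d directed, %d undirected, %d non-chronological\n",
                x$n_directed, x$n_undirected, x$n_nonchronological))
  invisible(x)
}

#' Aggregate CPDAGs from resampling runs into a summary graph
#'
#' An adjacency is retained when present in at least `min_freq` of the
#' input graphs; the retained edge carries its frequency (downstream edge
#' thickness).  The summary edge is drawn directed when one direction's
#' count strictly exceeds the opposite direction plus undirected
#' occurrences combined, otherwise undirected.
#'
#' @param graphs non-empty list of `mixed_graph`s over the same node set.
#' @param min_freq retention threshold in (0, 1].
#' @return a `mixed_graph` with an extra element `freq`: symmetric matrix
#'   of adjacency frequencies (0 for dropped pairs).
#' @export
aggregate_cpdags <- function(graphs, min_freq = 0.20) {
  if (!length(graphs)) stop("empty list of graphs")
  stopifnot(min_freq > 0, min_freq <= 1)
  ref <- graphs[[1]]
  sum_dir <- matrix(0, length(ref$nodes), length(ref$nodes),
                    dimnames = list(ref$nodes, ref$nodes))
  n_und <- sum_dir
  for (g in graphs) {
    check_same_nodes(g, ref)
    g <- align_nodes(g, ref)
    sum_dir <- sum_dir + directed_part(g)
    n_und <- n_und + undirected_part(g)
  }
  B <- length(graphs)
  freq <- (sum_dir + t(sum_dir) + n_und) / B
  keep <- freq >= min_freq
  amat <- matrix(0L, nrow(keep), ncol(keep), dimnames = dimnames(keep))
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (sum_dir[i, j] > sum_dir[j, i] + n_und[i, j]) {
      amat[i, j] <- 1L
    } else if (sum_dir[j, i] > sum_dir[i, j] + n_und[i, j]) {
      amat[j, i] <- 1L
    } else {
      amat[i, j] <- amat[j, i] <- 1L
    }
  }
  out <- new_mixed_graph(amat, ref$vars)
  out$freq <- freq * keep
  out
}
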