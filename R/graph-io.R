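#' Write a mixed graph in DOT format
#'
#' Undirected edges are emitted with `dir=none`; when the graph carries
#' aggregation frequencies (see [aggregate_cpdags]) each edge gets a
#' `freq` attribute and a `penwidth` proportional to it.
#'
#' @param g a `mixed_graph`.
#' @param path output file path.
#' @param name graph name in the DOT header.
#' @export
write_dot <- function(g, path, name = "cpdag") {
  e <- graph_edges(g)
  fr <- edge_freqs(g, e)
  lines <- c(sprintf("digraph %s {", name),
             paste0("  \"", g$nodes, "\";"))
  for (r in seq_len(nrow(e))) {
    attrs <- if (e$mark[r] == "undirected") "dir=none" else character()
    if (!is.na(fr[r]))
      attrs <- c(attrs, sprintf("freq=%.4f", fr[r]),
                 sprintf("penwidth=%.2f", 0.5 + 4 * fr[r]))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", e$from[r], e$to[r],
                              if (length(attrs)) paste0(" [", paste(attrs, collapse = ", "), "]") else ""))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Write a mixed graph in GraphML format
#'
#' Edges carry a `mark` attribute (`directed`/`undirected`) and, when
#' available, a `freq` attribute in \[0, 1\].
#'
#' @inheritParams write_dot
#' @export
write_graphml <- function(g, path) {
  e <- graph_edges(g)
  fr <- edge_freqs(g, e)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE), fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="mark" for="edge" attr.name="mark" attr.type="string"/>',
    '  <key id="freq" for="edge" attr.name="freq" attr.type="double"/>',
    '  <graph id="G" edgedefault="directed">',
    sprintf('    <node id="%s"/>', esc(g$nodes)))
  for (r in seq_len(nrow(e))) {
    lines <- c(lines,
      sprintf('    <edge source="%s" target="%s">', esc(e$from[r]), esc(e$to[r])),
      sprintf('      <data key="mark">%s</data>', e$mark[r]),
      if (!is.na(fr[r])) sprintf('      <data key="freq">%.6f</data>', fr[r]),
      '    </edge>')
  }
  writeLines(c(lines, "  </graph>", "</graphml>"), path)
  invisible(path)
}

#' Write a mixed graph as an edge-list CSV
#'
#' Columns `from,to,mark,freq` (`freq` empty when the graph carries no
#' aggregation frequencies).
#'
#' @inheritParams write_dot
#' @export
write_edges_csv <- function(g, path) {
  e <- graph_edges(g)
  e$freq <- edge_freqs(g, e)
  utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

edge_freqs <- function(g, e = graph_edges(g)) {
  if (is.null(g$freq)) return(rep(NA_real_, nrow(e)))
  mapply(function(a, b) g$freq[a, b], e$from, e$to, USE.NAMES = FALSE)
}

#' Read a mixed graph from an edge-list CSV
#'
#' Inverse of [write_edges_csv()].  Nodes absent from any edge must be
#' supplied through `nodes`.
#'
#' @param path CSV with columns `from,to,mark` (optional `freq`).
#' @param nodes optional full node set (character or [tiered_vars]).
#' @export
read_edges_csv <- function(path, nodes = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  vars <- NULL
  if (inherits(nodes, "tiered_vars")) { vars <- nodes; nodes <- nodes$names }
  if (is.null(nodes)) nodes <- sort(unique(c(e$from, e$to)))
  g <- mixed_graph(if (is.null(vars)) nodes else vars,
                   directed = as.matrix(e[e$mark == "directed", c("from", "to")]),
                   undirected = as.matrix(e[e$mark == "undirected", c("from", "to")]))
  g
}
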