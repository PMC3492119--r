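#' Extant or ancestral interaction graphs
#'
#' A thin container for an interaction network: a character node set and an
#' edge matrix (unordered pairs if undirected, ordered if directed). Used for
#' extant protein/regulatory networks and for inferred ancestral networks
#' (whose "nodes" are homology-group ids).
#'
#' @param nodes character vector of node ids.
#' @param edges two-column character matrix (or NULL). For undirected graphs
#'   each pair is stored in canonical sorted order.
#' @param directed logical.
#' @param selfloops logical; whether self-loops are permitted.
#' @return object of class \code{interaction_graph}.
#' @export
interaction_graph <- function(nodes = character(0), edges = NULL,
                              directed = FALSE, selfloops = FALSE) {
  nodes <- as.character(nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    mode(edges) <- "character"
  }
  nodes <- unique(c(nodes, as.vector(edges)))
  if (!directed && nrow(edges)) {
    sw <- edges[, 1] > edges[, 2]
    edges[sw, ] <- edges[sw, 2:1]
  }
  if (nrow(edges)) {
    if (!selfloops && any(edges[, 1] == edges[, 2]))
      stop("self-loop in a graph with selfloops = FALSE")
    key <- paste(edges[, 1], edges[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edge(s): ",
                                 paste(utils::head(sub("\r", " -- ", key[duplicated(key)]), 3),
                                       collapse = ", "))
  }
  dimnames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = directed,
                 selfloops = selfloops),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(if (x$directed) "Directed" else "Undirected", "interaction graph:",
      length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (x$selfloops) "(self-loops allowed)" else "", "\n")
  invisible(x)
}

#' Edge membership predicate (the interaction encoding)
#' @param graph an [interaction_graph()].
#' @param u,v node ids (vectorized).
#' @return logical: is \code{(u,v)} (ordered if directed) an edge?
#' @export
has_edge <- function(graph, u, v) {
  u <- as.character(u); v <- as.character(v)
  if (!graph$directed) { sw <- u > v; tmp <- u[sw]; u[sw] <- v[sw]; v[sw] <- tmp }
  paste(u, v, sep = "\r") %in% paste(graph$edges[, 1], graph$edges[, 2], sep = "\r")
}

#' Node degrees
#' @param graph an [interaction_graph()].
#' @param mode "total", "out" or "in" (out/in require a directed graph; a
#'   self-loop contributes 1 to out- and 1 to in-degree, 2 to total).
#' @return named integer vector over \code{graph$nodes}.
#' @export
graph_degree <- function(graph, mode = c("total", "out", "in")) {
  mode <- match.arg(mode)
  tab <- function(x) { t <- table(factor(x, levels = graph$nodes)); as.integer(t) }
  d <- switch(mode,
    total = tab(as.vector(graph$edges)),
    out = tab(graph$edges[, 1]),
    `in` = tab(graph$edges[, 2]))
  stats::setNames(d, graph$nodes)
}

#' @export
as.matrix.interaction_graph <- function(x, ...) {
  n <- length(x$nodes)
  m <- matrix(0L, n, n, dimnames = list(x$nodes, x$nodes))
  if (nrow(x$edges)) {
    i <- match(x$edges[, 1], x$nodes); j <- match(x$edges[, 2], x$nodes)
    m[cbind(i, j)] <- 1L
    if (!x$directed) m[cbind(j, i)] <- 1L
  }
  m
}

## equality of edge sets (and node sets), ignoring order
graphs_equal <- function(a, b, nodes = FALSE) {
  ek <- function(g) sort(paste(g$edges[, 1], g$edges[, 2], sep = "\r"))
  identical(ek(a), ek(b)) && (!nodes || setequal(a$nodes, b$nodes)) &&
    a$directed == b$directed
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges[, 1], to = graph$edges[, 2],
               stringsAsFactors = FALSE),
    directed = graph$directed,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}
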