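#' Minimum-cost flip sets on a duplication forest
#'
#' Computes, by dynamic programming over pairs of forest nodes, the minimum
#' total cost of interaction flip events needed for the forest to construct
#' a given extant graph, excluding 1- and 2-blocking loops (longer blocking
#' loops may remain; see [reconstruct_history()] for the fully valid greedy
#' solution). An interaction created while a pair's flip parity is even costs
#' \code{c_add}; removing one (odd parity) costs \code{c_loss}. With
#' \code{alpha > 0}, a flip between nodes whose existence intervals (from
#' branch lengths) are disjoint additionally pays \code{alpha} times the gap
#' between the intervals; \code{alpha = Inf} makes branch lengths hard
#' constraints.
#'
#' @param forest a [duplication_forest()] whose Present leaves include every
#'   node of \code{graph}.
#' @param graph an [interaction_graph()]; the directed recurrence is used
#'   when \code{graph$directed}.
#' @param c_add,c_loss nonnegative flip costs (defaults 1).
#' @param alpha nonnegative branch-length penalty factor (default 0;
#'   \code{Inf} allowed). Requires a forest built with branch lengths when
#'   positive.
#' @param forbidden optional two-column character matrix of node pairs whose
#'   flip options are disallowed. For a directed graph rows are ordered
#'   (forbid a-to-b); for an undirected graph both orders are forbidden.
#' @return An object of class \code{dp_tables}: a list with \code{cost} (the
#'   optimal total over the forest), \code{A} (the pair table, an
#'   \code{n x n x states} array with node-label dimnames; state 1 is even
#'   parity), \code{flips} (the backtracked optimal flip set, a data frame
#'   with columns \code{a}, \code{b}, \code{orientation}, \code{event}
#'   (\code{"add"}/\code{"loss"}), \code{cost}), and bookkeeping fields.
#' @examples
#' f <- read_forest(text = "((a,b)r);\nc;")
#' g <- interaction_graph(edges = rbind(c("a", "c"), c("b", "c")))
#' tab <- min_flip_cost(f, g)
#' tab$cost          # 1: a single flip at (r, c) explains both interactions
#' backtrack_flips(tab)
#' @export
min_flip_cost <- function(forest, graph, c_add = 1, c_loss = 1, alpha = 0,
                          forbidden = NULL) {
  if (graph$selfloops || (nrow(graph$edges) && any(graph$edges[, 1] == graph$edges[, 2])))
    stop("graph allows self-loops; use min_flip_cost_selfloops()")
  dp_run(forest, graph, c_add, c_loss, alpha, forbidden, selfloops = FALSE)
}

#' @rdname min_flip_cost
#' @details \code{min_flip_cost_directed} is the explicit entry point for the
#'   directed recurrence (four parity states per node pair: each direction
#'   may independently be flipped); \code{min_flip_cost} dispatches to it
#'   automatically for directed graphs.
#' @export
min_flip_cost_directed <- function(forest, graph, c_add = 1, c_loss = 1,
                                   alpha = 0, forbidden = NULL) {
  if (!graph$directed) stop("graph is undirected")
  min_flip_cost(forest, graph, c_add, c_loss, alpha, forbidden)
}

#' @rdname min_flip_cost
#' @details \code{min_flip_cost_selfloops} handles undirected graphs with
#'   self-loops (homodimers): a flip placed at \code{(u, u)} toggles all
#'   interactions, self-loops included, among the descendants of \code{u}.
#' @export
min_flip_cost_selfloops <- function(forest, graph, c_add = 1, c_loss = 1,
                                    alpha = 0, forbidden = NULL) {
  if (graph$directed) stop("self-loop variant is undirected")
  dp_run(forest, graph, c_add, c_loss, alpha, forbidden, selfloops = TRUE)
}

## shared driver
dp_run <- function(forest, graph, c_add, c_loss, alpha, forbidden, selfloops) {
  stopifnot(inherits(forest, "duplication_forest"),
            inherits(graph, "interaction_graph"),
            c_add >= 0, c_loss >= 0, alpha >= 0)
  n <- forest$n
  pres <- forest$label[forest$present %in% TRUE]
  miss <- setdiff(graph$nodes, pres)
  if (length(miss))
    stop("graph node(s) not Present leaves of the forest: ",
         paste(utils::head(miss, 5), collapse = ", "))

  adj <- matrix(0L, n, n)
  if (nrow(graph$edges)) {
    i <- forest_index(forest, graph$edges[, 1])
    j <- forest_index(forest, graph$edges[, 2])
    adj[cbind(i, j)] <- 1L
    if (!graph$directed) adj[cbind(j, i)] <- 1L
  }
  forbid <- matrix(FALSE, n, n)
  if (!is.null(forbidden) && NROW(forbidden) > 0) {
    forbidden <- as.matrix(forbidden)
    fi <- forest_index(forest, forbidden[, 1])
    fj <- forest_index(forest, forbidden[, 2])
    forbid[cbind(fi, fj)] <- TRUE
    if (!graph$directed) forbid[cbind(fj, fi)] <- TRUE
  }
  pen <- penalty_matrix(forest, alpha)
  present_vec <- ifelse(is.na(forest$present), TRUE, forest$present)

  res <- dp_flips_cpp(forest$left - 1L, forest$right - 1L, present_vec,
                      forest$post - 1L, forest$roots - 1L, adj,
                      graph$directed, selfloops, c_add, c_loss, pen, forbid,
                      forest$ein, forest$eout, forest$tree, backtrack = TRUE)
  dimnames(res$A) <- list(forest$label, forest$label, NULL)
  flips <- data.frame(
    a = forest$label[res$flip_a], b = forest$label[res$flip_b],
    orientation = rep(if (graph$directed) "->" else "--",
                      length(res$flip_a)),
    event = ifelse(res$flip_parity == 0, "add", "loss"),
    cost = res$flip_cost, stringsAsFactors = FALSE)
  structure(list(cost = res$total, A = res$A, S_roots = res$S_roots,
                 flips = flips, forest = forest, graph = graph,
                 c_add = c_add, c_loss = c_loss, alpha = alpha,
                 forbidden = forbidden, directed = graph$directed,
                 selfloops = selfloops),
            class = "dp_tables")
}

#' @export
print.dp_tables <- function(x, ...) {
  cat("Flip-parsimony DP:", if (x$directed) "directed," else "undirected,",
      "cost", format(x$cost), "with", nrow(x$flips), "flips",
      "(c_add =", x$c_add, ", c_loss =", x$c_loss, ", alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Recover the optimal flip set from DP tables
#'
#' Ties in the recurrence are broken deterministically (no-flip before flip,
#' splitting the lower-indexed node first), so the returned set is
#' reproducible.
#'
#' @param tables result of [min_flip_cost()] and variants.
#' @return data frame of flips (see [min_flip_cost()]).
#' @export
backtrack_flips <- function(tables) {
  stopifnot(inherits(tables, "dp_tables"))
  tables$flips
}

#' History implied by DP tables
#' @param tables a \code{dp_tables} object.
#' @return a [network_history()] carrying the backtracked flips.
#' @export
as_history <- function(tables) {
  network_history(tables$forest, tables$flips[c("a", "b", "orientation")],
                  directed = tables$directed, selfloops = tables$selfloops)
}
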