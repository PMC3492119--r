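#' Fit a valid parsimonious network history
#'
#' The central fitting function: given a duplication forest and an extant
#' interaction graph, finds a near-minimum-cost set of interaction flip
#' events whose history is \emph{valid} (admits a consistent timing, i.e.
#' contains no blocking loop of any length).
#'
#' The first dynamic-programming pass excludes 1- and 2-blocking loops by
#' construction and is a lower bound on the optimal valid cost. If its flip
#' set still contains a longer blocking loop, one flip of the loop is chosen
#' uniformly at random, that node pair is forbidden, and the DP is rerun;
#' this repeats until the solution is valid (it must terminate: the forbidden
#' set grows strictly, and an all-leaf placement is always valid).
#'
#' @inheritParams min_flip_cost
#' @param selfloops use the self-loop recurrence (undirected graphs with
#'   homodimers).
#' @param seed integer seed driving the random choice of which loop flip to
#'   forbid (the only randomness); same seed, same output.
#' @return An object of class \code{flip_reconstruction} with components
#'   \code{flips} (data frame of events), \code{cost}, \code{lower_bound}
#'   (first-pass DP cost), \code{iterations} (loop-breaking reruns),
#'   \code{forbidden} (pairs forbidden along the way), \code{history}
#'   (a valid [network_history()]), \code{tables} (final DP tables), and the
#'   call parameters. Methods: \code{print}, \code{summary}, \code{fitted}
#'   (the constructed graph), \code{plot}.
#' @examples
#' f <- read_forest(text = "((a,b)r);\nc;")
#' g <- interaction_graph(edges = rbind(c("a", "c"), c("b", "c")))
#' fit <- reconstruct_history(f, g, seed = 1)
#' fit$cost == fit$lower_bound   # no loop breaking needed here
#' @export
reconstruct_history <- function(forest, graph, c_add = 1, c_loss = 1,
                                alpha = 0, selfloops = FALSE, seed = 1L) {
  runner <- if (selfloops) min_flip_cost_selfloops else min_flip_cost
  tab <- runner(forest, graph, c_add, c_loss, alpha)
  lower <- tab$cost
  forbidden <- NULL
  iter <- 0L
  max_iter <- forest$n^2 + 1L
  ## private RNG stream so callers' simulations are unaffected
  rng <- with_rng_state(NULL, { set.seed(seed); NULL })$state
  repeat {
    h <- as_history(tab)
    loop <- find_blocking_loop(h)
    if (is.null(loop)) break
    if (iter >= max_iter) stop("loop breaking failed to terminate")
    iter <- iter + 1L
    cand <- unique(loop$flip)
    drawn <- with_rng_state(rng, sample.int(length(cand), 1L))
    rng <- drawn$state
    pick <- cand[drawn$value]
    row <- tab$flips[pick, ]
    forbidden <- rbind(forbidden, c(row$a, row$b))
    tab <- runner(forest, graph, c_add, c_loss, alpha, forbidden = forbidden)
  }
  structure(list(flips = tab$flips, cost = tab$cost, lower_bound = lower,
                 iterations = iter, forbidden = forbidden, history = h,
                 tables = tab, forest = forest, graph = graph,
                 c_add = c_add, c_loss = c_loss, alpha = alpha,
                 selfloops = selfloops, seed = seed),
            class = "flip_reconstruction")
}

## Evaluate expr under a saved RNG state (NULL = current), restoring the
## caller's stream afterwards; returns list(value, state).
with_rng_state <- function(state, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  if (!is.null(state)) assign(".Random.seed", state, envir = genv)
  value <- expr
  new_state <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  if (had) assign(".Random.seed", old, envir = genv)
  else if (!is.null(new_state))
    rm(list = ".Random.seed", envir = genv)
  list(value = value, state = new_state)
}

#' @export
print.flip_reconstruction <- function(x, ...) {
  cat("Parsimonious network history\n")
  cat("  events:", nrow(x$flips),
      sprintf("(%d gains, %d losses)", sum(x$flips$event == "add"),
              sum(x$flips$event == "loss")), "\n")
  cat("  cost:", format(x$cost), " lower bound:", format(x$lower_bound),
      sprintf(" (excess %.2f%%)",
              if (x$lower_bound > 0) 100 * (x$cost - x$lower_bound) / x$lower_bound else 0),
      "\n")
  cat("  loop-breaking iterations:", x$iterations, "\n")
  invisible(x)
}

#' @export
summary.flip_reconstruction <- function(object, ...) {
  out <- list(
    n_flips = nrow(object$flips),
    n_add = sum(object$flips$event == "add"),
    n_loss = sum(object$flips$event == "loss"),
    cost = object$cost, lower_bound = object$lower_bound,
    relative_excess = if (object$lower_bound > 0)
      (object$cost - object$lower_bound) / object$lower_bound else 0,
    iterations = object$iterations,
    valid = is_valid_history(object$history),
    n_forest_nodes = object$forest$n,
    n_graph_nodes = length(object$graph$nodes),
    n_graph_edges = nrow(object$graph$edges))
  class(out) <- "summary.flip_reconstruction"
  out
}

#' @export
print.summary.flip_reconstruction <- function(x, ...) {
  cat("Network history fit\n")
  cat(sprintf("  graph: %d nodes, %d edges; forest: %d nodes\n",
              x$n_graph_nodes, x$n_graph_edges, x$n_forest_nodes))
  cat(sprintf("  events: %d (%d gains, %d losses); cost %s\n",
              x$n_flips, x$n_add, x$n_loss, format(x$cost)))
  cat(sprintf("  lower bound %s; relative excess %.2f%%; %d loop-breaking iteration(s); valid: %s\n",
              format(x$lower_bound), 100 * x$relative_excess, x$iterations,
              x$valid))
  invisible(x)
}

#' @export
fitted.flip_reconstruction <- function(object, ...) {
  constructs(object$history)
}

#' @export
plot.flip_reconstruction <- function(x, ...) {
  f <- x$forest
  edges <- cbind(f$label[f$parent[!is.na(f$parent)]],
                 f$label[which(!is.na(f$parent))])
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = edges[, 1], to = edges[, 2], type = "tree"),
          if (nrow(x$flips))
            data.frame(from = x$flips$a, to = x$flips$b, type = "flip")),
    directed = FALSE,
    vertices = data.frame(name = f$label))
  cols <- ifelse(igraph::E(g)$type == "tree", "grey30", "firebrick")
  lty <- ifelse(igraph::E(g)$type == "tree", 1, 2)
  igraph::plot.igraph(g, edge.color = cols, edge.lty = lty,
                      vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(x)
}
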