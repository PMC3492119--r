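#' Network histories: duplication forest + interaction flip events
#'
#' A network history augments a duplication forest with \emph{flip edges}:
#' non-tree edges between forest nodes, each marking one interaction gain or
#' loss among the descendants of its endpoints. An extant pair of genes
#' \code{(x, y)} interacts exactly when an odd number of flips join the root
#' path of \code{x} to the root path of \code{y} (per direction, for directed
#' histories).
#'
#' @param forest a [duplication_forest()].
#' @param flips data frame with character columns \code{a}, \code{b} and
#'   optionally \code{orientation} (\code{"--"} undirected, \code{"->"} for
#'   a-to-b, \code{"<-"} for b-to-a) and numeric \code{t} (event time).
#' @param directed,selfloops history variant flags. A flip with \code{a == b}
#'   (a self-flip, toggling all interactions among the descendants of
#'   \code{a}, self-loops included) is only permitted when
#'   \code{selfloops = TRUE}.
#' @return object of class \code{network_history}.
#' @export
network_history <- function(forest, flips = NULL, directed = FALSE,
                            selfloops = FALSE) {
  stopifnot(inherits(forest, "duplication_forest"))
  if (is.null(flips) || NROW(flips) == 0L) {
    flips <- data.frame(a = character(0), b = character(0),
                        orientation = character(0), t = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    flips <- as.data.frame(flips, stringsAsFactors = FALSE)
    if (!all(c("a", "b") %in% names(flips))) stop("flips need columns a, b")
    flips$a <- as.character(flips$a); flips$b <- as.character(flips$b)
    if (is.null(flips$orientation))
      flips$orientation <- if (directed) "->" else "--"
    if (!all(flips$orientation %in% c("--", "->", "<-")))
      stop("orientation must be one of --, ->, <-")
    if (!directed && any(flips$orientation != "--"))
      stop("oriented flips in an undirected history")
    if (is.null(flips$t)) flips$t <- NA_real_
    forest_index(forest, flips$a); forest_index(forest, flips$b)
    if (!selfloops && any(flips$a == flips$b))
      stop("self-flip in a history with selfloops = FALSE")
  }
  structure(list(forest = forest, flips = flips, directed = directed,
                 selfloops = selfloops),
            class = "network_history")
}

#' @export
print.network_history <- function(x, ...) {
  cat("Network history:", length(x$forest$roots), "tree(s),",
      x$forest$n, "forest nodes,", nrow(x$flips), "flip events",
      if (x$directed) "(directed)" else "(undirected)", "\n")
  invisible(x)
}

## n x k logical: L[u, j] TRUE iff forest node u lies on the root path of the
## j-th listed leaf (ancestor-or-self).
root_path_membership <- function(forest, leaf_idx) {
  outer(forest$ein, forest$ein[leaf_idx], "<=") &
    outer(forest$eout, forest$eout[leaf_idx], ">=") &
    outer(forest$tree, forest$tree[leaf_idx], "==")
}

#' Extant graph constructed by a network history
#'
#' Applies the parity rule: the nodes of the constructed graph are the
#' Present leaves of the forest; a pair interacts iff an odd number of flips
#' have one endpoint on each root path (direction-wise for directed
#' histories; for the pair \code{(x, x)}, self-flips at ancestors of \code{x}
#' toggle its self-loop).
#'
#' @param history a [network_history()].
#' @return an [interaction_graph()].
#' @export
constructs <- function(history) {
  forest <- history$forest
  leaf_idx <- which(forest$present %in% TRUE)
  k <- length(leaf_idx)
  L <- root_path_membership(forest, leaf_idx)
  M <- matrix(0L, k, k)
  if (nrow(history$flips)) {
    ai <- forest_index(forest, history$flips$a)
    bi <- forest_index(forest, history$flips$b)
    for (f in seq_along(ai)) {
      A <- L[ai[f], ]; B <- L[bi[f], ]
      tog <- switch(history$flips$orientation[f],
        "--" = outer(A, B) | outer(B, A),
        "->" = outer(A, B),
        "<-" = outer(B, A))
      M <- M + tog
    }
  }
  M <- M %% 2L
  labs <- forest$label[leaf_idx]
  if (!history$selfloops && any(diag(M) == 1L))
    stop("history implies self-loops (flip joining a node to its own root path) ",
         "but selfloops = FALSE")
  if (history$directed) {
    w <- which(M == 1L, arr.ind = TRUE)
    if (!history$selfloops) w <- w[w[, 1] != w[, 2], , drop = FALSE]
  } else {
    Mu <- M; Mu[lower.tri(Mu)] <- 0L       # symmetric: keep upper + diagonal
    w <- which(Mu == 1L, arr.ind = TRUE)
    if (!history$selfloops) w <- w[w[, 1] != w[, 2], , drop = FALSE]
  }
  interaction_graph(nodes = labs,
                    edges = cbind(labs[w[, 1]], labs[w[, 2]]),
                    directed = history$directed, selfloops = history$selfloops)
}

## Oriented-flip digraph: vertex = (flip, role assignment (u,v)); arc i -> j
## iff u_j is a proper ancestor of v_i. A blocking loop is exactly a directed
## cycle here (tree edges are implicitly traversed root-ward->leaf-ward along
## the ancestor relation; flips are traversable in either role).
flip_digraph <- function(history) {
  forest <- history$forest
  fl <- history$flips
  if (!nrow(fl)) return(NULL)
  ai <- forest_index(forest, fl$a); bi <- forest_index(forest, fl$b)
  ## deterministic vertex order: sort flips by endpoint labels
  ord <- order(pmin(fl$a, fl$b), pmax(fl$a, fl$b))
  U <- V <- integer(0); flip_of <- integer(0)
  for (f in ord) {
    U <- c(U, ai[f], bi[f]); V <- c(V, bi[f], ai[f]); flip_of <- c(flip_of, f, f)
    if (ai[f] == bi[f]) { U <- U[-length(U)]; V <- V[-length(V)]
                          flip_of <- flip_of[-length(flip_of)] }
  }
  adj <- outer(forest$ein[V], forest$ein[U], ">") &
         outer(forest$eout[V], forest$eout[U], "<=") &
         outer(forest$tree[V], forest$tree[U], "==")
  list(U = U, V = V, flip_of = flip_of, adj = adj)
}

#' Find a blocking loop in a network history
#'
#' A k-blocking loop is a cyclic sequence of flips \code{\{u_i, v_i\}} where
#' each \code{u_(i+1 mod k)} is a \emph{proper} ancestor of \code{v_i}. Such
#' event sets admit no consistent timing, so histories containing one are
#' invalid.
#'
#' @param history a [network_history()].
#' @return \code{NULL} if none, else a data frame (one row per loop
#'   position) with columns \code{u}, \code{v} (endpoint roles) and
#'   \code{flip} (row index into \code{history$flips}).
#' @export
find_blocking_loop <- function(history) {
  fg <- flip_digraph(history)
  if (is.null(fg)) return(NULL)
  forest <- history$forest
  nv <- length(fg$U)
  self <- which(diag(fg$adj))
  if (length(self)) {            # 1-blocking loop: u proper ancestor of v
    i <- self[1]
    return(data.frame(u = forest$label[fg$U[i]], v = forest$label[fg$V[i]],
                      flip = fg$flip_of[i], stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_adjacency_matrix(fg$adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize >= 2L)
  if (!length(big)) return(NULL)
  ## deterministic: the component holding the smallest vertex id
  in_big <- comp$membership %in% big
  cid <- comp$membership[which(in_big)[1]]
  members <- comp$membership == cid
  ## walk smallest-successor-first inside the SCC until a vertex repeats
  walk <- integer(0)
  cur <- which(members)[1]
  repeat {
    if (cur %in% walk) { walk <- walk[seq(match(cur, walk), length(walk))]; break }
    walk <- c(walk, cur)
    succ <- which(fg$adj[cur, ] & members)
    cur <- succ[1]               # nonempty: every SCC vertex has an out-arc
  }
  data.frame(u = forest$label[fg$U[walk]], v = forest$label[fg$V[walk]],
             flip = fg$flip_of[walk], stringsAsFactors = FALSE)
}

#' Validity of a network history
#'
#' A history is valid iff its events admit a consistent timing, which holds
#' iff it contains no blocking loop.
#'
#' @param history a [network_history()].
#' @return logical.
#' @export
is_valid_history <- function(history) {
  is.null(find_blocking_loop(history))
}

#' Assign consistent event times to a network history
#'
#' The constructive counterpart of validity: a modified depth-first search
#' over tree edges gives every node integer creation/duplication times and
#' every flip an event time satisfying the coexistence conditions
#' (\code{tc(u) < td(u)}, children created at their parent's duplication
#' time, and \code{tc <= t(flip) < td} at both flip endpoints). A node whose
#' flip partner has no creation time yet is deferred and retried in rounds;
#' if a round completes no node, the deferred set certifies a blocking loop
#' and the history is invalid.
#'
#' @param history a [network_history()].
#' @return a list with \code{success}; on success integer times \code{tc},
#'   \code{td} (named by node label; \code{td = Inf} at leaves) and
#'   \code{tflip} (per flip row); on failure \code{stalled}, the labels of
#'   the deferred set.
#' @export
assign_times <- function(history) {
  forest <- history$forest
  n <- forest$n
  fl <- history$flips
  ai <- if (nrow(fl)) forest_index(forest, fl$a) else integer(0)
  bi <- if (nrow(fl)) forest_index(forest, fl$b) else integer(0)
  flips_at <- vector("list", n)
  for (f in seq_along(ai)) {
    flips_at[[ai[f]]] <- c(flips_at[[ai[f]]], f)
    if (bi[f] != ai[f]) flips_at[[bi[f]]] <- c(flips_at[[bi[f]]], f)
  }
  other <- function(f, u) ifelse(ai[f] == u, bi[f], ai[f])

  tc <- td <- rep(NA_real_, n)
  tflip <- rep(NA_real_, length(ai))
  tc[forest$roots] <- 0
  ready <- forest$roots
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    progress <- FALSE
    deferred <- integer(0)
    stack <- rev(ready)
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      fu <- flips_at[[u]]
      partners <- if (length(fu)) other(fu, u) else integer(0)
      if (length(partners) && anyNA(tc[partners])) {
        deferred <- c(deferred, u)
        next
      }
      if (length(fu)) {
        unset <- is.na(tflip[fu])
        tflip[fu[unset]] <- pmax(tc[u], tc[partners[unset]])
      }
      tdu <- max(tc[u] + 1, if (length(fu)) tflip[fu] + 1 else -Inf)
      if (is.na(forest$left[u])) {
        td[u] <- Inf
      } else {
        td[u] <- tdu
        tc[forest$left[u]] <- tdu; tc[forest$right[u]] <- tdu
        stack <- c(stack, forest$right[u], forest$left[u])
      }
      progress <- TRUE
    }
    if (!length(deferred)) break
    if (!progress)
      return(list(success = FALSE, stalled = forest$label[deferred]))
    ready <- deferred
  }
  names(tc) <- names(td) <- forest$label
  list(success = TRUE, tc = tc, td = td, tflip = tflip, rounds = rounds)
}
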