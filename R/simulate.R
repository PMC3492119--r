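#' Simulation parameters for network-evolution models
#'
#' Three growth models generate ground-truthed instances. The
#' degree-dependent model (DDM) mixes node duplication, node loss,
#' interaction gain and interaction loss with probabilities \code{p_ndup},
#' \code{p_nloss}, \code{p_egain}, \code{p_eloss}; objects are chosen by
#' degree: duplication/loss of node \code{u} with weight \code{1/k_u} (total
#' degree), gain of ordered non-edge \code{(u,v)} with weight \code{k_u^out}
#' (preferential attachment at the source, uniform target), loss of edge
#' \code{(u,v)} with weight \code{1/k_u^out}. The degree-independent model
#' (DIM) uses the same four operations with uniform object choice. The
#' Foster regulatory model grows by duplication only: the copy keeps each
#' incoming edge with \code{p_inkeep} and each outgoing edge with
#' \code{p_outkeep}, and gains an innovation edge with probability
#' \code{p_innovation}. In all models, nodes left with out-degree 0 are
#' removed (marked Absent), cascading.
#'
#' @param model "DDM", "DIM" or "Foster".
#' @param p_ndup,p_nloss,p_egain,p_eloss DDM/DIM operation probabilities
#'   (normalized to sum to 1).
#' @param p_inkeep,p_outkeep,p_innovation Foster retention/innovation
#'   probabilities.
#' @param seed_nodes,seed_edges size of the random connected seed graph.
#' @param ops_to_ancestor events from the seed to the ancestor X.
#' @param ops_per_lineage events on each lineage after speciation.
#' @return a \code{sim_params} list.
#' @export
sim_params <- function(model = c("DDM", "DIM", "Foster"),
                       p_ndup = 0.35, p_nloss = 0.05,
                       p_egain = 0.30, p_eloss = 0.30,
                       p_inkeep = 0.5, p_outkeep = 0.5, p_innovation = 0.1,
                       seed_nodes = 10L, seed_edges = 25L,
                       ops_to_ancestor = 200L, ops_per_lineage = 200L) {
  model <- match.arg(model)
  p <- c(ndup = p_ndup, nloss = p_nloss, egain = p_egain, eloss = p_eloss)
  if (any(p < 0) || sum(p) <= 0) stop("operation probabilities must be >= 0")
  p <- p / sum(p)
  stopifnot(p_inkeep >= 0, p_inkeep <= 1, p_outkeep >= 0, p_outkeep <= 1,
            p_innovation >= 0, p_innovation <= 1)
  structure(list(model = model, p = p, p_inkeep = p_inkeep,
                 p_outkeep = p_outkeep, p_innovation = p_innovation,
                 seed_nodes = as.integer(seed_nodes),
                 seed_edges = as.integer(seed_edges),
                 ops_to_ancestor = as.integer(ops_to_ancestor),
                 ops_per_lineage = as.integer(ops_per_lineage)),
            class = "sim_params")
}

#' Random connected directed seed graph
#'
#' \code{m >= n} gives a random Hamiltonian cycle plus \code{m - n} extra
#' random ordered pairs (so every node starts with out-degree >= 1);
#' \code{m = n - 1} gives a random spanning arborescence. No self-loops or
#' multi-edges.
#'
#' @param n,m node and edge counts (\code{n - 1 <= m <= n (n - 1)}).
#' @param labels node labels (default \code{s1..sn}).
#' @return a directed [interaction_graph()], weakly connected.
#' @export
random_seed_graph <- function(n, m, labels = sprintf("s%d", seq_len(n))) {
  if (m < n - 1 || m > n * (n - 1)) stop("infeasible (n, m) for a simple connected digraph")
  if (n == 1) return(interaction_graph(labels, directed = TRUE))
  if (m >= n) {
    perm <- sample.int(n)
    edges <- cbind(perm, c(perm[-1], perm[1]))
    if (m > n) {
      all_pairs <- which(outer(seq_len(n), seq_len(n), "!="))
      used <- (edges[, 2] - 1L) * n + edges[, 1]
      pool <- setdiff(all_pairs, used)
      extra <- sample(pool, m - n)
      edges <- rbind(edges, cbind((extra - 1L) %% n + 1L, (extra - 1L) %/% n + 1L))
    }
  } else {                       # m == n - 1: arborescence away from the root
    ord <- sample.int(n)
    edges <- cbind(ord[vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)], ord[2:n])
  }
  interaction_graph(labels, cbind(labels[edges[, 1]], labels[edges[, 2]]),
                    directed = TRUE)
}

## ---- mutable simulation state -------------------------------------------

## forest builder: grows a duplication forest as leaves split / go Absent
new_forest_builder <- function(root_labels) {
  fb <- new.env(parent = emptyenv())
  n <- length(root_labels)
  fb$label <- root_labels
  fb$parent <- rep(NA_integer_, n)
  fb$present <- rep(TRUE, n)          # NA once a leaf becomes internal
  fb$group <- root_labels
  fb$ctr <- 0L
  fb
}

fb_split_leaf <- function(fb, id) {
  g <- fb$group[id]
  fb$ctr <- fb$ctr + 2L
  labs <- paste0(g, ".", c(fb$ctr - 1L, fb$ctr))
  k <- length(fb$label)
  fb$label <- c(fb$label, labs)
  fb$parent <- c(fb$parent, id, id)
  fb$present[id] <- NA                # now an internal (duplication) node
  fb$present <- c(fb$present, TRUE, TRUE)
  fb$group <- c(fb$group, g, g)
  c(k + 1L, k + 2L)
}

fb_finalize <- function(fb) {
  duplication_forest(fb$label, fb$parent, fb$present, group = fb$group)
}

## graph state: slots with in/out adjacency, tied to forest leaves
new_sim_state <- function(graph, fb) {
  st <- new.env(parent = emptyenv())
  n <- length(graph$nodes)
  st$fb <- fb
  st$alive <- rep(TRUE, n)
  st$leaf <- match(graph$nodes, fb$label)  # forest node per slot
  if (anyNA(st$leaf)) stop("graph nodes must be forest leaves")
  st$out <- rep(list(integer(0)), n)
  st$inn <- rep(list(integer(0)), n)
  if (nrow(graph$edges)) {
    i <- match(graph$edges[, 1], graph$nodes)
    j <- match(graph$edges[, 2], graph$nodes)
    for (e in seq_along(i)) {
      st$out[[i[e]]] <- c(st$out[[i[e]]], j[e])
      st$inn[[j[e]]] <- c(st$inn[[j[e]]], i[e])
    }
  }
  st$outdeg <- vapply(st$out, length, 1L)
  st$indeg <- vapply(st$inn, length, 1L)
  st$flips <- list()
  st$events <- list()
  st$t <- 0L
  st
}

st_add_edge <- function(st, u, v) {
  st$out[[u]] <- c(st$out[[u]], v); st$inn[[v]] <- c(st$inn[[v]], u)
  st$outdeg[u] <- st$outdeg[u] + 1L; st$indeg[v] <- st$indeg[v] + 1L
}

st_del_edge <- function(st, u, v) {
  st$out[[u]] <- st$out[[u]][st$out[[u]] != v]
  st$inn[[v]] <- st$inn[[v]][st$inn[[v]] != u]
  st$outdeg[u] <- st$outdeg[u] - 1L; st$indeg[v] <- st$indeg[v] - 1L
}

st_log_flip <- function(st, u, v) {
  st$flips[[length(st$flips) + 1L]] <-
    list(a = st$fb$label[st$leaf[u]], b = st$fb$label[st$leaf[v]], t = st$t)
}

## remove a slot (node loss or pruning); marks the forest leaf Absent
st_remove_node <- function(st, u) {
  for (w in st$out[[u]]) if (w != u) {
    st$inn[[w]] <- st$inn[[w]][st$inn[[w]] != u]
    st$indeg[w] <- st$indeg[w] - 1L
  }
  for (w in st$inn[[u]]) if (w != u) {
    st$out[[w]] <- st$out[[w]][st$out[[w]] != u]
    st$outdeg[w] <- st$outdeg[w] - 1L
  }
  st$out[[u]] <- st$inn[[u]] <- integer(0)
  st$outdeg[u] <- st$indeg[u] <- 0L
  st$alive[u] <- FALSE
  st$fb$present[st$leaf[u]] <- FALSE
}

st_prune <- function(st) {
  repeat {
    z <- which(st$alive & st$outdeg == 0L)
    if (!length(z)) break
    for (u in z) st_remove_node(st, u)
  }
}

## duplicate slot u; the two children split the leaf. copy_edges = TRUE
## copies every incident edge to both children (DDM/DIM convention).
st_duplicate <- function(st, u, copy_edges = TRUE) {
  kids <- fb_split_leaf(st$fb, st$leaf[u])
  n <- length(st$alive)
  c1 <- n + 1L; c2 <- n + 2L
  st$alive <- c(st$alive, TRUE, TRUE)
  st$leaf <- c(st$leaf, kids)
  st$out <- c(st$out, list(integer(0)), list(integer(0)))
  st$inn <- c(st$inn, list(integer(0)), list(integer(0)))
  st$outdeg <- c(st$outdeg, 0L, 0L); st$indeg <- c(st$indeg, 0L, 0L)
  if (copy_edges) {
    selfloop <- u %in% st$out[[u]]
    for (w in st$out[[u]]) if (w != u) { st_add_edge(st, c1, w); st_add_edge(st, c2, w) }
    for (w in st$inn[[u]]) if (w != u) { st_add_edge(st, w, c1); st_add_edge(st, w, c2) }
    if (selfloop) { st_add_edge(st, c1, c1); st_add_edge(st, c2, c2)
                    st_add_edge(st, c1, c2); st_add_edge(st, c2, c1) }
  }
  st_remove_node_silent(st, u)
  c(c1, c2)
}

## detach a duplicated slot without marking its (now internal) leaf Absent
st_remove_node_silent <- function(st, u) {
  for (w in st$out[[u]]) if (w != u) {
    st$inn[[w]] <- st$inn[[w]][st$inn[[w]] != u]
    st$indeg[w] <- st$indeg[w] - 1L
  }
  for (w in st$inn[[u]]) if (w != u) {
    st$out[[w]] <- st$out[[w]][st$out[[w]] != u]
    st$outdeg[w] <- st$outdeg[w] - 1L
  }
  st$out[[u]] <- st$inn[[u]] <- integer(0)
  st$outdeg[u] <- st$indeg[u] <- 0L
  st$alive[u] <- FALSE
}

st_graph <- function(st) {
  ids <- which(st$alive)
  labs <- st$fb$label[st$leaf[ids]]
  edges <- NULL
  for (u in ids) if (length(st$out[[u]]))
    edges <- rbind(edges, cbind(st$fb$label[st$leaf[u]],
                                st$fb$label[st$leaf[st$out[[u]]]]))
  interaction_graph(labs, edges, directed = TRUE)
}

sim_abort <- function() stop(structure(class = c("ancnet_sim_empty", "error",
                                                 "condition"),
                                       list(message = "graph emptied during simulation",
                                            call = NULL)))

## ---- evolution loops ----------------------------------------------------

#' Evolve a simulation state
#'
#' Applies \code{n_ops} sampled events to a graph/forest state under the
#' DDM/DIM ([evolve_network()]) or Foster ([foster_evolve()]) model.
#' Operations are drawn among the currently feasible ones (probabilities
#' renormalized); every sampled event is applied. Interaction gains and
#' losses are logged as flip events at the forest leaves current at event
#' time, so the true history is available for end-to-end checks. If the
#' graph empties, a condition of class \code{ancnet_sim_empty} is signalled.
#'
#' @param st internal simulation state (graph + forest builder): most users
#'   call [generate_instance()] instead; exposed for distributional tests.
#' @param params a [sim_params()].
#' @param n_ops number of events.
#' @return the state, invisibly (modified in place).
#' @keywords internal
#' @export
evolve_network <- function(st, params, n_ops) {
  degree_weighted <- params$model == "DDM"
  p <- params$p
  for (op in seq_len(n_ops)) {
    st$t <- st$t + 1L
    ids <- which(st$alive)
    n <- length(ids)
    if (!n) sim_abort()
    avail <- (n - 1L) - st$outdeg[ids]     # gain targets per source (no self)
    gain_w <- if (degree_weighted) st$outdeg[ids] * avail else avail
    feas <- c(ndup = n >= 1L, nloss = n >= 1L,
              egain = sum(gain_w) > 0, eloss = sum(st$outdeg[ids]) > 0)
    pw <- p * feas
    kind <- names(p)[sample.int(4L, 1L, prob = pw)]
    if (kind == "ndup") {
      k <- st$outdeg[ids] + st$indeg[ids]
      w <- if (degree_weighted) 1 / k else rep(1, n)
      u <- ids[sample.int(n, 1L, prob = w)]
      st$events[[length(st$events) + 1L]] <- list(t = st$t, op = "ndup", u = u)
      st_duplicate(st, u)
    } else if (kind == "nloss") {
      k <- st$outdeg[ids] + st$indeg[ids]
      w <- if (degree_weighted) 1 / k else rep(1, n)
      u <- ids[sample.int(n, 1L, prob = w)]
      st$events[[length(st$events) + 1L]] <- list(t = st$t, op = "nloss", u = u)
      st_remove_node(st, u)
    } else if (kind == "egain") {
      u <- ids[sample.int(n, 1L, prob = gain_w)]
      cand <- setdiff(ids, c(u, st$out[[u]]))
      v <- cand[sample.int(length(cand), 1L)]
      st_add_edge(st, u, v)
      st_log_flip(st, u, v)
      st$events[[length(st$events) + 1L]] <- list(t = st$t, op = "egain", u = u, v = v)
    } else {
      w <- if (degree_weighted) as.numeric(st$outdeg[ids] > 0) else st$outdeg[ids]
      u <- ids[sample.int(n, 1L, prob = w)]
      v <- st$out[[u]][sample.int(length(st$out[[u]]), 1L)]
      st_del_edge(st, u, v)
      st_log_flip(st, u, v)
      st$events[[length(st$events) + 1L]] <- list(t = st$t, op = "eloss", u = u, v = v)
    }
    st_prune(st)
    if (!any(st$alive)) sim_abort()
  }
  invisible(st)
}

#' @rdname evolve_network
#' @export
foster_evolve <- function(st, params, n_ops) {
  for (op in seq_len(n_ops)) {
    st$t <- st$t + 1L
    ids <- which(st$alive)
    n <- length(ids)
    if (!n) sim_abort()
    u <- ids[sample.int(n, 1L)]
    outs <- st$out[[u]]; inns <- st$inn[[u]]
    kids <- st_duplicate(st, u, copy_edges = FALSE)
    c1 <- kids[1]; c2 <- kids[2]
    ## the originating copy keeps everything (no events logged)
    for (w in outs) if (w != u) st_add_edge(st, c1, w)
    for (w in inns) if (w != u) st_add_edge(st, w, c1)
    ## the new copy keeps each edge with the retention probabilities;
    ## a dropped edge is an interaction loss right after duplication
    for (w in outs) if (w != u) {
      if (stats::runif(1) < params$p_outkeep) st_add_edge(st, c2, w)
      else st_log_flip(st, c2, w)
    }
    for (w in inns) if (w != u) {
      if (stats::runif(1) < params$p_inkeep) st_add_edge(st, w, c2)
      else st_log_flip(st, w, c2)
    }
    st$events[[length(st$events) + 1L]] <- list(t = st$t, op = "ndup", u = u)
    if (stats::runif(1) < params$p_innovation) {
      alive_now <- which(st$alive)
      cand <- setdiff(alive_now, c(c2, st$out[[c2]]))
      if (length(cand)) {
        v <- cand[sample.int(length(cand), 1L)]
        st_add_edge(st, c2, v)
        st_log_flip(st, c2, v)
        st$events[[length(st$events) + 1L]] <- list(t = st$t, op = "egain",
                                                    u = c2, v = v)
      }
    }
    st_prune(st)
    if (!any(st$alive)) sim_abort()
  }
  invisible(st)
}

## ---- instance generation ------------------------------------------------

#' Degree-distribution acceptance filter for ancestral graphs
#'
#' Keeps an ancestor when its in-degrees fit an exponential distribution
#' with maximum-likelihood rate in [1.0, 1.2], or its out-degrees fit a
#' discrete power law (MLE with x_min = 1) with exponent in [1.8, 2.2].
#' Degenerate degree sequences (fewer than two distinct values) fail the
#' corresponding fit.
#'
#' @param X a directed [interaction_graph()].
#' @return logical.
#' @export
accept_instance <- function(X) {
  fits_degree_filter(graph_degree(X, "in"), graph_degree(X, "out"))
}

## the fits themselves, on raw degree sequences (exponential rate = 1/mean;
## discrete power law exponent = 1 + n / sum(log k), x_min = 1)
fits_degree_filter <- function(indeg, outdeg) {
  ok_exp <- FALSE
  if (length(unique(indeg)) >= 2L && mean(indeg) > 0) {
    rate <- 1 / mean(indeg)
    ok_exp <- rate >= 1.0 && rate <= 1.2
  }
  ok_pl <- FALSE
  k <- outdeg[outdeg >= 1]
  if (length(unique(outdeg)) >= 2L && length(k) >= 2L && sum(log(k)) > 0) {
    expo <- 1 + length(k) / sum(log(k))
    ok_pl <- expo >= 1.8 && expo <= 2.2
  }
  ok_exp || ok_pl
}

#' Generate a ground-truthed network-evolution instance
#'
#' A random connected seed graph is evolved to an ancestor X; X must pass
#' the degree-distribution filter ([accept_instance()]); a speciation event
#' then lets two lineages evolve independently from X, each on its own
#' duplication forest rooted at X's nodes (the homology groups). Interaction
#' events are logged as flips, so the true history of each lineage is
#' available; X's own interactions enter each lineage history as flips
#' between roots.
#'
#' @param params a [sim_params()].
#' @param seed optional integer; when given, \code{set.seed(seed)} first.
#' @param filter apply the acceptance filter to X (default TRUE).
#' @param max_attempts restarts allowed for rejected/emptied instances.
#' @return a \code{sim_instance}: list with ancestor \code{X}, extant
#'   \code{G1}, \code{G2}, forests \code{F1}, \code{F2}, flip logs
#'   \code{flips1}, \code{flips2} (root flips + events), event logs,
#'   \code{attempts}.
#' @export
generate_instance <- function(params, seed = NULL, filter = TRUE,
                              max_attempts = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  evolver <- if (params$model == "Foster") foster_evolve else evolve_network
  for (attempt in seq_len(max_attempts)) {
    res <- tryCatch({
      seedg <- random_seed_graph(params$seed_nodes, params$seed_edges)
      fb0 <- new_forest_builder(seedg$nodes)
      st0 <- new_sim_state(seedg, fb0)
      evolver(st0, params, params$ops_to_ancestor)
      X <- st_graph(st0)
      if (filter && !accept_instance(X)) NULL else {
        lineage <- function() {
          fb <- new_forest_builder(X$nodes)
          st <- new_sim_state(X, fb)
          ## ancestral interactions: root-level flips at time 0
          if (nrow(X$edges))
            for (e in seq_len(nrow(X$edges)))
              st$flips[[e]] <- list(a = X$edges[e, 1], b = X$edges[e, 2], t = 0L)
          evolver(st, params, params$ops_per_lineage)
          list(G = st_graph(st), F = fb_finalize(fb),
               flips = do.call(rbind, lapply(st$flips, function(f)
                 data.frame(a = f$a, b = f$b, orientation = "->", t = f$t,
                            stringsAsFactors = FALSE))),
               events = st$events)
        }
        l1 <- lineage(); l2 <- lineage()
        structure(list(X = X, G1 = l1$G, G2 = l2$G, F1 = l1$F, F2 = l2$F,
                       flips1 = l1$flips, flips2 = l2$flips,
                       events1 = l1$events, events2 = l2$events,
                       params = params, attempts = attempt),
                  class = "sim_instance")
      }
    }, ancnet_sim_empty = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop("no acceptable instance in ", max_attempts, " attempts")
}

#' @export
print.sim_instance <- function(x, ...) {
  cat("Simulated instance (", x$params$model, "): ancestor ",
      length(x$X$nodes), " nodes / ", nrow(x$X$edges), " edges; G1 ",
      length(x$G1$nodes), "/", nrow(x$G1$edges), "; G2 ",
      length(x$G2$nodes), "/", nrow(x$G2$edges), "\n", sep = "")
  invisible(x)
}

#' True lineage history of a simulated instance
#' @param instance a \code{sim_instance}.
#' @param lineage 1 or 2.
#' @return the [network_history()] of logged events; \code{constructs()} of
#'   it reproduces the extant graph.
#' @export
true_history <- function(instance, lineage = 1) {
  F <- if (lineage == 1) instance$F1 else instance$F2
  fl <- if (lineage == 1) instance$flips1 else instance$flips2
  network_history(F, fl, directed = TRUE)
}
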