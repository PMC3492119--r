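## Brute-force reference implementations. These re-derive everything from
## first principles (naive parent walks, exhaustive subset search) so they
## can serve as independent cross-checks of the dynamic program and of the
## blocking-loop detector on small instances.

## naive proper-ancestor test by walking parent pointers (no euler intervals)
naive_proper_ancestor <- function(forest, i, j) {
  p <- forest$parent[j]
  while (!is.na(p)) {
    if (p == i) return(TRUE)
    p <- forest$parent[p]
  }
  FALSE
}

#' Brute-force blocking-loop existence check
#'
#' Decides, directly from the definition, whether a history contains a
#' k-blocking loop: a cyclic sequence of flips (with endpoint roles) where
#' each successive flip's \code{u} endpoint is a proper ancestor of the
#' previous flip's \code{v} endpoint. The successor relation between
#' role-assigned flips is built with naive parent walks and closed
#' transitively; a loop exists iff some flip can reach itself.
#'
#' @param history a [network_history()].
#' @param k_max largest loop length considered (default: number of flips).
#' @return logical.
#' @export
brute_force_blocking_check <- function(history, k_max = NULL) {
  fl <- history$flips
  m <- nrow(fl)
  if (!m) return(FALSE)
  forest <- history$forest
  ai <- forest_index(forest, fl$a); bi <- forest_index(forest, fl$b)
  U <- c(ai, bi); V <- c(bi, ai)           # both role assignments
  nv <- length(U)
  R <- matrix(FALSE, nv, nv)
  for (i in seq_len(nv))
    for (j in seq_len(nv))
      R[i, j] <- naive_proper_ancestor(forest, U[j], V[i])
  if (is.null(k_max)) k_max <- m
  reach <- R
  for (step in seq_len(max(k_max - 1L, 0L))) {
    if (any(diag(reach))) return(TRUE)
    reach <- (reach %*% R) > 0
  }
  any(diag(reach))
}

#' Exhaustive minimum-flip search (test oracle)
#'
#' Iterative-deepening search over subsets of candidate flip edges, by
#' increasing subset size, for the cheapest set that constructs the target
#' graph and (optionally) forms a fully valid history. Unit costs only;
#' intended for forests of at most about a dozen nodes.
#'
#' @param forest a small [duplication_forest()].
#' @param graph target [interaction_graph()].
#' @param max_flips give up beyond this subset size.
#' @param require_valid if TRUE (default) solutions must contain no blocking
#'   loop of any length (checked by [brute_force_blocking_check()]); if
#'   FALSE only 1- and 2-blocking loops are excluded, mirroring the DP's
#'   relaxation.
#' @return list with \code{cost} (NA if the bounded search failed),
#'   \code{flips} (data frame), \code{feasible}.
#' @export
brute_force_min_flips <- function(forest, graph, max_flips = 5L,
                                  require_valid = TRUE) {
  leaf_idx <- which(forest$present %in% TRUE)
  k <- length(leaf_idx)
  directed <- graph$directed
  L <- root_path_membership(forest, leaf_idx)

  ## candidate flips: node pairs with Present leaves under both endpoints
  occupied <- which(vapply(seq_len(forest$n), function(u) any(L[u, ]), TRUE))
  pairs <- if (length(occupied) >= 2L) t(utils::combn(occupied, 2L)) else
    matrix(integer(0), 0, 2)
  ## drop comparable pairs: a flip on its own root path is a 1-blocking loop
  keep <- !mapply(function(i, j) naive_proper_ancestor(forest, i, j) ||
                                 naive_proper_ancestor(forest, j, i),
                  pairs[, 1], pairs[, 2])
  pairs <- pairs[keep, , drop = FALSE]
  if (directed)
    pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  nc <- nrow(pairs)

  ## per-candidate toggle masks over the leaf-pair space, packed into bits
  pair_index <- if (directed) {
    w <- which(outer(seq_len(k), seq_len(k), "!="))
    m <- matrix(0L, k, k); m[w] <- seq_along(w); m
  } else {
    m <- matrix(0L, k, k)
    idx <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) { idx <- idx + 1L
      m[i, j] <- idx; m[j, i] <- idx }
    m
  }
  nbits <- max(pair_index)
  nwords <- ceiling(nbits / 31)
  packmask <- function(tog) {
    bits <- sort(unique(pair_index[tog & pair_index > 0]))
    w <- integer(nwords)
    for (b in bits) {
      wi <- (b - 1) %/% 31 + 1
      w[wi] <- bitwOr(w[wi], bitwShiftL(1L, (b - 1) %% 31))
    }
    w
  }
  masks <- matrix(0L, nc, nwords)
  for (ci in seq_len(nc)) {
    A <- L[pairs[ci, 1], ]; B <- L[pairs[ci, 2], ]
    tog <- if (directed) outer(A, B) else outer(A, B) | outer(B, A)
    masks[ci, ] <- packmask(tog)
  }
  target <- {
    tg <- matrix(FALSE, k, k)
    if (nrow(graph$edges)) {
      i <- match(graph$edges[, 1], forest$label[leaf_idx])
      j <- match(graph$edges[, 2], forest$label[leaf_idx])
      tg[cbind(i, j)] <- TRUE
      if (!directed) tg[cbind(j, i)] <- TRUE
    }
    packmask(tg)
  }

  check_subset <- function(sub) {
    fl <- data.frame(a = forest$label[pairs[sub, 1]],
                     b = forest$label[pairs[sub, 2]],
                     orientation = rep(if (directed) "->" else "--",
                                       length(sub)),
                     stringsAsFactors = FALSE)
    h <- network_history(forest, fl, directed = directed)
    if (require_valid) {
      if (brute_force_blocking_check(h)) return(NULL)
    } else if (has_short_blocking_loop(forest, pairs[sub, , drop = FALSE])) {
      return(NULL)
    }
    fl
  }

  if (identical(target, integer(nwords))) {
    return(list(cost = 0, flips = check_subset(integer(0)), feasible = TRUE))
  }
  for (size in seq_len(min(max_flips, nc))) {
    subs <- utils::combn(nc, size)
    for (ci in seq_len(ncol(subs))) {
      sub <- subs[, ci]
      acc <- integer(nwords)
      for (s in sub) acc <- bitwXor(acc, masks[s, ])
      if (identical(acc, target)) {
        fl <- check_subset(sub)
        if (!is.null(fl)) return(list(cost = size, flips = fl, feasible = TRUE))
      }
    }
  }
  list(cost = NA_real_, flips = NULL, feasible = FALSE)
}

## direct 1-/2-blocking-loop test on a set of candidate index pairs
## (1-loops are pre-excluded from candidates; 2-loop: u1 panc v0, u0 panc v1
## under some role assignment)
has_short_blocking_loop <- function(forest, idx_pairs) {
  m <- nrow(idx_pairs)
  if (m < 2) return(FALSE)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    e1 <- idx_pairs[i, ]; e2 <- idx_pairs[j, ]
    for (r1 in 1:2) for (r2 in 1:2) {
      u0 <- e1[r1]; v0 <- e1[3 - r1]
      u1 <- e2[r2]; v1 <- e2[3 - r2]
      if (naive_proper_ancestor(forest, u1, v0) &&
          naive_proper_ancestor(forest, u0, v1)) return(TRUE)
    }
  }
  FALSE
}
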