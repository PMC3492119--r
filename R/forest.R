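#' Duplication forests
#'
#' A duplication forest is a collection of rooted binary trees describing the
#' duplication history of a set of genes. Each internal node is a duplication
#' event that replaces a gene by its two children; each leaf is either
#' \emph{Present} (an extant gene) or \emph{Absent} (a lineage that was lost).
#' Every tree belongs to one homology group: the set of genes descending from
#' a single ancestral gene.
#'
#' Internally a forest is a set of parallel vectors indexed by node:
#' \code{label}, \code{parent}, \code{left}, \code{right}, \code{present}
#' (logical, \code{NA} for internal nodes), \code{group}, \code{species},
#' \code{tc}/\code{td} (optional real-valued creation/duplication times
#' accumulated from branch lengths; \code{td = Inf} at leaves), \code{tree},
#' plus derived indices: a postorder (children before parents), depths, and
#' an interval numbering (\code{ein}, \code{eout}) supporting constant-time
#' proper-ancestor queries.
#'
#' @param label character vector of unique node labels.
#' @param parent integer vector; \code{NA} for roots. Children are assigned
#'   left/right in order of appearance.
#' @param present logical; \code{TRUE}/\code{FALSE} for leaves, \code{NA} for
#'   internal nodes (leaves are detected as nodes that are nobody's parent).
#' @param species optional character vector of species tags.
#' @param group optional character vector of homology-group ids; defaults to
#'   the root label of each tree.
#' @param blen optional numeric vector of branch lengths (length of the edge
#'   above each node; \code{NA} for roots). When supplied, node creation
#'   times \code{tc} are accumulated root-to-node and \code{td} is derived.
#' @return An object of class \code{duplication_forest}.
#' @seealso [read_forest()], [write_forest()], [network_history()]
#' @export
duplication_forest <- function(label, parent, present = NULL, species = NULL,
                               group = NULL, blen = NULL) {
  n <- length(label)
  stopifnot(n >= 1L)
  label <- as.character(label)
  if (anyDuplicated(label))
    stop("duplicate node labels: ", paste(unique(label[duplicated(label)]), collapse = ", "))
  parent <- as.integer(parent)
  if (length(parent) != n) stop("parent must have one entry per node")
  bad <- !is.na(parent) & (parent < 1L | parent > n)
  if (any(bad)) stop("parent index out of range")

  left <- right <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (is.na(p)) next
    if (is.na(left[p])) left[p] <- i
    else if (is.na(right[p])) right[p] <- i
    else stop("node '", label[p], "' has more than two children (trees must be binary)")
  }
  if (any(!is.na(left) & is.na(right)))
    stop("node '", label[which(!is.na(left) & is.na(right))[1]],
         "' has exactly one child (trees must be binary)")
  is_leaf <- is.na(left)

  if (is.null(present)) present <- ifelse(is_leaf, TRUE, NA)
  present <- as.logical(present)
  present[!is_leaf] <- NA
  if (any(is.na(present[is_leaf])))
    stop("every leaf must be flagged Present (TRUE) or Absent (FALSE)")

  if (is.null(species)) species <- rep(NA_character_, n)
  species <- as.character(species)

  roots <- which(is.na(parent))
  if (length(roots) == 0L) stop("forest has no root (parent cycle?)")

  ## tree assignment + structural walk (iterative, preorder/postorder/euler)
  tree <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  post <- integer(0)
  ein <- eout <- rep(NA_integer_, n)
  clock <- 0L
  for (ti in seq_along(roots)) {
    r <- roots[ti]
    stack <- c(r)          # nodes to enter
    state <- integer(0)    # postorder emission stack
    depth[r] <- 0L
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (u < 0L) { post <- c(post, -u); clock <- clock + 1L; eout[-u] <- clock; next }
      if (!is.na(tree[u])) stop("node '", label[u], "' reachable from two roots")
      tree[u] <- ti
      clock <- clock + 1L; ein[u] <- clock
      stack <- c(stack, -u)
      if (!is_leaf[u]) {
        depth[left[u]] <- depth[u] + 1L
        depth[right[u]] <- depth[u] + 1L
        stack <- c(stack, right[u], left[u])
      }
    }
  }
  if (any(is.na(tree))) stop("forest contains an unreachable node cycle")

  if (is.null(group)) {
    group <- label[roots][tree]
  } else {
    group <- as.character(group)
    ok <- tapply(group, tree, function(g) length(unique(g)) == 1L)
    if (!all(ok)) stop("homology group labels must be constant within a tree")
  }

  tc <- td <- rep(NA_real_, n)
  if (!is.null(blen)) {
    blen <- as.numeric(blen)
    tc[roots] <- 0
    for (u in rev(post)) {           # preorder: parents before children
      p <- parent[u]
      if (!is.na(p)) tc[u] <- tc[p] + if (is.na(blen[u])) 0 else blen[u]
    }
    td[is_leaf] <- Inf
    for (u in which(!is_leaf)) td[u] <- max(tc[left[u]], tc[right[u]])
  }

  structure(list(label = label, parent = parent, left = left, right = right,
                 present = present, species = species, group = group,
                 tc = tc, td = td, tree = tree, roots = roots, post = post,
                 depth = depth, ein = ein, eout = eout, n = n),
            class = "duplication_forest")
}

#' @export
print.duplication_forest <- function(x, ...) {
  nleaf <- sum(is.na(x$left))
  cat("Duplication forest: ", length(x$roots), " tree(s), ", x$n, " nodes, ",
      sum(x$present %in% TRUE), " Present / ", sum(x$present %in% FALSE),
      " Absent of ", nleaf, " leaves\n", sep = "")
  cat("Homology groups: ", paste(utils::head(x$group[x$roots], 8), collapse = ", "),
      if (length(x$roots) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

## index of a label vector, with validation
forest_index <- function(forest, ids) {
  i <- match(as.character(ids), forest$label)
  if (anyNA(i)) stop("unknown forest node id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  i
}

#' Proper-ancestor test
#'
#' \code{u} is a proper ancestor of \code{v} when \code{u != v} and \code{u}
#' lies on the path from \code{v} to its root. Vectorized over pairs.
#'
#' @param forest a [duplication_forest()].
#' @param u,v node labels (recycled to common length).
#' @return logical vector.
#' @export
is_proper_ancestor <- function(forest, u, v) {
  i <- forest_index(forest, u); j <- forest_index(forest, v)
  forest$tree[i] == forest$tree[j] & i != j &
    forest$ein[i] < forest$ein[j] & forest$eout[i] >= forest$eout[j]
}

## same, on integer indices (internal hot path)
panc_idx <- function(forest, i, j) {
  forest$tree[i] == forest$tree[j] & i != j &
    forest$ein[i] < forest$ein[j] & forest$eout[i] >= forest$eout[j]
}

#' Present leaves of a forest
#' @param forest a [duplication_forest()].
#' @return character vector of labels of leaves flagged Present.
#' @export
present_leaves <- function(forest) {
  forest$label[which(forest$present %in% TRUE)]
}

## leaf indices (Present only) under each node, as a list of integer vectors.
## leaves_under(forest)[[u]] relies on euler intervals: cheap, done on demand.
leaves_under <- function(forest, nodes = seq_len(forest$n), present_only = TRUE) {
  leaf <- which(is.na(forest$left) & (if (present_only) forest$present %in% TRUE else TRUE))
  lapply(nodes, function(u) {
    leaf[forest$tree[leaf] == forest$tree[u] &
         forest$ein[leaf] >= forest$ein[u] & forest$eout[leaf] <= forest$eout[u]]
  })
}

#' Existence-interval distance between two forest nodes
#'
#' The separation between the existence intervals \eqn{[t_c, t_d)} of two
#' nodes: \code{tc(v) - td(u)} when \code{u}'s interval ends before \code{v}'s
#' begins (and symmetrically), 0 when the intervals overlap. Used to penalize
#' flips between genes that, according to branch lengths, never coexisted.
#'
#' @param forest a [duplication_forest()] built with branch lengths.
#' @param u,v node labels.
#' @return nonnegative numeric vector.
#' @export
branch_penalty <- function(forest, u, v) {
  i <- forest_index(forest, u); j <- forest_index(forest, v)
  if (anyNA(forest$tc[c(i, j)]))
    stop("branch_penalty requires node times; build the forest with branch lengths")
  d <- pmax(forest$tc[j] - forest$td[i], forest$tc[i] - forest$td[j])
  pmax(d, 0)
}

## full n x n penalty matrix alpha * delta (Inf-safe); 0 matrix when alpha == 0
penalty_matrix <- function(forest, alpha) {
  n <- forest$n
  if (alpha == 0) return(matrix(0, n, n))
  if (anyNA(forest$tc))
    stop("alpha > 0 requires node times; build the forest with branch lengths")
  ## delta(u,v) = max(tc_v - td_u, tc_u - td_v, 0), symmetric
  d <- pmax(outer(forest$tc, forest$td, function(a, b) a - b),
            t(outer(forest$tc, forest$td, function(a, b) a - b)))
  d[d < 0] <- 0
  d[!is.finite(d)] <- 0            # leaf td = Inf never precedes anything
  if (is.infinite(alpha)) { m <- matrix(0, n, n); m[d > 0] <- Inf; m } else alpha * d
}
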