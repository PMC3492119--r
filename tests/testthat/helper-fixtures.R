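# Shared fixture builders. Everything is generated in code; forests come
# either from literal Newick or from the simulator's forest builder.

cherry_forest <- function() read_forest(text = "((a,b)r);\nc;")

# random duplication forest: `groups` singleton trees, then `splits` random
# leaf duplications, then each leaf goes Absent with prob p_absent (never all)
rand_forest <- function(groups = 3, splits = 3, p_absent = 0.2) {
  fb <- ancnet:::new_forest_builder(paste0("g", seq_len(groups)))
  for (s in seq_len(splits)) {
    leaves <- which(!is.na(fb$present) & fb$present)
    ancnet:::fb_split_leaf(fb, sample(leaves, 1))
  }
  leaves <- which(!is.na(fb$present) & fb$present)
  ab <- leaves[stats::runif(length(leaves)) < p_absent]
  if (length(ab) == length(leaves)) ab <- ab[-1]
  fb$present[ab] <- FALSE
  ancnet:::fb_finalize(fb)
}

# random graph over the Present leaves of a forest
rand_graph <- function(forest, max_edges = 3, directed = FALSE) {
  pl <- present_leaves(forest)
  if (length(pl) < 2) return(interaction_graph(pl, directed = directed))
  pairs <- if (directed) {
    keep <- which(outer(seq_along(pl), seq_along(pl), "!="))
    cbind(rep(pl, each = length(pl)), rep(pl, times = length(pl)))[keep, , drop = FALSE]
  } else t(utils::combn(pl, 2))
  ne <- min(sample(0:max_edges, 1), nrow(pairs))
  interaction_graph(pl, if (ne > 0) pairs[sample(nrow(pairs), ne), , drop = FALSE],
                    directed = directed)
}

# random history on a random forest (valid or not); incomparable_only
# restricts flips to non-ancestor pairs, which constructs() requires in the
# no-self-loop variant
rand_history <- function(max_flips = 5, incomparable_only = FALSE) {
  f <- rand_forest(sample(2:3, 1), sample(1:4, 1))
  nf <- sample(0:max_flips, 1)
  fl <- NULL
  if (nf > 0) {
    pairs <- t(utils::combn(f$label, 2))
    if (incomparable_only) {
      keep <- !(is_proper_ancestor(f, pairs[, 1], pairs[, 2]) |
                is_proper_ancestor(f, pairs[, 2], pairs[, 1]))
      pairs <- pairs[keep, , drop = FALSE]
    }
    pick <- pairs[sample(nrow(pairs), min(nf, nrow(pairs))), , drop = FALSE]
    fl <- data.frame(a = pick[, 1], b = pick[, 2], stringsAsFactors = FALSE)
  }
  network_history(f, fl)
}

edge_keys <- function(graph) {
  if (!nrow(graph$edges)) return(character(0))
  sort(paste(graph$edges[, 1], graph$edges[, 2], sep = "|"))
}

expect_same_graph <- function(a, b) {
  expect_identical(edge_keys(a), edge_keys(b))
}

# three cherries wired so the optimal DP solution is a 3-blocking loop:
# flips (rA,b1), (rB,c1), (rC,a1) each explain two edges at cost 1, and
# rB is an ancestor of b1, rC of c1, rA of a1
three_loop_instance <- function() {
  f <- read_forest(text = "((a1,a2)rA);\n((b1,b2)rB);\n((c1,c2)rC);")
  g <- interaction_graph(edges = rbind(
    c("a1", "b1"), c("a2", "b1"),
    c("b1", "c1"), c("b2", "c1"),
    c("c1", "a1"), c("c2", "a1")))
  list(forest = f, graph = g)
}
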