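#' Infer the parsimonious common ancestor of two extant networks
#'
#' Given the post-speciation duplication forests and extant interaction
#' networks of two species, estimates the ancestral network on homology
#' groups (the roots of the forests). The two lineages are assumed to evolve
#' independently after speciation, so the pair tables of the flip-parsimony
#' DP are computed per forest and combined: an ancestral interaction
#' \code{{r, q}} is created exactly when paying \code{c_add} for it and
#' explaining both extant networks from the flipped state is strictly
#' cheaper than explaining them from the interaction-free state. Ties yield
#' no edge. For directed networks the rule is applied per direction.
#'
#' @param F1,F2 [duplication_forest()]s; roots carry homology-group labels,
#'   which must match across forests (a group may be missing from one
#'   forest entirely — a lineage that lost it — and then contributes no cost).
#' @param G1,G2 extant [interaction_graph()]s (both directed or both not).
#' @param c_add,c_loss,alpha cost model, as in [min_flip_cost()].
#' @param selfloops use the self-loop DP for the extant networks.
#' @param ancestral_selfloops also infer ancestral homodimers \code{(r, r)}
#'   by the analogous rule on the subtree tables; off by default (the rule
#'   for self pairs is an extension, not part of the core method).
#' @return an \code{ancestral_graph} (an [interaction_graph()] whose nodes
#'   are homology-group ids), with attribute \code{"details"}: a data frame
#'   of per-pair costs with and without the ancestral interaction.
#' @examples
#' ## zero divergence: single-leaf forests recover the ancestor exactly
#' f <- read_forest(text = "a;\nb;\nc;")
#' g <- interaction_graph(edges = rbind(c("a", "b")))
#' x <- infer_ancestor(f, f, g, g)
#' sort(apply(x$edges, 1, paste, collapse = "-"))   # just a-b
#' @export
infer_ancestor <- function(F1, F2, G1, G2, c_add = 1, c_loss = 1, alpha = 0,
                           selfloops = FALSE, ancestral_selfloops = FALSE) {
  if (G1$directed != G2$directed) stop("G1 and G2 disagree on directedness")
  directed <- G1$directed
  runner <- if (selfloops) min_flip_cost_selfloops else min_flip_cost
  t1 <- runner(F1, G1, c_add, c_loss, alpha)
  t2 <- runner(F2, G2, c_add, c_loss, alpha)

  g1 <- F1$group[F1$roots]; g2 <- F2$group[F2$roots]
  if (anyDuplicated(g1) || anyDuplicated(g2))
    stop("duplicate homology-group labels within a forest")
  groups <- sort(union(g1, g2))

  ## A value for a root pair, relative to ordered roles (r, q); groups
  ## missing from a forest contribute 0
  rootA <- function(tab, gmap, r, q, s) {
    i <- match(r, names(gmap)); j <- match(q, names(gmap))
    if (is.na(i) || is.na(j)) return(0)
    tab$A[gmap[[i]], gmap[[j]], s + 1L]
  }
  m1 <- stats::setNames(as.list(F1$label[F1$roots]), g1)
  m2 <- stats::setNames(as.list(F2$label[F2$roots]), g2)

  det <- list()
  edges <- NULL
  eps <- 1e-9
  for (i in seq_along(groups)) {
    js <- if (directed) seq_along(groups)[-i] else
      if (i < length(groups)) (i + 1):length(groups) else integer(0)
    for (j in js) {
      r <- groups[i]; q <- groups[j]
      sflip <- if (directed) 1L else 1L        # flip the (r -> q) / pair bit
      lhs <- c_add + rootA(t1, m1, r, q, sflip) + rootA(t2, m2, r, q, sflip)
      rhs <- rootA(t1, m1, r, q, 0L) + rootA(t2, m2, r, q, 0L)
      place <- lhs < rhs - eps
      det[[length(det) + 1L]] <- data.frame(
        r = r, q = q, with_edge = lhs, without_edge = rhs, edge = place,
        stringsAsFactors = FALSE)
      if (place) edges <- rbind(edges, c(r, q))
    }
  }
  if (ancestral_selfloops && selfloops) {
    sval <- function(tab, gmap, F, r, p) {
      i <- match(r, names(gmap))
      if (is.na(i)) return(0)
      ridx <- which(F$label[F$roots] == gmap[[i]])
      (if (p == 0) tab$S_roots else tab$S_roots_odd)[ridx]
    }
    for (r in groups) {
      lhs <- c_add + sval(t1, m1, F1, r, 1) + sval(t2, m2, F2, r, 1)
      rhs <- sval(t1, m1, F1, r, 0) + sval(t2, m2, F2, r, 0)
      if (lhs < rhs - eps) edges <- rbind(edges, c(r, r))
    }
  }
  out <- interaction_graph(nodes = groups, edges = edges, directed = directed,
                           selfloops = ancestral_selfloops)
  class(out) <- c("ancestral_graph", class(out))
  attr(out, "details") <- do.call(rbind, det)
  out
}

#' @export
print.ancestral_graph <- function(x, ...) {
  cat("Inferred ancestral network:", length(x$nodes), "homology groups,",
      nrow(x$edges), if (x$directed) "directed" else "undirected",
      "interactions\n")
  invisible(x)
}
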