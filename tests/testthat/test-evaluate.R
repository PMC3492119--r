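# Scoring and experiment drivers.

test_that("precision/recall/F1 arithmetic and edge cases", {
  t4 <- interaction_graph(edges = rbind(c("a", "b"), c("b", "c"),
                                        c("c", "d"), c("a", "d")))
  expect_equal(unname(precision_recall_f1(t4, t4)), c(1, 1, 1))
  half <- interaction_graph(t4$nodes, rbind(c("a", "b"), c("b", "c")))
  expect_equal(unname(precision_recall_f1(half, t4)), c(1, 0.5, 2 / 3))
  other <- interaction_graph(t4$nodes, rbind(c("a", "c"), c("b", "d")))
  expect_equal(unname(precision_recall_f1(other, t4)), c(0, 0, 0))
  # no predictions: precision reported 1 (flagged), F1 collapses via recall
  none <- interaction_graph(t4$nodes)
  sc <- precision_recall_f1(none, t4)
  expect_equal(as.numeric(sc), c(1, 0, 0))
  expect_true(isTRUE(attr(sc, "no_predictions")))
  expect_error(precision_recall_f1(
    interaction_graph(edges = rbind(c("z1", "z2"))), t4), "no node ids")
})

test_that("scores are invariant under homology-group relabeling", {
  a <- interaction_graph(edges = rbind(c("g1", "g2"), c("g2", "g3")))
  b <- interaction_graph(c("g1", "g2", "g3"), rbind(c("g1", "g2")))
  s1 <- precision_recall_f1(b, a)
  relab <- function(g, map) interaction_graph(
    unname(map[g$nodes]), cbind(unname(map[g$edges[, 1]]), unname(map[g$edges[, 2]])))
  map <- c(g1 = "x", g2 = "y", g3 = "z")
  s2 <- precision_recall_f1(relab(b, map), relab(a, map))
  expect_equal(s1, s2)
})

test_that("excluding groups lost in both lineages only ever helps recall", {
  f_alive <- read_forest(text = "a;\nb;\nc;")
  truth <- interaction_graph(edges = rbind(c("a", "b"), c("b", "c")))
  inferred <- interaction_graph(c("a", "b", "c"), rbind(c("a", "b")))
  # no losses: identical to the plain score
  expect_equal(f1_excluding_lost(inferred, truth, f_alive, f_alive),
               precision_recall_f1(inferred, truth))
  # c lost in both lineages: the unrecoverable b-c edge leaves the truth
  f_lost <- read_forest(text = "a;\nb;\nc[&&NHX:P=0];")
  sc <- f1_excluding_lost(inferred, truth, f_lost, f_lost)
  expect_equal(unname(sc), c(1, 1, 1))
  # c lost in only one lineage: nothing is excluded
  sc1 <- f1_excluding_lost(inferred, truth, f_lost, f_alive)
  expect_equal(sc1, precision_recall_f1(inferred, truth))
  # Monte-Carlo: exclusion never lowers the F1 on simulated instances
  set.seed(19)
  p <- sim_params(ops_to_ancestor = 60, ops_per_lineage = 80)
  worse <- 0
  for (i in 1:10) {
    inst <- generate_instance(p, filter = FALSE)
    sc <- score_instance(inst)
    if (sc$score_excluding_lost[["f1"]] < sc$score[["f1"]] - 1e-9)
      worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("divergence sweep reports quartiles and hits 1.0 at distance zero", {
  p <- sim_params(ops_to_ancestor = 50)
  tab <- run_divergence_sweep(p, distances = c(0, 40), replicates = 3,
                              seed = 5)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$f1_median[tab$distance == 0], 1.0)
  expect_true(all(tab$f1_q1 <= tab$f1_median & tab$f1_median <= tab$f1_q3))
  # deterministic given the seed
  tab2 <- run_divergence_sweep(p, distances = c(0, 40), replicates = 3,
                               seed = 5)
  expect_identical(tab, tab2)
})

test_that("parameter sweep records loop-breaking statistics", {
  p <- sim_params(ops_to_ancestor = 50, ops_per_lineage = 50)
  grid <- data.frame(p_ndup = c(0.3, 0.4))
  tab <- run_parameter_sweep(p, grid, replicates = 2, seed = 7)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$max_relative_excess >= 0))
  expect_true(all(tab$f1_median >= 0 & tab$f1_median <= 1))
})
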