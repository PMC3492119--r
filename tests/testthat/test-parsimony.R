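# The flip-parsimony dynamic program and its variants.

test_that("undirected DP reproduces hand-checked minima", {
  f <- cherry_forest()
  # one edge between sibling leaves: a single flip
  g1 <- interaction_graph(c("a", "b", "c"), rbind(c("a", "b")))
  t1 <- min_flip_cost(f, g1)
  expect_equal(t1$cost, 1)
  expect_equal(nrow(t1$flips), 1L)
  # empty graph: zero flips at any forest
  g0 <- interaction_graph(c("a", "b", "c"))
  expect_equal(min_flip_cost(f, g0)$cost, 0)
  expect_equal(nrow(min_flip_cost(f, g0)$flips), 0L)
  # both of {a,c}, {b,c}: one internal flip at (r, c) beats two leaf flips
  g2 <- interaction_graph(edges = rbind(c("a", "c"), c("b", "c")))
  t2 <- min_flip_cost(f, g2)
  expect_equal(t2$cost, 1)
  expect_setequal(paste(t2$flips$a, t2$flips$b), "r c")
})

test_that("backtracked flip sets reconstruct the input graph", {
  f <- cherry_forest()
  g2 <- interaction_graph(edges = rbind(c("a", "c"), c("b", "c")))
  t2 <- min_flip_cost(f, g2)
  expect_same_graph(constructs(as_history(t2)), g2)
  expect_equal(sum(backtrack_flips(t2)$cost), t2$cost)
  set.seed(31)
  for (i in 1:30) {
    f <- rand_forest(sample(2:3, 1), sample(0:3, 1))
    g <- rand_graph(f, 4, directed = sample(c(TRUE, FALSE), 1))
    tab <- min_flip_cost(f, g)
    expect_same_graph(constructs(as_history(tab)), g)
    expect_equal(sum(tab$flips$cost), tab$cost)
  }
})

test_that("self-loop recurrence handles homodimers", {
  f1 <- read_forest(text = "a;")
  g1 <- interaction_graph("a", rbind(c("a", "a")), selfloops = TRUE)
  t1 <- min_flip_cost_selfloops(f1, g1)
  expect_equal(t1$cost, 1)
  f <- read_forest(text = "((a,b)r);")
  # clique incl. self-loops: one ancestral self-flip at r explains it all
  g2 <- interaction_graph(edges = rbind(c("a", "b"), c("a", "a"), c("b", "b")),
                          selfloops = TRUE)
  t2 <- min_flip_cost_selfloops(f, g2)
  expect_equal(t2$cost, 1)
  expect_equal(paste(t2$flips$a, t2$flips$b), "r r")
  h2 <- network_history(f, t2$flips, selfloops = TRUE)
  expect_same_graph(constructs(h2), g2)
  # plain edge without self-loops: the self-flip branch would overshoot
  g3 <- interaction_graph(c("a", "b"), rbind(c("a", "b")), selfloops = TRUE)
  t3 <- min_flip_cost_selfloops(f, g3)
  expect_equal(t3$cost, 1)
  expect_equal(paste(t3$flips$a, t3$flips$b), "a b")
})

test_that("directed DP chooses per-direction flips", {
  f <- cherry_forest()
  g1 <- interaction_graph(c("a","b","c"), rbind(c("a", "c"), c("b", "c")),
                          directed = TRUE)
  t1 <- min_flip_cost_directed(f, g1)
  expect_equal(t1$cost, 1)
  expect_equal(paste(t1$flips$a, t1$flips$b), "r c")
  g2 <- interaction_graph(c("a","b","c"), rbind(c("a", "c")), directed = TRUE)
  expect_equal(min_flip_cost(f, g2)$cost, 1)
  # mirror symmetry: reversing every edge preserves the optimum
  set.seed(17)
  for (i in 1:10) {
    f <- rand_forest(2, sample(1:3, 1))
    g <- rand_graph(f, 4, directed = TRUE)
    gr <- interaction_graph(g$nodes, g$edges[, 2:1, drop = FALSE],
                            directed = TRUE)
    expect_equal(min_flip_cost(f, g)$cost, min_flip_cost(f, gr)$cost)
  }
})

test_that("DP equals the exhaustive oracle on random small instances", {
  set.seed(23)
  for (i in 1:40) {
    directed <- i %% 3 == 0
    f <- rand_forest(sample(2:3, 1), sample(1:3, 1), p_absent = 0.15)
    g <- rand_graph(f, 3, directed = directed)
    tab <- min_flip_cost(f, g)
    fit <- reconstruct_history(f, g, seed = i)
    bf <- brute_force_min_flips(f, g, max_flips = 5)
    expect_true(bf$feasible)
    expect_lte(tab$cost, bf$cost + 1e-9)      # DP relaxes long loops
    expect_lte(bf$cost, fit$cost + 1e-9)      # greedy is valid, oracle optimal
    if (is_valid_history(as_history(tab)))
      expect_equal(tab$cost, bf$cost)
  }
})

test_that("cost model: scaling, bounds, forbidden monotonicity, parity classes", {
  set.seed(29)
  for (i in 1:15) {
    f <- rand_forest(sample(2:3, 1), sample(1:3, 1))
    g <- rand_graph(f, 4)
    base <- min_flip_cost(f, g)
    # leaf placement upper bound at unit costs
    expect_lte(base$cost, nrow(g$edges))
    # lambda-scaling of both costs scales the optimum
    sc <- min_flip_cost(f, g, c_add = 2.5, c_loss = 2.5)
    expect_equal(sc$cost, 2.5 * base$cost)
    # forbidding a used pair never lowers the cost
    if (nrow(base$flips)) {
      forb <- as.matrix(base$flips[1, c("a", "b")])
      expect_gte(min_flip_cost(f, g, forbidden = forb)$cost, base$cost - 1e-9)
    }
  }
  # asymmetric costs: a gain followed by a loss pays c_add + c_loss
  f <- read_forest(text = "((a,b)r);\nc;")
  g <- interaction_graph(edges = rbind(c("b", "c")))
  t_asym <- min_flip_cost(f, g, c_add = 11.4, c_loss = 1)
  # either one leaf gain (11.4) or gain at r then loss at (a,c) (12.4)
  expect_equal(t_asym$cost, 11.4)
  expect_equal(t_asym$flips$event, "add")
})

test_that("branch lengths penalize flips between non-overlapping intervals", {
  txt <- "((a:1,b:1)m:1,z:2)r;\n((c:1,d:1)k:5,w:6)q;"
  f <- read_forest(text = txt)
  # existence intervals: m = [1,2), k = [5,6) -> separation 3
  expect_equal(branch_penalty(f, "m", "k"), 3)
  expect_equal(branch_penalty(f, "m", "z"), 0)       # overlapping
  expect_equal(branch_penalty(f, "a", "k"), 0)       # leaf reaches present
  g <- interaction_graph(edges = rbind(c("a", "c"), c("a", "d"),
                                       c("b", "c"), c("b", "d")))
  expect_equal(min_flip_cost(f, g, alpha = 0)$cost, 1)          # flip (m,k)
  t_pen <- min_flip_cost(f, g, alpha = 0.1)
  expect_equal(t_pen$cost, 1 + 0.1 * 3)
  # alpha = Inf: (m,k) excluded; two flips between overlapping nodes instead
  t_inf <- min_flip_cost(f, g, alpha = Inf)
  expect_equal(t_inf$cost, 2)
  expect_false(any(paste(t_inf$flips$a, t_inf$flips$b) == "m k"))
  expect_error(min_flip_cost(cherry_forest(), g_err <- interaction_graph(c("a","b","c")),
                             alpha = 1), "branch lengths")
})

test_that("graphs with unknown nodes are rejected", {
  f <- cherry_forest()
  g <- interaction_graph(edges = rbind(c("a", "nope")))
  expect_error(min_flip_cost(f, g), "not Present leaves")
  fa <- read_forest(text = "((a[&&NHX:P=1],b[&&NHX:P=0])r);")
  gb <- interaction_graph(edges = rbind(c("a", "b")))
  expect_error(min_flip_cost(fa, gb), "not Present leaves")
})
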