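# The history-graph model: the parity rule, blocking loops, and the
# equivalence between loop-freeness and the existence of consistent times.

test_that("constructs applies the parity rule", {
  f <- cherry_forest()
  # no flips: nodes only
  h0 <- network_history(f)
  g0 <- constructs(h0)
  expect_setequal(g0$nodes, c("a", "b", "c"))
  expect_equal(nrow(g0$edges), 0L)
  # single leaf-level flip
  h1 <- network_history(f, data.frame(a = "a", b = "c"))
  expect_identical(edge_keys(constructs(h1)), "a|c")
  # two flips along the same root path cancel: {r,c} + {a,c} leaves only b-c
  h2 <- network_history(f, data.frame(a = c("r", "a"), b = c("c", "c")))
  expect_identical(edge_keys(constructs(h2)), "b|c")
})

test_that("constructs respects orientation and flip-order insensitivity", {
  f <- cherry_forest()
  hd <- network_history(f, data.frame(a = "r", b = "c", orientation = "->"),
                        directed = TRUE)
  expect_identical(edge_keys(constructs(hd)), c("a|c", "b|c"))
  hr <- network_history(f, data.frame(a = "r", b = "c", orientation = "<-"),
                        directed = TRUE)
  expect_identical(edge_keys(constructs(hr)), c("c|a", "c|b"))
  # set semantics: permuting flips never changes the graph
  set.seed(7)
  for (i in 1:20) {
    h <- rand_history(incomparable_only = TRUE)
    hp <- network_history(h$forest, h$flips[sample(nrow(h$flips)), , drop = FALSE])
    expect_same_graph(constructs(h), constructs(hp))
  }
})

test_that("flips into a node's own root path imply self-loops and error out", {
  f <- cherry_forest()
  h <- network_history(f, data.frame(a = "r", b = "a"))
  expect_error(constructs(h), "self-loops")
  expect_error(network_history(f, data.frame(a = "a", b = "a")), "self-flip")
})

test_that("blocking loops of length 1 and 2 are found, leaf flips never block", {
  f <- read_forest(text = "(((a,b)u,c)r);\n((d,e)q);")
  # k = 1: flip between a node and its proper descendant
  h1 <- network_history(f, data.frame(a = "u", b = "a"))
  l1 <- find_blocking_loop(h1)
  expect_equal(nrow(l1), 1L)
  expect_true(is_proper_ancestor(f, l1$u, l1$v))
  # k = 2 across trees: u1 anc v0, u0 anc v1
  h2 <- network_history(f, data.frame(a = c("u", "q"), b = c("d", "a")))
  l2 <- find_blocking_loop(h2)
  expect_equal(nrow(l2), 2L)
  expect_true(all(is_proper_ancestor(
    f, l2$u[c(2, 1)], l2$v)))
  # leaf-only flips cannot block
  h3 <- network_history(f, data.frame(a = c("a", "b", "d"), b = c("d", "e", "c")))
  expect_null(find_blocking_loop(h3))
  expect_true(is_valid_history(h3))
})

test_that("assign_times produces consistent times exactly on valid histories", {
  f <- read_forest(text = "(((a,b)u,c)r);\n((d,e)q);")
  h <- network_history(f, data.frame(a = c("a", "u"), b = c("d", "q")))
  tm <- assign_times(h)
  expect_true(tm$success)
  # conditions: tc < td, children inherit, flips within both intervals
  idx <- function(x) match(x, f$label)
  expect_true(all(tm$tc < tm$td))
  kids <- which(!is.na(f$parent))
  expect_equal(unname(tm$tc[kids]), unname(tm$td[f$parent[kids]]))
  for (k in seq_len(nrow(h$flips))) {
    for (e in c(h$flips$a[k], h$flips$b[k])) {
      expect_gte(tm$tflip[k], tm$tc[[e]])
      expect_lt(tm$tflip[k], tm$td[[e]])
    }
  }
  # 1-blocking loop: stalls with a certificate
  hb <- network_history(f, data.frame(a = "u", b = "b"))
  tb <- assign_times(hb)
  expect_false(tb$success)
  expect_true(length(tb$stalled) >= 1)
})

test_that("loop-freeness and timeability coincide on random histories", {
  # the two sides of the validity characterization, plus the brute-force
  # enumeration of the definition, agree case by case
  set.seed(42)
  n_valid <- 0
  for (i in 1:300) {
    h <- rand_history()
    v_loop <- is.null(find_blocking_loop(h))
    v_time <- assign_times(h)$success
    v_bf <- !brute_force_blocking_check(h)
    expect_equal(v_loop, v_time)
    expect_equal(v_loop, v_bf)
    n_valid <- n_valid + v_loop
  }
  expect_gt(n_valid, 50)          # the sample must exercise both outcomes
  expect_lt(n_valid, 250)
})

test_that("placing every interaction at its leaf pair is always valid", {
  set.seed(13)
  for (i in 1:20) {
    f <- rand_forest(sample(2:3, 1), sample(0:3, 1))
    g <- rand_graph(f, max_edges = 4)
    if (!nrow(g$edges)) next
    h <- network_history(f, data.frame(a = g$edges[, 1], b = g$edges[, 2]))
    expect_true(is_valid_history(h))
    expect_same_graph(constructs(h), g)
  }
})
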