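test_that("family score matches the closed-form parent-free expression", {
  set.seed(2)
  child <- rbinom(1000, 1, 0.5)
  p <- mean(child)
  h_nats <- -(p * log(p) + (1 - p) * log(1 - p))
  expect_equal(family_score(child), -1000 * h_nats - log(1000) / 2,
               tolerance = 1e-10)
})

test_that("a deterministic parent beats the empty family; noise parents lose", {
  set.seed(7)
  parent <- rbinom(1000, 1, 0.5)
  child <- parent
  expect_gt(family_score(child, cbind(parent)), family_score(child))
  # adding an irrelevant random parent to the saturated true model
  noise <- rbinom(1000, 1, 0.5)
  expect_lt(family_score(child, cbind(parent, noise)),
            family_score(child, cbind(parent)))
  expect_error(family_score(child, matrix(0L, 1000, 9)), "max_parents")
})

test_that("greedy search attains the exhaustive 3-node optimum on chains", {
  set.seed(12)
  n <- 5000L
  x <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(x, rbinom(n, 1, 0.1)))
  z <- as.integer(xor(y, rbinom(n, 1, 0.1)))
  values <- cbind(x = x, y = y, z = z)
  g <- learn_structure(values, restarts = 2, seed = 1)
  best_oracle <- max(vapply(oracle_all_dags_3(), function(e)
    oracle_dag_score(values, e), numeric(1)))
  expect_equal(g$score, best_oracle, tolerance = 1e-9)
  expect_setequal(skeleton_key(g$edges$parent, g$edges$child),
                  c("x|y", "y|z"))
})

test_that("independent fair coins produce an empty graph", {
  set.seed(30)
  values <- matrix(rbinom(5000 * 5, 1, 0.5), ncol = 5,
                   dimnames = list(NULL, letters[1:5]))
  g <- learn_structure(values, restarts = 1, seed = 3)
  expect_equal(nrow(g$edges), 0L)
})

test_that("structure learning is deterministic given the seed", {
  syn <- small_ensemble()
  ds <- concatenate_ensemble(list(syn$ensemble[[1]]))
  g1 <- learn_structure(ds, restarts = 2, seed = 5)
  g2 <- learn_structure(ds, restarts = 2, seed = 5)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$score, g2$score)
})

test_that("total score decomposes into family scores and edges stay acyclic", {
  set.seed(9)
  syn <- small_ensemble()
  g <- learn_structure(concatenate_ensemble(syn$ensemble), restarts = 1,
                       seed = 2)
  expect_equal(g$score, sum(g$node_score), tolerance = 1e-9)
  # acyclicity via topological elimination
  edges <- g$edges
  nodes <- g$nodes
  repeat {
    sinks <- setdiff(nodes, edges$parent)
    if (!length(sinks)) break
    edges <- edges[!(edges$child %in% sinks), , drop = FALSE]
    nodes <- setdiff(nodes, sinks)
    if (!nrow(edges)) break
  }
  expect_equal(nrow(edges), 0L)
})

test_that("constant columns are rejected or dropped as requested", {
  m <- cbind(a = rbinom(100, 1, 0.5), b = rbinom(100, 1, 0.5), c = 0L)
  expect_error(learn_structure(m), "constant")
  expect_warning(g <- learn_structure(m, on_constant = "drop"), "c")
  expect_setequal(g$nodes, c("a", "b"))
})

test_that("edge strengths are pairwise MI and weighted degree obeys the handshake identity", {
  set.seed(19)
  x <- rep(c(1L, 0L), each = 250L)
  values <- cbind(a = x, b = x,
                  c = as.integer(xor(x, rbinom(500, 1, 0.3))),
                  d = rbinom(500, 1, 0.5))
  g <- learn_structure(values, restarts = 1, seed = 1)
  g <- edge_strengths(g, values)
  for (i in seq_len(nrow(g$edges))) {
    expect_lt(abs(g$edges$strength_bits[i] -
                    pairwise_mi(values[, g$edges$parent[i]],
                                values[, g$edges$child[i]])), 1e-12)
    expect_gte(g$edges$strength_bits[i], 0)
  }
  # identical balanced columns joined by an edge score 1 bit
  ab <- g$edges[g$edges$parent %in% c("a", "b") &
                  g$edges$child %in% c("a", "b"), ]
  expect_equal(ab$strength_bits, 1.0)
  d <- weighted_degree(g)
  expect_equal(sum(d), 2 * sum(g$edges$strength_bits), tolerance = 1e-12)
  iso <- setdiff(g$nodes, c(g$edges$parent, g$edges$child))
  expect_true(all(d[iso] == 0))
})

test_that("neighborhoods are parents plus children, and export round trips", {
  edges <- data.frame(parent = c("a", "c"), child = c("b", "b"),
                      stringsAsFactors = FALSE)
  g <- structure(list(nodes = c("a", "b", "c", "d"), edges = edges,
                      node_score = NULL, score = NA_real_,
                      max_parents = 3L), class = "universal_graph")
  expect_setequal(graph_neighbors(g, "b"), c("a", "c"))
  expect_equal(graph_neighbors(g, "d"), character(0))
  expect_error(graph_neighbors(g, "zz"), "not in graph")
  g$edges$strength_bits <- c(0.5, 0.3)
  expect_equal(unname(weighted_degree(g)["b"]), 0.8)
  path <- withr::local_tempfile()
  write_graph_tsv(g, path)
  back <- read_graph_tsv(paste0(path, "_edges.tsv"), nodes = g$nodes)
  expect_equal(back$edges$parent, edges$parent)
  expect_equal(back$edges$strength_bits, c(0.5, 0.3))
})

test_that("planted sparse DAGs are recovered with high skeleton F1", {
  # 8 nodes, <= 2 parents, strong dependencies
  f1s <- vapply(1:8, function(s) {
    set.seed(400 + s)
    planted <- planted_dag_data(n = 4000L, flip = 0.08)
    g <- learn_structure(planted$values, restarts = 2, seed = s)
    skeleton_f1(g$edges, planted$truth)
  }, numeric(1))
  expect_gte(mean(f1s), 0.8)
})
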