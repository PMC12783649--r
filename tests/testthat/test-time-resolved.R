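test_that("windowed MI closed forms and bounds checks hold", {
  x <- rep(c(1L, 0L), 100)   # balanced up to the odd window length
  expect_equal(windowed_mi(x, x, t = 100L, half_width = 50L), 1.0,
               tolerance = 1e-4)
  expect_equal(windowed_mi(rep(0L, 200), x, 100L, 50L), 0.0)
  expect_error(windowed_mi(x, x, t = 10L, half_width = 50L), "bounds")
})

test_that("windowed MI matches the contingency oracle over many random windows", {
  set.seed(44)
  n <- 2000L
  x <- rbinom(n, 1, 0.4)
  y <- as.integer((x + rbinom(n, 1, 0.3)) %% 2L)
  for (i in 1:200) {
    d <- sample(20:200, 1)
    t <- sample((d + 1L):(n - d), 1)
    w <- (t - d):(t + d)
    expect_equal(windowed_mi(x, y, t, d), oracle_mi(x[w], y[w]),
                 tolerance = 1e-12)
  }
})

test_that("window optimization scans the grid and breaks ties upward", {
  grid <- window_grid(sizes = c(150L, 300L, 450L), stride = 10L)
  # identical streams: every window near 1 bit, and an exact tie
  # (all-zero MI for every size) resolves to the largest window
  x <- rep(c(1L, 0L), 500)
  opt <- optimize_window(x, x, t = 500L, grid = grid)
  expect_equal(opt$mi, 1.0, tolerance = 1e-4)
  tie <- optimize_window(rep(0L, 1000), rep(0L, 1000), t = 500L,
                         grid = grid)
  expect_equal(tie$mi, 0.0)
  expect_equal(tie$size, 450L)
  # near the start only the smallest window fits
  opt2 <- optimize_window(x, x, t = 76L, grid = grid)
  expect_equal(opt2$size, 150L)
  # before that, nothing fits
  opt3 <- optimize_window(x, x, t = 10L, grid = grid)
  expect_true(is.na(opt3$size) && is.na(opt3$mi))
})

test_that("a planted coupled block is matched by a window of its length", {
  set.seed(3)
  n <- 2000L
  t0 <- 1000L
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.5)
  block <- (t0 - 150L):(t0 + 149L)               # coupled block length 300
  y[block] <- x[block]
  grid <- window_grid()
  opt <- optimize_window(x, y, t0, grid)
  # verify the maximizer against explicit evaluation of every grid size
  per_size <- vapply(grid$sizes, function(s)
    windowed_mi(x, y, t0, s %/% 2L), numeric(1))
  expect_equal(opt$mi, max(per_size))
  expect_equal(opt$size, grid$sizes[max(which(per_size == max(per_size)))])
  expect_lte(abs(opt$size - 300L), 150L)
})

test_that("TRAC traces are additive over stored per-edge traces", {
  syn <- small_ensemble(seed = 23L)
  ds <- concatenate_ensemble(syn$ensemble)
  g <- learn_structure(ds, restarts = 1, seed = 1)
  grid <- window_grid(stride = 50L)
  tr <- trac_traces(syn$ensemble[[1]], g, grid)
  for (node in tr$nodes) {
    inc <- which(tr$edges$parent == node | tr$edges$child == node)
    if (!length(inc)) next
    expect_identical(tr$D[, node],
                     unname(rowSums(tr$edge_mi[, inc, drop = FALSE])))
  }
  # spot-check stored edge values against direct windowed MI calls
  vals <- syn$ensemble[[1]]$values
  for (e in sample(nrow(tr$edges), min(4L, nrow(tr$edges)))) {
    for (ti in sample(which(!is.na(tr$edge_mi[, e])), 5L)) {
      expect_lt(abs(tr$edge_mi[ti, e] -
                      windowed_mi(vals[, tr$edges$parent[e]],
                                  vals[, tr$edges$child[e]],
                                  tr$times[ti],
                                  tr$chosen_window[ti, e] %/% 2L)), 1e-12)
    }
  }
})

test_that("trace values are bounded by the neighborhood size and never negative", {
  syn <- small_ensemble(seed = 29L)
  g <- learn_structure(concatenate_ensemble(syn$ensemble), restarts = 1,
                       seed = 2)
  tr <- trac_traces(syn$ensemble[[2]], g, window_grid(stride = 100L))
  for (node in tr$nodes) {
    v <- tr$D[, node]
    deg <- length(graph_neighbors(g, node))
    expect_true(all(v[!is.na(v)] >= 0))
    expect_true(all(v[!is.na(v)] <= deg + 1e-9))
  }
  # boundary times where no window fits are missing, not zero
  expect_true(all(is.na(tr$D[tr$times < min(tr$grid$sizes) / 2, ])))
})

test_that("halving the stride preserves values at shared evaluation times", {
  syn <- small_ensemble(seed = 31L)
  g <- learn_structure(concatenate_ensemble(syn$ensemble), restarts = 1,
                       seed = 4)
  tr100 <- trac_traces(syn$ensemble[[1]], g, window_grid(stride = 100L))
  tr50 <- trac_traces(syn$ensemble[[1]], g, window_grid(stride = 50L))
  shared <- match(tr100$times, tr50$times)
  expect_identical(tr50$D[shared, ], tr100$D)
})

test_that("independent streams stay below one bit of weighted degree", {
  set.seed(55)
  ok <- vapply(1:5, function(s) {
    set.seed(500 + s)
    m <- matrix(rbinom(6000 * 10, 1, 0.5), ncol = 10,
                dimnames = list(NULL, sprintf("A:ALA:%d_A:LEU:%d",
                                              1:10 * 7, 300 + 1:10 * 7)))
    fp <- fingerprint(m)
    # a fixed ring topology over the ten streams
    edges <- data.frame(parent = colnames(m),
                        child = colnames(m)[c(2:10, 1)],
                        stringsAsFactors = FALSE)
    g <- structure(list(nodes = colnames(m), edges = edges,
                        node_score = NULL, score = NA_real_,
                        max_parents = 3L), class = "universal_graph")
    tr <- trac_traces(fp, g, window_grid(stride = 50L))
    max(tr$D, na.rm = TRUE) < 1
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("shuffling time collapses transition peaks to the bias floor", {
  syn <- small_ensemble(seed = 61L)
  fp <- syn$ensemble[[1]]
  g <- learn_structure(concatenate_ensemble(syn$ensemble), restarts = 1,
                       seed = 6)
  grid <- window_grid(stride = 100L)
  tr <- trac_traces(fp, g, grid)
  set.seed(1)
  shuffled <- apply(fp$values, 2L, sample)  # break each stream's timing
  colnames(shuffled) <- fp$contact_labels
  tr_shuf <- trac_traces(fingerprint(shuffled, "shuffled"), g, grid)
  expect_lt(max(tr_shuf$D, na.rm = TRUE), max(tr$D, na.rm = TRUE) / 2)
})
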