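bump <- function(center, height, width, times) {
  height * exp(-((times - center) / width)^2)
}

test_that("find_peaks reports threshold-exceeding local maxima in time order", {
  times <- seq(1, 2000, by = 10)
  one <- bump(800, 1.5, 100, times)
  p <- find_peaks(one, times, threshold = 1.0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$time, 801)
  expect_equal(p$amplitude, 1.5, tolerance = 1e-3)  # apex between grid points
  expect_equal(nrow(find_peaks(bump(800, 0.5, 100, times), times, 1.0)), 0L)
  two <- bump(500, 1.2, 60, times) + bump(1500, 1.4, 60, times)
  p2 <- find_peaks(two, times, 1.0, min_separation = 200L)
  expect_equal(nrow(p2), 2L)
  expect_true(all(diff(p2$time) > 0))
})

test_that("close conflicting maxima keep the higher; plateaus report centers", {
  times <- seq(1, 1000, by = 10)
  v <- bump(400, 1.2, 50, times) + bump(520, 1.6, 50, times)
  p <- find_peaks(v, times, 1.0, min_separation = 400L)
  expect_equal(nrow(p), 1L)
  expect_equal(p$amplitude, max(v))
  # plateau: flat top of five evaluation points
  v2 <- c(rep(0, 10), rep(1.5, 5), rep(0, 10))
  t2 <- seq_along(v2) * 10
  p2 <- find_peaks(v2, t2, 1.0)
  expect_equal(p2$time, 130)  # center of points 11..15
})

test_that("peak detection is threshold-monotone", {
  set.seed(77)
  times <- seq(1, 3000, by = 10)
  v <- bump(500, 1.8, 80, times) + bump(1500, 1.1, 80, times) +
    bump(2500, 2.4, 80, times)
  lo <- find_peaks(v, times, 0.9, min_separation = 300L)
  hi <- find_peaks(v, times, 2.0, min_separation = 300L)
  expect_true(all(hi$time %in% lo$time))
  expect_lte(nrow(hi), nrow(lo))
})

fake_traces <- function(amp_matrix, times = seq(1, 5000, by = 10),
                        peak_times = NULL) {
  nodes <- rownames(amp_matrix)
  lapply(seq_len(ncol(amp_matrix)), function(k) {
    D <- vapply(nodes, function(nd) {
      ctr <- if (is.null(peak_times)) 2500 else peak_times[nd, k]
      bump(ctr, amp_matrix[nd, k], 100, times)
    }, numeric(length(times)))
    structure(list(times = times, nodes = nodes, D = D,
                   edges = data.frame(parent = character(),
                                      child = character()),
                   edge_mi = NULL, chosen_window = NULL,
                   trajectory_id = sprintf("t%d", k),
                   grid = window_grid(stride = 10L)),
              class = "trac_traces")
  })
}

test_that("ranking is by prevalence first, then mean amplitude, then label", {
  amp <- rbind(a = c(0.5, 1.8, 1.9), b = c(1.2, 1.3, 1.4),
               c = c(1.8, 1.8, 1.8), d = c(0.2, 0.3, 0.2))
  rk <- rank_contacts(fake_traces(amp), threshold = 1.0)
  # b and c are above in 3/3 and outrank a (2/3) regardless of amplitude;
  # their tie is resolved by mean amplitude: c (1.8) over b (1.3)
  expect_equal(rk$ranking$node, c("c", "b", "a", "d"))
  # all-below-threshold input still yields a total ranking
  rk2 <- rank_contacts(fake_traces(amp / 10), threshold = 1.0)
  expect_equal(nrow(rk2$ranking), 4L)
  expect_equal(rk2$ranking$node[1], "c")
})

test_that("key-TRAC selection enforces all three criteria", {
  amp <- rbind(a = c(1.5, 1.6, 1.7),   # everywhere above, one peak
               b = c(1.5, 1.6, 0.4),   # misses one trajectory
               c = c(1.5, 1.6, 1.7))   # everywhere above, many peaks
  traces <- fake_traces(amp)
  # give node c five separated peaks per trajectory
  for (k in seq_along(traces)) {
    tm <- traces[[k]]$times
    traces[[k]]$D[, "c"] <- Reduce(`+`, lapply(1:5 * 800, function(ctr)
      bump(ctr, 1.7, 60, tm)))
  }
  rk <- rank_contacts(traces, 1.0)
  pk <- ensemble_peaks(traces, 1.0, min_separation = 300L)
  sel <- select_key_tracs(rk, pk, 1.0, max_peaks = 2L)
  expect_equal(sel, "a")
  sel2 <- select_key_tracs(rk, pk, 1.0, require_all_trajectories = FALSE,
                           max_peaks = 2L)
  expect_setequal(sel2, c("a", "b"))
})

test_that("the data-driven threshold is the pooled trace standard deviation", {
  amp <- rbind(a = c(1.5, 1.6, 1.7), b = c(0.5, 0.6, 0.7))
  traces <- fake_traces(amp)
  pooled <- unlist(lapply(traces, function(tr) tr$D[!is.na(tr$D)]))
  expect_equal(ensemble_std_threshold(traces), sd(pooled))
  expect_gt(ensemble_std_threshold(traces), 0)
})

test_that("precedence classification demands strict order in every trajectory", {
  amp <- rbind(a = c(1.5, 1.5, 1.5), b = c(1.5, 1.5, 1.5))
  pt <- rbind(a = c(1000, 1200, 900), b = c(2000, 2400, 1800))
  pk <- ensemble_peaks(fake_traces(amp, peak_times = pt), 1.0,
                       min_separation = 300L)
  ord <- classify_order(pk[["a"]], pk[["b"]])
  expect_equal(as.character(ord), "a_precedes_b")
  # antisymmetry
  expect_equal(as.character(classify_order(pk[["b"]], pk[["a"]])),
               "b_precedes_a")
  # one flipped trajectory breaks the order
  pt2 <- pt; pt2["b", 2] <- 600
  pk2 <- ensemble_peaks(fake_traces(amp, peak_times = pt2), 1.0,
                        min_separation = 300L)
  expect_equal(as.character(classify_order(pk2[["a"]], pk2[["b"]])),
               "unordered")
  # simultaneous first peaks are unordered
  pt3 <- pt; pt3["b", ] <- pt3["a", ]
  pk3 <- ensemble_peaks(fake_traces(amp, peak_times = pt3), 1.0,
                        min_separation = 300L)
  expect_equal(as.character(classify_order(pk3[["a"]], pk3[["b"]])),
               "unordered")
})

test_that("trajectories lacking peaks are excluded and counted", {
  amp <- rbind(a = c(1.5, 1.5, 1.5), b = c(1.5, 1.5, 0.2))
  pt <- rbind(a = c(1000, 1200, 900), b = c(2000, 2400, 1800))
  pk <- ensemble_peaks(fake_traces(amp, peak_times = pt), 1.0,
                       min_separation = 300L)
  ord <- classify_order(pk[["a"]], pk[["b"]])
  expect_equal(as.character(ord), "a_precedes_b")
  expect_equal(attr(ord, "n_excluded"), 1L)
  none <- lapply(pk[["b"]], function(x) x[0, ])
  expect_error(classify_order(pk[["a"]], none), "shared")
})

test_that("connectors are common neighbors excluding the hubs", {
  edges <- data.frame(parent = c("a", "b", "a"),
                      child = c("c", "c", "b"),
                      stringsAsFactors = FALSE)
  g <- structure(list(nodes = c("a", "b", "c", "d"), edges = edges,
                      node_score = NULL, score = NA_real_,
                      max_parents = 3L), class = "universal_graph")
  expect_equal(find_connectors(g, "a", "b"), "c")
  expect_equal(find_connectors(g, "a", "d"), character(0))
  expect_false(any(c("a", "b") %in% find_connectors(g, "a", "b")))
  expect_error(find_connectors(g, "a", "zz"), "not in graph")
})
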