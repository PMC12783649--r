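# Time-resolved re-parametrization of the universal graph: sliding-window
# mutual information along one trajectory, window-size optimization over
# a grid, and per-node TRAC traces D_i(t).

#' Candidate window grid for sliding-window MI
#'
#' Sizes are FULL window widths in time steps (the window at time t is
#' [t - size/2, t + size/2]); the default grid spans 150 to 1050 steps.
#'
#' @param sizes even full window widths, ascending.
#' @param stride evaluation stride in frames.
#' @return object of class \code{"window_grid"}.
#' @export
window_grid <- function(sizes = seq(150L, 1050L, by = 150L), stride = 10L) {
  sizes <- as.integer(sizes)
  if (any(sizes %% 2L != 0L)) {
    stop("window sizes must be even (full widths 2*delta)", call. = FALSE)
  }
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("window sizes must be strictly ascending", call. = FALSE)
  }
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(sizes = sizes, stride = as.integer(stride)),
            class = "window_grid")
}

#' Sliding-window mutual information at one time point
#'
#' Plug-in MI (bits) of two binary streams restricted to the window
#' [t - half_width, t + half_width]: MI = H(x_w) + H(y_w) - H(x_w, y_w).
#'
#' @param x,y binary streams of equal length.
#' @param t 1-based center frame.
#' @param half_width delta, in frames; the full window must lie inside
#'   the trajectory.
#' @return MI in bits.
#' @export
windowed_mi <- function(x, y, t, half_width) {
  n <- length(x)
  if (length(y) != n) stop("streams differ in length", call. = FALSE)
  lo <- t - half_width
  hi <- t + half_width
  if (lo < 1L || hi > n) {
    stop(sprintf("window [%d, %d] exceeds trajectory bounds [1, %d]",
                 lo, hi, n), call. = FALSE)
  }
  pairwise_mi(x[lo:hi], y[lo:hi])
}

# MI of one edge at all eval times for one half width, via prefix sums.
# Returns NA at infeasible times.
edge_mi_at_times <- function(cx, cy, cxy, ts, half_width, n) {
  lo <- ts - half_width
  hi <- ts + half_width
  ok <- lo >= 1L & hi <= n
  out <- rep(NA_real_, length(ts))
  if (!any(ok)) return(out)
  lo <- lo[ok]; hi <- hi[ok]
  w <- hi - lo + 1L
  s11 <- cxy[hi + 1L] - cxy[lo]
  sx <- cx[hi + 1L] - cx[lo]
  sy <- cy[hi + 1L] - cy[lo]
  out[ok] <- mi_from_counts(s11, sx - s11, sy - s11, w - sx - sy + s11)
  out
}

#' Optimal-window MI at one time point
#'
#' Evaluates [windowed_mi()] for every feasible grid size at time t and
#' returns the maximizer; ties are broken toward the largest feasible
#' window (small windows inflate the plug-in estimate).
#'
#' @param x,y binary streams.
#' @param t 1-based center frame.
#' @param grid a [window_grid()].
#' @return list with \code{size} (chosen full width) and \code{mi}
#'   (bits); both NA when no grid size fits at t.
#' @export
optimize_window <- function(x, y, t, grid = window_grid()) {
  stopifnot(inherits(grid, "window_grid"))
  n <- length(x)
  best_mi <- NA_real_
  best_size <- NA_integer_
  for (size in grid$sizes) {       # ascending: ties resolve to largest
    d <- size %/% 2L
    if (t - d < 1L || t + d > n) next
    mi <- windowed_mi(x, y, t, d)
    if (is.na(best_mi) || mi >= best_mi) {
      best_mi <- mi
      best_size <- size
    }
  }
  list(size = best_size, mi = best_mi)
}

# Optimized MI for one edge at all eval times (vectorized over t per
# window size). Returns list(mi, size) vectors with NA where no window fits.
edge_trace <- function(x, y, ts, grid) {
  n <- length(x)
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  cxy <- c(0, cumsum(x * y))
  mi_best <- rep(NA_real_, length(ts))
  size_best <- rep(NA_integer_, length(ts))
  for (size in grid$sizes) {
    d <- size %/% 2L
    mi <- edge_mi_at_times(cx, cy, cxy, ts, d, n)
    upd <- !is.na(mi) & (is.na(mi_best) | mi >= mi_best)
    mi_best[upd] <- mi[upd]
    size_best[upd] <- size
  }
  list(mi = mi_best, size = size_best)
}

#' Time-resolved allosteric community traces for one trajectory
#'
#' Re-parametrizes the universal graph along a single trajectory: for
#' every graph edge, the sliding-window MI (optimized over the window
#' grid) is evaluated on a uniform time stride; the TRAC trace of node i
#' is then D_i(t) = sum over graph neighbors j of MI_t(i, j | delta).
#' Per-edge traces are retained so the additivity identity can be
#' audited. Times where no grid window fits are reported as missing.
#'
#' @param x a [fingerprint()] restricted to the contact set C. Graph
#'   nodes absent from the matrix are treated as constant-zero columns
#'   with a warning.
#' @param graph a \code{universal_graph}.
#' @param grid a [window_grid()].
#' @return object of class \code{"trac_traces"}: evaluation times,
#'   per-edge MI matrix (times x edges), chosen window sizes, and the
#'   node trace matrix D (times x nodes).
#' @export
trac_traces <- function(x, graph, grid = window_grid()) {
  stopifnot(inherits(x, "fingerprint"), inherits(graph, "universal_graph"),
            inherits(grid, "window_grid"))
  n <- nrow(x$values)
  ts <- seq.int(1L, n, by = grid$stride)
  values <- x$values
  missing <- setdiff(graph$nodes, colnames(values))
  if (length(missing)) {
    warning("graph nodes absent from fingerprint treated as constant zero: ",
            paste(missing, collapse = ", "), call. = FALSE)
    zero <- matrix(0L, nrow = n, ncol = length(missing),
                   dimnames = list(NULL, missing))
    values <- cbind(values, zero)
  }
  edges <- graph$edges
  ne <- nrow(edges)
  edge_mi <- matrix(NA_real_, nrow = length(ts), ncol = ne)
  edge_size <- matrix(NA_integer_, nrow = length(ts), ncol = ne)
  if (ne) {
    colnames(edge_mi) <- paste(edges$parent, edges$child, sep = " -> ")
    colnames(edge_size) <- colnames(edge_mi)
    for (e in seq_len(ne)) {
      tr <- edge_trace(values[, edges$parent[e]], values[, edges$child[e]],
                       ts, grid)
      edge_mi[, e] <- tr$mi
      edge_size[, e] <- tr$size
    }
  }
  D <- matrix(NA_real_, nrow = length(ts), ncol = length(graph$nodes),
              dimnames = list(NULL, graph$nodes))
  for (i in seq_along(graph$nodes)) {
    node <- graph$nodes[i]
    inc <- which(edges$parent == node | edges$child == node)
    if (!length(inc)) {
      # empty neighborhood: valid all-zero trace wherever windows fit
      feas <- if (ne) !is.na(edge_mi[, 1L]) else
        (ts - grid$sizes[1L] %/% 2L >= 1L) &
        (ts + grid$sizes[1L] %/% 2L <= n)
      D[feas, i] <- 0
    } else if (length(inc) == 1L) {
      D[, i] <- edge_mi[, inc]
    } else {
      D[, i] <- rowSums(edge_mi[, inc, drop = FALSE])
    }
  }
  structure(list(times = ts, nodes = graph$nodes, D = D,
                 edges = edges, edge_mi = edge_mi,
                 chosen_window = edge_size,
                 trajectory_id = x$trajectory_id,
                 grid = grid),
            class = "trac_traces")
}

#' @export
print.trac_traces <- function(x, ...) {
  cat(sprintf("TRAC traces '%s': %d nodes, %d edges, %d evaluation times (stride %d)\n",
              x$trajectory_id, length(x$nodes), nrow(x$edges),
              length(x$times), x$grid$stride))
  invisible(x)
}

#' Export TRAC traces as long-format CSV plus per-node summary
#'
#' Writes \code{<path>_edges.csv} (parent, child, t, window, mi_bits)
#' and \code{<path>_nodes.csv} (node, max D_i(t), argmax t).
#'
#' @param x a \code{trac_traces} object.
#' @param path base path.
#' @export
write_trac_csv <- function(x, path) {
  stopifnot(inherits(x, "trac_traces"))
  ne <- nrow(x$edges)
  long <- do.call(rbind, lapply(seq_len(ne), function(e) {
    data.frame(parent = x$edges$parent[e], child = x$edges$child[e],
               t = x$times, window = x$chosen_window[, e],
               mi_bits = x$edge_mi[, e], stringsAsFactors = FALSE)
  }))
  if (is.null(long)) {
    long <- data.frame(parent = character(), child = character(),
                       t = integer(), window = integer(),
                       mi_bits = numeric())
  }
  utils::write.csv(long, paste0(path, "_edges.csv"), row.names = FALSE)
  amax <- apply(x$D, 2L, function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_)
    else c(max(v, na.rm = TRUE), x$times[which.max(v)])
  })
  utils::write.csv(data.frame(node = x$nodes,
                              max_D = amax[1L, ], argmax_t = amax[2L, ]),
                   paste0(path, "_nodes.csv"), row.names = FALSE)
  invisible(path)
}
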