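# Peak detection on TRAC traces, ensemble-wide ranking of contacts,
# key-TRAC selection by the three reproducibility criteria,
# enabler/effector precedence classification, and connector contacts.

#' Detect peaks in one node's TRAC trace
#'
#' Peaks are local maxima above \code{threshold} bits; of two maxima
#' closer than \code{min_separation} frames, the higher one is kept.
#' Plateau maxima report the center time.
#'
#' @param values trace values on a uniform stride (NA = not evaluable).
#' @param times evaluation times (frames) matching \code{values}.
#' @param threshold amplitude threshold in bits (default 1.0).
#' @param min_separation minimum distance between retained peaks,
#'   in frames.
#' @return data.frame with columns \code{time} (strictly increasing)
#'   and \code{amplitude}; zero rows when nothing exceeds the threshold.
#' @export
find_peaks <- function(values, times, threshold = 1.0,
                       min_separation = 0L) {
  stopifnot(length(values) == length(times))
  ok <- !is.na(values)
  v <- values[ok]
  tt <- times[ok]
  n <- length(v)
  empty <- data.frame(time = numeric(0), amplitude = numeric(0))
  if (n == 0L) return(empty)
  # local maxima with plateau handling: runs of equal value whose
  # neighbors on both sides are strictly lower (or absent)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  is_max <- vapply(seq_len(nr), function(i) {
    left <- if (i == 1L) -Inf else r$values[i - 1L]
    right <- if (i == nr) -Inf else r$values[i + 1L]
    r$values[i] > left && r$values[i] > right
  }, logical(1))
  cand <- which(is_max & r$values > threshold)
  if (!length(cand)) return(empty)
  center <- (starts[cand] + ends[cand]) %/% 2L
  peaks <- data.frame(time = tt[center], amplitude = r$values[cand])
  if (min_separation > 0L && nrow(peaks) > 1L) {
    keep <- logical(nrow(peaks))
    ord <- order(-peaks$amplitude, peaks$time)
    for (i in ord) {
      if (!any(keep & abs(peaks$time - peaks$time[i]) < min_separation)) {
        keep[i] <- TRUE
      }
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  peaks <- peaks[order(peaks$time), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Data-driven amplitude threshold for an ensemble
#'
#' The "about one standard deviation" alternative to the fixed 1-bit
#' threshold: the standard deviation of all evaluated trace values
#' across all nodes and trajectories.
#'
#' @param traces list of \code{trac_traces}.
#' @return threshold in bits.
#' @export
ensemble_std_threshold <- function(traces) {
  stats::sd(unlist(lapply(traces, function(tr) tr$D[!is.na(tr$D)])))
}

#' Default peak separation for a window grid
#'
#' Twice the largest grid window, so a single transition event is not
#' double-counted as two peaks.
#' @param grid a [window_grid()].
#' @export
default_min_separation <- function(grid) 2L * max(grid$sizes)

#' Rank contacts across a trajectory ensemble
#'
#' The amplitude of a node in a trajectory is the maximum of D_i(t).
#' Primary ranking key: number of trajectories with amplitude above
#' \code{threshold} (descending); secondary: mean amplitude
#' (descending); ties broken by label.
#'
#' @param traces list of \code{trac_traces}, one per trajectory, sharing
#'   a node set.
#' @param threshold amplitude threshold in bits (default 1.0).
#' @return list with \code{amplitudes} (nodes x trajectories),
#'   \code{above} (boolean overlay), and \code{ranking} (data.frame in
#'   rank order: node, n_above, mean_amplitude).
#' @export
rank_contacts <- function(traces, threshold = 1.0) {
  stopifnot(length(traces) >= 1L)
  nodes <- traces[[1L]]$nodes
  for (tr in traces) {
    if (!identical(tr$nodes, nodes)) {
      stop("all trajectories must share the same node set", call. = FALSE)
    }
  }
  amp <- vapply(traces, function(tr) {
    apply(tr$D, 2L, function(v) if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
  }, numeric(length(nodes)))
  amp <- matrix(amp, nrow = length(nodes),
                dimnames = list(nodes,
                                vapply(traces, `[[`, character(1),
                                       "trajectory_id")))
  above <- amp > threshold
  n_above <- rowSums(above)
  mean_amp <- rowMeans(amp)
  ord <- order(-n_above, -mean_amp, nodes)
  ranking <- data.frame(node = nodes[ord], n_above = n_above[ord],
                        mean_amplitude = mean_amp[ord],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(amplitudes = amp, above = above, ranking = ranking,
                 threshold = threshold),
            class = "ranking_matrix")
}

#' @export
print.ranking_matrix <- function(x, ...) {
  cat(sprintf("Contact ranking: %d nodes x %d trajectories (threshold %.2f bits)\n",
              nrow(x$amplitudes), ncol(x$amplitudes), x$threshold))
  print(utils::head(x$ranking, 10L))
  invisible(x)
}

#' Per-node, per-trajectory peak sets for an ensemble
#'
#' @param traces list of \code{trac_traces}.
#' @param threshold peak amplitude threshold in bits.
#' @param min_separation see [find_peaks()]; defaults to twice the
#'   largest grid window of the first trajectory.
#' @return nested list: \code{peaksets[[node]][[trajectory_id]]} is a
#'   [find_peaks()] data.frame.
#' @export
ensemble_peaks <- function(traces, threshold = 1.0,
                           min_separation = NULL) {
  if (is.null(min_separation)) {
    min_separation <- default_min_separation(traces[[1L]]$grid)
  }
  nodes <- traces[[1L]]$nodes
  out <- lapply(nodes, function(node) {
    per <- lapply(traces, function(tr) {
      find_peaks(tr$D[, node], tr$times, threshold, min_separation)
    })
    names(per) <- vapply(traces, `[[`, character(1), "trajectory_id")
    per
  })
  names(out) <- nodes
  out
}

#' Select key TRACs by the three reproducibility criteria
#'
#' A node is a key TRAC iff (1) its amplitude exceeds the threshold,
#' (2) it does so in all trajectories (configurable), and (3) it shows
#' no more than \code{max_peaks} peaks in any single trajectory --
#' the signature of a macro-state transition rather than microstate
#' noise.
#'
#' @param ranking a \code{ranking_matrix} from [rank_contacts()].
#' @param peaksets output of [ensemble_peaks()] at the same threshold.
#' @param amplitude_threshold bits; 1.0 for key-TRAC selection, 2.0 is
#'   the preset for the evolutionary analysis handoff.
#' @param require_all_trajectories criterion (2) switch.
#' @param max_peaks criterion (3) cap (default 2).
#' @return character vector of selected nodes (possibly empty, with a
#'   warning).
#' @export
select_key_tracs <- function(ranking, peaksets,
                             amplitude_threshold = 1.0,
                             require_all_trajectories = TRUE,
                             max_peaks = 2L) {
  stopifnot(inherits(ranking, "ranking_matrix"))
  n_traj <- ncol(ranking$amplitudes)
  above <- ranking$amplitudes > amplitude_threshold
  sel <- vapply(rownames(ranking$amplitudes), function(node) {
    n_above <- sum(above[node, ])
    crit2 <- if (require_all_trajectories) n_above == n_traj else n_above >= 1L
    npk <- vapply(peaksets[[node]], nrow, integer(1))
    crit13 <- n_above >= 1L && all(npk <= max_peaks)
    crit2 && crit13
  }, logical(1))
  out <- rownames(ranking$amplitudes)[sel]
  if (!length(out)) {
    warning("no node satisfies all key-TRAC criteria", call. = FALSE)
  }
  out
}

#' Classify the temporal order of two nodes' signals
#'
#' Across all trajectories where both nodes show at least one peak,
#' compares the FIRST peak times: \code{"a_precedes_b"} iff a's first
#' peak is strictly earlier in every such trajectory (the
#' enabler/effector assignment); symmetrically for b; otherwise
#' \code{"unordered"}. Trajectories where either node lacks peaks are
#' excluded and counted.
#'
#' @param peaks_a,peaks_b per-trajectory peak lists for the two nodes
#'   (elements of [ensemble_peaks()] output).
#' @return character label with attribute \code{n_excluded}.
#' @export
classify_order <- function(peaks_a, peaks_b) {
  traj <- intersect(names(peaks_a), names(peaks_b))
  both <- traj[vapply(traj, function(k) {
    nrow(peaks_a[[k]]) > 0L && nrow(peaks_b[[k]]) > 0L
  }, logical(1))]
  if (!length(both)) {
    stop("no shared trajectory where both nodes show peaks", call. = FALSE)
  }
  ta <- vapply(both, function(k) peaks_a[[k]]$time[1L], numeric(1))
  tb <- vapply(both, function(k) peaks_b[[k]]$time[1L], numeric(1))
  label <- if (all(ta < tb)) "a_precedes_b"
           else if (all(tb < ta)) "b_precedes_a"
           else "unordered"
  structure(label, n_excluded = length(traj) - length(both))
}

#' Connector contacts between two hub nodes
#'
#' All nodes (excluding the hubs themselves) adjacent in the universal
#' graph, direction ignored, to BOTH hubs -- the contacts that link an
#' enabler and an effector community.
#'
#' @param graph a \code{universal_graph}.
#' @param hub_a,hub_b hub node labels.
#' @return character vector of connector labels.
#' @export
find_connectors <- function(graph, hub_a, hub_b) {
  na <- graph_neighbors(graph, hub_a)
  nb <- graph_neighbors(graph, hub_b)
  setdiff(intersect(na, nb), c(hub_a, hub_b))
}

#' Export a ranking matrix as CSV
#'
#' Amplitude matrix with the boolean overlay appended, mirroring the
#' heat-map presentation of ensemble rankings.
#'
#' @param x a \code{ranking_matrix}.
#' @param path output path.
#' @export
write_ranking_csv <- function(x, path) {
  stopifnot(inherits(x, "ranking_matrix"))
  amp <- as.data.frame(x$amplitudes, check.names = FALSE)
  ab <- as.data.frame(x$above, check.names = FALSE)
  names(ab) <- paste0(names(ab), "_above")
  utils::write.csv(cbind(node = rownames(amp), amp, ab), path,
                   row.names = FALSE)
  invisible(path)
}
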