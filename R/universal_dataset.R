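# Construction of the universal dataset D^U: transition-proxy smoothing
# and change-point location, enriched subsampling around the transition,
# and plain concatenation.

#' Centered simple moving average
#'
#' Centered window of \code{window} frames; at the edges the window
#' shrinks to the available frames.
#'
#' @param x numeric trace, one value per frame.
#' @param window full window width in frames (>= 1).
#' @return smoothed trace of the same length.
#' @export
moving_average <- function(x, window = 1L) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window exceeds trace length", call. = FALSE)
  if (window == 1L) return(x)
  h1 <- (window - 1L) %/% 2L
  h2 <- window - 1L - h1
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate a single transition in a 1-D proxy trace
#'
#' Least-squares single change point: the split minimizing the total
#' within-segment sum of squared deviations of the (optionally smoothed)
#' trace. Used on, e.g., a TM3-TM6 interhelical distance trace whose
#' drop marks the macro-state transition.
#'
#' @param x numeric trace (length >= 10).
#' @param smoothing_window moving-average window applied before the scan
#'   (default 1 = no smoothing).
#' @return the 1-based index of the first frame of the second segment,
#'   or \code{NA_integer_} (with a warning) for a constant trace where no
#'   transition exists.
#' @export
detect_transition <- function(x, smoothing_window = 1L) {
  n <- length(x)
  if (n < 10L) stop("trace too short for change-point detection", call. = FALSE)
  s <- moving_average(x, smoothing_window)
  if (max(s) == min(s)) {
    warning("constant trace: no transition found", call. = FALSE)
    return(NA_integer_)
  }
  # two-segment SSE via prefix sums, evaluated at every split in O(n)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)            # last index of first segment
  sse1 <- cs2[k] - cs[k]^2 / k
  sum2 <- cs[n] - cs[k]
  sse2 <- (cs2[n] - cs2[k]) - sum2^2 / (n - k)
  k_best <- which.min(sse1 + sse2)
  k_best + 1L
}

#' Universal dataset container
#'
#' Rows x contacts binary matrix aggregated over an ensemble, with
#' per-row provenance (trajectory id, 1-based source frame).
#'
#' @keywords internal
universal_dataset <- function(values, provenance, sampling_config = list()) {
  stopifnot(nrow(values) == nrow(provenance))
  storage.mode(values) <- "integer"
  structure(list(values = values,
                 contact_labels = colnames(values),
                 provenance = provenance,
                 sampling_config = sampling_config),
            class = "universal_dataset")
}

#' @export
print.universal_dataset <- function(x, ...) {
  cat(sprintf("Universal dataset: %d rows x %d contacts from %d trajectories (%s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$provenance$trajectory_id)),
              if (length(x$sampling_config)) x$sampling_config$mode
              else "unspecified"))
  invisible(x)
}

check_dataset_budget <- function(n_rows, n_contacts,
                                 max_rows = 15000L, max_contacts = 1000L) {
  if (n_rows > max_rows || n_contacts > max_contacts) {
    warning(sprintf(paste0("dataset of %d rows x %d contacts exceeds the ",
                           "recommended budget (~%d rows, ~%d contacts) for ",
                           "tractable graph learning"),
                    n_rows, n_contacts, max_rows, max_contacts),
            call. = FALSE)
  }
  invisible(NULL)
}

#' Transition-enriched subsampling of an ensemble
#'
#' For each trajectory, draws \code{n_per_traj} frames uniformly with
#' replacement from a region of \code{region} frames centered at that
#' trajectory's transition point (clipped to the trajectory bounds), and
#' stacks the drawn rows in trajectory order. One seeded generator
#' stream per trajectory (seed + trajectory index) makes per-trajectory
#' draws reproducible independent of ensemble order.
#'
#' @param ensemble list of [fingerprint()] objects already restricted to
#'   the common contact set C.
#' @param transitions integer vector of per-trajectory transition frames
#'   (1-based), e.g. from [detect_transition()].
#' @param region total width of the sampling region in frames
#'   (default 5000, i.e. +/- 2500 around the transition).
#' @param n_per_traj frames drawn per trajectory.
#' @param seed integer seed.
#' @return a \code{universal_dataset} with per-row provenance.
#' @export
enriched_sample <- function(ensemble, transitions, region = 5000L,
                            n_per_traj, seed = 1L) {
  stopifnot(length(ensemble) >= 1L,
            length(transitions) == length(ensemble),
            n_per_traj >= 1L, region >= 1L)
  labels <- ensemble[[1L]]$contact_labels
  for (fp in ensemble) {
    if (!identical(fp$contact_labels, labels)) {
      stop("ensemble fingerprints must share an identical contact set; ",
           "restrict to C first", call. = FALSE)
    }
  }
  half <- region / 2
  blocks <- vector("list", length(ensemble))
  prov <- vector("list", length(ensemble))
  for (k in seq_along(ensemble)) {
    fp <- ensemble[[k]]
    n_frames <- nrow(fp$values)
    t_star <- transitions[k]
    if (is.na(t_star)) {
      stop("missing transition point for trajectory ", fp$trajectory_id,
           call. = FALSE)
    }
    lo <- max(1L, as.integer(ceiling(t_star - half)))
    hi <- min(n_frames, as.integer(floor(t_star + half - 1)))
    if (lo > hi) stop("sampling region empty after clipping for trajectory ",
                      fp$trajectory_id, call. = FALSE)
    rng <- local({
      set.seed(seed + k)
      sample(lo:hi, n_per_traj, replace = TRUE)
    })
    blocks[[k]] <- fp$values[rng, , drop = FALSE]
    prov[[k]] <- data.frame(trajectory_id = fp$trajectory_id,
                            source_frame = rng,
                            stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- labels
  provenance <- do.call(rbind, prov)
  check_dataset_budget(nrow(values), ncol(values))
  universal_dataset(values, provenance,
                    sampling_config = list(mode = "enriched",
                                           region = region,
                                           n_per_traj = n_per_traj,
                                           seed = seed))
}

#' Concatenate an ensemble into a universal dataset
#'
#' Stacks all frames of all trajectories in input order, recording
#' provenance. All fingerprints must share the contact set C; with
#' \code{zero_fill = TRUE} (union-mode feature combination) the label
#' union is used and absent contacts become zero columns.
#'
#' @param ensemble list of [fingerprint()] objects.
#' @param zero_fill allow differing label sets, filling absences with 0.
#' @return a \code{universal_dataset}.
#' @export
concatenate_ensemble <- function(ensemble, zero_fill = FALSE) {
  stopifnot(length(ensemble) >= 1L)
  labels <- ensemble[[1L]]$contact_labels
  if (zero_fill) {
    labels <- Reduce(union, lapply(ensemble, `[[`, "contact_labels"))
    ensemble <- lapply(ensemble, restrict_contacts, labels = labels,
                       zero_fill = TRUE)
  } else {
    for (fp in ensemble) {
      if (!identical(fp$contact_labels, labels)) {
        stop("irreconcilable contact sets; use zero_fill = TRUE for ",
             "union-mode combination", call. = FALSE)
      }
    }
  }
  values <- do.call(rbind, lapply(ensemble, `[[`, "values"))
  colnames(values) <- labels
  provenance <- do.call(rbind, lapply(ensemble, function(fp) {
    data.frame(trajectory_id = fp$trajectory_id,
               source_frame = seq_len(nrow(fp$values)),
               stringsAsFactors = FALSE)
  }))
  check_dataset_budget(nrow(values), ncol(values))
  universal_dataset(values, provenance,
                    sampling_config = list(mode = "concatenate"))
}

#' Read a 1-D transition-proxy trace from a text/CSV file
#'
#' Accepts a single-column file (one value per frame) or a CSV whose
#' last column holds the values.
#'
#' @param path input path.
#' @return numeric vector.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    as.numeric(df[[ncol(df)]])
  } else {
    as.numeric(scan(path, what = double(), quiet = TRUE,
                    comment.char = "#"))
  }
}

#' Write a universal dataset (values CSV + provenance sidecar CSV)
#'
#' @param x a \code{universal_dataset}.
#' @param path base path; writes \code{<path>.csv} and
#'   \code{<path>_provenance.csv}.
#' @export
write_universal_dataset <- function(x, path) {
  stopifnot(inherits(x, "universal_dataset"))
  utils::write.csv(as.data.frame(x$values, check.names = FALSE),
                   paste0(path, ".csv"), row.names = FALSE)
  utils::write.csv(x$provenance, paste0(path, "_provenance.csv"),
                   row.names = FALSE)
  invisible(path)
}
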