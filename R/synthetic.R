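# Synthetic fixtures with the statistical structure the method assumes:
# multi-trajectory binary contact ensembles with planted dependency
# communities switching at a coordinated macro-transition, plus labeled
# toy alignments with planted conserved and class-specific columns.

synthetic_contact_label <- function(i) {
  # plausible residue-pair labels spaced >1 apart so neighbor exclusion
  # never removes planted contacts
  sprintf("A:ALA:%d_A:LEU:%d", 10L + 3L * i, 110L + 3L * i)
}

#' Generate a synthetic multi-trajectory contact ensemble
#'
#' Each community follows a latent two-state signal that switches at its
#' assigned time (jittered per trajectory): members copy the latent
#' state with probability \code{coupling} and otherwise flip to a fair
#' coin. Background contacts are independent two-state Markov chains at
#' the baseline flip rate, so windowed MI faces realistic
#' autocorrelation. A transition-proxy trace (emulating a TM3-TM6
#' interhelical distance) steps down at the effector switch.
#'
#' The defaults are the reference study conditions used throughout the
#' package's tests: 12 trajectories of 8,000 frames over 40 contacts,
#' an enabler community of 5 contacts at coupling 0.95 switching at
#' frame 3,000 (jitter 200), an effector community of 5 switching at
#' 5,000, and 30 independent background contacts.
#'
#' @param n_trajectories,n_frames,n_contacts ensemble dimensions.
#' @param communities list of communities, each a list with \code{size},
#'   \code{coupling} in [0, 1], and \code{role} ("enabler" or
#'   "effector").
#' @param t_e,t_f enabler and effector switch frames (t_e < t_f).
#' @param jitter per-trajectory uniform jitter of switch times (frames).
#' @param baseline_flip per-frame flip probability of background Markov
#'   chains.
#' @param proxy_high,proxy_low,proxy_noise_sd transition-proxy levels
#'   (Angstrom-like units) and additive noise.
#' @param seed integer seed; the run is fully reproducible.
#' @return list with \code{ensemble} (list of [fingerprint()]),
#'   \code{traces} (list of numeric proxy traces), and \code{truth}
#'   (planted communities, per-trajectory switch times, parameters).
#' @export
generate_ensemble <- function(n_trajectories = 12L, n_frames = 8000L,
                              n_contacts = 40L,
                              communities = list(
                                list(size = 5L, coupling = 0.95,
                                     role = "enabler"),
                                list(size = 5L, coupling = 0.95,
                                     role = "effector")),
                              t_e = 3000L, t_f = 5000L, jitter = 200L,
                              baseline_flip = 0.02,
                              proxy_high = 12, proxy_low = 4,
                              proxy_noise_sd = 0.5,
                              seed = 1L) {
  sizes <- vapply(communities, function(cm) as.integer(cm$size), integer(1))
  if (sum(sizes) > n_contacts) {
    stop("community sizes exceed n_contacts", call. = FALSE)
  }
  if (t_e + jitter >= t_f - jitter) {
    stop("infeasible timing: enabler and effector switch windows overlap",
         call. = FALSE)
  }
  labels <- vapply(seq_len(n_contacts), synthetic_contact_label, character(1))
  membership <- rep("background", n_contacts)
  idx <- 0L
  comm_members <- vector("list", length(communities))
  for (ci in seq_along(communities)) {
    comm_members[[ci]] <- idx + seq_len(sizes[ci])
    membership[comm_members[[ci]]] <- paste0("community_", ci)
    idx <- idx + sizes[ci]
  }
  background <- which(membership == "background")
  set.seed(seed)
  ensemble <- vector("list", n_trajectories)
  traces <- vector("list", n_trajectories)
  switch_times <- matrix(NA_integer_, n_trajectories, length(communities))
  for (k in seq_len(n_trajectories)) {
    m <- matrix(0L, nrow = n_frames, ncol = n_contacts,
                dimnames = list(NULL, labels))
    te_k <- t_e + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
    tf_k <- t_f + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
    for (ci in seq_along(communities)) {
      cm <- communities[[ci]]
      t_switch <- if (identical(cm$role, "effector")) tf_k else te_k
      switch_times[k, ci] <- t_switch
      latent <- as.integer(seq_len(n_frames) < t_switch)
      for (j in comm_members[[ci]]) {
        copy <- stats::runif(n_frames) < cm$coupling
        noise <- as.integer(stats::runif(n_frames) < 0.5)
        m[, j] <- ifelse(copy, latent, noise)
      }
    }
    for (j in background) {
      flips <- stats::runif(n_frames) < baseline_flip
      start <- as.integer(stats::runif(1L) < 0.5)
      m[, j] <- (start + c(0L, cumsum(flips[-1L]))) %% 2L
    }
    ensemble[[k]] <- fingerprint(m, trajectory_id = sprintf("traj%02d", k))
    traces[[k]] <- ifelse(seq_len(n_frames) < tf_k, proxy_high, proxy_low) +
      stats::rnorm(n_frames, sd = proxy_noise_sd)
  }
  colnames(switch_times) <- paste0("community_", seq_along(communities))
  truth <- list(membership = stats::setNames(membership, labels),
                communities = lapply(comm_members, function(i) labels[i]),
                roles = vapply(communities, `[[`, character(1), "role"),
                switch_times = switch_times,
                coupling = vapply(communities, function(cm) cm$coupling,
                                  numeric(1)),
                t_e = t_e, t_f = t_f, jitter = jitter,
                baseline_flip = baseline_flip, seed = seed)
  list(ensemble = ensemble, traces = traces, truth = truth)
}

#' Generate a labeled toy alignment with planted column classes
#'
#' Conserved positions share one residue across all classes; positions
#' specific to a class carry a residue unique to that class (other
#' classes draw from a disjoint pool); background positions are sampled
#' from a per-position residue set of \code{background_diversity} types.
#'
#' @param n_per_class sequences per class.
#' @param classes class labels.
#' @param L alignment length.
#' @param conserved_positions positions planted as fully conserved.
#' @param specific_positions named list (class -> positions) of planted
#'   perfectly specific positions; all planted sets must be disjoint.
#' @param background_diversity number of residue types per background
#'   column (1 = invariant background).
#' @param seed integer seed.
#' @return list with \code{msa} (a [labeled_msa()]) and \code{truth}
#'   (the planted sets).
#' @export
generate_msa <- function(n_per_class = 6L, classes = c("D2", "D3", "B2"),
                         L = 30L,
                         conserved_positions = c(3L, 7L),
                         specific_positions = list(D2 = 12L, D3 = c(15L, 18L)),
                         background_diversity = 5L, seed = 1L) {
  planted <- c(conserved_positions, unlist(specific_positions,
                                           use.names = FALSE))
  if (anyDuplicated(planted)) {
    stop("planted position sets must be disjoint", call. = FALSE)
  }
  if (length(planted) && max(planted) > L) {
    stop("planted positions exceed alignment length", call. = FALSE)
  }
  if (!all(names(specific_positions) %in% classes)) {
    stop("specific_positions names must be class labels", call. = FALSE)
  }
  set.seed(seed)
  n_seq <- n_per_class * length(classes)
  cls <- rep(classes, each = n_per_class)
  m <- matrix("", nrow = n_seq, ncol = L)
  for (i in seq_len(L)) {
    pool <- sample(AA20, background_diversity)
    m[, i] <- sample(pool, n_seq, replace = TRUE)
  }
  for (i in conserved_positions) m[, i] <- sample(AA20, 1L)
  for (cl in names(specific_positions)) {
    for (i in specific_positions[[cl]]) {
      res <- sample(AA20)
      own <- res[1L]                     # unique to the target class
      other_pool <- res[2:4]             # disjoint pool for the rest
      m[cls == cl, i] <- own
      m[cls != cl, i] <- sample(other_pool, sum(cls != cl), replace = TRUE)
    }
  }
  seqs <- apply(m, 1L, paste0, collapse = "")
  names(seqs) <- sprintf("seq%02d|%s", seq_len(n_seq), cls)
  list(msa = labeled_msa(seqs, cls),
       truth = list(conserved = sort(conserved_positions),
                    specific = lapply(specific_positions, sort),
                    classes = classes, seed = seed))
}
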