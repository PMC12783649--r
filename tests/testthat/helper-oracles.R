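# Independent oracles used across the suite. Each is deliberately coded
# from first principles, on a different computational route than the
# implementation it checks.

# Plug-in MI oracle: builds the full 2x2 joint probability table with
# table() and sums p * log2(p / (px * py)) cell by cell.
oracle_mi <- function(x, y) {
  tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  as.numeric(total)
}

# Brute-force single change point: explicit two-segment SSE at every
# split, using mean() and sum() directly.
oracle_changepoint <- function(x) {
  n <- length(x)
  sse <- vapply(seq_len(n - 1L), function(k) {
    a <- x[1:k]
    b <- x[(k + 1L):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  which.min(sse) + 1L  # first index of the second segment
}

# All labeled DAGs on 3 nodes (25 of them): enumerate the 3^3 = 27
# orientation assignments of the three possible undirected pairs
# (absent / forward / backward) and drop the 2 cyclic triangles.
oracle_all_dags_3 <- function() {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  dags <- list()
  for (o1 in 0:2) for (o2 in 0:2) for (o3 in 0:2) {
    edges <- matrix(integer(0), nrow = 0L, ncol = 2L)
    orient <- c(o1, o2, o3)
    for (p in 1:3) {
      if (orient[p] == 1L) edges <- rbind(edges, pairs[[p]])
      if (orient[p] == 2L) edges <- rbind(edges, rev(pairs[[p]]))
    }
    if (!is.null(edges)) {
      # acyclic iff some permutation topologically orders every edge
      perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
      ok <- FALSE
      for (perm in perms) {
        pos <- match(1:3, perm)
        if (all(pos[edges[, 1L]] < pos[edges[, 2L]])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next  # cyclic
    }
    dags[[length(dags) + 1L]] <- edges
  }
  dags
}

# Total BIC score of an explicit 3-node DAG given as an edge matrix.
oracle_dag_score <- function(values, edges) {
  total <- 0
  for (child in 1:3) {
    parents <- if (is.null(edges)) integer(0) else edges[edges[, 2L] == child, 1L]
    total <- total + family_score(values[, child],
                                  if (length(parents))
                                    values[, parents, drop = FALSE]
                                  else NULL)
  }
  total
}

# Undirected skeleton F1 between an edge data.frame and a truth set of
# unordered label pairs (each "a|b" with a < b).
skeleton_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

skeleton_f1 <- function(edges, truth_keys) {
  found <- unique(skeleton_key(edges$parent, edges$child))
  tp <- length(intersect(found, truth_keys))
  if (tp == 0L) return(0)
  prec <- tp / length(found)
  rec <- tp / length(truth_keys)
  2 * prec * rec / (prec + rec)
}

# Planted sparse random DAG over 8 binary nodes with <= 2 parents and
# strong, faithful dependencies: single-parent children are noisy
# copies, two-parent children noisy ORs (every parent remains
# marginally informative). Returns the data and the skeleton truth.
planted_dag_data <- function(n, flip = 0.1) {
  p <- 8L
  values <- matrix(0L, n, p, dimnames = list(NULL, letters[1:p]))
  truth <- character(0)
  values[, 1] <- rbinom(n, 1, 0.5)
  for (j in 2:p) {
    n_pa <- min(sample(1:2, 1L), j - 1L)
    pa <- sample(seq_len(j - 1L), n_pa)
    sig <- if (n_pa == 1L) values[, pa]
           else as.integer(values[, pa[1L]] | values[, pa[2L]])
    values[, j] <- as.integer(xor(sig, rbinom(n, 1, flip)))
    truth <- c(truth, skeleton_key(letters[pa], letters[rep(j, n_pa)]))
  }
  list(values = values, truth = truth)
}

# Small random binary matrix with labeled columns, for property tests.
random_fingerprint <- function(n_frames, n_contacts, p1 = 0.5,
                               trajectory_id = "t") {
  m <- matrix(as.integer(runif(n_frames * n_contacts) < p1),
              nrow = n_frames,
              dimnames = list(NULL, sprintf("A:GLY:%d_A:VAL:%d",
                                            seq_len(n_contacts) * 5L,
                                            200L + seq_len(n_contacts) * 5L)))
  fingerprint(m, trajectory_id)
}

# Shared small synthetic ensemble (kept modest so module tests stay fast).
small_ensemble <- function(seed = 11L) {
  generate_ensemble(
    n_trajectories = 3L, n_frames = 3000L, n_contacts = 16L,
    communities = list(list(size = 4L, coupling = 0.95, role = "enabler"),
                       list(size = 4L, coupling = 0.95, role = "effector")),
    t_e = 1000L, t_f = 2000L, jitter = 100L, seed = seed)
}
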