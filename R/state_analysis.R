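# Conformational-state delineation: PCA of a selected contact
# subnetwork's fingerprint columns and seeded k-means partitioning of
# the score space, with states renumbered in order of first occurrence.

#' PCA projection of a contact subnetwork
#'
#' Column-centered (not scaled: unit-variance scaling of 0/1 columns
#' distorts rare contacts) principal component analysis via singular
#' value decomposition. Deterministic up to component sign; the sign is
#' fixed by making each loading vector's largest-magnitude entry
#' positive.
#'
#' @param x a [fingerprint()] restricted to the contact subset of
#'   interest (e.g. the combined enabler + effector subnetwork).
#' @param k number of components to retain (default 2).
#' @return object of class \code{"state_projection"}: \code{scores}
#'   (frames x k), \code{loadings} (contacts x k, orthonormal columns),
#'   \code{explained} (variance fractions of ALL components,
#'   non-increasing), and \code{center}.
#' @export
pca_project <- function(x, k = 2L) {
  stopifnot(inherits(x, "fingerprint"))
  m <- x$values
  storage.mode(m) <- "double"
  nonconst <- matrixStats_colAny(x$values)
  if (sum(nonconst) < k) {
    stop(sprintf("need >= %d non-constant contacts, found %d", k,
                 sum(nonconst)), call. = FALSE)
  }
  center <- colMeans(m)
  mc <- sweep(m, 2L, center)
  sv <- svd(mc)
  rank <- sum(sv$d > sv$d[1L] * 1e-10)
  if (k > rank) {
    stop(sprintf("k = %d exceeds matrix rank %d", k, rank), call. = FALSE)
  }
  var_all <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", seq_len(k))
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained = var_all, center = center,
                 trajectory_id = x$trajectory_id),
            class = "state_projection")
}

#' @export
print.state_projection <- function(x, ...) {
  cat(sprintf("State projection '%s': %d frames, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              x$trajectory_id, nrow(x$scores), ncol(x$scores),
              100 * x$explained[1L],
              if (length(x$explained) > 1L) 100 * x$explained[2L] else 0))
  invisible(x)
}

#' Assign conformational states by clustering the PCA scores
#'
#' Seeded k-means partition of the score space; state labels are
#' renumbered by first occurrence along the trajectory, so state 1
#' temporally precedes state 2, which precedes state 3.
#'
#' @param projection a \code{state_projection}.
#' @param n_states number of states (default 3).
#' @param seed integer seed for the k-means initialization.
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @return integer vector of state labels per frame (1 = earliest).
#' @export
assign_states <- function(projection, n_states = 3L, seed = 1L,
                          nstart = 10L, iter.max = 100L) {
  stopifnot(inherits(projection, "state_projection"), n_states >= 1L)
  scores <- projection$scores
  n_distinct <- nrow(unique(scores))
  if (n_states > n_distinct) {
    stop(sprintf("n_states = %d exceeds the %d distinct score points",
                 n_states, n_distinct), call. = FALSE)
  }
  if (n_states == 1L) return(rep(1L, nrow(scores)))
  set.seed(seed)
  km <- stats::kmeans(scores, centers = n_states, nstart = nstart,
                      iter.max = iter.max)
  raw <- km$cluster
  first_seen <- unique(raw)
  match(raw, first_seen)
}

#' Top-loading contacts per principal component
#'
#' @param projection a \code{state_projection}.
#' @param n number of contacts per component.
#' @return data.frame (component, rank, contact, loading).
#' @export
top_loading_contacts <- function(projection, n = 10L) {
  stopifnot(inherits(projection, "state_projection"))
  L <- projection$loadings
  do.call(rbind, lapply(seq_len(ncol(L)), function(j) {
    ord <- order(-abs(L[, j]))[seq_len(min(n, nrow(L)))]
    data.frame(component = colnames(L)[j], rank = seq_along(ord),
               contact = rownames(L)[ord], loading = L[ord, j],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Export a state projection (scores, loadings, labels) as CSV
#'
#' @param projection a \code{state_projection}.
#' @param path base path; writes \code{<path>_scores.csv} and
#'   \code{<path>_loadings.csv}.
#' @param labels optional per-frame state labels to append.
#' @export
write_states_csv <- function(projection, path, labels = NULL) {
  stopifnot(inherits(projection, "state_projection"))
  sc <- data.frame(frame = seq_len(nrow(projection$scores)),
                   projection$scores, check.names = FALSE)
  if (!is.null(labels)) sc$state <- labels
  utils::write.csv(sc, paste0(path, "_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(contact = rownames(projection$loadings),
                              projection$loadings, check.names = FALSE),
                   paste0(path, "_loadings.csv"), row.names = FALSE)
  invisible(path)
}
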