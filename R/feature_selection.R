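# Reduction of the full contact set to the significant set C:
# sequence-neighbor exclusion, pairwise mutual-information filtering,
# and combination of per-trajectory kept sets.

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Mutual information of a 2x2 contingency table (bits)
#'
#' Plug-in estimator from cell counts (n11, n10, n01, n00), log base 2,
#' with the 0 log 0 = 0 convention. Vectorized over counts.
#'
#' @keywords internal
mi_from_counts <- function(n11, n10, n01, n00) {
  # transposing the table leaves MI unchanged; canonicalize the
  # off-diagonal cells so MI(x, y) and MI(y, x) are bitwise identical
  lo <- pmin(n10, n01)
  n01 <- pmax(n10, n01)
  n10 <- lo
  n <- n11 + n10 + n01 + n00
  px1 <- (n11 + n10) / n
  py1 <- (n11 + n01) / n
  hx <- -(plogp(px1) + plogp(1 - px1))
  hy <- -(plogp(py1) + plogp(1 - py1))
  hxy <- -(plogp(n11 / n) + plogp(n10 / n) + plogp(n01 / n) + plogp(n00 / n))
  mi <- hx + hy - hxy
  pmax(mi, 0)  # guard tiny negative rounding
}

#' Pairwise mutual information between two binary columns
#'
#' Plug-in MI (bits) from the empirical 2x2 contingency table. Bounded by
#' min(H(x), H(y)) <= 1 bit for binary variables.
#'
#' @param x,y binary vectors of equal length.
#' @return mutual information in bits.
#' @export
pairwise_mi <- function(x, y) {
  if (length(x) != length(y)) {
    stop("columns differ in length: ", length(x), " vs ", length(y),
         call. = FALSE)
  }
  if (length(x) == 0L) stop("empty columns", call. = FALSE)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  mi_from_counts(n11, n10, n01, n00)
}

#' Full pairwise MI matrix of a binary matrix
#'
#' Computes all p x p plug-in MI values (bits) from cross-products of the
#' 0/1 columns; deterministic and identical to calling [pairwise_mi()] on
#' every pair.
#'
#' @param values frames x contacts 0/1 matrix.
#' @return symmetric p x p matrix of MI values with zero diagonal.
#' @export
mi_matrix <- function(values) {
  x <- values
  storage.mode(x) <- "double"
  n <- nrow(x)
  n11 <- crossprod(x)
  ones <- colSums(x)
  n10 <- outer(ones, ones, function(a, b) a) - n11  # x=1 & y=0
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  mi <- mi_from_counts(n11, n10, n01, n00)
  mi <- matrix(mi, ncol = ncol(x), dimnames = dimnames(n11))
  diag(mi) <- 0
  mi
}

#' Exclude contacts between sequence-neighboring residues
#'
#' Drops every intra-chain contact whose endpoints are within
#' \code{min_separation} residues of each other; inter-chain contacts are
#' always kept.
#'
#' @param x a [fingerprint()] object.
#' @param min_separation drop contacts with |resid_a - resid_b| <= this
#'   value when the endpoints share a chain. Default 1 (exclude i, i+/-1).
#' @return filtered [fingerprint()].
#' @export
exclude_neighbors <- function(x, min_separation = 1L) {
  stopifnot(inherits(x, "fingerprint"), min_separation >= 1L)
  if (ncol(x$values) == 0L) return(x)
  ends <- parse_contact_label(x$contact_labels)
  drop <- ends$chain_a == ends$chain_b &
    abs(ends$resid_a - ends$resid_b) <= min_separation
  keep_labels <- x$contact_labels[!drop]
  fingerprint(x$values[, keep_labels, drop = FALSE],
              x$trajectory_id, x$frame_time_step)
}

#' Filter contacts by maximum pairwise mutual information
#'
#' Within one trajectory, a contact is kept iff its maximum plug-in MI
#' with any other contact exceeds \code{threshold} bits. Constant columns
#' carry no information and are always dropped.
#'
#' @param x a [fingerprint()] object with at least two contacts.
#' @param threshold MI threshold in bits (default 0.01).
#' @return list with elements \code{fingerprint} (filtered matrix) and
#'   \code{report} (data.frame: label, trajectory, kept, reason, max_mi).
#' @export
mi_filter <- function(x, threshold = 0.01) {
  stopifnot(inherits(x, "fingerprint"))
  p <- ncol(x$values)
  if (p < 2L) stop("mi_filter needs at least two contacts", call. = FALSE)
  colvar <- matrixStats_colAny(x$values)  # TRUE if non-constant
  mi <- mi_matrix(x$values)
  max_mi <- apply(mi, 2L, max)
  kept <- max_mi > threshold & colvar
  reason <- rep(NA_character_, p)
  reason[!colvar] <- "constant"
  reason[colvar & !kept] <- "low-MI"
  report <- data.frame(label = x$contact_labels,
                       trajectory = x$trajectory_id,
                       kept = kept, reason = reason, max_mi = max_mi,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(fingerprint = fingerprint(x$values[, kept, drop = FALSE],
                                 x$trajectory_id, x$frame_time_step),
       report = report)
}

# TRUE per column iff the column is non-constant
matrixStats_colAny <- function(values) {
  if (nrow(values) == 0L) return(rep(FALSE, ncol(values)))
  s <- colSums(values)
  s > 0L & s < nrow(values)
}

#' Combine per-trajectory kept contact sets into the final set C
#'
#' @param kept_sets list of character vectors, one per trajectory.
#' @param mode \code{"intersection"} (default: kept in every trajectory)
#'   or \code{"union"} (kept in any; absent columns are later
#'   zero-filled).
#' @return character vector of contact labels, in the order of their
#'   first appearance.
#' @export
combine_features <- function(kept_sets, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(kept_sets) >= 1L)
  out <- if (mode == "intersection") Reduce(intersect, kept_sets)
         else Reduce(union, kept_sets)
  if (length(out) == 0L) {
    stop("feature combination produced an empty contact set; ",
         "consider relaxing the MI threshold", call. = FALSE)
  }
  out
}

#' Run neighbor exclusion and MI filtering across an ensemble
#'
#' Convenience wrapper applying [exclude_neighbors()] and [mi_filter()]
#' to each trajectory and combining the kept sets with
#' [combine_features()].
#'
#' @param ensemble list of [fingerprint()] objects.
#' @param min_separation see [exclude_neighbors()].
#' @param threshold see [mi_filter()].
#' @param mode see [combine_features()].
#' @return list with \code{contacts} (final set C) and \code{report}
#'   (row-bound per-trajectory reports).
#' @export
select_features <- function(ensemble, min_separation = 1L,
                            threshold = 0.01,
                            mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  res <- lapply(ensemble, function(fp) {
    mi_filter(exclude_neighbors(fp, min_separation), threshold)
  })
  kept_sets <- lapply(res, function(r) r$report$label[r$report$kept])
  list(contacts = combine_features(kept_sets, mode),
       report = do.call(rbind, lapply(res, `[[`, "report")))
}
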