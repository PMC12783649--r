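# Evolutionary analysis of alignment positions: Von Neumann entropy
# conservation scoring with a substitution-similarity density matrix,
# and the fully-conserved / perfectly-specific position classification
# with the specificity ratio rho = log2(|S|/|C|).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Unit-diagonal amino-acid similarity from BLOSUM50
#'
#' Raw BLOSUM entries are log-odds scores with negative values and are
#' unusable directly as similarities; they are min-max mapped to [0, 1]
#' (b' = (b - min)/(max - min)) and rescaled so diagonal entries are 1
#' (s_ab = b'_ab / sqrt(b'_aa b'_bb)), clipped to [0, 1].
#'
#' @return symmetric 20 x 20 similarity matrix over the standard amino
#'   acids with unit diagonal.
#' @export
blosum50_similarity <- function() {
  b <- get_blosum50()[AA20, AA20]
  bp <- (b - min(b)) / (max(b) - min(b))
  d <- sqrt(diag(bp))
  s <- bp / outer(d, d)
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  s
}

get_blosum50 <- function() {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}

#' Identity similarity matrix (20 amino acids)
#' @export
identity_similarity <- function() {
  diag(1, 20L, 20L, names = FALSE) |>
    `dimnames<-`(list(AA20, AA20))
}

#' Labeled multiple sequence alignment
#'
#' @param sequences character vector of aligned sequences (equal length,
#'   gap character \code{"-"}), optionally named.
#' @param classes per-sequence class label (e.g. receptor subtype).
#' @return object of class \code{"labeled_msa"} holding the residue
#'   matrix (sequences x columns) and the class labels.
#' @export
labeled_msa <- function(sequences, classes) {
  sequences <- toupper(as.character(sequences))
  stopifnot(length(sequences) == length(classes), length(sequences) >= 1L)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) {
    stop("aligned sequences must share one length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bad <- !(m %in% c(AA20, "-"))
  if (any(bad)) {
    stop("alignment contains non-standard characters: ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- names(sequences)
  structure(list(residues = m, classes = as.character(classes), L = L),
            class = "labeled_msa")
}

#' Read a labeled MSA from FASTA plus a class-label table
#'
#' @param fasta_path aligned FASTA file.
#' @param labels either a path to a two-column CSV (sequence id, class)
#'   or a named character vector id -> class; if NULL, the class is
#'   parsed from the id suffix after the last \code{"|"}.
#' @return a [labeled_msa()].
#' @export
read_labeled_msa <- function(fasta_path, labels = NULL) {
  aln <- Biostrings::readAAStringSet(fasta_path)
  seqs <- as.character(aln)
  ids <- names(aln)
  if (is.null(labels)) {
    cls <- sub("^.*\\|", "", ids)
  } else {
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      df <- utils::read.csv(labels, stringsAsFactors = FALSE)
      labels <- stats::setNames(as.character(df[[2L]]), df[[1L]])
    }
    cls <- unname(labels[ids])
    if (anyNA(cls)) {
      stop("missing class label for sequence(s): ",
           paste(ids[is.na(cls)], collapse = ", "), call. = FALSE)
    }
  }
  names(seqs) <- ids
  labeled_msa(seqs, cls)
}

#' Density matrix of one alignment column
#'
#' Gaps are dropped and residue frequencies renormalized; with P the
#' diagonal matrix of frequencies and S the unit-diagonal similarity,
#' the density matrix is rho = P^(1/2) S P^(1/2) / tr(P^(1/2) S P^(1/2)).
#' The symmetric construction guarantees a real, non-negative spectrum.
#'
#' @param column character vector of residues (one per sequence).
#' @param similarity 20 x 20 similarity matrix (default
#'   [blosum50_similarity()]).
#' @return 20 x 20 density matrix (trace 1), or NULL for an all-gap
#'   column.
#' @export
column_density_matrix <- function(column, similarity = blosum50_similarity()) {
  res <- column[column != "-"]
  if (!length(res)) return(NULL)
  f <- stats::setNames(numeric(20L), AA20)
  tab <- table(factor(res, levels = AA20))
  f[names(tab)] <- as.numeric(tab) / length(res)
  sf <- sqrt(f)
  m <- outer(sf, sf) * similarity[AA20, AA20]
  m / sum(diag(m))
}

#' Von Neumann entropy of a density matrix (base-20 logarithm)
#'
#' S = -sum(lambda * log20(lambda)) over the eigenvalues of rho, with
#' the 0 log 0 = 0 convention; eigenvalues below 1e-12 are treated as 0.
#' The base-20 logarithm makes the maximum attainable entropy 1
#' (uniform spectrum over the 20 amino acids).
#'
#' @param rho density matrix (symmetric, trace 1).
#' @return entropy in [0, 1].
#' @export
vn_entropy <- function(rho) {
  if (abs(sum(diag(rho)) - 1) > 1e-8) {
    stop("not a density matrix: trace differs from 1", call. = FALSE)
  }
  lambda <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 1e-12] <- 0
  pos <- lambda[lambda > 0]
  -sum(pos * log(pos) / log(20))
}

#' Per-column conservation profile of an alignment
#'
#' For every column, the Von Neumann entropy S_i of its density matrix
#' and the conservation score C_i = 1 - S_i (1 = invariant column).
#' All-gap columns are flagged missing; columns with more than 50% gaps
#' are flagged low-confidence.
#'
#' @param msa a [labeled_msa()].
#' @param similarity 20 x 20 similarity matrix.
#' @param annotations optional named list of position sets (e.g.
#'   central-contact, connector, neighborhood residues) recorded as
#'   logical columns for grouped score comparisons.
#' @return data.frame of class \code{"conservation_profile"}: position,
#'   entropy, score, gap_fraction, low_confidence, plus one logical
#'   column per annotation set.
#' @export
conservation_score <- function(msa, similarity = blosum50_similarity(),
                               annotations = NULL) {
  stopifnot(inherits(msa, "labeled_msa"))
  L <- msa$L
  entropy <- numeric(L)
  gap_fraction <- numeric(L)
  for (i in seq_len(L)) {
    col <- msa$residues[, i]
    gap_fraction[i] <- mean(col == "-")
    rho <- column_density_matrix(col, similarity)
    entropy[i] <- if (is.null(rho)) NA_real_ else vn_entropy(rho)
  }
  out <- data.frame(position = seq_len(L), entropy = entropy,
                    score = 1 - entropy, gap_fraction = gap_fraction,
                    low_confidence = gap_fraction > 0.5)
  for (nm in names(annotations)) {
    out[[nm]] <- out$position %in% annotations[[nm]]
  }
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Classify positions as fully conserved or perfectly specific
#'
#' Over a supplied position subset (e.g. the residues of a TRAC), a
#' position is FULLY CONSERVED iff one single residue type occurs in
#' every sequence of every class, and PERFECTLY SPECIFIC for the target
#' class iff all target-class sequences share one residue type that
#' never occurs at that position in any other class. By default any gap
#' disqualifies a position from either set.
#'
#' @param msa a [labeled_msa()].
#' @param positions 1-based alignment positions to classify.
#' @param target_class class label whose specific positions are sought.
#' @param allow_gaps if TRUE, gaps are ignored rather than
#'   disqualifying.
#' @return object of class \code{"specificity_result"}: the conserved
#'   and specific position sets and their counts.
#' @export
classify_positions <- function(msa, positions, target_class,
                               allow_gaps = FALSE) {
  stopifnot(inherits(msa, "labeled_msa"))
  if (!length(positions)) stop("empty position subset", call. = FALSE)
  if (any(positions < 1L | positions > msa$L)) {
    stop("positions outside the alignment", call. = FALSE)
  }
  if (!(target_class %in% msa$classes)) {
    stop("class not present in alignment: ", target_class, call. = FALSE)
  }
  in_target <- msa$classes == target_class
  conserved <- logical(length(positions))
  specific <- logical(length(positions))
  for (j in seq_along(positions)) {
    col <- msa$residues[, positions[j]]
    has_gap <- any(col == "-")
    if (has_gap && !allow_gaps) next
    cc <- col[col != "-"]
    if (!length(cc)) next
    conserved[j] <- length(unique(cc)) == 1L
    tgt <- col[in_target]
    oth <- col[!in_target]
    tgt_res <- unique(tgt[tgt != "-"])
    if (length(tgt_res) == 1L && !any(tgt == "-") &&
        !(tgt_res %in% oth)) {
      specific[j] <- TRUE
    }
  }
  # a position cannot be both: specific requires absence from other
  # classes, conserved requires identity across all
  specific <- specific & !conserved
  structure(list(positions = positions,
                 conserved = positions[conserved],
                 specific = positions[specific],
                 n_conserved = sum(conserved),
                 n_specific = sum(specific),
                 target_class = target_class),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("Specificity of class '%s' over %d positions: |C| = %d, |S| = %d, rho = %s\n",
              x$target_class, length(x$positions), x$n_conserved,
              x$n_specific, format(specificity_ratio(x))))
  invisible(x)
}

#' Specificity ratio rho = log2(|S| / |C|)
#'
#' Negative values denote position sets dominated by full conservation
#' (purifying selection), positive values sets dominated by
#' class-specific positions (adaptive selection). Degenerate counts
#' yield sentinels: |C| = 0 gives +Inf, |S| = 0 gives -Inf, both zero
#' gives NaN.
#'
#' @param result a \code{specificity_result}.
#' @return numeric ratio (possibly +/-Inf or NaN).
#' @export
specificity_ratio <- function(result) {
  stopifnot(inherits(result, "specificity_result"))
  s <- result$n_specific
  c_ <- result$n_conserved
  if (s == 0L && c_ == 0L) return(NaN)
  if (c_ == 0L) return(Inf)
  if (s == 0L) return(-Inf)
  log2(s / c_)
}

#' Export a conservation profile as CSV
#'
#' @param profile a \code{conservation_profile}.
#' @param path output path.
#' @export
write_conservation_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
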