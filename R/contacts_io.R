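# Parsing of GetContacts-style tab-separated contact records and their
# reduction to binary per-frame contact fingerprint matrices.

KNOWN_CONTACT_KINDS <- c("sb", "pc", "ps", "ts", "vdw", "hb", "hbbb", "hbsb",
                         "hbss", "wb", "wb2", "hblb", "hbls", "lwb", "lwb2")

#' Parse an atom identifier token
#'
#' Splits a \code{"CHAIN:RESNAME:RESID:ATOM"} token (the atom name is
#' optional) into its residue-level components; the atom name is dropped.
#'
#' @param token character vector of atom identifier tokens.
#' @return data.frame with columns \code{chain}, \code{resname},
#'   \code{resid} (integer).
#' @keywords internal
parse_atom_token <- function(token) {
  parts <- strsplit(token, ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3L, logical(1))
  if (any(bad)) {
    stop("malformed atom token(s): ",
         paste(token[bad], collapse = ", "), call. = FALSE)
  }
  chain <- vapply(parts, `[`, character(1), 1L)
  resname <- vapply(parts, `[`, character(1), 2L)
  resid_chr <- vapply(parts, `[`, character(1), 3L)
  resid <- suppressWarnings(as.integer(resid_chr))
  if (anyNA(resid)) {
    stop("unparsable residue index in token(s): ",
         paste(token[is.na(resid)], collapse = ", "), call. = FALSE)
  }
  data.frame(chain = chain, resname = resname, resid = resid,
             stringsAsFactors = FALSE)
}

#' Read a GetContacts-style contact file
#'
#' Reads the tab-separated per-frame interaction records produced by
#' contact-detection tools: one line per interaction with fields
#' \code{frame}, \code{interaction-type}, and two atom identifiers of the
#' form \code{"CHAIN:RESNAME:RESID:ATOM"}. Lines starting with \code{#}
#' are comments. Atom-level identifiers are reduced to residue level.
#'
#' @param path path to the contact file.
#' @return data.frame of contact records with columns \code{frame}
#'   (0-based integer), \code{kind}, and the two residue endpoints
#'   (\code{chain_a}, \code{resname_a}, \code{resid_a}, and likewise
#'   \code{_b}). Unknown interaction-type tokens are kept with kind
#'   \code{"other"} and a warning.
#' @export
read_getcontacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(frame = integer(), kind = character(),
                      chain_a = character(), resname_a = character(),
                      resid_a = integer(), chain_b = character(),
                      resname_b = character(), resid_b = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1L]
    stop(sprintf("parse error at line %d: expected >= 4 tab-separated fields, got %d",
                 line_no[bad], nf[bad]), call. = FALSE)
  }
  frame <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 1L)))
  if (anyNA(frame)) {
    bad <- which(is.na(frame))[1L]
    stop(sprintf("parse error at line %d: unparsable frame index", line_no[bad]),
         call. = FALSE)
  }
  if (any(frame < 0L)) {
    stop("negative frame index encountered", call. = FALSE)
  }
  kind <- vapply(fields, `[`, character(1), 2L)
  unknown <- !(kind %in% KNOWN_CONTACT_KINDS)
  if (any(unknown)) {
    warning("unknown interaction-type token(s): ",
            paste(unique(kind[unknown]), collapse = ", "),
            "; records kept with kind \"other\"", call. = FALSE)
    kind[unknown] <- "other"
  }
  tok_a <- vapply(fields, `[`, character(1), 3L)
  tok_b <- vapply(fields, `[`, character(1), 4L)
  a <- tryCatch(parse_atom_token(tok_a), error = function(e)
    stop("parse error in residue tokens: ", conditionMessage(e), call. = FALSE))
  b <- tryCatch(parse_atom_token(tok_b), error = function(e)
    stop("parse error in residue tokens: ", conditionMessage(e), call. = FALSE))
  same <- a$chain == b$chain & a$resid == b$resid
  if (any(same)) {
    stop(sprintf("parse error at line %d: contact joins a residue to itself",
                 line_no[which(same)[1L]]), call. = FALSE)
  }
  data.frame(frame = frame, kind = kind,
             chain_a = a$chain, resname_a = a$resname, resid_a = a$resid,
             chain_b = b$chain, resname_b = b$resname, resid_b = b$resid,
             stringsAsFactors = FALSE)
}

residue_token <- function(chain, resname, resid) {
  paste(chain, resname, resid, sep = ":")
}

#' Canonical residue-pair contact label
#'
#' Orders the two endpoints so that the endpoint with the smaller
#' \code{(chain, resid)} comes first, preventing duplicate columns for
#' \code{(a,b)} and \code{(b,a)}.
#'
#' @keywords internal
canonical_pair_label <- function(chain_a, resname_a, resid_a,
                                 chain_b, resname_b, resid_b) {
  swap <- (chain_b < chain_a) | (chain_b == chain_a & resid_b < resid_a)
  ta <- ifelse(swap, residue_token(chain_b, resname_b, resid_b),
               residue_token(chain_a, resname_a, resid_a))
  tb <- ifelse(swap, residue_token(chain_a, resname_a, resid_a),
               residue_token(chain_b, resname_b, resid_b))
  paste(ta, tb, sep = "_")
}

#' Split contact labels back into endpoint fields
#' @keywords internal
parse_contact_label <- function(labels) {
  base <- sub("@.*$", "", labels)  # strip any interaction-type suffix
  ends <- strsplit(base, "_", fixed = TRUE)
  bad <- lengths(ends) != 2L
  if (any(bad)) {
    stop("unparsable contact label(s): ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  a <- parse_atom_token(vapply(ends, `[`, character(1), 1L))
  b <- parse_atom_token(vapply(ends, `[`, character(1), 2L))
  names(a) <- paste0(names(a), "_a")
  names(b) <- paste0(names(b), "_b")
  cbind(a, b)
}

#' Construct a contact fingerprint matrix
#'
#' @param values frames x contacts matrix with entries in \{0, 1\};
#'   column names are the contact labels.
#' @param trajectory_id identifier of the source trajectory.
#' @param frame_time_step optional time per frame (ns).
#' @return object of class \code{"fingerprint"}.
#' @export
fingerprint <- function(values, trajectory_id = "traj",
                        frame_time_step = NULL) {
  values <- as.matrix(values)
  if (length(values) && !all(values %in% c(0, 1))) {
    stop("fingerprint entries must all be 0 or 1", call. = FALSE)
  }
  labels <- colnames(values)
  if (is.null(labels) && ncol(values) > 0L) {
    stop("fingerprint columns must carry contact labels", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate contact labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(values) <- "integer"
  structure(list(values = values,
                 contact_labels = labels,
                 trajectory_id = trajectory_id,
                 frame_time_step = frame_time_step),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("Contact fingerprint '%s': %d frames x %d contacts\n",
              x$trajectory_id, nrow(x$values), ncol(x$values)))
  if (!is.null(x$frame_time_step)) {
    cat(sprintf("  frame time step: %g ns\n", x$frame_time_step))
  }
  invisible(x)
}

#' @export
dim.fingerprint <- function(x) dim(x$values)

#' Binarize contact records into a fingerprint matrix
#'
#' Converts parsed contact records into a frames x contacts 0/1 matrix:
#' entry (f, c) is 1 iff any record for contact c exists at frame f.
#' With \code{collapse_types = TRUE} (the default) all interaction types
#' between the same residue pair map to one column, matching the
#' residue-pair granularity of the graph nodes; with the flag off each
#' (pair, type) combination keeps its own column (label suffix
#' \code{"@kind"}). Columns are ordered canonically by the (chain, resid)
#' of their endpoints.
#'
#' @param records data.frame as returned by [read_getcontacts()].
#' @param n_frames total number of frames in the trajectory.
#' @param collapse_types merge interaction types per residue pair.
#' @param trajectory_id identifier stored in the result.
#' @param frame_time_step optional time per frame (ns).
#' @return a [fingerprint()] object. Frames are 0-based in the records;
#'   row \code{f + 1} of the matrix corresponds to record frame \code{f}.
#' @export
binarize <- function(records, n_frames, collapse_types = TRUE,
                     trajectory_id = "traj", frame_time_step = NULL) {
  stopifnot(n_frames >= 1L)
  if (nrow(records) && max(records$frame) >= n_frames) {
    stop(sprintf("record frame %d out of range for n_frames = %d",
                 max(records$frame), n_frames), call. = FALSE)
  }
  if (nrow(records) == 0L) {
    m <- matrix(0L, nrow = n_frames, ncol = 0L)
    return(fingerprint(m, trajectory_id, frame_time_step))
  }
  lab <- canonical_pair_label(records$chain_a, records$resname_a,
                              records$resid_a, records$chain_b,
                              records$resname_b, records$resid_b)
  if (!collapse_types) lab <- paste0(lab, "@", records$kind)
  ulab <- unique(lab)
  ends <- parse_contact_label(ulab)
  ord <- order(ends$chain_a, ends$resid_a, ends$chain_b, ends$resid_b, ulab)
  ulab <- ulab[ord]
  m <- matrix(0L, nrow = n_frames, ncol = length(ulab),
              dimnames = list(NULL, ulab))
  m[cbind(records$frame + 1L, match(lab, ulab))] <- 1L
  fingerprint(m, trajectory_id, frame_time_step)
}

FINGERPRINT_FORMAT <- "drumbeat-fingerprint v1"

#' Write a fingerprint matrix to a self-describing text file
#'
#' The format is plain text: a version line, header lines carrying the
#' trajectory id, dimensions and contact labels, then one row of 0/1
#' digits per frame. The round trip through [read_fingerprint()] is
#' lossless.
#'
#' @param x a [fingerprint()] object.
#' @param path output path.
#' @export
write_fingerprint <- function(x, path) {
  stopifnot(inherits(x, "fingerprint"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", FINGERPRINT_FORMAT), con)
  writeLines(paste0("#trajectory_id\t", x$trajectory_id), con)
  writeLines(paste0("#frame_time_step\t",
                    if (is.null(x$frame_time_step)) "NA"
                    else format(x$frame_time_step, digits = 17)), con)
  writeLines(paste0("#dims\t", nrow(x$values), "\t", ncol(x$values)), con)
  writeLines(paste0("#contacts\t",
                    paste(x$contact_labels, collapse = "\t")), con)
  if (nrow(x$values)) {
    writeLines(apply(x$values, 1L, paste0, collapse = ""), con)
  }
  invisible(path)
}

#' Read a fingerprint matrix written by [write_fingerprint()]
#'
#' @param path input path.
#' @return a [fingerprint()] object identical to the one written.
#' @export
read_fingerprint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || lines[1L] != paste0("#", FINGERPRINT_FORMAT)) {
    stop("not a ", FINGERPRINT_FORMAT, " file: ", path, call. = FALSE)
  }
  get_field <- function(i, key) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (parts[1L] != paste0("#", key)) {
      stop("format error: expected header '", key, "' at line ", i,
           call. = FALSE)
    }
    parts[-1L]
  }
  trajectory_id <- get_field(2L, "trajectory_id")
  fts <- get_field(3L, "frame_time_step")
  frame_time_step <- if (identical(fts, "NA")) NULL else as.numeric(fts)
  dims <- as.integer(get_field(4L, "dims"))
  labels <- get_field(5L, "contacts")
  if (length(labels) != dims[2L]) {
    stop("format error: label count does not match declared dimensions",
         call. = FALSE)
  }
  body <- lines[-(1:5)]
  if (length(body) != dims[1L]) {
    stop(sprintf("format error: expected %d data rows, found %d (truncated file?)",
                 dims[1L], length(body)), call. = FALSE)
  }
  if (dims[1L] == 0L || dims[2L] == 0L) {
    m <- matrix(0L, nrow = dims[1L], ncol = dims[2L],
                dimnames = if (dims[2L]) list(NULL, labels) else NULL)
    return(fingerprint(m, trajectory_id, frame_time_step))
  }
  if (any(nchar(body) != dims[2L])) {
    stop("format error: data row width does not match contact count",
         call. = FALSE)
  }
  bits <- matrix(as.integer(unlist(strsplit(body, "", fixed = TRUE),
                                   use.names = FALSE)),
                 nrow = dims[1L], ncol = dims[2L], byrow = TRUE,
                 dimnames = list(NULL, labels))
  fingerprint(bits, trajectory_id, frame_time_step)
}

#' Export a fingerprint matrix as CSV
#'
#' Interoperability export: frame index column plus one 0/1 column per
#' contact label.
#'
#' @param x a [fingerprint()] object.
#' @param path output path.
#' @export
export_fingerprint_csv <- function(x, path) {
  stopifnot(inherits(x, "fingerprint"))
  df <- data.frame(frame = seq_len(nrow(x$values)) - 1L, x$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Restrict a fingerprint to a contact subset
#'
#' @param x a [fingerprint()] object.
#' @param labels contact labels to keep, in the requested order.
#' @param zero_fill if TRUE, labels absent from \code{x} become all-zero
#'   columns (union-mode feature combination); if FALSE, absent labels
#'   are an error.
#' @return a [fingerprint()] with exactly \code{labels} as columns.
#' @export
restrict_contacts <- function(x, labels, zero_fill = FALSE) {
  stopifnot(inherits(x, "fingerprint"))
  missing <- setdiff(labels, x$contact_labels)
  if (length(missing) && !zero_fill) {
    stop("contacts absent from fingerprint: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- matrix(0L, nrow = nrow(x$values), ncol = length(labels),
              dimnames = list(NULL, labels))
  present <- intersect(labels, x$contact_labels)
  m[, present] <- x$values[, present, drop = FALSE]
  fingerprint(m, x$trajectory_id, x$frame_time_step)
}
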