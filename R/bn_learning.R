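# Score-based structure learning of the universal graph: a directed
# acyclic probabilistic model over binary contacts, scored with the
# decomposable BIC/MDL criterion and searched by greedy hill climbing
# with add/delete/reverse moves and seeded random restarts.

#' BIC/MDL family score of a binary child given binary parents
#'
#' Maximized multinomial log-likelihood (natural log) of the child given
#' each parent configuration, minus \code{(log n)/2} times the number of
#' free parameters (one per parent configuration for a binary child).
#' The total network score is the sum of family scores (decomposable).
#'
#' @param child binary vector.
#' @param parents binary matrix with one column per parent (or NULL /
#'   zero columns for the empty parent set).
#' @param max_parents guard on the parent-configuration table size.
#' @return family score (log scale; natural log).
#' @export
family_score <- function(child, parents = NULL, max_parents = 8L) {
  n <- length(child)
  k <- if (is.null(parents)) 0L else ncol(as.matrix(parents))
  if (k > max_parents) {
    stop(sprintf("parent set of size %d exceeds max_parents = %d", k,
                 max_parents), call. = FALSE)
  }
  if (k == 0L) {
    cfg <- rep(1L, n)
    q <- 1L
  } else {
    pm <- as.matrix(parents)
    cfg <- as.integer(pm %*% 2^(seq_len(k) - 1L)) + 1L
    q <- 2L^k
  }
  n1 <- tabulate2(cfg, q, child)
  nt <- tabulate(cfg, q)
  n0 <- nt - n1
  ll <- sum(xlogx(n1)) + sum(xlogx(n0)) - sum(xlogx(nt))
  ll - (log(n) / 2) * q
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# counts of child == 1 per configuration
tabulate2 <- function(cfg, q, child) {
  out <- rep(0L, q)
  t1 <- tabulate(cfg[child == 1L], q)
  if (length(t1)) out[seq_along(t1)] <- t1
  out
}

# ---- internal search machinery -------------------------------------------

# reachability: is there a directed path from `from` to `to` in adj list?
dag_has_path <- function(children_of, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(length(children_of))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    kids <- children_of[[v]]
    if (to %in% kids) return(TRUE)
    stack <- c(stack, kids[!seen[kids]])
  }
  FALSE
}

cached_family_score <- function(cache, values, child, parents) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  val <- cache[[key]]
  if (is.null(val)) {
    val <- family_score(values[, child],
                        if (length(parents)) values[, parents, drop = FALSE]
                        else NULL)
    cache[[key]] <- val
  }
  val
}

# One greedy hill climb from a given parent-set list.
hill_climb <- function(values, parents_of, max_parents, cache, eps = 1e-9) {
  p <- ncol(values)
  children_of <- lapply(seq_len(p), function(i)
    which(vapply(parents_of, function(pa) i %in% pa, logical(1))))
  fam <- vapply(seq_len(p), function(i)
    cached_family_score(cache, values, i, parents_of[[i]]), numeric(1))
  repeat {
    best <- list(delta = eps, move = NULL)
    for (child in seq_len(p)) {
      pa <- parents_of[[child]]
      # additions
      if (length(pa) < max_parents) {
        for (parent in seq_len(p)) {
          if (parent == child || parent %in% pa) next
          if (dag_has_path(children_of, child, parent)) next  # would cycle
          delta <- cached_family_score(cache, values, child, c(pa, parent)) -
            fam[child]
          if (delta > best$delta) {
            best <- list(delta = delta,
                         move = list(op = "add", child = child, parent = parent))
          }
        }
      }
      # deletions
      for (parent in pa) {
        delta <- cached_family_score(cache, values, child,
                                     setdiff(pa, parent)) - fam[child]
        if (delta > best$delta) {
          best <- list(delta = delta,
                       move = list(op = "delete", child = child, parent = parent))
        }
      }
      # reversals: parent -> child becomes child -> parent
      for (parent in pa) {
        if (length(parents_of[[parent]]) >= max_parents) next
        # reversed edge child -> parent cycles iff another path
        # parent ~> child survives removal of the original edge
        ch2 <- children_of
        ch2[[parent]] <- setdiff(ch2[[parent]], child)
        if (dag_has_path(ch2, parent, child)) next
        delta <- (cached_family_score(cache, values, child,
                                      setdiff(pa, parent)) - fam[child]) +
          (cached_family_score(cache, values, parent,
                               c(parents_of[[parent]], child)) - fam[parent])
        if (delta > best$delta) {
          best <- list(delta = delta,
                       move = list(op = "reverse", child = child, parent = parent))
        }
      }
    }
    if (is.null(best$move)) break
    m <- best$move
    if (m$op == "add") {
      parents_of[[m$child]] <- c(parents_of[[m$child]], m$parent)
      children_of[[m$parent]] <- c(children_of[[m$parent]], m$child)
    } else if (m$op == "delete") {
      parents_of[[m$child]] <- setdiff(parents_of[[m$child]], m$parent)
      children_of[[m$parent]] <- setdiff(children_of[[m$parent]], m$child)
    } else {
      parents_of[[m$child]] <- setdiff(parents_of[[m$child]], m$parent)
      children_of[[m$parent]] <- setdiff(children_of[[m$parent]], m$child)
      parents_of[[m$parent]] <- c(parents_of[[m$parent]], m$child)
      children_of[[m$child]] <- c(children_of[[m$child]], m$parent)
    }
    touched <- if (m$op == "reverse") c(m$child, m$parent) else m$child
    for (i in touched) {
      fam[i] <- cached_family_score(cache, values, i, parents_of[[i]])
    }
  }
  list(parents_of = parents_of, score = sum(fam))
}

# seeded random DAG: random topological order, each candidate edge kept
# with probability prob subject to the parent cap
random_parent_sets <- function(p, max_parents, prob = 0.1) {
  ord <- sample.int(p)
  parents_of <- vector("list", p)
  for (idx in seq_len(p)) parents_of[[idx]] <- integer(0)
  if (p >= 2L) {
    for (j in 2:p) {
      child <- ord[j]
      cand <- ord[seq_len(j - 1L)]
      pick <- cand[stats::runif(length(cand)) < prob]
      if (length(pick) > max_parents) pick <- pick[seq_len(max_parents)]
      parents_of[[child]] <- pick
    }
  }
  parents_of
}

#' Learn the universal graph by greedy score-based search
#'
#' Hill climbing over add/delete/reverse edge moves maximizing the total
#' BIC/MDL score, starting from the empty graph plus \code{restarts}
#' seeded random restarts; the best-scoring directed acyclic graph found
#' is returned. Deterministic given the seed.
#'
#' @param dataset a \code{universal_dataset}, or a plain 0/1 matrix with
#'   column names.
#' @param max_parents maximum parents per node (default 3).
#' @param restarts number of random restarts beyond the empty start.
#' @param seed integer seed for the restarts.
#' @param on_constant \code{"error"} (default) rejects constant columns,
#'   \code{"drop"} removes them with a warning.
#' @return object of class \code{"universal_graph"}: node labels, a
#'   data.frame of directed edges (parent, child), per-node family
#'   scores, and the total score.
#' @export
learn_structure <- function(dataset, max_parents = 3L, restarts = 2L,
                            seed = 1L, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  values <- if (inherits(dataset, "universal_dataset")) dataset$values
            else as.matrix(dataset)
  if (ncol(values) < 2L) stop("need at least two contacts", call. = FALSE)
  if (is.null(colnames(values))) {
    stop("dataset columns must carry contact labels", call. = FALSE)
  }
  const <- !matrixStats_colAny(values)
  if (any(const)) {
    if (on_constant == "error") {
      stop("constant column(s): ",
           paste(colnames(values)[const], collapse = ", "), call. = FALSE)
    }
    warning("dropping constant column(s): ",
            paste(colnames(values)[const], collapse = ", "), call. = FALSE)
    values <- values[, !const, drop = FALSE]
  }
  # deterministic node order for reproducible tie-breaking
  values <- values[, order(colnames(values)), drop = FALSE]
  p <- ncol(values)
  cache <- new.env(parent = emptyenv())
  empty <- lapply(seq_len(p), function(i) integer(0))
  best <- hill_climb(values, empty, max_parents, cache)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      set.seed(seed + r)
      start <- random_parent_sets(p, max_parents)
      cand <- hill_climb(values, start, max_parents, cache)
      if (cand$score > best$score + 1e-9) best <- cand
    }
  }
  labels <- colnames(values)
  edges <- do.call(rbind, lapply(seq_len(p), function(child) {
    pa <- best$parents_of[[child]]
    if (!length(pa)) return(NULL)
    data.frame(parent = labels[pa], child = labels[child],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  node_score <- vapply(seq_len(p), function(i)
    cached_family_score(cache, values, i, best$parents_of[[i]]), numeric(1))
  names(node_score) <- labels
  structure(list(nodes = labels, edges = edges,
                 node_score = node_score, score = best$score,
                 max_parents = max_parents),
            class = "universal_graph")
}

#' @export
print.universal_graph <- function(x, ...) {
  cat(sprintf("Universal graph: %d nodes, %d directed edges, score %.2f\n",
              length(x$nodes), nrow(x$edges), x$score))
  invisible(x)
}

#' Attach edge strengths (pairwise MI, bits) to a universal graph
#'
#' The strength of each directed edge is the plug-in mutual information
#' of its two endpoints over the full universal dataset, in bits --
#' the same units as the time-resolved layer.
#'
#' @param graph a \code{universal_graph}.
#' @param dataset the \code{universal_dataset} (or 0/1 matrix) the graph
#'   was learned from.
#' @return the graph with a \code{strength_bits} column on its edges.
#' @export
edge_strengths <- function(graph, dataset) {
  stopifnot(inherits(graph, "universal_graph"))
  values <- if (inherits(dataset, "universal_dataset")) dataset$values
            else as.matrix(dataset)
  missing <- setdiff(graph$nodes, colnames(values))
  if (length(missing)) {
    stop("graph nodes absent from dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  graph$edges$strength_bits <- vapply(seq_len(nrow(graph$edges)), function(i) {
    pairwise_mi(values[, graph$edges$parent[i]],
                values[, graph$edges$child[i]])
  }, numeric(1))
  graph
}

#' Weighted degree of every node
#'
#' D_i = sum of the strengths (bits) of all edges incident to node i,
#' direction ignored; isolated nodes score 0.
#'
#' @param graph a \code{universal_graph} with strengths attached.
#' @return named numeric vector over all nodes.
#' @export
weighted_degree <- function(graph) {
  stopifnot(inherits(graph, "universal_graph"))
  if (is.null(graph$edges$strength_bits)) {
    stop("edge strengths not computed; call edge_strengths() first",
         call. = FALSE)
  }
  d <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  for (i in seq_len(nrow(graph$edges))) {
    s <- graph$edges$strength_bits[i]
    d[graph$edges$parent[i]] <- d[graph$edges$parent[i]] + s
    d[graph$edges$child[i]] <- d[graph$edges$child[i]] + s
  }
  d
}

#' Graph neighborhood of a node
#'
#' The undirected neighborhood: parents and children of \code{node}
#' (moral co-parents excluded).
#'
#' @param graph a \code{universal_graph}.
#' @param node node label.
#' @return character vector of neighbor labels.
#' @export
graph_neighbors <- function(graph, node) {
  stopifnot(inherits(graph, "universal_graph"))
  if (!(node %in% graph$nodes)) {
    stop("node not in graph: ", node, call. = FALSE)
  }
  unique(c(graph$edges$parent[graph$edges$child == node],
           graph$edges$child[graph$edges$parent == node]))
}

#' Export a universal graph as edge-list TSV plus node table
#'
#' Writes \code{<path>_edges.tsv} (parent, child, strength_bits) and
#' \code{<path>_nodes.tsv} (node, weighted_degree).
#'
#' @param graph a \code{universal_graph} with strengths.
#' @param path base path.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "universal_graph"))
  utils::write.table(graph$edges, paste0(path, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- weighted_degree(graph)
  utils::write.table(data.frame(node = names(d), weighted_degree = d),
                     paste0(path, "_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a universal graph from an edge-list TSV
#'
#' @param path path to a \code{*_edges.tsv} written by
#'   [write_graph_tsv()].
#' @param nodes optional full node set (to preserve isolated nodes).
#' @return a \code{universal_graph}.
#' @export
read_graph_tsv <- function(path, nodes = NULL) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$parent, edges$child)))
  structure(list(nodes = nodes, edges = edges,
                 node_score = NULL, score = NA_real_,
                 max_parents = NA_integer_),
            class = "universal_graph")
}
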