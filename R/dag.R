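#' Directed acyclic graphs over named variables
#'
#' A `clg_dag` stores a node roster and a parent list. Arcs are ordered
#' (parent, child) pairs; the structure is kept acyclic at all times —
#' mutating helpers refuse arcs that would close a directed cycle.
#'
#' @param nodes character vector of unique node names.
#' @param arcs two-column character matrix (from, to) or a data frame with
#'   columns `from`/`to`; may be empty.
#' @return An object of class `clg_dag`.
#' @export
empty_dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes), length(nodes) >= 1L)
  parents <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  g <- structure(list(nodes = nodes, parents = parents), class = "clg_dag")
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.matrix(arcs)
    for (i in seq_len(nrow(arcs))) g <- add_arc(g, arcs[i, 1], arcs[i, 2])
  }
  g
}

#' @rdname empty_dag
#' @param dag a `clg_dag`.
#' @export
dag_arcs <- function(dag) {
  from <- character(0); to <- character(0)
  for (v in dag$nodes) {
    p <- dag$parents[[v]]
    if (length(p)) { from <- c(from, p); to <- c(to, rep(v, length(p))) }
  }
  cbind(from = from, to = to)
}

#' @rdname empty_dag
#' @export
n_arcs <- function(dag) sum(lengths(dag$parents))

has_arc <- function(dag, from, to) from %in% dag$parents[[to]]

# TRUE iff a directed path from `from` to `to` exists
has_path <- function(dag, from, to) {
  if (from == to) return(TRUE)
  children <- children_map(dag)
  frontier <- from
  seen <- character(0)
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

children_map <- function(dag) {
  ch <- stats::setNames(rep(list(character()), length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) for (p in dag$parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  ch
}

#' @rdname empty_dag
#' @param from,to node names of the arc's tail and head.
#' @export
add_arc <- function(dag, from, to) {
  stopifnot(from %in% dag$nodes, to %in% dag$nodes)
  if (from == to) stop("self-loop ", from, " -> ", to)
  if (has_arc(dag, from, to)) stop("duplicate arc ", from, " -> ", to)
  if (has_path(dag, to, from))
    stop("arc ", from, " -> ", to, " would create a cycle")
  dag$parents[[to]] <- c(dag$parents[[to]], from)
  dag
}

#' @rdname empty_dag
#' @export
drop_arc <- function(dag, from, to) {
  if (!has_arc(dag, from, to)) stop("no arc ", from, " -> ", to)
  dag$parents[[to]] <- setdiff(dag$parents[[to]], from)
  dag
}

#' @rdname empty_dag
#' @export
reverse_arc <- function(dag, from, to) {
  dag <- drop_arc(dag, from, to)
  add_arc(dag, to, from)
}

#' @rdname empty_dag
#' @export
is_acyclic <- function(dag) {
  !is.null(topo_sort_or_null(dag))
}

topo_sort_or_null <- function(dag) {
  indeg <- lengths(dag$parents)
  children <- children_map(dag)
  queue <- sort(names(indeg)[indeg == 0L])
  order <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (c in children[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- sort(c(queue, c))
    }
  }
  if (length(order) == length(dag$nodes)) order else NULL
}

#' Topological order of a DAG
#'
#' Deterministic (lexicographic Kahn) ordering; errors if the graph holds a
#' directed cycle.
#'
#' @param dag a `clg_dag`.
#' @return character vector of node names, parents before children.
#' @export
topo_sort <- function(dag) {
  ord <- topo_sort_or_null(dag)
  if (is.null(ord)) stop("graph contains a directed cycle")
  ord
}

#' Undirected skeleton of a DAG
#'
#' @param dag a `clg_dag`.
#' @return two-column character matrix of unordered pairs, each row sorted
#'   lexicographically, rows unique.
#' @export
skeleton <- function(dag) {
  a <- dag_arcs(dag)
  if (nrow(a) == 0) return(cbind(from = character(0), to = character(0)))
  sk <- t(apply(a, 1, sort))
  sk <- unique(sk)
  colnames(sk) <- c("from", "to")
  sk
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Structural Hamming distance between two graphs' skeletons
#'
#' Counts undirected edges present in one skeleton but not the other.
#'
#' @param a,b `clg_dag` objects on the same node set.
#' @return integer distance.
#' @export
shd_skeleton <- function(a, b) {
  stopifnot(setequal(a$nodes, b$nodes))
  ka <- apply(skeleton(a), 1, paste, collapse = "|")
  kb <- apply(skeleton(b), 1, paste, collapse = "|")
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' @export
print.clg_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", n_arcs(x), "arcs\n")
  a <- dag_arcs(x)
  if (nrow(a)) {
    ord <- order(a[, 1], a[, 2])
    for (i in ord) cat("  ", a[i, 1], "->", a[i, 2], "\n")
  }
  invisible(x)
}

#' Convert a DAG to an igraph object
#'
#' @param dag a `clg_dag`.
#' @return a directed `igraph` graph.
#' @export
as_igraph <- function(dag) {
  a <- dag_arcs(dag)
  igraph::graph_from_data_frame(
    data.frame(from = a[, 1], to = a[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = dag$nodes, stringsAsFactors = FALSE))
}

#' Export a DAG as GraphML or DOT
#'
#' @param dag a `clg_dag`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dag_graphml <- function(dag, path) {
  igraph::write_graph(as_igraph(dag), path, format = "graphml")
  invisible(path)
}

#' @rdname write_dag_graphml
#' @export
write_dag_dot <- function(dag, path) {
  igraph::write_graph(as_igraph(dag), path, format = "dot")
  invisible(path)
}

#' Read a DAG from a GraphML file
#'
#' @param path a GraphML file written by [write_dag_graphml()].
#' @return a `clg_dag`.
#' @export
read_dag_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  empty_dag(nodes, el)
}
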