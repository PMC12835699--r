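# Node centrality statistics for a learned network: directed degree counts
# plus closeness and betweenness on the undirected, unweighted skeleton, with
# the standardizations used for reporting.

#' Centrality statistics of a DAG
#'
#' Degree counts directed arcs (in, out, total); closeness and betweenness
#' are computed on the undirected skeleton. Closeness is
#' `(n - 1) / sum of distances`; on a disconnected skeleton the harmonic
#' variant (`sum(1/dist) / (n - 1)`) is substituted with a message, since
#' classic closeness is undefined across components. Standardized
#' betweenness divides by `(n - 1)(n - 2) / 2`, the maximum attainable on an
#' undirected graph; closeness is already on `[0, 1]` for connected graphs.
#'
#' @param dag a `clg_dag` with at least one node.
#' @return a data frame of class `clg_centrality`: one row per node with
#'   `degree_in`, `degree_out`, `degree_total`, `closeness`, `betweenness`,
#'   `closeness_std`, `betweenness_std`. Node order follows the DAG roster.
#' @export
centrality <- function(dag) {
  if (!length(dag$nodes)) stop("empty node set")
  nodes <- dag$nodes
  nv <- length(nodes)
  deg_in <- lengths(dag$parents[nodes])
  ch <- children_map(dag)
  deg_out <- lengths(ch[nodes])
  g <- igraph::as_undirected(as_igraph(dag), mode = "collapse")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  dmat <- igraph::distances(g)
  connected <- all(is.finite(dmat))
  if (nv > 1) {
    if (connected) {
      clo <- (nv - 1) / rowSums(dmat)
    } else {
      message("skeleton is disconnected; reporting harmonic closeness")
      inv <- 1 / dmat
      diag(inv) <- 0
      clo <- rowSums(inv) / (nv - 1)
    }
  } else clo <- 0
  btw_max <- if (nv > 2) (nv - 1) * (nv - 2) / 2 else 1
  out <- data.frame(node = nodes,
                    degree_in = as.integer(deg_in),
                    degree_out = as.integer(deg_out),
                    degree_total = as.integer(deg_in + deg_out),
                    closeness = as.numeric(clo[nodes]),
                    betweenness = as.numeric(btw[nodes]),
                    closeness_std = as.numeric(clo[nodes]),
                    betweenness_std = as.numeric(btw[nodes]) / btw_max,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("clg_centrality", "data.frame")
  out
}

#' Write a centrality table as CSV
#'
#' @param tab a [centrality()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
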