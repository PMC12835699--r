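# Independent brute-force oracles, deliberately naive: shortest-path
# enumeration for centrality, step-down Holm by literal definition,
# contingency-table log-likelihood.

# all shortest paths between every ordered pair by exhaustive BFS-free
# path enumeration on the undirected skeleton (graphs <= 8 nodes)
oracle_centrality <- function(dag) {
  nodes <- dag$nodes
  nv <- length(nodes)
  sk <- skeleton(dag)
  adj <- matrix(FALSE, nv, nv, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(sk))) {
    adj[sk[i, 1], sk[i, 2]] <- TRUE
    adj[sk[i, 2], sk[i, 1]] <- TRUE
  }
  # enumerate all simple paths between a and b, keep the shortest
  all_paths <- function(a, b) {
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == b) { found[[length(found) + 1L]] <<- path; return() }
      for (nx in nodes[adj[last, ]])
        if (!(nx %in% path)) walk(c(path, nx))
    }
    walk(a)
    if (!length(found)) return(list())
    lens <- vapply(found, length, 0L)
    found[lens == min(lens)]
  }
  btw <- stats::setNames(numeric(nv), nodes)
  dist <- matrix(Inf, nv, nv, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    sp <- all_paths(nodes[i], nodes[j])
    if (!length(sp)) next
    dist[i, j] <- dist[j, i] <- length(sp[[1]]) - 1
    inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tb <- table(inner) / length(sp)
      btw[names(tb)] <- btw[names(tb)] + as.numeric(tb)
    }
  }
  connected <- all(is.finite(dist))
  clo <- if (connected) (nv - 1) / rowSums(dist) else {
    inv <- 1 / dist; diag(inv) <- 0
    rowSums(inv) / (nv - 1)
  }
  list(betweenness = btw, closeness = clo, connected = connected)
}

# literal step-down Holm: reject-and-adjust one hypothesis at a time
oracle_holm <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  remaining <- seq_len(m)
  running_max <- 0
  for (step in seq_len(m)) {
    i <- remaining[which.min(p[remaining])]
    a <- min(1, max(running_max, (m - step + 1) * p[i]))
    adj[i] <- a
    running_max <- a
    remaining <- setdiff(remaining, i)
  }
  adj
}

# saturated empirical log-likelihood of a two-way contingency table:
# sum n_ij log(n_ij / n)
oracle_contingency_loglik <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum(tab[tab > 0] * log(tab[tab > 0] / n))
}

# random connected undirected graph returned as a clg_dag (arcs oriented
# low -> high index, so the skeleton is the graph itself)
random_connected_dag <- function(seed, max_nodes = 8) {
  set.seed(seed)
  nv <- sample(3:max_nodes, 1)
  nodes <- sprintf("n%02d", seq_len(nv))
  dag <- empty_dag(nodes)
  # random spanning tree guarantees connectivity
  perm <- sample(nodes)
  for (i in 2:nv)
    dag <- add_arc(dag, sort(c(perm[i - 1], perm[i]))[1],
                   sort(c(perm[i - 1], perm[i]))[2])
  extra <- utils::combn(nodes, 2)
  for (j in sample(ncol(extra))) {
    if (stats::runif(1) < 0.25) {
      u <- extra[1, j]; v <- extra[2, j]
      if (!has_arc(dag, u, v)) dag <- add_arc(dag, u, v)
    }
  }
  dag
}
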