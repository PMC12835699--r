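# Score-based DAG search: greedy hill climbing over add/delete/reverse moves
# from an empty start, plus a tabu variant that escapes local optima by
# accepting the best non-tabu move even when worsening.

SCORE_TOL <- 1e-9  # a move must improve the score by more than this

#' Blacklist forbidding continuous-to-discrete arcs
#'
#' Discrete variables may never be children of continuous variables in a CLG
#' network; the search never adds such arcs.
#'
#' @param spec a [variable_spec()].
#' @return two-column character matrix of forbidden (from, to) arcs.
#' @export
default_blacklist <- function(spec) {
  cont <- spec$name[spec$kind == "continuous"]
  disc <- spec$name[spec$kind == "discrete"]
  if (!length(cont) || !length(disc))
    return(cbind(from = character(0), to = character(0)))
  g <- expand.grid(from = cont, to = disc, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[order(g$from, g$to), , drop = FALSE])
}

blacklist_keys <- function(blacklist) {
  if (is.null(blacklist) || NROW(blacklist) == 0) return(character(0))
  paste(blacklist[, 1], blacklist[, 2], sep = "->")
}

# descendants of every node as a boolean reachability matrix
reachability <- function(dag) {
  nodes <- dag$nodes
  ch <- children_map(dag)
  reach <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  for (s in nodes) {
    frontier <- ch[[s]]
    while (length(frontier)) {
      frontier <- frontier[!reach[s, frontier]]
      if (!length(frontier)) break
      reach[s, frontier] <- TRUE
      frontier <- unique(unlist(ch[frontier], use.names = FALSE))
    }
  }
  reach
}

# path u ~> v that does not use the direct arc u -> v
has_indirect_path <- function(ch, u, v) {
  frontier <- setdiff(ch[[u]], v)
  seen <- character(0)
  while (length(frontier)) {
    if (v %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(ch[frontier], use.names = FALSE)),
                        seen)
  }
  FALSE
}

# All legal single-arc moves from `dag` with their score deltas.
# Returns a data frame (op, from, to, delta) sorted for deterministic
# tie-breaking: lexicographic by (op, from, to).
legal_moves <- function(dag, enc, bl_keys, cache) {
  nodes <- dag$nodes
  reach <- reachability(dag)
  ch <- children_map(dag)
  cur <- vapply(nodes, function(v)
    local_score(v, dag$parents[[v]], enc, cache), 0)
  acc <- vector("list", length(nodes) * length(nodes))
  k <- 0L
  for (v in nodes) {
    pv <- dag$parents[[v]]
    for (u in nodes) {
      if (u == v) next
      if (u %in% pv) {
        # delete u -> v
        d_del <- local_score(v, setdiff(pv, u), enc, cache) - cur[[v]]
        k <- k + 1L; acc[[k]] <- list("delete", u, v, d_del)
        # reverse u -> v (becomes v -> u)
        if (!(paste(v, u, sep = "->") %in% bl_keys) &&
            !has_indirect_path(ch, u, v)) {
          d_rev <- d_del +
            local_score(u, c(dag$parents[[u]], v), enc, cache) - cur[[u]]
          k <- k + 1L; acc[[k]] <- list("reverse", u, v, d_rev)
        }
      } else if (!(v %in% dag$parents[[u]])) {
        # add u -> v
        if (paste(u, v, sep = "->") %in% bl_keys) next
        if (reach[v, u]) next
        d_add <- local_score(v, c(pv, u), enc, cache) - cur[[v]]
        k <- k + 1L; acc[[k]] <- list("add", u, v, d_add)
      }
    }
  }
  acc <- acc[seq_len(k)]
  mv <- data.frame(
    op = vapply(acc, `[[`, "", 1L),
    from = vapply(acc, `[[`, "", 2L),
    to = vapply(acc, `[[`, "", 3L),
    delta = vapply(acc, `[[`, 0, 4L),
    stringsAsFactors = FALSE)
  mv[order(mv$op, mv$from, mv$to), , drop = FALSE]
}

apply_move <- function(dag, op, from, to) {
  switch(op,
         add = add_arc(dag, from, to),
         delete = drop_arc(dag, from, to),
         reverse = reverse_arc(dag, from, to),
         stop("unknown operator ", op))
}

dag_fingerprint <- function(dag) {
  a <- dag_arcs(dag)
  if (nrow(a) == 0) return("")
  paste(sort(paste(a[, 1], a[, 2], sep = ">")), collapse = ";")
}

#' Greedy hill-climbing structure search
#'
#' Starts from the arcless graph and repeatedly applies the single-arc
#' addition, deletion or reversal with the largest positive BIC delta (legal =
#' result acyclic and not blacklisted), stopping at a local optimum. Ties are
#' broken lexicographically by (operator, parent, child) so runs are
#' deterministic; `seed` only matters when `restarts > 0`.
#'
#' @param data complete data frame.
#' @param spec matching [variable_spec()].
#' @param blacklist forbidden arcs; defaults to [default_blacklist()].
#' @param seed integer seed for the optional random restarts.
#' @param restarts number of perturb-and-reclimb restarts (default 0, a
#'   single deterministic run).
#' @return list with elements `dag` (the learned `clg_dag`) and `trace`
#'   (class `clg_search_trace`: accepted moves, `final_score`, `converged`).
#' @export
hill_climb <- function(data, spec, blacklist = default_blacklist(spec),
                       seed = NULL, restarts = 0L) {
  enc <- encode_dataset(data, spec)
  if (enc$n < 10) stop("need n >= 10")
  cache <- new.env(parent = emptyenv())
  bl_keys <- blacklist_keys(blacklist)
  res <- climb_from(empty_dag(spec_names(spec)), enc, bl_keys, cache)
  if (restarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    best <- res
    for (r in seq_len(restarts)) {
      start <- perturb_dag(best$dag, bl_keys, n_moves = 3L)
      cand <- climb_from(start, enc, bl_keys, cache)
      if (cand$trace$final_score > best$trace$final_score) best <- cand
    }
    res <- best
  }
  res
}

climb_from <- function(dag, enc, bl_keys, cache) {
  moves <- list()
  score <- bic_score_enc(dag, enc, cache)$total
  repeat {
    mv <- legal_moves(dag, enc, bl_keys, cache)
    if (nrow(mv) == 0) break
    i <- which.max(mv$delta)  # first max after lexicographic sort
    if (mv$delta[i] <= SCORE_TOL) break
    dag <- apply_move(dag, mv$op[i], mv$from[i], mv$to[i])
    score <- score + mv$delta[i]
    moves[[length(moves) + 1L]] <-
      data.frame(op = mv$op[i], from = mv$from[i], to = mv$to[i],
                 delta = mv$delta[i], stringsAsFactors = FALSE)
  }
  trace <- structure(
    list(iterations = if (length(moves)) do.call(rbind, moves) else
           data.frame(op = character(0), from = character(0),
                      to = character(0), delta = numeric(0)),
         final_score = score, converged = TRUE),
    class = "clg_search_trace")
  list(dag = dag, trace = trace)
}

perturb_dag <- function(dag, bl_keys, n_moves = 3L) {
  for (i in seq_len(n_moves)) {
    cand <- expand.grid(from = dag$nodes, to = dag$nodes,
                        stringsAsFactors = FALSE)
    cand <- cand[cand$from != cand$to, ]
    cand <- cand[!(paste(cand$from, cand$to, sep = "->") %in% bl_keys), ]
    cand <- cand[sample.int(nrow(cand)), ]
    for (j in seq_len(nrow(cand))) {
      u <- cand$from[j]; v <- cand$to[j]
      if (has_arc(dag, u, v)) { dag <- drop_arc(dag, u, v); break }
      if (!has_arc(dag, v, u) && !has_path(dag, v, u)) {
        dag <- add_arc(dag, u, v); break
      }
    }
  }
  dag
}

#' @export
print.clg_search_trace <- function(x, ...) {
  cat("Search trace:", nrow(x$iterations), "accepted moves; final score",
      format(x$final_score), "\n")
  invisible(x)
}

#' Tabu structure search
#'
#' Hill climbing extended with a tabu list of the last `tabu_length` visited
#' structures (arc-set fingerprints): when no move improves the score, the
#' best non-tabu move is applied even if worsening, for up to
#' `max_worsening_moves` consecutive non-improving steps. Returns the
#' best-scoring structure visited.
#'
#' @inheritParams hill_climb
#' @param tabu_length number of recent structures barred from revisiting.
#' @param max_worsening_moves budget of consecutive non-improving accepted
#'   moves before termination; 0 degenerates to pure greedy search.
#' @return as [hill_climb()].
#' @export
tabu_search <- function(data, spec, blacklist = default_blacklist(spec),
                        tabu_length = 10L, max_worsening_moves = 10L,
                        seed = NULL) {
  stopifnot(tabu_length >= 1L, max_worsening_moves >= 0L)
  enc <- encode_dataset(data, spec)
  if (enc$n < 10) stop("need n >= 10")
  cache <- new.env(parent = emptyenv())
  bl_keys <- blacklist_keys(blacklist)
  dag <- empty_dag(spec_names(spec))
  score <- bic_score_enc(dag, enc, cache)$total
  best_dag <- dag; best_score <- score
  tabu <- dag_fingerprint(dag)
  moves <- list()
  worsening <- 0L
  repeat {
    mv <- legal_moves(dag, enc, bl_keys, cache)
    if (nrow(mv) == 0) break
    a <- dag_arcs(dag)
    cur_keys <- if (nrow(a)) paste(a[, 1], a[, 2], sep = ">") else character(0)
    fps <- vapply(seq_len(nrow(mv)), function(i) {
      k <- paste(mv$from[i], mv$to[i], sep = ">")
      ks <- switch(mv$op[i],
                   add = c(cur_keys, k),
                   delete = setdiff(cur_keys, k),
                   reverse = c(setdiff(cur_keys, k),
                               paste(mv$to[i], mv$from[i], sep = ">")))
      paste(sort(ks), collapse = ";")
    }, "")
    ok <- !(fps %in% tabu)
    if (!any(ok)) break
    mv <- mv[ok, , drop = FALSE]; fps <- fps[ok]
    i <- which.max(mv$delta)
    if (score + mv$delta[i] > best_score + SCORE_TOL) {
      worsening <- 0L
    } else {
      if (worsening >= max_worsening_moves) break
      worsening <- worsening + 1L
    }
    dag <- apply_move(dag, mv$op[i], mv$from[i], mv$to[i])
    score <- score + mv$delta[i]
    moves[[length(moves) + 1L]] <-
      data.frame(op = mv$op[i], from = mv$from[i], to = mv$to[i],
                 delta = mv$delta[i], stringsAsFactors = FALSE)
    tabu <- c(tabu, fps[i])
    if (length(tabu) > tabu_length) tabu <- tabu[-1]
    if (score > best_score) { best_score <- score; best_dag <- dag }
  }
  trace <- structure(
    list(iterations = if (length(moves)) do.call(rbind, moves) else
           data.frame(op = character(0), from = character(0),
                      to = character(0), delta = numeric(0)),
         final_score = best_score, converged = TRUE),
    class = "clg_search_trace")
  list(dag = best_dag, trace = trace)
}

#' Verify local optimality of a learned structure
#'
#' Re-scores every legal single-arc move at `dag`; returns the largest delta
#' found (a local optimum has no delta above the acceptance tolerance).
#'
#' @inheritParams hill_climb
#' @param dag structure to certify.
#' @return largest single-move score delta (numeric).
#' @export
best_move_delta <- function(dag, data, spec,
                            blacklist = default_blacklist(spec)) {
  enc <- encode_dataset(data, spec)
  mv <- legal_moves(dag, enc, blacklist_keys(blacklist),
                    new.env(parent = emptyenv()))
  if (nrow(mv) == 0) return(-Inf)
  max(mv$delta)
}

#' Audit a hill-climbing trace against full rescoring
#'
#' Replays every accepted move of a hill-climbing run and compares its cached
#' incremental delta with the difference of two from-scratch [bic_score()]
#' totals (computed with a fresh cache). The maximum absolute discrepancy
#' certifies the delta bookkeeping.
#'
#' @inheritParams hill_climb
#' @return list: `max_discrepancy`, `n_moves`, `trace`.
#' @export
audit_trace <- function(data, spec, blacklist = default_blacklist(spec)) {
  res <- hill_climb(data, spec, blacklist)
  enc <- encode_dataset(data, spec)
  fresh <- new.env(parent = emptyenv())
  dag <- empty_dag(spec_names(spec))
  before <- bic_score_enc(dag, enc, fresh)$total
  worst <- 0
  it <- res$trace$iterations
  for (i in seq_len(nrow(it))) {
    dag <- apply_move(dag, it$op[i], it$from[i], it$to[i])
    after <- bic_score_enc(dag, enc, fresh)$total
    worst <- max(worst, abs((after - before) - it$delta[i]))
    before <- after
  }
  list(max_discrepancy = worst, n_moves = nrow(it), trace = res$trace)
}

#' Write a search trace as JSON lines
#'
#' One accepted move per line (`op`, `from`, `to`, `delta`), suitable for
#' audit tooling.
#'
#' @param trace a `clg_search_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  it <- trace$iterations
  for (i in seq_len(nrow(it)))
    writeLines(jsonlite::toJSON(as.list(it[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
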