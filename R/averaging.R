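# Bootstrap model averaging: learn a structure per nonparametric resample,
# accumulate arc strength (fraction of resamples containing the edge in
# either direction) and direction confidence, threshold into a consensus
# ("averaged") network, and compare edge sets between networks.

#' Learn one structure per bootstrap resample
#'
#' For `b = 1..B`, draws `n` records with replacement (deterministic given
#' `seed` and `b`) and runs the configured learner under the standard
#' blacklist.
#'
#' @param data complete data frame.
#' @param spec matching [variable_spec()].
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param learner `"hill_climb"` or `"tabu"`.
#' @param blacklist forbidden arcs; defaults to [default_blacklist()].
#' @param .identity_resample test hook: use the original data for every
#'   replicate instead of resampling (degenerate bootstrap).
#' @return list of `B` learned `clg_dag` objects.
#' @export
bootstrap_networks <- function(data, spec, B = 200L, seed = 1L,
                               learner = c("hill_climb", "tabu"),
                               blacklist = default_blacklist(spec),
                               .identity_resample = FALSE) {
  stopifnot(B >= 1)
  learner <- match.arg(learner)
  n <- nrow(data)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- if (.identity_resample) seq_len(n)
           else sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      if (learner == "hill_climb")
        hill_climb(data[idx, , drop = FALSE], spec, blacklist)
      else
        tabu_search(data[idx, , drop = FALSE], spec, blacklist),
      error = function(e)
        stop("bootstrap replicate ", b, ": ", conditionMessage(e)))
    out[[b]] <- res$dag
  }
  out
}

#' Arc strength and direction confidence across learned structures
#'
#' For every unordered node pair, `strength` is the fraction of structures
#' containing the arc in either direction and `direction` the fraction of
#' those favoring each orientation (the two orientation fractions sum to 1
#' whenever strength > 0).
#'
#' @param dags non-empty list of `clg_dag` objects on a shared node set.
#' @return An object of class `clg_arc_confidence`: a data frame with one row
#'   per unordered pair (`a < b` lexicographically): `strength`,
#'   `dir_a_to_b`, `dir_b_to_a`.
#' @export
arc_confidence <- function(dags) {
  stopifnot(length(dags) >= 1)
  nodes <- dags[[1]]$nodes
  for (g in dags)
    if (!setequal(g$nodes, nodes)) stop("inconsistent node sets")
  nodes <- sort(nodes)
  pairs <- t(utils::combn(nodes, 2))
  B <- length(dags)
  n_any <- n_fwd <- numeric(nrow(pairs))
  key <- paste(pairs[, 1], pairs[, 2])
  for (g in dags) {
    a <- dag_arcs(g)
    if (!nrow(a)) next
    fwd <- a[, 1] < a[, 2]
    k <- ifelse(fwd, paste(a[, 1], a[, 2]), paste(a[, 2], a[, 1]))
    i <- match(k, key)
    n_any[i] <- n_any[i] + 1
    n_fwd[i[fwd]] <- n_fwd[i[fwd]] + 1
  }
  out <- data.frame(a = pairs[, 1], b = pairs[, 2],
                    strength = n_any / B,
                    dir_a_to_b = ifelse(n_any > 0, n_fwd / n_any, 0),
                    dir_b_to_a = ifelse(n_any > 0, 1 - n_fwd / n_any, 0),
                    stringsAsFactors = FALSE)
  structure(list(table = out, nodes = dags[[1]]$nodes, B = B),
            class = "clg_arc_confidence")
}

#' @export
print.clg_arc_confidence <- function(x, ...) {
  nz <- x$table[x$table$strength > 0, , drop = FALSE]
  cat("Arc confidence over", x$B, "networks:",
      nrow(nz), "pairs with positive strength\n")
  invisible(x)
}

# Significance threshold for arc strengths: the strength level whose step
# function is closest (L1) to the empirical CDF of the observed strengths.
# For each candidate noise fraction a (a jump of the idealized CDF from a to
# 1 at the top of the scale), the L1 distance between the piecewise-constant
# ECDF and the constant a over (0, 1) is minimized; the threshold is the
# smallest observed strength whose ECDF value reaches the argmin.
estimate_strength_threshold <- function(strengths) {
  s <- sort(strengths)
  if (all(s == 0)) return(1)
  xs <- unique(s)
  Fn <- stats::ecdf(s)
  breaks <- c(0, xs, 1)
  heights <- Fn(breaks[-length(breaks)])
  widths <- diff(breaks)
  cand_a <- unique(c(0, Fn(xs)))
  l1 <- vapply(cand_a, function(a) sum(abs(heights - a) * widths), 0)
  a_star <- cand_a[which.min(l1)]
  # noise quantile at the argmin; include the first strength class above it
  q <- stats::quantile(s, a_star, type = 1, names = FALSE)
  above <- xs[xs > q]
  if (length(above)) min(above) else max(xs)
}

#' Consensus network from arc confidences
#'
#' Includes every pair with `strength >= threshold`, oriented by majority
#' direction fraction (exact ties resolved toward the lexicographically
#' smaller parent). If the independently oriented pairs close a directed
#' cycle, the weakest-strength arc in each remaining cycle is dropped until
#' the result is acyclic (logged via a message). `threshold = "auto"` uses
#' the L1 step-function significance threshold estimated from the strength
#' distribution.
#'
#' @param conf a [arc_confidence()] object.
#' @param threshold proportion in `[0, 1]`, or `"auto"`.
#' @return list: `dag` (the consensus `clg_dag`), `threshold` (the value
#'   used), `dropped` (arcs removed by cycle repair).
#' @export
averaged_network <- function(conf, threshold = 0.5) {
  tab <- conf$table
  if (identical(threshold, "auto"))
    threshold <- estimate_strength_threshold(tab$strength)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1] or \"auto\"")
  sel <- tab[tab$strength >= threshold & tab$strength > 0, , drop = FALSE]
  sel <- sel[order(-sel$strength, sel$a, sel$b), , drop = FALSE]
  dag <- empty_dag(conf$nodes)
  dropped <- character(0)
  for (i in seq_len(nrow(sel))) {
    fwd <- sel$dir_a_to_b[i] >= sel$dir_b_to_a[i]  # tie -> lexicographic
    from <- if (fwd) sel$a[i] else sel$b[i]
    to <- if (fwd) sel$b[i] else sel$a[i]
    if (has_path(dag, to, from)) {
      # strongest-first insertion: an arc closing a cycle is the weakest in
      # that cycle, so dropping it is the deterministic repair
      dropped <- c(dropped, paste(from, "->", to))
      next
    }
    dag <- add_arc(dag, from, to)
  }
  if (length(dropped))
    message("cycle repair dropped: ", paste(dropped, collapse = ", "))
  list(dag = dag, threshold = threshold, dropped = dropped)
}

#' Compare the edge sets of two networks
#'
#' @param a,b `clg_dag` objects on the same node set.
#' @param ignore_direction compare skeletons instead of directed arcs.
#' @return list of class `clg_edge_comparison`: `shared`, `unique_to_first`,
#'   `unique_to_second`.
#' @export
compare_edges <- function(a, b, ignore_direction = FALSE) {
  if (!setequal(a$nodes, b$nodes)) stop("node sets differ")
  key <- function(g) {
    ar <- if (ignore_direction) skeleton(g) else dag_arcs(g)
    if (!nrow(ar)) character(0) else paste(ar[, 1], ar[, 2], sep = "->")
  }
  ka <- key(a); kb <- key(b)
  structure(list(shared = length(intersect(ka, kb)),
                 unique_to_first = length(setdiff(ka, kb)),
                 unique_to_second = length(setdiff(kb, ka)),
                 ignore_direction = ignore_direction),
            class = "clg_edge_comparison")
}

#' @export
print.clg_edge_comparison <- function(x, ...) {
  cat(sprintf("Edges: %d shared, %d unique to first, %d unique to second%s\n",
              x$shared, x$unique_to_first, x$unique_to_second,
              if (x$ignore_direction) " (skeletons)" else ""))
  invisible(x)
}

#' Write an arc-confidence table as CSV
#'
#' @param conf a [arc_confidence()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_arc_confidence <- function(conf, path) {
  utils::write.csv(conf$table, path, row.names = FALSE)
  invisible(path)
}
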