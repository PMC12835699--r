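# Conditional linear Gaussian (CLG) network core: the local distribution of a
# discrete node is a multinomial CPT over discrete-parent configurations; the
# local distribution of a continuous node is, per discrete-parent
# configuration, a linear regression on its continuous parents with Gaussian
# residuals. Continuous parents of discrete nodes are structurally excluded.

SD_FLOOR <- 1e-6  # residual-sd floor for degenerate configurations

# ---- internal encoded dataset -----------------------------------------------

# Integer codes for discrete columns, numeric matrix for continuous ones.
# All family-score and likelihood computations run off this encoding.
encode_dataset <- function(data, spec) {
  data <- conform_data(data, spec)
  if (anyNA(data)) stop("data must be complete (no missing cells)")
  dvars <- spec$name[spec$kind == "discrete"]
  cvars <- spec$name[spec$kind == "continuous"]
  disc <- if (length(dvars)) {
    m <- vapply(dvars, function(v) as.integer(data[[v]]), integer(nrow(data)))
    matrix(m, nrow = nrow(data), dimnames = list(NULL, dvars))
  } else matrix(integer(0), nrow(data), 0)
  cont <- if (length(cvars)) {
    m <- vapply(cvars, function(v) as.numeric(data[[v]]), numeric(nrow(data)))
    matrix(m, nrow = nrow(data), dimnames = list(NULL, cvars))
  } else matrix(numeric(0), nrow(data), 0)
  nlev <- stats::setNames(vapply(dvars, function(v)
    length(levels_of(spec, v)), 0L), dvars)
  list(n = nrow(data), disc = disc, cont = cont, nlev = nlev, spec = spec,
       data = data)
}

# 1-based configuration index over discrete parents (first parent varies
# fastest, matching expand.grid); returns all-1s when there are none.
config_index <- function(enc, dparents) {
  n <- enc$n
  if (!length(dparents)) return(list(idx = rep(1L, n), n_config = 1L))
  idx <- rep(1L, n)
  stride <- 1L
  for (p in dparents) {
    idx <- idx + (enc$disc[, p] - 1L) * stride
    stride <- stride * enc$nlev[[p]]
  }
  list(idx = idx, n_config = as.integer(stride))
}

# level labels of configuration k (1-based), as a named character vector
config_labels <- function(spec, dparents, k) {
  out <- character(length(dparents))
  names(out) <- dparents
  k <- k - 1L
  for (i in seq_along(dparents)) {
    lv <- levels_of(spec, dparents[i])
    out[i] <- lv[(k %% length(lv)) + 1L]
    k <- k %/% length(lv)
  }
  out
}

# ---- family log-likelihood and parameter counts -----------------------------

# Maximized log-likelihood of one node's local distribution plus its free
# parameter count. `parents` may mix kinds; continuous parents of a discrete
# node are a caller error (the blacklist forbids them upstream).
family_loglik <- function(node, parents, enc) {
  spec <- enc$spec
  disc_child <- is_discrete(spec, node)
  dparents <- parents[is_discrete(spec, parents)]
  cparents <- setdiff(parents, dparents)
  if (disc_child && length(cparents))
    stop("continuous parent of discrete node: ",
         paste(cparents, collapse = ", "), " -> ", node)
  cfg <- config_index(enc, dparents)
  if (disc_child) {
    L <- enc$nlev[[node]]
    counts <- tabulate((enc$disc[, node] - 1L) * cfg$n_config + cfg$idx,
                       nbins = cfg$n_config * L)
    tab <- matrix(as.numeric(counts), cfg$n_config, L)
    rs <- rowSums(tab)
    nz <- tab > 0
    ll <- sum(tab[nz] * log(tab[nz] / rs[row(tab)][nz]))
    d <- (L - 1) * cfg$n_config
  } else {
    y <- enc$cont[, node]
    k <- length(cparents)
    X <- if (k) enc$cont[, cparents, drop = FALSE] else NULL
    ll <- 0
    for (c in seq_len(cfg$n_config)) {
      rows <- which(cfg$idx == c)
      nc <- length(rows)
      if (nc == 0L) next
      yc <- y[rows]
      if (k) {
        fit <- stats::.lm.fit(cbind(1, X[rows, , drop = FALSE]), yc)
        rss <- sum(fit$residuals^2)
      } else {
        rss <- sum((yc - mean(yc))^2)
      }
      s2 <- max(rss / nc, SD_FLOOR^2)
      ll <- ll - nc / 2 * (log(2 * pi * s2) + rss / (nc * s2))
    }
    d <- cfg$n_config * (1 + k + 1)
  }
  list(loglik = ll, d = d)
}

family_key <- function(node, parents) {
  paste0(node, "|", paste(sort(parents), collapse = ","))
}

# BIC family score with memoisation: log L - (d/2) log n, higher is better
local_score <- function(node, parents, enc, cache = NULL) {
  key <- family_key(node, parents)
  if (!is.null(cache)) {
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  fl <- family_loglik(node, parents, enc)
  s <- fl$loglik - fl$d / 2 * log(enc$n)
  if (!is.null(cache)) assign(key, s, envir = cache)
  s
}

# ---- exported operations ----------------------------------------------------

#' Maximum-likelihood CLG parameters for a fixed structure
#'
#' Discrete nodes receive conditional probability tables of empirical
#' frequencies (parent configurations with no observations fall back to the
#' uniform distribution); continuous nodes receive, per discrete-parent
#' configuration, an ordinary-least-squares regression on their continuous
#' parents with maximum-likelihood residual variance (denominator = the
#' configuration's row count). Configurations with too few rows to identify
#' the regression fall back to the pooled fit; residual standard deviations
#' are floored at `1e-6` with a warning.
#'
#' @param dag a [empty_dag()] structure whose nodes are columns of `data`.
#' @param data a complete data frame.
#' @param spec the matching [variable_spec()].
#' @return An object of class `clg_params`: per node, either a CPT
#'   (`configs x levels` matrix) or regression coefficients
#'   (`configs x (1 + #continuous parents)`) plus residual sds.
#' @export
fit_parameters <- function(dag, data, spec) {
  enc <- encode_dataset(data, spec)
  fit_parameters_enc(dag, enc)
}

fit_parameters_enc <- function(dag, enc, singular = c("error", "repair")) {
  singular <- match.arg(singular)
  spec <- enc$spec
  stopifnot(all(dag$nodes %in% spec$name))
  out <- list()
  for (node in dag$nodes) {
    parents <- dag$parents[[node]]
    dparents <- parents[is_discrete(spec, parents)]
    cparents <- setdiff(parents, dparents)
    cfg <- config_index(enc, dparents)
    if (is_discrete(spec, node)) {
      if (length(cparents))
        stop("continuous parent of discrete node '", node, "'")
      L <- enc$nlev[[node]]
      counts <- tabulate((enc$disc[, node] - 1L) * cfg$n_config + cfg$idx,
                         nbins = cfg$n_config * L)
      tab <- matrix(as.numeric(counts), cfg$n_config, L)
      rs <- rowSums(tab)
      cpt <- tab / ifelse(rs > 0, rs, 1)
      cpt[rs == 0, ] <- 1 / L
      colnames(cpt) <- levels_of(spec, node)
      out[[node]] <- list(kind = "discrete", node = node,
                          dparents = dparents, cpt = cpt)
    } else {
      y <- enc$cont[, node]
      k <- length(cparents)
      coef <- matrix(0, cfg$n_config, 1 + k,
                     dimnames = list(NULL, c("(intercept)", cparents)))
      sds <- numeric(cfg$n_config)
      pooled <- c(mean(y), rep(0, k))
      pooled_sd <- stats::sd(y) * sqrt((enc$n - 1) / enc$n)
      for (c in seq_len(cfg$n_config)) {
        rows <- which(cfg$idx == c)
        nc <- length(rows)
        if (nc < k + 2L) {
          coef[c, ] <- pooled
          sds[c] <- max(pooled_sd, SD_FLOOR)
          next
        }
        Xc <- cbind(rep(1, nc), if (k) enc$cont[rows, cparents, drop = FALSE])
        fit <- stats::.lm.fit(Xc, y[rows])
        if (fit$rank < ncol(Xc)) {
          if (singular == "error")
            stop("singular regression for node '", node,
                 "' (collinear continuous parents)")
          b <- stats::qr.coef(qr(Xc), y[rows]); b[is.na(b)] <- 0
          fit$coefficients <- b
          fit$residuals <- y[rows] - Xc %*% b
        }
        coef[c, ] <- fit$coefficients
        s <- sqrt(sum(fit$residuals^2) / nc)
        if (s < SD_FLOOR) {
          warning("residual sd floored for node '", node, "'")
          s <- SD_FLOOR
        }
        sds[c] <- s
      }
      out[[node]] <- list(kind = "continuous", node = node,
                          dparents = dparents, cparents = cparents,
                          coef = coef, sd = sds)
    }
  }
  structure(list(nodes = out, dag = dag, spec = spec), class = "clg_params")
}

#' @export
print.clg_params <- function(x, ...) {
  nd <- vapply(x$nodes, function(f) f$kind == "discrete", NA)
  cat("CLG parameters:", length(x$nodes), "nodes (",
      sum(nd), "discrete,", sum(!nd), "continuous )\n")
  invisible(x)
}

#' Joint log-likelihood of complete data under a fitted CLG network
#'
#' Sum over records of the log joint density, factorized over node families.
#' Returns `-Inf` if any record hits a zero-probability CPT cell.
#'
#' @param params a [fit_parameters()] object.
#' @param dag the structure the parameters were fitted on.
#' @param data a complete data frame.
#' @param spec the matching [variable_spec()].
#' @return a single number (log scale).
#' @export
log_likelihood <- function(params, dag, data, spec) {
  enc <- encode_dataset(data, spec)
  total <- 0
  for (node in dag$nodes) {
    fam <- params$nodes[[node]]
    cfg <- config_index(enc, fam$dparents)
    if (fam$kind == "discrete") {
      p <- fam$cpt[cbind(cfg$idx, enc$disc[, node])]
      if (any(p == 0)) return(-Inf)
      total <- total + sum(log(p))
    } else {
      mu <- fam$coef[cfg$idx, 1]
      for (j in seq_along(fam$cparents))
        mu <- mu + fam$coef[cfg$idx, 1 + j] * enc$cont[, fam$cparents[j]]
      total <- total +
        sum(stats::dnorm(enc$cont[, node], mu, fam$sd[cfg$idx], log = TRUE))
    }
  }
  total
}

#' Decomposable BIC network score
#'
#' Per-node family score `log L - (d/2) log n` (maximized-likelihood
#' convention: higher is better), where `d` counts the family's free
#' parameters — `(levels - 1) * prod(parent levels)` for a discrete node; per
#' discrete-parent configuration `1 intercept + #continuous-parent slopes +
#' 1 variance` for a continuous node. The total is the sum over nodes.
#'
#' @inheritParams fit_parameters
#' @return An object of class `clg_score` with elements `total` and
#'   `per_node` (named numeric vector).
#' @export
bic_score <- function(dag, data, spec) {
  enc <- encode_dataset(data, spec)
  if (enc$n < 2) stop("need n >= 2")
  bic_score_enc(dag, enc)
}

bic_score_enc <- function(dag, enc, cache = NULL) {
  per <- vapply(dag$nodes, function(v)
    local_score(v, dag$parents[[v]], enc, cache), 0)
  structure(list(total = sum(per), per_node = per), class = "clg_score")
}

#' @export
print.clg_score <- function(x, ...) {
  cat("BIC network score:", format(x$total), "\n")
  invisible(x)
}

#' Enumerate every DAG on a small node set
#'
#' Exhaustive oracle for validating the structure search: yields each labeled
#' DAG containing no blacklisted arc exactly once. Guarded to at most 6 nodes.
#'
#' @param spec a [variable_spec()] (its names define the node set).
#' @param blacklist two-column character matrix of forbidden (from, to) arcs,
#'   or `NULL`.
#' @return list of `clg_dag` objects.
#' @export
enumerate_dags <- function(spec, blacklist = NULL) {
  nodes <- spec_names(spec)
  if (length(nodes) > 6L) stop("enumerate_dags is limited to 6 nodes")
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  if (!is.null(blacklist) && NROW(blacklist) > 0) {
    bkey <- paste(blacklist[, 1], blacklist[, 2], sep = "->")
    keep <- !(paste(pairs$from, pairs$to, sep = "->") %in% bkey)
    pairs <- pairs[keep, , drop = FALSE]
  }
  out <- list()
  recurse <- function(i, dag) {
    if (i > nrow(pairs)) {
      out[[length(out) + 1L]] <<- dag
      return(invisible())
    }
    recurse(i + 1L, dag)  # exclude arc i
    f <- pairs$from[i]; t <- pairs$to[i]
    if (!has_path(dag, t, f)) recurse(i + 1L, add_arc(dag, f, t))
  }
  recurse(1L, empty_dag(nodes))
  out
}

# Best achievable BIC over all DAGs on <= 6 nodes, via per-family caching.
exhaustive_best_score <- function(data, spec, blacklist = NULL) {
  enc <- encode_dataset(data, spec)
  cache <- new.env(parent = emptyenv())
  dags <- enumerate_dags(spec, blacklist)
  scores <- vapply(dags, function(g) bic_score_enc(g, enc, cache)$total, 0)
  list(best = max(scores), dag = dags[[which.max(scores)]], scores = scores)
}
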