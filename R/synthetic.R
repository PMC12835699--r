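# Synthetic generator emulating the CATIE schizophrenia baseline roster:
# 21 variables (6 discrete demographics; CDSS, DAI, ITAQ, five MATRICS
# cognitive domains, three PANSS subscales, three CGI indices and a QOL total
# as continuous), a known ground-truth CLG network with published-size
# standardized coefficients, ~2.4% MCAR missingness and a handful of rows
# with more than half their cells missing.

#' The CATIE-like variable roster
#'
#' 21 variables in the reporting order used throughout the package: six
#' discrete demographics, then the clinical, cognitive and quality-of-life
#' totals as continuous variables.
#'
#' @return a [variable_spec()].
#' @export
catie_spec <- function() {
  variable_spec(
    name = c("age", "sex", "race", "marital", "education", "employment",
             "cdss", "dai", "itaq",
             "matrics_verbal", "matrics_vigilance", "matrics_speed",
             "matrics_reasoning", "matrics_memory",
             "panss_general", "panss_negative", "panss_positive",
             "cgi_drug", "cgi_alcohol", "cgi_severity", "qol"),
    kind = c(rep("discrete", 6), rep("continuous", 15)),
    levels = c(list(c("<30", "31-45", ">45"),
                    c("male", "female"),
                    c("white", "black", "asian", "other"),
                    c("never_married", "ever_married"),
                    c("less_than_hs", "high_school", "beyond_hs"),
                    c("working", "not_working")),
               vector("list", 15)),
    role = c(rep("demographic", 6), rep("clinical", 3), rep("cognitive", 5),
             rep("clinical", 6), "qol"),
    ordered = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, rep(FALSE, 15))
  )
}

# standardized coefficients of the default ground truth (effect_scale = 1);
# continuous -> continuous arcs plus the one discrete parent of QOL
catie_truth_arcs <- function() {
  data.frame(
    from = c("matrics_speed", "matrics_speed", "matrics_memory",
             "matrics_speed", "matrics_speed", "matrics_memory",
             "dai",
             "matrics_memory", "cdss",
             "matrics_speed", "panss_general", "cdss", "cgi_alcohol",
             "panss_general",
             "cdss", "panss_positive",
             "panss_positive",
             "dai", "cdss", "cgi_severity", "panss_negative",
             "matrics_speed", "employment"),
    to = c("matrics_verbal", "matrics_vigilance", "matrics_vigilance",
           "matrics_memory", "matrics_reasoning", "matrics_reasoning",
           "itaq",
           "panss_general", "panss_general",
           "panss_negative", "panss_negative", "panss_negative",
           "panss_negative",
           "panss_positive",
           "cgi_drug", "cgi_drug",
           "cgi_severity",
           "qol", "qol", "qol", "qol", "qol", "qol"),
    beta = c(0.45, 0.55, 0.20,
             0.60, 0.40, 0.25,
             0.30,
             -0.14, 0.35,
             -0.25, 0.61, -0.14, -0.10,
             0.64,
             0.15, 0.20,
             0.45,
             0.15, -0.18, -0.15, -0.33, 0.12, -0.32),
    stringsAsFactors = FALSE)
}

# marginal level probabilities of the discrete roots (Table-1-like fractions)
catie_discrete_marginals <- function() {
  list(age = c(0.18, 0.47, 0.35),
       sex = c(0.744, 0.256),
       race = c(0.604, 0.350, 0.023, 0.023),
       education = c(0.25, 0.50, 0.25))
}

# CPTs of the two discrete variables with a discrete parent
catie_discrete_cpts <- function() {
  list(
    # P(marital | age): younger participants far more often never married
    marital = matrix(c(0.85, 0.15,
                       0.62, 0.38,
                       0.40, 0.60), nrow = 3, byrow = TRUE,
                     dimnames = list(NULL, c("never_married", "ever_married"))),
    # P(employment | education): employment rises with education;
    # marginal P(working) ~ 0.151
    employment = matrix(c(0.06, 0.94,
                          0.14, 0.86,
                          0.26, 0.74), nrow = 3, byrow = TRUE,
                        dimnames = list(NULL, c("working", "not_working")))
  )
}

#' Construct the CATIE-like ground-truth network
#'
#' Builds the 21-node conditional linear Gaussian network whose arcs and
#' standardized coefficients mirror the published symptom-network findings
#' (processing speed parenting every other cognitive domain, the
#' speed-to-negative-symptoms path at -0.25, the six parents of QOL, and so
#' on). Residual variances are solved so that every continuous node has unit
#' marginal variance at `effect_scale = 1`; rescaling `effect_scale` scales
#' every coefficient while leaving residual variances unchanged.
#'
#' @param seed integer; kept for interface stability (the default truth is
#'   deterministic).
#' @param effect_scale positive multiplier on all ground-truth coefficients;
#'   0 yields a continuous block of independent noise.
#' @return An object of class `clg_truth`: `dag`, `params` (a `clg_params`),
#'   `spec`, and `annotations` (data frame from/to/beta of the standardized
#'   coefficients the arcs mimic, at `effect_scale = 1`).
#' @export
make_catie_like_truth <- function(seed = 1L, effect_scale = 1) {
  stopifnot(effect_scale >= 0)
  spec <- catie_spec()
  arcs <- catie_truth_arcs()
  disc_arcs <- data.frame(from = c("age", "education"),
                          to = c("marital", "employment"),
                          stringsAsFactors = FALSE)
  dag <- empty_dag(spec_names(spec))
  for (i in seq_len(nrow(disc_arcs)))
    dag <- add_arc(dag, disc_arcs$from[i], disc_arcs$to[i])
  for (i in seq_len(nrow(arcs)))
    dag <- add_arc(dag, arcs$from[i], arcs$to[i])

  marg <- catie_discrete_marginals()
  cpts <- catie_discrete_cpts()

  # exact marginal level probabilities for every discrete node, via the full
  # joint over the (small) discrete subnetwork
  dvars <- spec$name[spec$kind == "discrete"]
  joint <- expand.grid(lapply(dvars, function(v)
    seq_along(levels_of(spec, v))), KEEP.OUT.ATTRS = FALSE)
  names(joint) <- dvars
  pr <- rep(1, nrow(joint))
  for (v in dvars) {
    p <- dag$parents[[v]]
    if (!length(p)) {
      pr <- pr * marg[[v]][joint[[v]]]
    } else {
      pr <- pr * cpts[[v]][cbind(joint[[p]], joint[[v]])]
    }
  }
  dmarg <- lapply(dvars, function(v)
    as.numeric(tapply(pr, joint[[v]], sum)))
  names(dmarg) <- dvars

  # residual variances solved at effect_scale = 1 by exact covariance
  # propagation over the continuous block; discrete parents of continuous
  # nodes are roots of independent discrete components in this truth, so
  # their contribution is an independent additive variance of beta^2
  cvars <- spec$name[spec$kind == "continuous"]
  ord <- intersect(topo_sort(dag), cvars)
  C <- diag(length(cvars))
  dimnames(C) <- list(cvars, cvars)
  resid_var <- stats::setNames(numeric(length(cvars)), cvars)
  for (v in ord) {
    pa <- arcs[arcs$to == v, , drop = FALSE]
    cpa <- pa[pa$from %in% cvars, , drop = FALSE]
    dpa <- pa[!(pa$from %in% cvars), , drop = FALSE]
    v_sys <- 0
    if (nrow(cpa)) {
      b <- cpa$beta
      Cxx <- C[cpa$from, cpa$from, drop = FALSE]
      v_sys <- v_sys + drop(t(b) %*% Cxx %*% b)
      for (z in cvars)
        if (z != v) C[v, z] <- C[z, v] <- sum(b * C[cpa$from, z])
    }
    v_sys <- v_sys + sum(dpa$beta^2)
    rv <- 1 - v_sys
    if (rv <= 0.05)
      stop("ground-truth coefficients leave node '", v,
           "' with residual variance ", format(rv))
    resid_var[v] <- rv
    C[v, v] <- 1
  }

  # assemble clg_params
  nodes <- list()
  for (v in dvars) {
    p <- dag$parents[[v]]
    cpt <- if (!length(p)) matrix(marg[[v]], 1,
                                  dimnames = list(NULL, levels_of(spec, v)))
           else cpts[[v]]
    nodes[[v]] <- list(kind = "discrete", node = v, dparents = p, cpt = cpt)
  }
  for (v in cvars) {
    pa <- arcs[arcs$to == v, , drop = FALSE]
    cpa <- pa[pa$from %in% cvars, , drop = FALSE]
    dpa <- pa[!(pa$from %in% cvars), , drop = FALSE]
    dparents <- dpa$from
    n_config <- if (length(dparents))
      prod(vapply(dparents, function(d) length(levels_of(spec, d)), 0))
    else 1L
    coef <- matrix(0, n_config, 1 + nrow(cpa),
                   dimnames = list(NULL, c("(intercept)", cpa$from)))
    if (nrow(cpa)) coef[, -1] <- matrix(cpa$beta * effect_scale,
                                        n_config, nrow(cpa), byrow = TRUE)
    for (cfgi in seq_len(n_config)) {
      lab <- config_labels(spec, dparents, cfgi)
      shift <- 0
      for (ii in seq_along(dparents)) {
        d <- dparents[ii]
        lv <- levels_of(spec, d)
        code <- match(lab[[d]], lv) - 1
        p1 <- dmarg[[d]]
        mu_code <- sum((seq_along(lv) - 1) * p1)
        sd_code <- sqrt(sum(((seq_along(lv) - 1) - mu_code)^2 * p1))
        delta <- dpa$beta[ii] / sd_code
        shift <- shift + delta * (code - mu_code) * effect_scale
      }
      coef[cfgi, 1] <- shift
    }
    nodes[[v]] <- list(kind = "continuous", node = v, dparents = dparents,
                       cparents = cpa$from, coef = coef,
                       sd = rep(sqrt(resid_var[[v]]), n_config))
  }
  params <- structure(list(nodes = nodes[spec_names(spec)], dag = dag,
                           spec = spec), class = "clg_params")
  ann <- rbind(arcs, cbind(disc_arcs, beta = NA_real_))
  structure(list(dag = dag, params = params, spec = spec,
                 annotations = ann, effect_scale = effect_scale,
                 seed = seed),
            class = "clg_truth")
}

#' @export
print.clg_truth <- function(x, ...) {
  cat("Ground-truth CLG network:", length(x$dag$nodes), "nodes,",
      n_arcs(x$dag), "arcs (effect scale", x$effect_scale, ")\n")
  invisible(x)
}

#' Ancestral sampling from a CLG network
#'
#' Draws `n` complete records in a topological order of the structure:
#' discrete cells from the CPT row selected by the sampled discrete parents,
#' continuous cells from the linear-Gaussian family of the sampled
#' discrete-parent configuration.
#'
#' @param net a `clg_truth` (or any list with `dag`, `params`, `spec`).
#' @param n number of records.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @return a data frame (`n` rows; factor columns for discrete variables).
#' @export
sample_dataset <- function(net, n, seed = 1L) {
  stopifnot(n >= 1)
  dag <- net$dag; params <- net$params; spec <- net$spec
  ord <- topo_sort(dag)  # errors on a cyclic graph
  set.seed(seed)
  out <- vector("list", length(ord))
  names(out) <- ord
  code <- list()  # integer codes of sampled discrete nodes
  for (v in ord) {
    fam <- params$nodes[[v]]
    cfg_idx <- rep(1L, n)
    stride <- 1L
    for (d in fam$dparents) {
      cfg_idx <- cfg_idx + (code[[d]] - 1L) * stride
      stride <- stride * length(levels_of(spec, d))
    }
    if (fam$kind == "discrete") {
      lv <- levels_of(spec, v)
      u <- stats::runif(n)
      ix <- integer(n)
      for (cfgi in unique(cfg_idx)) {
        rows <- which(cfg_idx == cfgi)
        cum <- cumsum(fam$cpt[cfgi, ])
        ix[rows] <- findInterval(u[rows], cum) + 1L
      }
      code[[v]] <- ix
      out[[v]] <- factor(lv[ix], levels = lv)
    } else {
      mu <- fam$coef[cfg_idx, 1]
      for (j in seq_along(fam$cparents))
        mu <- mu + fam$coef[cfg_idx, 1 + j] * out[[fam$cparents[j]]]
      out[[v]] <- mu + stats::rnorm(n) * fam$sd[cfg_idx]
    }
  }
  as.data.frame(out[spec_names(spec)[spec_names(spec) %in% ord]],
                stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defaults emulate the CATIE deposit's bookkeeping: 1460 enrolled records of
#' which 10 carry more than half their cells missing (and are meant to be
#' filtered), and 2.4% of the remaining cells missing completely at random.
#'
#' @param n number of records to generate.
#' @param seed integer master seed.
#' @param missing_rate MCAR cell-missingness rate in `[0, 0.5)`.
#' @param n_bad_rows rows given strictly more than 50% missing cells.
#' @param effect_scale multiplier on all ground-truth coefficients.
#' @return a list of class `clg_generator_config`.
#' @export
generator_config <- function(n = 1460L, seed = 1L, missing_rate = 0.024,
                             n_bad_rows = 10L, effect_scale = 1) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 0.5,
            n_bad_rows >= 0, n_bad_rows < n, effect_scale >= 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 missing_rate = missing_rate,
                 n_bad_rows = as.integer(n_bad_rows),
                 effect_scale = effect_scale),
            class = "clg_generator_config")
}

#' Inject missing cells into a complete dataset
#'
#' Cells outside the designated bad rows are blanked completely at random at
#' `missing_rate`; each of `n_bad_rows` randomly chosen rows gets strictly
#' more than 50% of its cells blanked (to exercise the row filter).
#' Deterministic given `config$seed`.
#'
#' @param data complete data frame.
#' @param config a [generator_config()].
#' @return the data frame with `NA` cells.
#' @export
inject_missingness <- function(data, config) {
  stopifnot(!anyNA(data))
  n <- nrow(data); p <- ncol(data)
  if (config$missing_rate == 0 && config$n_bad_rows == 0) return(data)
  set.seed(config$seed + 104729L)
  bad <- if (config$n_bad_rows > 0) sample.int(n, config$n_bad_rows)
         else integer(0)
  good <- setdiff(seq_len(n), bad)
  if (config$missing_rate > 0 && length(good)) {
    mask <- matrix(stats::runif(length(good) * p) < config$missing_rate,
                   length(good), p)
    for (j in seq_len(p)) data[good[mask[, j]], j] <- NA
  }
  m_bad <- floor(p / 2) + 1L  # strictly more than half the cells
  for (r in bad) data[r, sample.int(p, m_bad)] <- NA
  data
}

#' Generate a CATIE-like dataset end to end
#'
#' Convenience wrapper: builds the ground truth, draws `config$n` complete
#' records, and injects missingness.
#'
#' @param config a [generator_config()].
#' @return list: `data` (with missing cells), `complete` (pre-missingness),
#'   `truth` (the `clg_truth`), `spec`.
#' @export
generate_catie_like <- function(config = generator_config()) {
  truth <- make_catie_like_truth(seed = config$seed,
                                 effect_scale = config$effect_scale)
  complete <- sample_dataset(truth, config$n, seed = config$seed)
  data <- inject_missingness(complete, config)
  list(data = data, complete = complete, truth = truth, spec = truth$spec)
}

#' Export a ground-truth network
#'
#' Writes the structure as GraphML and the parameters (CPTs and per-
#' configuration regressions) as JSON.
#'
#' @param truth a `clg_truth`.
#' @param dir output directory (created if absent).
#' @return character vector of the two file paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "truth.graphml")
  jpath <- file.path(dir, "truth_params.json")
  write_dag_graphml(truth$dag, gpath)
  write_params_json(truth$params, jpath)
  invisible(c(gpath, jpath))
}
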