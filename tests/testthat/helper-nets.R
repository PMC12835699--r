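# Hand-assembled miniature CLG networks used as fixtures. The params object
# mirrors the structure produced by fit_parameters(): per node either a CPT
# over discrete-parent configurations or per-configuration regression
# coefficients plus residual sds.

mini_net <- function(spec, arcs, families) {
  dag <- empty_dag(spec$name, arcs)
  params <- structure(list(nodes = families, dag = dag, spec = spec),
                      class = "clg_params")
  list(dag = dag, params = params, spec = spec)
}

cont_family <- function(node, cparents = character(0), coef = 0, sd = 1,
                        dparents = character(0), n_config = 1L) {
  cm <- matrix(coef, n_config, 1 + length(cparents), byrow = TRUE,
               dimnames = list(NULL, c("(intercept)", cparents)))
  list(kind = "continuous", node = node, dparents = dparents,
       cparents = cparents, coef = cm, sd = rep(sd, length.out = n_config))
}

disc_family <- function(node, levels, probs, dparents = character(0)) {
  cpt <- matrix(probs, ncol = length(levels), byrow = TRUE,
                dimnames = list(NULL, levels))
  list(kind = "discrete", node = node, dparents = dparents, cpt = cpt)
}

# single continuous node x ~ N(mean, sd^2)
net_single_cont <- function(mean = 0, sd = 1) {
  spec <- variable_spec("x", "continuous")
  mini_net(spec, NULL, list(x = cont_family("x", coef = mean, sd = sd)))
}

# x ~ N(0,1), y = slope * x + eps(sd)
net_two_cont <- function(slope = 0.5, sd = 1) {
  spec <- variable_spec(c("x", "y"), "continuous")
  mini_net(spec, rbind(c("x", "y")),
           list(x = cont_family("x"),
                y = cont_family("y", "x", c(0, slope), sd)))
}

# standardized bivariate normal with correlation rho (x -> y)
net_bivariate <- function(rho) {
  spec <- variable_spec(c("x", "y"), "continuous")
  mini_net(spec, rbind(c("x", "y")),
           list(x = cont_family("x"),
                y = cont_family("y", "x", c(0, rho), sqrt(1 - rho^2))))
}

# single binary root with P(level 1) = p1
net_binary_root <- function(p1 = 0.744) {
  spec <- variable_spec("d", "discrete", list(c("a", "b")))
  mini_net(spec, NULL, list(d = disc_family("d", c("a", "b"), c(p1, 1 - p1))))
}

# chain x -> y -> z, unit residual sds
net_chain3 <- function(slope = 0.8) {
  spec <- variable_spec(c("x", "y", "z"), "continuous")
  mini_net(spec, rbind(c("x", "y"), c("y", "z")),
           list(x = cont_family("x"),
                y = cont_family("y", "x", c(0, slope)),
                z = cont_family("z", "y", c(0, slope))))
}

chain3_data <- function(n = 2000, seed = 1, slope = 0.8) {
  sample_dataset(net_chain3(slope), n, seed = seed)
}

# random 4-node CLG problem (1 discrete + 3 continuous by default):
# random blacklist-respecting DAG, random CPTs and regressions
random_clg_truth <- function(seed, n_disc = 1, n_cont = 3) {
  set.seed(seed)
  dn <- if (n_disc) paste0("d", seq_len(n_disc)) else character(0)
  cn <- paste0("c", seq_len(n_cont))
  spec <- variable_spec(c(dn, cn),
                        c(rep("discrete", n_disc), rep("continuous", n_cont)),
                        c(rep(list(c("l1", "l2")), n_disc),
                          vector("list", n_cont)))
  ord <- c(sample(dn), sample(cn))  # discrete first: respects the blacklist
  dag <- empty_dag(spec$name)
  for (j in seq_along(ord)) for (i in seq_len(j - 1)) {
    u <- ord[i]; v <- ord[j]
    if (is_discrete(spec, v) && !is_discrete(spec, u)) next
    if (stats::runif(1) < 0.4) dag <- add_arc(dag, u, v)
  }
  fams <- list()
  for (v in spec$name) {
    pa <- dag$parents[[v]]
    dpa <- pa[is_discrete(spec, pa)]
    cpa <- setdiff(pa, dpa)
    ncfg <- if (length(dpa)) prod(vapply(dpa, function(d)
      length(levels_of(spec, d)), 0)) else 1L
    if (is_discrete(spec, v)) {
      p1 <- stats::runif(ncfg, 0.2, 0.8)
      cpt <- cbind(l1 = p1, l2 = 1 - p1)
      fams[[v]] <- list(kind = "discrete", node = v, dparents = dpa,
                        cpt = cpt)
    } else {
      k <- length(cpa)
      slopes <- stats::runif(k, 0.3, 0.8) * sample(c(-1, 1), k, TRUE)
      icpts <- if (length(dpa)) stats::runif(ncfg, -1, 1) else 0
      cm <- cbind(icpts, matrix(rep(slopes, each = ncfg), ncfg))
      colnames(cm) <- c("(intercept)", cpa)
      fams[[v]] <- list(kind = "continuous", node = v, dparents = dpa,
                        cparents = cpa, coef = cm, sd = rep(1, ncfg))
    }
  }
  mini_net(spec, dag_arcs(dag), fams)
}

# independent standard normals, no structure
independent_data <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(stats::rnorm(n * p), n, p))
  names(d) <- paste0("v", seq_len(p))
  d
}
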