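test_that("parameter MLE matches closed forms", {
  # parentless binary node at the CATIE male fraction
  spec <- variable_spec("d", "discrete", list(c("a", "b")))
  d <- data.frame(d = rep(c("a", "b"), c(744, 256)))
  p <- fit_parameters(empty_dag("d"), d, spec)
  expect_equal(as.numeric(p$nodes$d$cpt), c(0.744, 0.256))

  # parentless continuous node: mean and ML sd
  spec2 <- variable_spec("x", "continuous")
  set.seed(1); x <- stats::rnorm(500, 3, 2)
  p2 <- fit_parameters(empty_dag("x"), data.frame(x = x), spec2)
  expect_equal(unname(p2$nodes$x$coef[1, 1]), mean(x))
  expect_equal(p2$nodes$x$sd[1],
               sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)

  # regression slope recovered at n = 50000
  d3 <- sample_dataset(net_two_cont(slope = 0.5), 50000, seed = 2)
  spec3 <- variable_spec(c("x", "y"), "continuous")
  dag3 <- empty_dag(c("x", "y"), rbind(c("x", "y")))
  p3 <- fit_parameters(dag3, d3, spec3)
  expect_lt(abs(p3$nodes$y$coef[1, "x"] - 0.5), 0.02)
})

test_that("fit_parameters enforces its preconditions", {
  spec <- variable_spec(c("x", "y"), "continuous")
  expect_error(fit_parameters(empty_dag(c("x", "y")),
                              data.frame(x = c(1, NA), y = c(1, 2)), spec),
               "complete")
  # perfectly collinear parents -> singular design
  set.seed(3)
  x <- stats::rnorm(50)
  d <- data.frame(x = x, x2 = 2 * x, y = stats::rnorm(50))
  spec2 <- variable_spec(c("x", "x2", "y"), "continuous")
  dag <- empty_dag(c("x", "x2", "y"), rbind(c("x", "y"), c("x2", "y")))
  expect_error(fit_parameters(dag, d, spec2), "singular")
})

test_that("log-likelihood matches closed forms and factorizes", {
  net <- net_single_cont()
  ll <- log_likelihood(net$params, net$dag, data.frame(x = 0), net$spec)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)

  # factorization: joint equals the sum of per-node conditional terms
  d <- sample_dataset(net_chain3(), 200, seed = 4)
  spec <- variable_spec(c("x", "y", "z"), "continuous")
  dag <- net_chain3()$dag
  params <- fit_parameters(dag, d, spec)
  ll_joint <- log_likelihood(params, dag, d, spec)
  ll_nodes <- 0
  for (v in c("x", "y", "z")) {
    fam <- params$nodes[[v]]
    mu <- fam$coef[1, 1]
    if (length(fam$cparents)) mu <- mu + fam$coef[1, 2] * d[[fam$cparents]]
    ll_nodes <- ll_nodes + sum(stats::dnorm(d[[v]], mu, fam$sd, log = TRUE))
  }
  expect_equal(ll_joint, ll_nodes, tolerance = 1e-8)
})

test_that("records hitting zero-probability CPT cells give -Inf loglik", {
  spec <- variable_spec("d", "discrete", list(c("a", "b")))
  train <- data.frame(d = rep("a", 20))
  params <- fit_parameters(empty_dag("d"), train, spec)
  expect_equal(log_likelihood(params, empty_dag("d"),
                              data.frame(d = "b"), spec), -Inf)
})

test_that("complete discrete graph attains the saturated contingency loglik", {
  set.seed(5)
  d <- data.frame(a = sample(c("u", "v"), 300, TRUE),
                  b = sample(c("p", "q", "r"), 300, TRUE))
  spec <- variable_spec(c("a", "b"), "discrete",
                        list(c("u", "v"), c("p", "q", "r")))
  dag <- empty_dag(c("a", "b"), rbind(c("a", "b")))
  params <- fit_parameters(dag, d, spec)
  ll <- log_likelihood(params, dag, d, spec)
  expect_equal(ll, oracle_contingency_loglik(d$a, d$b), tolerance = 1e-8)
})

test_that("the BIC score decomposes over families", {
  d <- sample_dataset(net_chain3(), 500, seed = 6)
  spec <- variable_spec(c("x", "y", "z"), "continuous")
  g0 <- empty_dag(c("x", "y", "z"))
  g1 <- add_arc(g0, "x", "y")
  s0 <- bic_score(g0, d, spec)
  s1 <- bic_score(g1, d, spec)
  expect_equal(s0$total, sum(s0$per_node), tolerance = 1e-8)
  # only the child's family changes
  expect_equal(s1$per_node[["x"]], s0$per_node[["x"]], tolerance = 1e-10)
  expect_equal(s1$per_node[["z"]], s0$per_node[["z"]], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(s1$per_node[["y"]], s0$per_node[["y"]])))
  expect_equal(s1$total - s0$total, s1$per_node[["y"]] - s0$per_node[["y"]],
               tolerance = 1e-8)
})

test_that("a real dependency repays its BIC penalty", {
  d <- sample_dataset(net_two_cont(slope = 0.8), 2000, seed = 7)
  spec <- variable_spec(c("x", "y"), "continuous")
  s_true <- bic_score(empty_dag(c("x", "y"), rbind(c("x", "y"))), d, spec)
  s_empty <- bic_score(empty_dag(c("x", "y")), d, spec)
  expect_gt(s_true$total, s_empty$total)
})

test_that("score consistency holds across seeds", {
  spec <- variable_spec(c("x", "y"), "continuous")
  dag_t <- empty_dag(c("x", "y"), rbind(c("x", "y")))
  wins <- 0
  for (s in 1:20) {
    d <- sample_dataset(net_two_cont(slope = 0.5), 2000, seed = 100 + s)
    wins <- wins +
      (bic_score(dag_t, d, spec)$total > bic_score(empty_dag(c("x", "y")),
                                                   d, spec)$total)
  }
  expect_gte(wins, 20 * 0.99)
})

test_that("DAG enumeration yields each labeled DAG exactly once", {
  s2 <- variable_spec(c("a", "b"), "continuous")
  expect_length(enumerate_dags(s2), 3)
  s3 <- variable_spec(c("a", "b", "c"), "continuous")
  dags3 <- enumerate_dags(s3)
  expect_length(dags3, 25)
  fps <- vapply(dags3, clgnet:::dag_fingerprint, "")
  expect_false(anyDuplicated(fps) > 0)
  # mixed pair under the blacklist: only the empty graph and D -> C remain
  sm <- variable_spec(c("D", "C"), c("discrete", "continuous"),
                      list(c("l1", "l2"), NULL))
  expect_length(enumerate_dags(sm, default_blacklist(sm)), 2)
  s7 <- variable_spec(paste0("n", 1:7), "continuous")
  expect_error(enumerate_dags(s7), "6 nodes")
})

test_that("the complete DAG dominates unpenalized likelihood on 3 nodes", {
  d <- sample_dataset(net_chain3(), 300, seed = 8)
  spec <- variable_spec(c("x", "y", "z"), "continuous")
  dags <- enumerate_dags(spec)
  lls <- vapply(dags, function(g) {
    p <- fit_parameters(g, d, spec)
    log_likelihood(p, g, d, spec)
  }, 0)
  n_max_arcs <- vapply(dags, n_arcs, 0L)
  expect_true(which.max(lls) %in% which(n_max_arcs == 3))
})
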