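test_that("a degenerate bootstrap reproduces the single-data network", {
  d <- chain3_data(n = 500, seed = 3)
  spec <- spec_from_data(d)
  boot <- bootstrap_networks(d, spec, B = 1, seed = 1,
                             .identity_resample = TRUE)
  hc <- hill_climb(d, spec)
  expect_identical(clgnet:::dag_fingerprint(boot[[1]]),
                   clgnet:::dag_fingerprint(hc$dag))
})

test_that("arc confidence counts strengths and directions exactly", {
  nodes <- c("A", "B")
  d1 <- empty_dag(nodes, rbind(c("A", "B")))
  d2 <- empty_dag(nodes, rbind(c("A", "B")))
  d3 <- empty_dag(nodes, rbind(c("B", "A")))
  d4 <- empty_dag(nodes)
  conf <- arc_confidence(list(d1, d2, d3, d4))
  row <- conf$table[conf$table$a == "A" & conf$table$b == "B", ]
  expect_equal(row$strength, 0.75)
  expect_equal(row$dir_a_to_b, 2 / 3)
  expect_equal(row$dir_b_to_a, 1 / 3)

  # identical dags: all strengths 0 or 1; single dag: indicator function
  conf_id <- arc_confidence(list(d1, d1, d1))
  expect_true(all(conf_id$table$strength %in% c(0, 1)))
  conf_1 <- arc_confidence(list(d3))
  expect_equal(conf_1$table$strength,
               as.numeric(conf_1$table$a == "A" & conf_1$table$b == "B"))
  expect_equal(conf_1$table$dir_b_to_a[conf_1$table$strength == 1], 1)

  d5 <- empty_dag(c("A", "C"))
  expect_error(arc_confidence(list(d1, d5)), "inconsistent node sets")
})

test_that("strong edges are stable and noise edges are not", {
  d <- chain3_data(n = 2000, seed = 21)
  spec <- spec_from_data(d)
  conf <- arc_confidence(bootstrap_networks(d, spec, B = 50, seed = 31))
  xy <- conf$table$strength[conf$table$a == "x" & conf$table$b == "y"]
  expect_gte(xy, 0.9)

  dn <- independent_data(2000, p = 3, seed = 22)
  confn <- arc_confidence(bootstrap_networks(dn, spec_from_data(dn),
                                             B = 50, seed = 32))
  expect_true(all(confn$table$strength <= 0.5))
})

test_that("thresholding the averaged network is a monotone filter", {
  nodes <- c("A", "B", "C")
  dags <- list(empty_dag(nodes, rbind(c("A", "B"), c("B", "C"))),
               empty_dag(nodes, rbind(c("A", "B"))),
               empty_dag(nodes, rbind(c("A", "B"))),
               empty_dag(nodes, rbind(c("A", "B"), c("C", "B"))))
  conf <- arc_confidence(dags)
  # strengths: A-B = 1, B-C = 0.5
  a5 <- averaged_network(conf, 0.5)
  expect_equal(n_arcs(a5$dag), 2)
  a9 <- averaged_network(conf, 0.9)
  expect_equal(n_arcs(a9$dag), 1)
  expect_true(has_arc(a9$dag, "A", "B"))
  # raising the threshold never adds an arc
  keys <- function(g) apply(dag_arcs(g), 1, paste, collapse = ">")
  for (t2 in c(0.6, 0.8, 1)) {
    at <- averaged_network(conf, t2)
    expect_true(all(keys(at$dag) %in% keys(a5$dag)))
  }
  # consensus at 0.5 with unanimous structures returns exactly those arcs
  conf_u <- arc_confidence(dags[c(1, 1, 1)])
  au <- averaged_network(conf_u, 0.5)
  expect_identical(clgnet:::dag_fingerprint(au$dag),
                   clgnet:::dag_fingerprint(dags[[1]]))
  expect_error(averaged_network(conf, 1.5), "threshold")
})

test_that("the automatic threshold separates clear signal from noise", {
  strengths <- c(rep(0.02, 20), rep(0.98, 5))
  t_auto <- clgnet:::estimate_strength_threshold(strengths)
  expect_gt(t_auto, 0.02)
  expect_lte(t_auto, 0.98)
})

test_that("cycle repair keeps the consensus acyclic", {
  # construct confidences whose majority orientations form a 3-cycle
  nodes <- c("A", "B", "C")
  cyc <- list(empty_dag(nodes, rbind(c("A", "B"), c("B", "C"))),
              empty_dag(nodes, rbind(c("B", "C"), c("C", "A"))),
              empty_dag(nodes, rbind(c("C", "A"), c("A", "B"))))
  conf <- arc_confidence(cyc)
  suppressMessages(av <- averaged_network(conf, 0.5))
  expect_true(is_acyclic(av$dag))
})

test_that("edge comparison counts shared and unique arcs", {
  nodes <- c("X", "Y", "Z")
  a <- empty_dag(nodes, rbind(c("X", "Y"), c("Y", "Z")))
  expect_equal(compare_edges(a, a)$shared, 2)
  expect_equal(compare_edges(a, a)$unique_to_first, 0)
  b <- empty_dag(nodes, rbind(c("Y", "X")))
  cmp_dir <- compare_edges(a, b, ignore_direction = FALSE)
  expect_equal(cmp_dir$shared, 0)
  expect_equal(cmp_dir$unique_to_first, 2)
  expect_equal(cmp_dir$unique_to_second, 1)
  cmp_sk <- compare_edges(a, b, ignore_direction = TRUE)
  expect_equal(cmp_sk$shared, 1)
  expect_error(compare_edges(a, empty_dag(c("X", "Y"))), "node sets")
})

test_that("confidence tables are deterministic given the seed", {
  d <- chain3_data(n = 400, seed = 6)
  spec <- spec_from_data(d)
  c1 <- arc_confidence(bootstrap_networks(d, spec, B = 10, seed = 5))
  c2 <- arc_confidence(bootstrap_networks(d, spec, B = 10, seed = 5))
  expect_identical(c1$table, c2$table)
})
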