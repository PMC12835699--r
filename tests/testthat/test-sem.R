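test_that("numeric encoding follows the documented codings", {
  spec <- variable_spec(
    c("sex", "age", "race", "score"),
    c("discrete", "discrete", "discrete", "continuous"),
    list(c("male", "female"), c("<30", "31-45", ">45"),
         c("white", "black", "asian", "other"), NULL),
    ordered = c(FALSE, TRUE, FALSE, FALSE))
  d <- data.frame(sex = c("male", "female", "male"),
                  age = c("<30", ">45", "31-45"),
                  race = c("white", "asian", "black"),
                  score = c(1.5, 2.5, 0.5))
  enc <- encode_for_sem(d, spec)
  expect_equal(unname(enc$matrix[, "sex"]), c(0, 1, 0))
  expect_equal(unname(enc$matrix[, "age"]), c(0, 2, 1))
  expect_setequal(enc$colmap$race,
                  c("race.black", "race.asian", "race.other"))
  expect_equal(unname(enc$matrix[, "race.asian"]), c(0, 1, 0))
  expect_equal(unname(enc$matrix[, "score"]), d$score)
  d1 <- d; d1$sex <- rep("male", 3)
  expect_error(encode_for_sem(d1, spec), "one observed level")
})

test_that("Holm adjustment matches hand-derived and literal step-down values", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:20, 1))
    got <- holm_adjust(p)
    expect_equal(got, oracle_holm(p), tolerance = 1e-12)
    expect_equal(got, stats::p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(got >= p))
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))
  }
})

test_that("fit indices honour their closed-form anchors", {
  fi <- fit_indices(10, 10, 200, 20, 500)   # T = df: perfect fit
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  fi0 <- fit_indices(200, 20, 200, 20, 500) # no improvement over the null
  expect_equal(fi0$cfi, 0)
  expect_error(fit_indices(1, 0, 0, 0, 100), "df_null")
})

test_that("a saturated path model reproduces the sample covariance", {
  set.seed(23)
  d <- as.data.frame(matrix(stats::rnorm(200 * 3), 200, 3))
  names(d) <- c("a", "b", "c")
  dag <- empty_dag(c("a", "b", "c"),
                   rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  fit <- fit_path_model(dag, as.matrix(d))
  expect_equal(fit$global$df, 0)
  expect_lt(abs(fit$global$chi_square), 1e-6)
  expect_equal(fit$global$rmsea, 0)
})

test_that("a single standardized arc recovers the Pearson correlation", {
  set.seed(29)
  x <- stats::rnorm(300)
  y <- 0.6 * x + stats::rnorm(300)
  m <- cbind(x = x, y = y)
  dag <- empty_dag(c("x", "y"), rbind(c("x", "y")))
  fit <- fit_path_model(dag, m)
  expect_equal(fit$paths$beta, stats::cor(x, y), tolerance = 1e-10)
})

test_that("known path-model coefficients are recovered at n = 5000", {
  truth <- net_chain3(slope = 0.8)
  d <- sample_dataset(truth, 5000, seed = 31)
  fit <- fit_path_model(truth$dag, as.matrix(d))
  for (i in seq_len(nrow(fit$paths)))
    expect_lt(abs(fit$paths$b[i] - 0.8), 0.05)
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
  expect_true(all(fit$paths$p_holm >= fit$paths$p - 1e-15))
})

test_that("equation-wise estimates ignore node-order permutations", {
  g <- generate_catie_like(generator_config(n = 500, seed = 41,
                                            missing_rate = 0,
                                            n_bad_rows = 0))
  enc <- encode_for_sem(g$complete, g$spec)
  fit1 <- fit_path_model(g$truth$dag, enc)
  # same dag with nodes listed in reverse order
  dag_rev <- empty_dag(rev(g$truth$dag$nodes), dag_arcs(g$truth$dag))
  fit2 <- fit_path_model(dag_rev, enc)
  m1 <- fit1$paths[order(fit1$paths$from, fit1$paths$to), ]
  m2 <- fit2$paths[order(fit2$paths$from, fit2$paths$to), ]
  expect_equal(m1$b, m2$b, tolerance = 1e-10)
  expect_equal(fit1$global$chi_square, fit2$global$chi_square,
               tolerance = 1e-8)
})

test_that("information criteria order true and null arcs correctly", {
  better <- worse <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    truth <- net_chain3(slope = 0.4)
    d <- as.matrix(sample_dataset(truth, 1450, seed = 500 + s))
    dag_t <- truth$dag
    dag_missing <- drop_arc(dag_t, "y", "z")      # remove a true arc
    dag_extra <- add_arc(dag_t, "x", "z")          # add a null arc
    bic <- function(g) fit_path_model(g, d)$global$bic
    better <- better + (bic(dag_t) < bic(dag_missing))
    worse <- worse + (bic(dag_extra) > bic(dag_t))
  }
  expect_gte(better, n_seeds - 1)
  expect_gte(worse, n_seeds - 1)
})

test_that("singular designs are reported with the offending node", {
  set.seed(43)
  x <- stats::rnorm(100)
  m <- cbind(x = x, x2 = 2 * x, y = stats::rnorm(100))
  dag <- empty_dag(c("x", "x2", "y"), rbind(c("x", "y"), c("x2", "y")))
  expect_error(fit_path_model(dag, m), "singular design for node 'y'")
})
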