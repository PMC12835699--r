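test_that("row filter drops strictly-above-threshold rows only", {
  d <- as.data.frame(matrix(1, 4, 20))
  d[1, 1:11] <- NA  # 11/20 = 0.55 > 0.5 -> removed
  d[2, 1:10] <- NA  # exactly 0.5 -> retained
  res <- filter_rows_by_missingness(d, 0.5)
  expect_equal(res$n_removed, 1)
  expect_equal(nrow(res$data), 3)
  # a 21-column row with 11 missing (0.524) is removed
  d21 <- as.data.frame(matrix(1, 2, 21))
  d21[2, 1:11] <- NA
  expect_equal(filter_rows_by_missingness(d21, 0.5)$n_removed, 1)
  expect_error(filter_rows_by_missingness(
    as.data.frame(matrix(NA_real_, 2, 3)), 0.5), "all rows")
})

test_that("filter-then-impute reproduces the generator's bookkeeping", {
  g <- generate_catie_like(generator_config(n = 1460, seed = 2,
                                            missing_rate = 0.024,
                                            n_bad_rows = 10))
  f <- filter_rows_by_missingness(g$data, 0.5)
  expect_equal(f$n_removed, 10)
  expect_equal(nrow(f$data), 1450)
  expect_lt(abs(mean(is.na(f$data)) - 0.024), 0.005)
})

test_that("age categorization follows the three published bands", {
  out <- categorize_age(c(29, 30, 31, 45, 46))
  expect_equal(as.character(out), c("<30", "<30", "31-45", "31-45", ">45"))
  expect_identical(levels(out), c("<30", "31-45", ">45"))
  expect_error(categorize_age(c(30, -1)), "positive")
})

test_that("standardization hits mean 0 / sd 1 and is idempotent", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  s <- standardize_columns(d, c("a", "b"))
  expect_equal(s$a, c(-1, 0, 1))
  expect_equal(mean(s$b), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s$b), 1, tolerance = 1e-12)
  s2 <- standardize_columns(s, c("a", "b"))
  expect_equal(s2$a, s$a, tolerance = 1e-12)
  expect_error(standardize_columns(data.frame(z = rep(1, 3)), "z"),
               "zero-variance")
})

test_that("imputation returns complete data without touching observed cells", {
  g <- generate_catie_like(generator_config(n = 300, seed = 4,
                                            missing_rate = 0.05,
                                            n_bad_rows = 0))
  mask <- is.na(g$data)
  res <- impute_random_forest(g$data, g$spec, n_trees = 20, seed = 9)
  expect_false(anyNA(res$data))
  expect_equal(res$report$cell_missing_fraction, mean(mask),
               tolerance = 1e-12)
  for (j in seq_len(ncol(g$data)))
    expect_identical(res$data[[j]][!mask[, j]],
                     clgnet:::conform_data(g$data, g$spec)[[j]][!mask[, j]])
  # deterministic given seed
  res2 <- impute_random_forest(g$data, g$spec, n_trees = 20, seed = 9)
  expect_identical(res$data, res2$data)
})

test_that("complete data passes through imputation unchanged", {
  g <- generate_catie_like(generator_config(n = 100, seed = 8,
                                            missing_rate = 0,
                                            n_bad_rows = 0))
  res <- impute_random_forest(g$data, g$spec, seed = 1)
  expect_equal(res$report$n_iterations, 1)
  expect_identical(res$data, clgnet:::conform_data(g$data, g$spec))
})

test_that("random-forest imputation beats mean imputation on a strong signal", {
  set.seed(31)
  n <- 400
  x <- stats::rnorm(n)
  y <- x + stats::rnorm(n, sd = 0.1)
  spec <- variable_spec(c("x", "y"), "continuous")
  d <- data.frame(x = x, y = y)
  idx <- sample.int(n, 40)
  d$y[idx] <- NA
  res <- impute_random_forest(d, spec, n_trees = 50, seed = 2)
  nrmse_rf <- sqrt(mean((res$data$y[idx] - y[idx])^2)) / stats::sd(y)
  nrmse_mean <- sqrt(mean((mean(d$y, na.rm = TRUE) - y[idx])^2)) /
    stats::sd(y)
  expect_lt(nrmse_rf, nrmse_mean)
})

test_that("random-forest imputation beats mode imputation given a strong discrete predictor", {
  set.seed(37)
  n <- 600
  d1 <- factor(sample(c("a", "b"), n, TRUE, prob = c(0.5, 0.5)))
  # d2 tracks d1 closely: the Bayes classifier differs from the mode
  d2 <- factor(ifelse(stats::runif(n) < 0.9, as.character(d1),
                      ifelse(d1 == "a", "b", "a")), levels = c("a", "b"))
  spec <- variable_spec(c("d1", "d2"), "discrete",
                        list(c("a", "b"), c("a", "b")))
  d <- data.frame(d1 = d1, d2 = d2)
  idx <- sample.int(n, 60)
  d$d2[idx] <- NA
  res <- impute_random_forest(d, spec, n_trees = 50, seed = 3)
  tab <- table(d$d2[-idx])
  mode_lv <- names(tab)[which.max(tab)]
  pfc_rf <- mean(res$data$d2[idx] != d2[idx])
  pfc_mode <- mean(mode_lv != as.character(d2[idx]))
  expect_lt(pfc_rf, pfc_mode)
})

test_that("imputation rejects unusable inputs", {
  spec <- variable_spec(c("x", "y"), "continuous")
  bad <- data.frame(x = c(NA_real_, NA_real_), y = c(1, 2))
  expect_error(impute_random_forest(bad, spec), "zero observed")
  ok <- data.frame(x = c(1, NA), y = c(1, 2))
  expect_error(impute_random_forest(ok, spec, max_iter = 0), "max_iter")
})
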