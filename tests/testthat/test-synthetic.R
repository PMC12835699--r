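test_that("the CATIE-like truth carries the published arc roster", {
  truth <- make_catie_like_truth(seed = 1, effect_scale = 1)
  expect_equal(length(truth$dag$nodes), 21)
  ann <- truth$annotations
  beta_of <- function(f, t) ann$beta[ann$from == f & ann$to == t]
  expect_equal(beta_of("matrics_speed", "panss_negative"), -0.25)
  expect_equal(beta_of("panss_negative", "qol"), -0.33)
  expect_equal(beta_of("panss_general", "panss_negative"), 0.61)
  expect_equal(beta_of("panss_general", "panss_positive"), 0.64)
  expect_equal(beta_of("cdss", "panss_general"), 0.35)
  expect_equal(beta_of("cdss", "panss_negative"), -0.14)
  expect_equal(beta_of("matrics_memory", "panss_general"), -0.14)
  expect_equal(beta_of("panss_positive", "cgi_severity"), 0.45)
  expect_equal(beta_of("matrics_speed", "qol"), 0.12)
  expect_equal(beta_of("employment", "qol"), -0.32)
  # processing speed parents every other cognitive domain, positively
  for (m in c("matrics_verbal", "matrics_vigilance", "matrics_reasoning",
              "matrics_memory"))
    expect_gt(beta_of("matrics_speed", m), 0)
  # six parents of QOL as published
  expect_setequal(truth$dag$parents[["qol"]],
                  c("dai", "cdss", "cgi_severity", "panss_negative",
                    "matrics_speed", "employment"))
  # demographics are roots or have only discrete parents
  spec <- truth$spec
  for (v in spec$name[spec$kind == "discrete"])
    expect_true(all(is_discrete(spec, truth$dag$parents[[v]])))
  # blacklist: no continuous -> discrete arc anywhere
  a <- dag_arcs(truth$dag)
  expect_false(any(!is_discrete(spec, a[, 1]) & is_discrete(spec, a[, 2])))
})

test_that("effect_scale 0 zeroes coefficients but keeps residual sds", {
  t1 <- make_catie_like_truth(effect_scale = 1)
  t0 <- make_catie_like_truth(effect_scale = 0)
  for (v in t0$spec$name[t0$spec$kind == "continuous"]) {
    f0 <- t0$params$nodes[[v]]; f1 <- t1$params$nodes[[v]]
    expect_true(all(f0$coef == 0))
    expect_equal(f0$sd, f1$sd)
  }
})

test_that("residual variances give unit marginal variance at scale 1", {
  truth <- make_catie_like_truth()
  d <- sample_dataset(truth, 50000, seed = 42)
  for (v in c("matrics_memory", "panss_negative", "qol", "cgi_severity"))
    expect_lt(abs(stats::var(d[[v]]) - 1), 0.05)
})

test_that("ancestral sampling matches its distributional contracts", {
  # isolated continuous node: LLN bound on the mean
  d1 <- sample_dataset(net_single_cont(), 10000, seed = 7)
  expect_lt(abs(mean(d1$x)), 4 / sqrt(10000))
  # two-node net: OLS slope recovers the generating coefficient
  d2 <- sample_dataset(net_two_cont(slope = 0.5), 50000, seed = 8)
  slope <- unname(stats::coef(stats::lm(y ~ x, d2))["x"])
  expect_lt(abs(slope - 0.5), 0.02)
  # binary root frequency (the CATIE male fraction)
  d3 <- sample_dataset(net_binary_root(0.744), 100000, seed = 9)
  expect_lt(abs(mean(d3$d == "a") - 0.744), 0.01)
})

test_that("sampling errors on a cyclic structure", {
  net <- net_two_cont()
  net$dag$parents$x <- "y"  # force a 2-cycle past the class invariant
  expect_error(sample_dataset(net, 10, seed = 1), "cycle")
})

test_that("generation is byte-identical under a fixed config", {
  cfg <- generator_config(n = 200, seed = 11, missing_rate = 0.05,
                          n_bad_rows = 3)
  a <- generate_catie_like(cfg)
  b <- generate_catie_like(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$complete, b$complete)
})

test_that("annotated coefficients are recovered from a large sample", {
  truth <- make_catie_like_truth()
  d <- sample_dataset(truth, 50000, seed = 13)
  enc <- encode_for_sem(d, truth$spec)
  fit <- fit_path_model(truth$dag, enc)
  ann <- truth$annotations[!is.na(truth$annotations$beta), ]
  got <- merge(ann, fit$paths, by = c("from", "to"))
  expect_equal(nrow(got), nrow(ann))
  expect_lt(max(abs(got$beta.x - got$beta.y)), 0.02)
})

test_that("missingness injection honours rates, bad rows and determinism", {
  cfg0 <- generator_config(n = 100, seed = 3, missing_rate = 0,
                           n_bad_rows = 0)
  truth <- make_catie_like_truth()
  comp <- sample_dataset(truth, 100, seed = 3)
  expect_identical(inject_missingness(comp, cfg0), comp)

  cfg <- generator_config(n = 1460, seed = 5, missing_rate = 0.024,
                          n_bad_rows = 10)
  big <- sample_dataset(truth, 1460, seed = 5)
  holey <- inject_missingness(big, cfg)
  frac <- rowMeans(is.na(holey))
  expect_equal(sum(frac > 0.5), 10)
  expect_identical(inject_missingness(big, cfg), holey)

  cfg2 <- generator_config(n = 1000, seed = 6, missing_rate = 0.05,
                           n_bad_rows = 0)
  d2 <- sample_dataset(truth, 1000, seed = 6)
  h2 <- inject_missingness(d2, cfg2)
  expect_lt(abs(mean(is.na(h2)) - 0.05), 0.01)

  expect_error(generator_config(missing_rate = 0.6), "missing_rate")
  expect_error(generator_config(n = 5, n_bad_rows = 5))
})

test_that("dataset CSV + spec round-trip preserves values and kinds", {
  cfg <- generator_config(n = 50, seed = 21, missing_rate = 0.1,
                          n_bad_rows = 2)
  g <- generate_catie_like(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_mixed_csv(g$data, csv)
  write_var_spec(g$spec, yml)
  spec2 <- read_var_spec(yml)
  back <- read_mixed_csv(csv, spec2)
  expect_equal(dim(back), dim(g$data))
  expect_identical(is.na(back), is.na(g$data))
  expect_equal(back$qol, g$data$qol, tolerance = 1e-12)
  expect_identical(as.character(back$sex), as.character(g$data$sex))
})
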