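test_that("kinetic and demand sampling covers the documented intervals", {
  topo <- build_topology("linear", "none")
  set.seed(123)
  kc <- replicate(2000, sample_parameters(topo)$params$kcat[[1]])
  expect_gte(min(kc), 1e-3)
  expect_lte(max(kc), 2)
  ks <- stats::ks.test(kc, "punif", 1e-3, 2)
  expect_gt(ks$p.value, 0.01)

  set.seed(5)
  dd <- replicate(500, sample_parameters(topo)$dilution_values)
  expect_gte(min(dd), 0.2)
  expect_lte(max(dd), 0.8)

  set.seed(77)
  a <- sample_parameters(topo)
  set.seed(77)
  b <- sample_parameters(topo)
  expect_identical(a, b)
})

test_that("scenarios produce one record per run, reproducibly", {
  cfg <- scenario_config("tiny", kind = "linear", inhibition = "none",
                         n_runs = 3L, seed = 9L, budget = 2e3)
  rec1 <- run_scenario(cfg)
  expect_equal(nrow(rec1), 3L)
  # distinct sampled demands per run
  expect_equal(length(unique(rec1$dil_v_growth_1)), 3L)
  rec2 <- run_scenario(cfg)
  expect_identical(rec1, rec2)
})

test_that("paired scans reuse identical sampled parameters", {
  cfg <- scenario_config("paired", kind = "linear", inhibition = "initial",
                         n_runs = 2L, seed = 4L, budget = 2e3)
  scan <- kr_scan(cfg, kr_grid = c(0.5, 5), include_uninhibited = FALSE)
  d1 <- scan$records[[1]][, grep("^dil_", names(scan$records[[1]]))]
  d2 <- scan$records[[2]][, grep("^dil_", names(scan$records[[2]]))]
  expect_identical(d1, d2)
  expect_error(kr_scan(cfg, kr_grid = numeric()), "non-empty")
  expect_error(kr_scan(cfg, kr_grid = c(0, 1)), "positive")
})

test_that("rank-sum comparisons match exact enumeration", {
  cmp <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$p.value, 0.1)  # extreme labeling 2/20, two-sided

  # identical samples: p = 1 with a tie warning
  expect_warning(tie <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)),
                 "identical")
  expect_equal(tie$p.value, 1)

  # enumeration oracle agreement for small untied samples
  set.seed(8)
  for (i in 1:10) {
    x <- round(runif(5), 3)
    y <- round(runif(6) + 0.2, 3)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value, enum_ranksum_p(x, y),
                 tolerance = 1e-12)
  }

  # the large-sample normal approximation tracks enumeration on
  # subsamples of six
  set.seed(9)
  x <- rnorm(50)
  y <- rnorm(50, 0.5)
  approx_p <- wilcoxon_rank_sum(x, y)$p.value
  expect_gt(approx_p, 0)
  xs <- x[1:6]; ys <- y[1:6]
  expect_equal(wilcoxon_rank_sum(xs, ys)$p.value, enum_ranksum_p(xs, ys),
               tolerance = 0.02)
})

test_that("control-point counting implements the share rule", {
  expect_equal(count_control_points(c(e1 = 0, e2 = 0, e3 = 0)), 0L)
  expect_equal(count_control_points(c(1, 1, 0.01, 0.01, 0.01)), 2L)
  expect_equal(count_control_points(c(1, 0.2, 0.2, 0.2, 0.2)), 5L)
  # boundary: share must strictly exceed tau
  expect_equal(count_control_points(c(1, 1, 1, 1), tau = 0.25), 0L)
  expect_error(count_control_points(c(1, 2), tau = 0), "tau")
})

test_that("ensemble medians summarize only feasible runs", {
  rec <- data.frame(feasible = c(TRUE, TRUE, FALSE),
                    reg_e1 = c(1, 3, 100), reg_e2 = c(0, 0.2, 50))
  med <- ensemble_medians(rec)
  expect_equal(unname(med), c(2, 0.1))
  expect_equal(names(med), c("e1", "e2"))
})
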