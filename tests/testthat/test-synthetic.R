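test_that("generated annotations are reproducible and well formed", {
  cfg <- annotation_config(n_genomes = 2L, genes_per_genome = 40L,
                           seed = 11L)
  a <- generate_annotation(cfg)
  b <- generate_annotation(cfg)
  expect_identical(a, b)
  ann <- a[[1]]
  expect_true(all(ann$start <= ann$end))
  expect_false(is.unsorted(ann$start))
  # operon members are contiguous and co-directional
  for (op in unique(stats::na.omit(ann$operon_id))) {
    idx <- which(ann$operon_id %in% op)
    expect_true(all(diff(idx) == 1L))
    expect_equal(length(unique(ann$strand[idx])), 1L)
  }
  # pathway chains carry consistent position labels
  pw <- split(ann[!is.na(ann$pathway_id), ], ann$pathway_id[
    !is.na(ann$pathway_id)])
  for (d in pw) {
    expect_true(all(d$position %in% c("initial", "intermediate", "terminal",
                                      "pre_branch", "branch",
                                      "pre_converging", "converging")))
    expect_equal(sum(d$position == "initial"), 1L)
  }
  # genes never overlap
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
})

test_that("planted branch effects are recovered from pooled genomes", {
  cfg <- annotation_config(n_genomes = 30L, genes_per_genome = 40L,
                           delta = c(branch = 200), seed = 21L)
  anns <- generate_annotation(cfg)
  prof <- do.call(rbind, lapply(anns, function(a) analyze_genome(a)$relative))
  # the additive plant lengthens branch promoters, which can push a
  # pathway over the sparse/pervasive cut; recovery is assessed on all
  # pathways so the classification step does not censor the effect
  cmp <- positional_comparison(prof, "pre_branch_vs_branch",
                               sparse_only = FALSE)
  expect_lt(cmp$p.value, 0.01)
  expect_lt(cmp$medians[1], cmp$medians[2])
})

test_that("planted PTM shrinkage shortens promoters of modified enzymes", {
  cfg <- annotation_config(n_genomes = 30L, genes_per_genome = 40L,
                           ptm_factor = 0.4, ptm_rate = 0.4, seed = 22L)
  anns <- generate_annotation(cfg)
  prof <- do.call(rbind, lapply(anns, function(a) analyze_genome(a)$relative))
  cmp <- positional_comparison(prof, "ptm_vs_no_ptm")
  expect_lt(cmp$p.value, 0.05)
  expect_lt(cmp$medians[1], cmp$medians[2])  # ptm group shorter
})

test_that("null data give calibrated rejection rates", {
  set.seed(23)
  n_rep <- 60L
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- annotation_config(n_genomes = 6L, genes_per_genome = 30L,
                             seed = 1000L + r)
    anns <- generate_annotation(cfg)
    prof <- do.call(rbind, lapply(anns,
                                  function(a) analyze_genome(a)$relative))
    p <- positional_comparison(prof, "pre_branch_vs_branch",
                               sparse_only = FALSE)$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # binomial band around 0.05 at n = 60
  expect_lte(rate, 0.15)
})

test_that("recovery strengthens with the number of genomes", {
  ps <- vapply(c(6L, 16L, 40L), function(n) {
    cfg <- annotation_config(n_genomes = n, genes_per_genome = 40L,
                             delta = c(branch = 150), seed = 31L)
    anns <- generate_annotation(cfg)
    prof <- do.call(rbind, lapply(anns,
                                  function(a) analyze_genome(a)$relative))
    positional_comparison(prof, "pre_branch_vs_branch",
                          sparse_only = FALSE)$p.value
  }, numeric(1))
  expect_true(ps[3] < ps[1])
  expect_lt(ps[3], 0.01)
})

test_that("scenario suites encode the experiment grid", {
  ms <- generate_scenario_suite("m_scan", n_runs = 5L, seed = 2L)
  expect_length(ms, 3L)
  expect_equal(vapply(ms, `[[`, numeric(1), "m"), c(0.06, 0.10, 0.15))
  # configs differ only in m
  strip <- function(cfg) cfg[setdiff(names(cfg), c("id", "m"))]
  expect_identical(strip(ms[[1]]), strip(ms[[3]]))

  il <- generate_scenario_suite("inhibition_linear")
  expect_length(il, 4L)
  expect_setequal(vapply(il, `[[`, numeric(1), "sigma"), c(0.1, 0.1, 10, 10))

  ks <- generate_scenario_suite("kr_scan")
  expect_length(ks, 6L)
  expect_equal(length(unique(vapply(ks, `[[`, numeric(1), "seed"))), 1L)
  kr <- vapply(ks, `[[`, numeric(1), "kr")
  expect_equal(range(kr), c(1e-2, 1e2))

  dv <- generate_scenario_suite("diverging_nested")
  expect_length(dv, 4L)
  expect_error(generate_scenario_suite("unknown"))
})
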