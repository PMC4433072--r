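test_that("promoter lengths follow the upstream-gap sharing rule", {
  # co-directional pair: full gap to the downstream gene
  g <- genes_df(list("A", 101, 200, "+"), list("B", 301, 400, "+"))
  pl <- promoter_lengths(g)
  expect_equal(pl$promoter_length[pl$gene_id == "B"], 100)
  expect_false(pl$shared[pl$gene_id == "B"])

  # divergent pair: the gap is shared equally
  g2 <- genes_df(list("A", 101, 200, "-"), list("B", 301, 400, "+"))
  pl2 <- promoter_lengths(g2)
  expect_equal(pl2$promoter_length[pl2$gene_id == "B"], 50)
  expect_equal(pl2$promoter_length[pl2$gene_id == "A"], 50)
  expect_true(all(pl2$shared))

  # overlapping coding regions: missing
  g3 <- genes_df(list("A", 101, 250, "+"), list("B", 201, 400, "+"))
  pl3 <- promoter_lengths(g3)
  expect_true(is.na(pl3$promoter_length[pl3$gene_id == "B"]))

  # replicon boundary: missing
  expect_true(is.na(pl$promoter_length[pl$gene_id == "A"]))
})

test_that("intergenic base pairs are conserved under sharing", {
  set.seed(14)
  for (i in 1:20) {
    gap <- sample(10:300, 1)
    a_end <- 500
    g <- genes_df(list("A", 101, a_end, "-"),
                  list("B", a_end + gap + 1, a_end + gap + 600, "+"))
    pl <- promoter_lengths(g)
    expect_equal(sum(pl$promoter_length), gap)
  }
})

test_that("operon members inherit the leader promoter", {
  g <- genes_df(list("A", 1, 500, "+"),
                list("B", 701, 1200, "+", "op1"),
                list("C", 1210, 1700, "+", "op1"),
                list("D", 2000, 2500, "-"))
  pl <- promoter_lengths(g)
  # leader B has gap 200 from A; member C inherits it
  expect_equal(pl$promoter_length[pl$gene_id == "B"], 200)
  expect_equal(pl$promoter_length[pl$gene_id == "C"], 200)
  expect_equal(pl$anchor[pl$gene_id == "C"], "B")
  # minus-strand leader of a minus-strand operon is the rightmost member
  g2 <- genes_df(list("A", 1, 500, "-", "opX"),
                 list("B", 600, 1100, "-", "opX"),
                 list("C", 1400, 1900, "-"))
  pl2 <- promoter_lengths(g2)
  expect_equal(pl2$anchor[pl2$gene_id == "A"], "B")
  expect_equal(pl2$promoter_length[pl2$gene_id == "B"], 299)

  expect_error(promoter_lengths(genes_df(list("A", 10, 5, "+"))), "start")
  bad <- genes_df(list("A", 1, 100, "+", "op"), list("B", 200, 300, "+"),
                  list("C", 400, 500, "+", "op"))
  expect_error(promoter_lengths(bad), "contiguous")
})

test_that("relative promoter lengths normalize within pathway and genome", {
  asg <- data.frame(gene_id = c("g1", "g2", "g3", "n1", "n2"),
                    promoter_length = c(100, 200, 300, 150, 250))
  memb <- data.frame(gene_id = c("g1", "g2", "g3"),
                     pathway_id = "pw1")
  rel <- relative_promoter_lengths(asg, memb, c("n1", "n2"))
  expect_equal(rel$relative_length, c(-0.5, 0, 0.5))

  # missing members drop out of the pathway mean
  asg2 <- data.frame(gene_id = c("g1", "g2", "g3", "n1"),
                     promoter_length = c(100, NA, 300, 100))
  rel2 <- relative_promoter_lengths(asg2, memb, "n1")
  expect_equal(rel2$relative_length, c(-1, NA, 1))

  expect_error(relative_promoter_lengths(
    data.frame(gene_id = "g1", promoter_length = 10), memb, "zz"),
    "non-metabolic")
})

test_that("relative lengths are invariant under uniform rescaling", {
  set.seed(15)
  asg <- data.frame(gene_id = paste0("g", 1:8),
                    promoter_length = runif(8, 20, 400))
  memb <- data.frame(gene_id = paste0("g", 1:4), pathway_id = "pw")
  r1 <- relative_promoter_lengths(asg, memb, paste0("g", 5:8))
  asg2 <- asg
  asg2$promoter_length <- asg2$promoter_length * 3.7
  r2 <- relative_promoter_lengths(asg2, memb, paste0("g", 5:8))
  expect_equal(r1$relative_length, r2$relative_length, tolerance = 1e-12)
})

test_that("the 60% rule classifies sparse vs pervasive with a strict cut", {
  expect_equal(classify_pathway(c(40, 60), 100), "sparse")     # mean 50
  expect_equal(classify_pathway(c(60, 80), 100), "pervasive")  # mean 70
  expect_equal(classify_pathway(c(50, 70), 100), "pervasive")  # exactly 60
  expect_error(classify_pathway(c(10, NA), 100), "two genes")
  # monotone: lengthening a promoter never flips pervasive -> sparse
  set.seed(16)
  for (i in 1:20) {
    lens <- runif(4, 10, 150)
    cls <- classify_pathway(lens, 100)
    cls2 <- classify_pathway(lens + c(30, 0, 0, 0), 100)
    expect_false(cls == "pervasive" && cls2 == "sparse")
  }
})

test_that("positional comparisons pool groups and test differences", {
  set.seed(17)
  prof <- data.frame(
    relative_length = c(rnorm(40, 0, 0.1), rnorm(40, 0.5, 0.1)),
    position = rep(c("pre_branch", "branch"), each = 40),
    ptm_count = 0L, class = "sparse")
  cmp <- positional_comparison(prof, "pre_branch_vs_branch")
  expect_lt(cmp$p.value, 1e-6)
  expect_lt(cmp$medians[1], cmp$medians[2])
  expect_error(positional_comparison(prof, "initial_vs_terminal"),
               "at least two")
})

test_that("annotation tables round-trip through the TSV dialect", {
  ann <- generate_annotation(annotation_config(n_genomes = 1L,
                                               genes_per_genome = 30L,
                                               seed = 3L))[[1]]
  path <- tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, path, seed = 3L)
  back <- read_annotation_tsv(path)
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$start, ann$start)
  expect_equal(back$is_metabolic, ann$is_metabolic)
  expect_error(read_annotation_tsv({
    f <- tempfile(); writeLines("gene_id\tstart\na\t1", f); f
  }), "lacks columns")
})
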