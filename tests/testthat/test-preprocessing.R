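test_that("experiment_design validates its invariants", {
  d <- experiment_design(c(0, 2, 6), c("ctrl", "trt"), control = "ctrl",
                         replicates = 3)
  expect_s3_class(d, "experiment_design")
  expect_named(d$replicates, c("ctrl", "trt"))

  expect_error(experiment_design(c(0), c("a"), replicates = 1),
               "at least 2 time points")
  expect_error(experiment_design(c(0, 0, 2), c("a"), replicates = 1),
               "strictly increasing")
  expect_error(experiment_design(c(0, 1), c("a", "b"), control = "x",
                                 replicates = 1), "control")
  expect_error(experiment_design(c(0, 1), c("a"), control = "a",
                                 replicates = 1), "at least 2 conditions")
  expect_error(experiment_design(c(0, 1), c("a"), replicates = 0),
               "positive")
})

test_that("loading rearranges a table into per-condition tensors", {
  # 1 gene, 1 condition, T = 2, R = 1: identity rearrangement
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "m.tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t5.0\t7.0"), f)
  design <- experiment_design(c(0, 1), "only", replicates = 1)
  cmap <- data.frame(sample = c("s1", "s2"), condition = "only",
                     time = c(0, 1), replicate = 1)
  tens <- load_expression(f, design, cmap)
  expect_equal(dim(tens$only$values), c(1, 1, 2))
  expect_equal(as.vector(tens$only$values), c(5, 7))

  # two-condition, 6 time points, 3 replicates layout
  design2 <- experiment_design(0:5, c("ctrl", "ind"), control = "ctrl",
                               replicates = 3)
  G <- 11
  set.seed(42)
  sim_tens <- list(
    ctrl = condition_tensor("ctrl", array(rnorm(G * 3 * 6, 8), c(G, 3, 6)),
                            sprintf("g%02d", 1:G)),
    ind = condition_tensor("ind", array(rnorm(G * 3 * 6, 8), c(G, 3, 6)),
                           sprintf("g%02d", 1:G)))
  f2 <- file.path(tmp, "m2.tsv"); cm2 <- file.path(tmp, "cm2.tsv")
  write_expression(sim_tens, design2, f2, cm2)
  back <- load_expression(f2, design2, cm2)
  expect_equal(dim(back$ctrl$values), c(G, 3, 6))
  expect_equal(dim(back$ind$values), c(G, 3, 6))
  # round trip reproduces every cell (write uses 10 significant digits)
  expect_equal(back$ctrl$values, sim_tens$ctrl$values, tolerance = 1e-8)
  expect_equal(back$ind$values, sim_tens$ind$values, tolerance = 1e-8)
  expect_identical(back$ctrl$feature_ids, sim_tens$ctrl$feature_ids)
})

test_that("loader rejects malformed designs and data", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "m.tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t5.0\t7.0"), f)
  design <- experiment_design(c(0, 1), "only", replicates = 1)

  # missing cell
  cmap <- data.frame(sample = "s1", condition = "only", time = 0,
                     replicate = 1)
  expect_error(load_expression(f, design, cmap),
               "no sample column for cell \\(condition=only, time=1")
  # duplicated cell
  cmap2 <- data.frame(sample = c("s1", "s2"), condition = "only",
                      time = c(0, 0), replicate = 1)
  expect_error(load_expression(f, design, cmap2), "duplicated sample columns")
  # non-numeric entry names row and column
  writeLines(c("feature_id\ts1\ts2", "g1\t5.0\toops"), f)
  cmap3 <- data.frame(sample = c("s1", "s2"), condition = "only",
                      time = c(0, 1), replicate = 1)
  expect_error(load_expression(f, design, cmap3),
               "non-numeric entry 'oops' at row 'g1', column 's2'")
  # missing values are rejected, not imputed
  writeLines(c("feature_id\ts1\ts2", "g1\t5.0\tNA"), f)
  expect_error(load_expression(f, design, cmap3), "missing value")
})

test_that("unequal replicate counts force mean summarization with warning", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "m.tsv")
  writeLines(c("feature_id\ta1\ta2\tb1\tb2\tb3\tb4",
               "g1\t1\t2\t3\t5\t4\t6"), f)
  design <- experiment_design(c(0, 1), c("A", "B"), control = "A",
                              replicates = c(A = 1, B = 2))
  cmap <- data.frame(sample = c("a1", "a2", "b1", "b2", "b3", "b4"),
                     condition = rep(c("A", "B"), c(2, 4)),
                     time = c(0, 1, 0, 0, 1, 1),
                     replicate = c(1, 1, 1, 2, 1, 2))
  expect_warning(tens <- load_expression(f, design, cmap),
                 "unequal replicate counts")
  expect_equal(dim(tens$A$values)[2], 1L)
  expect_equal(dim(tens$B$values)[2], 1L)
  expect_equal(as.vector(tens$B$values), c(mean(c(3, 5)), mean(c(4, 6))))
})

test_that("delta transform differences consecutive time points", {
  ct <- condition_tensor("a", array(c(5, 7, 4), c(1, 1, 3)), "g1")
  expect_equal(as.vector(delta_transform(ct)$deltas), c(2, -3))

  # constant profiles give all-zero deltas
  flat <- condition_tensor("a", array(3.7, c(2, 2, 4)), c("g1", "g2"))
  expect_true(all(delta_transform(flat)$deltas == 0))

  # identical shapes with different offsets become identical delta rows
  prof <- c(1, 4, 2, 2)
  shifted <- condition_tensor("a", array(rbind(prof, prof + 5), c(2, 1, 4)),
                              c("lo", "hi"))
  dd <- delta_transform(shifted)$deltas
  expect_equal(dd[1, 1, ], dd[2, 1, ])

  # T < 2 is not constructible / not transformable
  one <- condition_tensor("a", array(1, c(1, 1, 1)), "g1")
  expect_error(delta_transform(one), "at least 2 time points")
})

test_that("replicate summarization collapses to the chosen statistic", {
  ct <- condition_tensor("a", array(c(1, 2, 3), c(1, 3, 1)), "g1")
  expect_equal(as.vector(summarize_replicates(ct, "mean")$values), 2)
  ct2 <- condition_tensor("a", array(c(1, 2, 100), c(1, 3, 1)), "g1")
  expect_equal(as.vector(summarize_replicates(ct2, "median")$values), 2)
  # R = 1 is an identity for both methods
  ct3 <- condition_tensor("a", array(c(1, 5), c(1, 1, 2)), "g1")
  expect_identical(summarize_replicates(ct3, "mean"), ct3)
  expect_identical(summarize_replicates(ct3, "median"), ct3)
  expect_error(summarize_replicates(ct, "mode"), "unknown replicate summary")
})

test_that("summarize-then-difference equals difference-then-summarize (mean)", {
  set.seed(11)
  for (i in 1:5) {
    G <- sample(1:6, 1); R <- sample(2:4, 1); Tn <- sample(3:7, 1)
    ct <- random_condition_tensor(G, R, Tn)
    a <- delta_transform(summarize_replicates(ct, "mean"))$deltas
    d <- delta_transform(ct)
    b <- array(apply(d$deltas, c(1, 3), mean), dim(a))
    expect_equal(as.vector(a), as.vector(b), tolerance = 1e-12)
  }
})

test_that("feature shuffling is seeded, joint and invertible", {
  set.seed(3)
  d1 <- random_delta_tensor(8, 2, 3, "ctrl")
  d2 <- delta_tensor("case", d1$deltas + 1, d1$feature_ids)

  s1 <- shuffle_features(list(ctrl = d1, case = d2), seed = 99)
  s2 <- shuffle_features(list(ctrl = d1, case = d2), seed = 99)
  expect_identical(attr(s1, "permutation"), attr(s2, "permutation"))
  expect_identical(s1$ctrl$deltas, s2$ctrl$deltas)

  # identical permutation across conditions, inverse restores the input
  perm <- attr(s1, "permutation"); inv <- attr(s1, "inverse")
  expect_identical(s1$ctrl$feature_ids, s1$case$feature_ids)
  expect_identical(s1$ctrl$feature_ids[inv], d1$feature_ids)
  expect_equal(s1$case$deltas[inv, , ], d2$deltas)

  # the multiset of per-feature delta matrices is unchanged
  expect_setequal(s1$ctrl$feature_ids, d1$feature_ids)
  for (g in d1$feature_ids)
    expect_equal(s1$ctrl$deltas[match(g, s1$ctrl$feature_ids), , ],
                 d1$deltas[match(g, d1$feature_ids), , ])

  # G = 1 is a no-op
  one <- random_delta_tensor(1, 2, 3)
  expect_equal(shuffle_features(list(one), seed = 1)[[1]]$deltas, one$deltas)

  # mismatched ids across conditions
  d3 <- delta_tensor("case", d1$deltas, rev(d1$feature_ids))
  expect_error(shuffle_features(list(d1, d3), seed = 1), "alignment error")
})
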