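test_that("compute_cpm scales each library to one million", {
  m <- make_counts(matrix(c(3, 1, 5, 15), 2, 2))
  cpm <- compute_cpm(m)
  expect_equal(unname(cpm[, 1]), c(750000, 250000))
  expect_equal(unname(colSums(cpm)), rep(1e6, 2), tolerance = 1e-6)

  one <- counts_from_cpm(matrix(5, 1, 1, dimnames = list("gA", "sA")))
  expect_equal(compute_cpm(one)["gA", "sA"], 5)

  bad <- make_counts(matrix(c(1, 0), 1, 2), samples = c("ok", "empty"))
  expect_error(compute_cpm(bad), "empty")
})

test_that("filter_expressed requires the CPM rule in every group", {
  groups <- rep(c("A", "B"), each = 3)
  # g1 expressed everywhere, g2 all zero, g3 passes in 3 of A but 2 of B
  cpm <- matrix(0, 3, 6, dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:6)))
  cpm["g1", ] <- 1
  cpm["g3", c(1, 2, 3, 4, 5)] <- 1
  counts <- counts_from_cpm(cpm)
  kept <- filter_expressed(counts, groups, cpm_threshold = 0.05,
                           min_samples_per_group = 3)
  expect_true("g1" %in% rownames(kept))
  expect_false("g2" %in% rownames(kept))
  expect_false("g3" %in% rownames(kept))

  expect_error(filter_expressed(counts, rep(c("A", "B"), c(2, 4))),
               "min_samples_per_group")
})

test_that("filter_expressed is monotone in the CPM threshold", {
  set.seed(11)
  counts <- make_counts(matrix(rnbinom(200 * 8, mu = 3, size = 1), 200, 8))
  groups <- rep(c("A", "B"), each = 4)
  prev <- Inf
  for (thr in c(0.01, 1, 10, 100)) {
    n <- nrow(filter_expressed(counts, groups, cpm_threshold = thr,
                               min_samples_per_group = 3))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("de_test fold change follows pseudocounted CPM group means", {
  # group A at 10 cpm, group B at 100 cpm for the first gene
  cpm <- matrix(50, 2, 6, dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  cpm["g1", 1:3] <- c(9, 10, 11)
  cpm["g1", 4:6] <- c(99, 100, 101)
  counts <- counts_from_cpm(cpm)
  de <- de_test(counts, rep(c("A", "B"), each = 3), ref = "A")
  expect_equal(de$log2fc[de$gene == "g1"], log2(101 / 11), tolerance = 1e-9)
})

test_that("identical groups give zero statistics and p = 1", {
  set.seed(2)
  half <- make_counts(matrix(rnbinom(50 * 3, mu = 100, size = 5), 50, 3))
  counts <- cbind(half, half)
  colnames(counts) <- sprintf("s%d", 1:6)
  de <- de_test(counts, rep(c("A", "B"), each = 3))
  expect_true(all(de$stat == 0))
  expect_true(all(de$p == 1))
})

test_that("de_test is antisymmetric under group swap", {
  set.seed(3)
  counts <- make_counts(matrix(rnbinom(100 * 8, mu = 200, size = 5), 100, 8))
  g <- rep(c("A", "B"), each = 4)
  d1 <- de_test(counts, g, ref = "A")
  d2 <- de_test(counts, g, ref = "B")
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$stat, -d2$stat)
  expect_equal(d1$p, d2$p)
})

test_that("de_test matches stats::t.test on log2 CPM", {
  set.seed(4)
  counts <- make_counts(matrix(rnbinom(20 * 10, mu = 300, size = 3), 20, 10))
  g <- rep(c("A", "B"), each = 5)
  de <- de_test(counts, g, ref = "A")
  l <- log2(compute_cpm(counts) + 1)
  for (i in c(1, 7, 20)) {
    tt <- t.test(l[i, g == "B"], l[i, g == "A"])
    expect_equal(de$stat[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("null simulation keeps the type-I error near nominal", {
  set.seed(5)
  counts <- make_counts(matrix(rnbinom(2000 * 20, mu = 150, size = 8), 2000, 20))
  de <- de_test(counts, rep(c("A", "B"), each = 10))
  expect_gte(mean(de$p < 0.05), 0.03)
  expect_lte(mean(de$p < 0.05), 0.07)
})

test_that("bh_adjust performs the step-up adjustment in input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("cluster_samples matches a brute-force average-linkage oracle", {
  set.seed(7)
  expr <- make_counts(matrix(rnorm(30 * 5), 30, 5))
  res <- cluster_samples(expr)
  z <- expr[, order(colnames(expr))]
  z <- t(scale(t(z)))
  oracle <- avg_linkage_heights(dist(t(z)))
  expect_equal(sort(res$hclust$height), sort(oracle), tolerance = 1e-9)
})

test_that("duplicated samples merge before anything else", {
  set.seed(8)
  base <- matrix(rnorm(40 * 2), 40, 2)
  expr <- make_counts(cbind(base[, 1], base[, 1], base[, 2], base[, 2]),
                      samples = c("A", "A2", "B", "B2"))
  res <- cluster_samples(expr)
  first_two <- res$hclust$merge[1:2, ]
  merged <- lapply(1:2, function(i) sort(res$hclust$labels[-first_two[i, ]]))
  expect_true(all(res$hclust$height[1:2] < 1e-9))
  expect_setequal(vapply(merged, paste, "", collapse = ","),
                  c("A,A2", "B,B2"))
  expect_error(cluster_samples(expr[, 1, drop = FALSE]), "2 samples")
  expect_error(cluster_samples(expr, genes = "nope"), "absent")
})
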