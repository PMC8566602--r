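test_that("entropy and clonality match hand-derived values", {
  # uniform two-clone repertoire: maximum entropy, zero clonality
  m2 <- repertoire_metrics(clono_table(c(50, 50)))
  expect_equal(m2$entropy, log(2), tolerance = 1e-12)
  expect_equal(m2$clonality, 0, tolerance = 1e-12)

  # single clone: limit convention H = 0, C = 1, flagged
  m1 <- repertoire_metrics(clono_table(500))
  expect_equal(m1$entropy, 0)
  expect_equal(m1$clonality, 1)
  expect_true(m1$single_clone)

  # frequencies (0.9, 0.1)
  m <- repertoire_metrics(clono_table(c(90, 10)))
  expect_equal(m$entropy, 0.32508, tolerance = 1e-5)
  expect_equal(m$clonality, 1 - m$entropy / log(2), tolerance = 1e-12)
  expect_equal(m$clonality, 0.53101, tolerance = 2e-5)
  expect_equal(m$gini, 0.4, tolerance = 1e-12)

  # uniform n-clone repertoire: H = ln n for several n
  for (n in c(3, 10, 64)) {
    mn <- repertoire_metrics(clono_table(rep(7, n)))
    expect_equal(mn$entropy, log(n), tolerance = 1e-12)
    expect_equal(mn$gini, 0)
  }
  expect_error(repertoire_metrics(clono_table(c(5, 0))), ">= 1")
})

test_that("sorted-form Gini agrees with the O(n^2) pairwise oracle", {
  m <- gini_index(clono_table(c(97, 1, 1, 1)))
  expect_equal(m$gini, gini_pairwise(c(0.97, 0.01, 0.01, 0.01)),
               tolerance = 1e-12)
  expect_equal(m$gini, 0.72, tolerance = 0.005)

  set.seed(51)
  for (r in 1:20) {
    cnt <- sample(1:500, sample(2:60, 1), replace = TRUE)
    f <- cnt / sum(cnt)
    expect_equal(gini_index(clono_table(cnt))$gini, gini_pairwise(f),
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant to clonotype relabeling", {
  set.seed(52)
  cnt <- sample(1:200, 30)
  t1 <- clono_table(cnt)
  t2 <- t1
  t2$clonotype_key <- sprintf("OTHER-%03d", sample(30))
  expect_equal(repertoire_metrics(t1)[, -1], repertoire_metrics(t2)[, -1])
})

test_that("splitting a clone in half strictly increases entropy", {
  # note C = 1 - H/ln(n) need not fall: the ln(n) denominator grows too,
  # so only the unnormalized entropy is guaranteed monotone here
  set.seed(53)
  for (r in 1:10) {
    cnt <- 2 * sample(1:100, sample(3:20, 1))
    m0 <- repertoire_metrics(clono_table(cnt))
    split_cnt <- c(cnt[-1], cnt[1] / 2, cnt[1] / 2)
    m1 <- repertoire_metrics(clono_table(split_cnt))
    expect_gt(m1$entropy, m0$entropy)
  }
})

test_that("diversity indices stay in their analytic ranges", {
  set.seed(54)
  for (r in 1:20) {
    cnt <- sample(1:1000, sample(2:100, 1), replace = TRUE)
    m <- repertoire_metrics(clono_table(cnt))
    expect_lte(m$entropy, log(m$richness) + 1e-12)
    expect_gte(m$clonality, 0); expect_lte(m$clonality, 1)
    expect_gte(m$gini, 0); expect_lt(m$gini, 1)
  }
})

test_that("clonal occupancy partitions repertoire mass", {
  one <- clonal_occupancy(clono_table(100))
  expect_equal(one$occ_hyperexpanded, 1)
  expect_equal(one$occ_rare + one$occ_small + one$occ_medium + one$occ_large, 0)

  # f = (0.5, 0.4, 0.1): everything above 1% lands in the top bin
  three <- clonal_occupancy(clono_table(c(50, 40, 10)))
  expect_equal(unlist(three[, -1], use.names = FALSE), c(0, 0, 0, 0, 1))

  set.seed(55)
  for (r in 1:10) {
    cnt <- sample(1:10000, sample(5:500, 1), replace = TRUE)
    occ <- clonal_occupancy(clono_table(cnt))
    expect_equal(sum(occ[, -1]), 1, tolerance = 1e-9)
  }
  expect_error(clonal_occupancy(clono_table(c(3, 4)), bin_edges = c(0, 2)),
               "bin_edges")
  expect_error(clonal_occupancy(clono_table(c(3, 4)),
                                bin_edges = c(0, 0.5, 0.2, 1)), "bin_edges")
})

test_that("duplicate (sample, key) rows aggregate by summing", {
  tab <- data.frame(sample_id = "s1",
                    clonotype_key = c("k1", "k1", "k2"),
                    count = c(40, 50, 10))
  m <- repertoire_metrics(tab)
  expect_equal(m$richness, 2)
  expect_equal(m$entropy, -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
})

test_that("AIRR-style clonotype files round-trip", {
  tab <- clono_table(c(12, 5, 3), sample = "donor1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotypes(tab, path)
  back <- read_clonotypes(path)
  expect_equal(back$count, sort(tab$count, decreasing = TRUE))

  airr <- data.frame(sample_id = "d2", v_call = "TRBV7",
                     junction = c("TGTGCC", "TGTGCG"), j_call = "TRBJ2",
                     duplicate_count = c(9, 4))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(airr, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_clonotypes(p2)
  expect_equal(parsed$clonotype_key,
               c("TRBV7-TGTGCC-TRBJ2", "TRBV7-TGTGCG-TRBJ2"))
  expect_equal(parsed$count, c(9, 4))
})
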