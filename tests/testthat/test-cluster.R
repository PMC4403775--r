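test_that("single linkage on a line merges nearest pairs at their gaps", {
  X <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  d <- hcluster(X, "single")
  expect_equal(d$height, c(1, 9))
  expect_identical(merge_leafsets(d$merge), list(1:2, 1:3))
  expect_identical(d$metric, "euclidean")
})

test_that("merge sequences match stats::hclust on random instances", {
  withr::with_seed(51, {
    for (rep in 1:100) {
      X <- matrix(rnorm(8 * 3), 8, 3)
      rownames(X) <- paste0("i", 1:8)
      de <- stats::dist(X)
      for (scheme in c("single", "average", "ward")) {
        mine <- hcluster(X, scheme)
        ref <- stats::hclust(if (scheme == "ward") de^2 else de,
                             method = switch(scheme, single = "single",
                                             average = "average", ward = "ward.D"))
        expect_equal(mine$height, ref$height, tolerance = 1e-10)
        expect_identical(merge_leafsets(mine$merge), merge_leafsets(ref$merge))
      }
      # MST characterization of single linkage
      expect_equal(sort(hcluster(X, "single")$height), oracle_mst_heights(X),
                   tolerance = 1e-12)
    }
  })
})

test_that("merge heights are nondecreasing for all three schemes", {
  withr::with_seed(52, {
    for (rep in 1:20) {
      X <- matrix(rnorm(12 * 4), 12, 4)
      for (scheme in c("single", "average", "ward")) {
        expect_true(all(diff(hcluster(X, scheme)$height) >= -1e-12))
      }
    }
  })
})

test_that("partition cuts behave at the extremes and recover planted clouds", {
  withr::with_seed(53, {
    centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
    lab <- rep(1:3, each = 4)
    X <- centers[lab, ] + matrix(rnorm(24, sd = 0.3), 12, 2)
    rownames(X) <- paste0("i", 1:12)
  })
  d <- hcluster(X, "average")
  expect_identical(unname(partition(d, 12)), 1:12)
  expect_identical(unname(partition(d, 1)), rep(1L, 12))
  for (scheme in c("single", "average", "ward")) {
    p3 <- partition(hcluster(X, scheme), 3)
    expect_equal(unname(p3), match(lab, unique(lab)), ignore_attr = TRUE)
  }
})

test_that("partitions are invariant to row order up to relabeling", {
  withr::with_seed(54, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    rownames(X) <- paste0("i", 1:10)
    perm <- sample(10)
  })
  for (scheme in c("single", "ward")) {
    p_orig <- partition(hcluster(X, scheme), 3)
    p_perm <- partition(hcluster(X[perm, ], scheme), 3)
    expect_equal(rand_index(unname(p_orig[perm]), unname(p_perm)), 1)
  }
})

test_that("robustness check agrees on planted clouds, disagrees on a chain", {
  withr::with_seed(55, {
    centers <- matrix(c(0, 0, 20, 0), 2, 2, byrow = TRUE)
    lab <- rep(1:2, each = 6)
    X <- centers[lab, ] + matrix(rnorm(24, sd = 0.5), 12, 2)
  })
  rc <- robustness_check(X, 2)
  expect_true(rc$all_agree)
  expect_true(all(rc$rand$rand_index == 1))
  expect_setequal(names(rc$partitions), c("single", "average", "ward"))

  # uniformly spaced line: single linkage chains (11 + 1), average and Ward
  # cut the middle, so the three partitions differ
  line <- matrix(0:11, ncol = 1, dimnames = list(paste0("i", 1:12), NULL))
  rl <- robustness_check(line, 2)
  expect_false(rl$all_agree)
  expect_identical(unname(rl$partitions$average), unname(rl$partitions$ward))
  expect_false(identical(unname(rl$partitions$single),
                         unname(rl$partitions$average)))
  expect_lt(rl$rand$rand_index[rl$rand$scheme_a == "single" &
                               rl$rand$scheme_b == "average"], 1)

  # duplicated identical profiles agree trivially
  dup <- rbind(X[1:3, ], X[1:3, ])
  rownames(dup) <- paste0("r", 1:6)
  expect_true(robustness_check(dup, 2)$all_agree)
})

test_that("dendrograms export to hclust and newick", {
  withr::with_seed(56, X <- matrix(rnorm(15), 5, 3,
                                   dimnames = list(paste0("g", 1:5), NULL)))
  d <- hcluster(X, "average")
  h <- as.hclust(d)
  expect_s3_class(h, "hclust")
  expect_equal(sort(h$order), 1:5)
  nwk <- ape::write.tree(ape::as.phylo(h))
  expect_match(nwk, "^\\(.*g1.*\\);$")
  td <- tidy(d)
  expect_equal(nrow(td), 4)
  expect_identical(td$height, d$height)
})
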