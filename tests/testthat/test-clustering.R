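test_that("pearson_correlation handles binary profiles and degeneracy", {
  expect_equal(pearson_correlation(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(pearson_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(pearson_correlation(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 0, 1)), "zero-variance")
  expect_error(pearson_correlation(1, 1), "at least two")
})

test_that("correlation distance matches a direct double loop", {
  set.seed(11)
  m <- matrix(rbinom(28, 1, 0.5), 7, 4,
              dimnames = list(paste0("DNp0", 1:7), c("A1", "A2", "A3", "A4")))
  # guard against degenerate rows in this fixture
  m[1, ] <- c(1, 0, 0, 1)
  d <- suppressWarnings(correlation_distance_matrix(m, axis = "rows"))
  for (i in rownames(d)) {
    for (j in rownames(d)) {
      if (i == j) {
        expect_equal(unname(d[i, j]), 0)
      } else {
        expect_equal(unname(d[i, j]), 1 - cor(m[i, ], m[j, ]),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
})

test_that("identical profiles have distance zero", {
  m <- rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0), c = c(0, 1, 1, 0))
  colnames(m) <- paste0("N", 1:4)
  d <- correlation_distance_matrix(m, axis = "rows")
  expect_equal(unname(d["a", "b"]), 0)
})

test_that("zero-variance profiles follow the chosen degeneracy policy", {
  m <- cbind(A = c(1, 0, 1), B = c(0, 1, 0), C = c(0, 0, 0))
  rownames(m) <- paste0("DNp0", 1:3)
  expect_warning(d <- correlation_distance_matrix(m, axis = "cols"), "C")
  expect_false("C" %in% colnames(d))
  expect_equal(attr(d, "excluded"), "C")

  d2 <- correlation_distance_matrix(m, axis = "cols", degenerate = "max")
  expect_equal(unname(d2["C", "A"]), 2)
  expect_equal(unname(d2["C", "C"]), 0)
})

test_that("the worked four-leaf dissimilarity clusters at heights 2, 4, 8", {
  d <- matrix(c(0, 2, 6, 10,
                2, 0, 6, 10,
                6, 6, 0, 4,
                10, 10, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dend <- average_linkage(d)
  expect_equal(dend$height, c(2, 4, 8))
  expect_equal(dend$merge[1, ], c(-2L, -1L), ignore_attr = TRUE)
  expect_equal(dend$merge[2, ], c(-4L, -3L), ignore_attr = TRUE)
  cl <- cut_dendrogram(dend, k = 2)
  expect_equal(unname(cl), c(1L, 1L, 2L, 2L))
  expect_equal(names(cl), LETTERS[1:4])
})

test_that("a two-leaf tree merges at the pairwise distance", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"),
                                                       c("x", "y")))
  dend <- average_linkage(d)
  expect_equal(dend$height, 0.4)
})

test_that("average linkage equals the naive definition-based oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:9, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    dend <- average_linkage(d)
    oracle <- naive_average_linkage(d)
    expect_equal(dend$height, oracle$height, tolerance = 1e-10)
    # partitions after each merge agree too
    for (k in (n - 1):2) {
      cl <- cut_dendrogram(dend, k = k)
      want <- oracle$partitions[[n - k]]
      got <- split(seq_len(n), cl)
      expect_equal(pair_counting_ari(cl, {
        lab <- integer(n)
        for (ci in seq_along(want)) lab[want[[ci]]] <- ci
        lab
      }), 1)
    }
  }
})

test_that("merge heights agree with the reference average-linkage tool", {
  for (seed in 21:30) {
    set.seed(seed)
    n <- sample(5:12, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    mine <- average_linkage(d)
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-10)
  }
})

test_that("dendrogram heights are monotone non-decreasing", {
  for (seed in 31:50) {
    set.seed(seed)
    n <- sample(3:10, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    h <- average_linkage(d)$height
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("linkage is invariant under label permutation up to relabeling", {
  set.seed(7)
  n <- 8
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
  d <- d + t(d)
  labs <- paste0("L", 1:n)
  dimnames(d) <- list(labs, labs)
  dend <- average_linkage(d)
  perm <- sample(n)
  dp <- d[perm, perm]
  dend_p <- average_linkage(dp)
  expect_equal(sort(dend$height), sort(dend_p$height), tolerance = 1e-10)
  for (k in c(2, 3, 5)) {
    a <- cut_dendrogram(dend, k = k)
    b <- cut_dendrogram(dend_p, k = k)[names(a)]
    expect_equal(pair_counting_ari(unname(a), unname(b)), 1)
  }
})

test_that("flat cuts cover the degenerate ends and height cuts", {
  d <- matrix(c(0, 2, 6, 10,
                2, 0, 6, 10,
                6, 6, 0, 4,
                10, 10, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dend <- average_linkage(d)
  expect_equal(unname(cut_dendrogram(dend, k = 4)), 1:4)
  expect_equal(unname(cut_dendrogram(dend, k = 1)), rep(1L, 4))
  expect_equal(unname(cut_dendrogram(dend, h = 5)), c(1L, 1L, 2L, 2L))
  expect_error(cut_dendrogram(dend, k = 9), "between")
  expect_error(cut_dendrogram(dend), "exactly one")
})

test_that("autocorrelation equals 1 - correlation distance", {
  cat1 <- random_catalog(4, n = 14)
  m <- build_matrix(cat1, "vnc", "varicose")
  r <- suppressWarnings(autocorrelation(m, axis = "cols"))
  d <- suppressWarnings(correlation_distance_matrix(m, axis = "cols"))
  expect_equal(unclass(r), 1 - unclass(d), ignore_attr = TRUE)
  expect_equal(unname(diag(unclass(r))), rep(1, nrow(r)))

  # a duplicated column correlates perfectly
  m2 <- cbind(m, DUP = m[, "Wing"])
  r2 <- suppressWarnings(autocorrelation(m2, axis = "cols"))
  expect_equal(unname(r2["Wing", "DUP"]), 1)
})

test_that("newick export writes a tree ape can parse back", {
  d <- matrix(c(0, 2, 6, 10,
                2, 0, 6, 10,
                6, 6, 0, 4,
                10, 10, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dend <- average_linkage(d)
  nwk <- export_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, LETTERS[1:4])
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(dend, path)
  expect_true(file.exists(path))
})
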