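test_that("profiles count neurite voxels in the right bins", {
  arr <- array(0L, dim = c(4, 4, 10))
  # five neurite voxels in slice 4 (occupying [3, 4) um along AP)
  arr[cbind(c(1, 2, 3, 4, 1), c(1, 1, 1, 1, 2), 4)] <- 1L
  mask <- voxel_mask(arr)
  p <- profile_along_axis(mask, axis = "AP", bin = 1)
  expect_equal(sum(p$count), 5)
  expect_equal(p$count[4], 5)          # bin covering [3, 4)
  expect_equal(p$position[4], 3.5)     # reported at the bin center
  expect_equal(sum(p$count[-4]), 0)
})

test_that("soma and axon voxels are excluded from the profile", {
  arr <- array(0L, dim = c(4, 4, 10))
  arr[1, 1, 3] <- 2L  # soma
  arr[2, 2, 5] <- 3L  # axon
  mask <- voxel_mask(arr)
  expect_warning(p <- profile_along_axis(mask), "zero profile")
  expect_equal(sum(p$count), 0)
  expect_true(p$empty)

  # including the axon label brings its voxel back
  p2 <- profile_along_axis(mask, exclude_labels = "soma")
  expect_equal(sum(p2$count), 1)
})

test_that("profile mass equals a brute-force voxel tally", {
  for (seed in 1:5) {
    set.seed(seed)
    arr <- array(sample(0:3, 4 * 4 * 30, replace = TRUE,
                        prob = c(0.8, 0.1, 0.05, 0.05)),
                 dim = c(4, 4, 30))
    mask <- voxel_mask(arr)
    p <- suppressWarnings(profile_along_axis(mask, bin = 1))
    expect_equal(sum(p$count), sum(arr == 1L))
    for (k in seq_along(p$count)) {
      expect_equal(p$count[k], sum(arr[, , k] == 1L))
    }
  }
})

test_that("normalization scales the peak to one and is idempotent", {
  p <- axis_profile(c(2, 4, 8))
  np <- normalize_profile(p)
  expect_equal(np$count, c(0.25, 0.5, 1.0))
  expect_equal(normalize_profile(np)$count, np$count)

  z <- suppressWarnings(axis_profile(c(0, 0, 0)))
  nz <- normalize_profile(z)
  expect_equal(nz$count, c(0, 0, 0))
  expect_true(nz$empty)
})

test_that("center of mass is the count-weighted mean position", {
  expect_equal(center_of_mass(axis_profile(1, position = 2)), 2)
  expect_equal(center_of_mass(axis_profile(c(1, 1), position = c(0, 1))),
               0.5)
  expect_error(center_of_mass(suppressWarnings(axis_profile(c(0, 0)))),
               "zero-mass")
  # normalization must not move the center of mass
  p <- axis_profile(c(1, 5, 3, 1))
  expect_equal(center_of_mass(normalize_profile(p)), center_of_mass(p))
})

test_that("profile ordering sorts by center of mass, stably", {
  ps <- list(axis_profile(1, position = 5),
             axis_profile(1, position = 2),
             axis_profile(1, position = 9))
  expect_equal(order_profiles(ps), c(2L, 1L, 3L))
  ties <- list(axis_profile(1, position = 3),
               axis_profile(1, position = 3),
               axis_profile(1, position = 1))
  expect_equal(order_profiles(ties), c(3L, 1L, 2L))

  set.seed(8)
  rand <- lapply(1:10, function(i) axis_profile(runif(20, 0, 2)))
  coms <- vapply(rand, center_of_mass, numeric(1))
  expect_equal(order_profiles(rand), order(coms))
})

test_that("center of mass is translation-equivariant", {
  set.seed(3)
  arr <- array(0L, dim = c(4, 4, 40))
  arr[cbind(sample(4, 30, TRUE), sample(4, 30, TRUE),
            sample(5:15, 30, TRUE))] <- 1L
  mask <- voxel_mask(arr)
  com0 <- center_of_mass(profile_along_axis(mask))
  shift <- 7L
  arr2 <- array(0L, dim = c(4, 4, 40))
  arr2[, , (1 + shift):40] <- arr[, , 1:(40 - shift)]
  com1 <- center_of_mass(profile_along_axis(voxel_mask(arr2)))
  expect_equal(com1, com0 + shift)
})

test_that("synthetic masks recover the planted centroid", {
  for (centroid in c(20.3, 50, 77.7)) {
    mask <- generate_voxel_mask(centroid = centroid, spread = 3, n = 5000,
                                dim = c(32, 32, 100), seed = 11)
    com <- center_of_mass(profile_along_axis(mask))
    expect_lt(abs(com - centroid), 0.5)
  }
  # zero spread concentrates every voxel in one bin
  mask0 <- generate_voxel_mask(centroid = 10, spread = 0, n = 50,
                               dim = c(16, 16, 40), seed = 2)
  p0 <- profile_along_axis(mask0)
  expect_equal(sum(p0$count > 0), 1)
  expect_lt(abs(center_of_mass(p0) - 10), 0.51)

  # determinism
  m1 <- generate_voxel_mask(30, 2, n = 500, seed = 9)
  m2 <- generate_voxel_mask(30, 2, n = 500, seed = 9)
  expect_identical(m1$array, m2$array)
})

test_that("soma/axon blobs in synthetic masks stay out of the profile", {
  mask <- generate_voxel_mask(centroid = 50, spread = 2, n = 2000,
                              dim = c(32, 32, 100), soma_at = 5,
                              axon_at = 90, seed = 4)
  p <- profile_along_axis(mask)
  expect_equal(p$count[6], 0)   # soma blob bin
  expect_equal(p$count[91], 0)  # axon blob bin
  expect_lt(abs(center_of_mass(p) - 50), 0.5)
})

test_that("rank-sum association flags the more posterior class", {
  sep <- c(lapply(c(1, 2, 3, 4), function(x) axis_profile(1, position = x)),
           lapply(c(10, 11, 12, 13), function(x) axis_profile(1, position = x)))
  labels <- rep(c("leg", "dorsal"), each = 4)
  res <- com_class_association(sep, labels)
  expect_equal(res$direction, "dorsal")
  expect_true(res$exact)
  # perfectly separated: the two extreme assignments out of C(8,4) = 70
  expect_equal(res$p_value, 2 / 70)

  # symmetric classes sit at the null expectation
  sym <- lapply(c(1, 2, 3, 4, 1, 2, 3, 4),
                function(x) axis_profile(1, position = x))
  res2 <- com_class_association(sym, rep(c("a", "b"), each = 4))
  expect_equal(res2$statistic, res2$null_mean)
  expect_equal(res2$p_value, 1)

  expect_error(com_class_association(sym, rep("a", 8)), "two classes")
})

test_that("exact permutation p-values agree with the reference rank-sum test", {
  set.seed(21)
  for (i in 1:5) {
    coms1 <- runif(5, 0, 10)
    coms2 <- runif(6, 3, 13)
    ps <- c(lapply(coms1, function(x) axis_profile(1, position = x)),
            lapply(coms2, function(x) axis_profile(1, position = x)))
    labels <- c(rep("A", 5), rep("B", 6))
    mine <- com_class_association(ps, labels)
    ref <- wilcox.test(coms1, coms2, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("TIFF stacks round trip into voxel masks", {
  skip_if_not_installed("tiff")
  arr <- array(0L, dim = c(6, 5, 8))
  arr[2, 3, 4] <- 1L
  arr[1, 1, 2] <- 2L
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  mask <- read_voxel_mask(path)
  expect_equal(dim(mask$array), dim(arr))
  expect_equal(which(mask$array == 1L), which(arr == 1L))
  expect_equal(which(mask$array == 2L), which(arr == 2L))
})
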