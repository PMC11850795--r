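test_that("channel division matches the elementwise definition", {
  expect_equal(channel_division_correct(matrix(10, 4, 4), matrix(0, 4, 4), offset = 1),
               matrix(10, 4, 4))
  expect_equal(channel_division_correct(matrix(10, 1, 1), matrix(9, 1, 1), offset = 1),
               matrix(1, 1, 1))
  set.seed(3)
  sig <- matrix(runif(32 * 32, 0, 100), 32, 32)
  div <- matrix(runif(32 * 32, 0, 50), 32, 32)
  expect_equal(channel_division_correct(sig, div, 0.5), sig / (div + 0.5),
               tolerance = 1e-12)
  expect_true(all(channel_division_correct(sig, div, 0.5) >= 0))
  expect_error(channel_division_correct(sig, div, 0), class = "celltrax_parameter_error")
  expect_error(channel_division_correct(sig, matrix(0, 2, 2), 1),
               class = "celltrax_geometry_error")
})

test_that("merge_labels takes first-wins priority and keeps provenance", {
  a <- array(0L, c(8, 8)); a[2:3, 2:3] <- 1L
  b <- array(0L, c(8, 8)); b[6:7, 6:7] <- 4L
  m <- merge_labels(list(cells = label_image(a, 1), virus = label_image(b, 1)))
  expect_equal(sort(unique(as.vector(m$labels$array[m$labels$array > 0]))), c(1L, 2L))
  expect_equal(sum(m$labels$array > 0), 8)  # disjoint union conserves voxels
  expect_equal(m$provenance$source, c("cells", "virus"))

  m2 <- merge_labels(list(first = label_image(a, 1), second = label_image(a, 1)))
  expect_equal(nrow(m2$provenance), 1)
  expect_equal(m2$provenance$source, "first")

  expect_error(merge_labels(list(label_image(a, 1), label_image(array(0L, c(4, 4)), 1))),
               class = "celltrax_geometry_error")
})

test_that("merged voxels equal a brute-force priority scan on random blobs", {
  set.seed(12)
  mk <- function() {
    arr <- array(0L, c(20, 20))
    for (lab in 1:3) {
      cx <- sample(3:18, 1); cy <- sample(3:18, 1)
      arr[pmax(1, cx - 2):pmin(20, cx + 2), pmax(1, cy - 2):pmin(20, cy + 2)] <- lab
    }
    arr
  }
  srcs <- list(s1 = mk(), s2 = mk(), s3 = mk())
  m <- merge_labels(lapply(srcs, label_image, voxel_size = 1))
  # oracle: first source claiming each voxel wins
  prov <- m$provenance
  for (v in which(m$labels$array > 0)) {
    lab <- m$labels$array[v]
    src_idx <- match(prov$source[prov$label == lab], names(srcs))
    claimed <- which(vapply(srcs, function(s) s[v] > 0, logical(1)))
    expect_equal(src_idx, min(claimed))
    expect_equal(prov$source_label[prov$label == lab], srcs[[src_idx]][v])
  }
  # disjoint-union conservation on non-overlapping inputs
  d1 <- array(0L, c(10, 10)); d1[1:2, 1:2] <- 7L
  d2 <- array(0L, c(10, 10)); d2[8:9, 8:9] <- 7L
  md <- merge_labels(list(label_image(d1, 1), label_image(d2, 1)))
  expect_equal(sum(md$labels$array > 0), sum(d1 > 0) + sum(d2 > 0))
})

test_that("measure_objects handles degenerate and rod-limit shapes", {
  arr <- array(0L, c(5, 5, 5)); arr[3, 3, 3] <- 1L
  one <- measure_objects(label_image(arr, 1))
  expect_equal(one$volume, 1)
  expect_equal(c(one$lambda1, one$lambda2, one$lambda3), c(0, 0, 0))
  expect_equal(one$asphericity, 0)
  expect_equal(one$kappa_sq, 0)

  rod <- array(0L, c(3, 3, 11)); rod[2, 2, 2:10] <- 1L  # 1x1x9 voxel rod
  rm_ <- measure_objects(label_image(rod, 1))
  expect_equal(rm_$lambda2, 0); expect_equal(rm_$lambda3, 0)
  expect_equal(rm_$kappa_sq, 1)
  expect_equal(rm_$prolateness, 1)
  expect_equal(rm_$volume, 9)

  expect_error(measure_objects(label_image(arr, 1), ids = 99),
               class = "celltrax_lookup_error")
  expect_error(measure_objects(label_image(array(0L, c(4, 4)), 1)),
               class = "celltrax_input_error")
})

test_that("centroids, eigenvalues and intensities match brute-force moment sums", {
  set.seed(5)
  arr <- array(0L, c(12, 14, 16))
  blob <- which(array(runif(length(arr)) < 0.1, dim(arr)))
  arr[blob[1:80]] <- 1L
  intens <- array(runif(length(arr), 0, 100), dim(arr))
  vox <- c(2, 1, 0.5)  # anisotropic (z, y, x)
  res <- measure_objects(label_image(arr, vox), channels = list(sig = intens))
  idx <- arrayInd(which(arr == 1L), dim(arr))
  pos <- sweep(idx - 0.5, 2, vox, `*`)[, 3:1, drop = FALSE]  # to x,y,z
  expect_equal(c(res$x, res$y, res$z), unname(colMeans(pos)), tolerance = 1e-9)
  cov_oracle <- crossprod(sweep(pos, 2, colMeans(pos))) / nrow(pos)
  lam <- sort(eigen(cov_oracle, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(c(res$lambda1, res$lambda2, res$lambda3), lam, tolerance = 1e-9)
  expect_equal(res$volume, nrow(pos) * prod(vox))
  expect_equal(res$mean_sig, mean(intens[arr == 1L]), tolerance = 1e-12)
})

test_that("volume totals are invariant under label permutation", {
  set.seed(6)
  arr <- array(sample(0:3, 200, replace = TRUE), c(10, 20))
  img <- label_image(arr, 1)
  perm <- array(0L, dim(arr))
  perm[arr == 1L] <- 3L; perm[arr == 2L] <- 1L; perm[arr == 3L] <- 2L
  m1 <- measure_objects(img)
  m2 <- measure_objects(label_image(perm, 1))
  expect_equal(sum(m1$volume), sum(m2$volume))
  expect_equal(sort(m1$n_voxels), sort(m2$n_voxels))
})

test_that("shape descriptors are invariant under rigid rotation (discretised rod)", {
  straight <- simulate_ellipsoid_label(c(10, 2), voxel_size = 0.25)
  rotated <- simulate_ellipsoid_label(c(10, 2), voxel_size = 0.25, angle = 45)
  s1 <- measure_objects(straight)
  s2 <- measure_objects(rotated)
  expect_equal(s2$kappa_sq, s1$kappa_sq, tolerance = 0.02)
  expect_equal(s2$asphericity, s1$asphericity, tolerance = 0.05 * s1$asphericity)
  expect_equal(s2$volume, s1$volume, tolerance = 0.02 * s1$volume)
})

test_that("rendered ellipsoid matches the analytic gyration tensor", {
  ell <- simulate_ellipsoid_label(c(8, 4, 4) / 2, voxel_size = 0.5)  # semi-axes 4,2,2
  m <- measure_objects(ell)
  expect_gt(m$prolateness, 0)
  lam_true <- c(16, 4, 4) / 5  # a^2/5, b^2/5, c^2/5
  kappa_true <- gyration_shape_oracle(lam_true)
  expect_equal(m$kappa_sq, kappa_true, tolerance = 0.1 * kappa_true)
  expect_equal(m$lambda1, 16 / 5, tolerance = 0.1 * 16 / 5)
})
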