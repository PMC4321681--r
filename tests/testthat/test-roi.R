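test_that("sphere mask matches brute-force voxel-center enumeration", {
  # 4 mm voxels, 5 mm diameter: radius 2.5 mm < spacing, only the center voxel
  g4 <- vox_grid(c(8, 8, 8), voxel_mm = 4)
  m <- sphere_mask(c(16, 16, 16), 5, g4)
  expect_equal(sum(m), 1)
  expect_true(m[5, 5, 5])

  # 1 mm voxels, center on a voxel center: count equals brute force
  g1 <- vox_grid(c(21, 21, 21), voxel_mm = 1)
  ctr <- c(10, 10, 10)
  m1 <- sphere_mask(ctr, 5, g1)
  brute <- 0
  for (i in 0:20) for (j in 0:20) for (k in 0:20)
    if (sum((c(i, j, k) - ctr)^2) <= 2.5^2) brute <- brute + 1
  expect_equal(sum(m1), brute)

  # corner center: clipped at the grid, no out-of-bounds voxels
  mc <- sphere_mask(c(0, 0, 0), 5, g1)
  expect_lt(sum(mc), brute)
  expect_equal(dim(mc), c(21L, 21L, 21L))

  # far-outside center: empty mask with a warning
  expect_warning(mo <- sphere_mask(c(100, 100, 100), 5, g4), "no voxel centers")
  expect_equal(sum(mo), 0)
})

test_that("threshold_and_cluster applies the extent filter", {
  z <- array(0, c(16, 16, 16))
  expect_equal(nrow(threshold_and_cluster(z, 2.3)), 0)

  # planted blobs: 20 voxels and 10 voxels, face-connected
  z[2:6, 2:5, 2] <- 4            # 20 voxels
  z[10:14, 10:11, 10] <- 4       # 10 voxels
  z[4, 3, 2] <- 5.5              # peak inside the large blob
  tab <- threshold_and_cluster(z, 2.3, min_voxels = 15)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 20)
  expect_equal(tab$peak_z, 5.5)
  expect_equal(c(tab$peak_i, tab$peak_j, tab$peak_k), c(4, 3, 2))

  # dropping the extent threshold reveals both
  tab2 <- threshold_and_cluster(z, 2.3, min_voxels = 1)
  expect_equal(sort(tab2$size), c(10, 20))

  # single supra-threshold voxel
  z1 <- array(0, c(5, 5, 5)); z1[3, 4, 2] <- 5
  t1 <- threshold_and_cluster(z1, 2.3, min_voxels = 1)
  expect_equal(t1$size, 1)
  expect_equal(c(t1$peak_i, t1$peak_j, t1$peak_k), c(3, 4, 2))
})

test_that("raising min_voxels never increases the cluster count", {
  set.seed(12)
  z <- array(rnorm(20^3, sd = 2), c(20, 20, 20))
  counts <- sapply(c(1, 2, 5, 10, 20),
                   function(mv) nrow(threshold_and_cluster(z, 2.3, mv)))
  expect_true(all(diff(counts) <= 0))
})

test_that("diagonal voxels are separate clusters under 6-connectivity", {
  z <- array(0, c(4, 4, 4))
  z[1, 1, 1] <- 3; z[2, 2, 1] <- 3  # touch only at an edge
  expect_equal(nrow(threshold_and_cluster(z, 2.3, 1, connectivity = 6)), 2)
  expect_equal(nrow(threshold_and_cluster(z, 2.3, 1, connectivity = 18)), 1)
})

test_that("extract_mean_timeseries averages exactly over the mask", {
  vol <- array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10))
  m <- array(FALSE, c(4, 4, 4)); m[2, 3, 1] <- TRUE
  expect_equal(extract_mean_timeseries(vol, m), vol[2, 3, 1, ])

  # two voxels holding s and -s average to zero
  s <- rnorm(10)
  vol[1, 1, 1, ] <- s; vol[1, 2, 1, ] <- -s
  m2 <- array(FALSE, c(4, 4, 4)); m2[1, 1:2, 1] <- TRUE
  expect_equal(extract_mean_timeseries(vol, m2), rep(0, 10))

  expect_error(extract_mean_timeseries(vol, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("standardize_series is exact, idempotent and affine-invariant", {
  z <- standardize_series(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(mean(z^2), 1)
  expect_equal(standardize_series(z), z, tolerance = 1e-12)
  x <- rnorm(50)
  expect_equal(standardize_series(3.2 * x - 7), standardize_series(x),
               tolerance = 1e-10)
  expect_equal(standardize_series(-2 * x), -standardize_series(x),
               tolerance = 1e-10)
  expect_error(standardize_series(rep(1, 10), label = "ACC"), "ACC")
})

test_that("noise-free synthetic volumes round-trip through the extraction pipeline", {
  spec <- chain3_spec(seed = 3, n_time = 40, n_subjects = 1)
  panel <- standardize_panel(simulate_usem(spec))
  g <- vox_grid(c(16, 16, 16), voxel_mm = 2)
  centers <- list(c(6, 6, 6), c(20, 20, 20), c(6, 20, 24))
  vol <- make_synthetic_volume(centers, panel, g, noise_sd = 0)
  # planted spheres recover the planted series exactly
  for (r in 1:3)
    expect_equal(extract_mean_timeseries(vol$bold, vol$masks[[r]]),
                 unname(panel$subjects[[1]][, r]), tolerance = 1e-12)
  # full pipeline: threshold -> cluster -> sphere -> extract -> standardize
  rec <- extract_roi_panel(vol$bold, vol$zmap, g, min_voxels = 1)
  expect_equal(unname(rec$subjects[[1]]), unname(panel$subjects[[1]]),
               tolerance = 1e-10)
  # z-map peaks coincide with planted centers
  tab <- attr(rec, "clusters")
  got <- lapply(seq_len(nrow(tab)),
                function(i) c(tab$peak_x[i], tab$peak_y[i], tab$peak_z_mm[i]))
  expect_setequal(got, centers)
})

test_that("synthetic volumes respect extent filtering and the seed contract", {
  spec <- chain3_spec(seed = 3, n_time = 10, n_subjects = 1)
  panel <- standardize_panel(simulate_usem(spec))
  panel$subjects[[1]] <- panel$subjects[[1]][, 1, drop = FALSE]
  panel$roi_labels <- panel$roi_labels[1]
  g <- vox_grid(c(20, 20, 20), voxel_mm = 1)
  # 5 mm sphere on a 1 mm grid plants an 81-voxel blob, a 2.6 mm sphere a
  # 7-voxel blob; only the former survives the 15-voxel extent rule
  vol_big <- make_synthetic_volume(list(c(6, 6, 6)), panel, g, sphere_mm = 5)
  vol_small <- make_synthetic_volume(list(c(15, 15, 15)), panel, g,
                                     sphere_mm = 2.6)
  z <- pmax(vol_big$zmap, vol_small$zmap)
  expect_equal(sum(vol_big$zmap > 0), 81)
  expect_equal(sum(vol_small$zmap > 0), 7)
  tab <- threshold_and_cluster(z, 2.3, min_voxels = 15)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 81)

  v1 <- make_synthetic_volume(list(c(6, 6, 6)), panel, g, noise_sd = 1, seed = 4)
  v2 <- make_synthetic_volume(list(c(6, 6, 6)), panel, g, noise_sd = 1, seed = 4)
  expect_identical(v1$bold, v2$bold)
  expect_error(make_synthetic_volume(list(c(90, 0, 0)), panel, g),
               "outside the grid")
})

test_that("volumes round-trip through NIfTI with their affine", {
  d <- withr::local_tempdir()
  g <- vox_grid(c(6, 5, 4), affine = {
    a <- diag(c(2, 2, 2.6, 1)); a[1:3, 4] <- c(-10, -12, -8); a
  })
  arr <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
  f <- file.path(d, "bold.nii.gz")
  write_volume(arr, g, f)
  back <- read_volume(f)
  expect_equal(back$data, arr, tolerance = 1e-6)
  expect_equal(back$grid$affine, g$affine, tolerance = 1e-5)
})
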