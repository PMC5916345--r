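test_that("Gaussian smoothing: identity, constants, and the analytic kernel", {
  v <- pet_volume(array(stats::runif(12^3), c(12, 12, 12)), c(2, 2, 2))
  expect_equal(unclass(smooth_map(v, 0)), unclass(v))
  const <- pet_volume(array(3.7, c(8, 8, 8)), c(2, 2, 2))
  expect_equal(as.numeric(smooth_map(const, 5)), rep(3.7, 8^3),
               tolerance = 1e-12)
  # delta image: voxel values equal the product of per-axis bin-integrated
  # Gaussian masses (closed form)
  d <- c(17, 17, 17)
  delta <- array(0, d); delta[9, 9, 9] <- 1
  fwhm <- 4; voxmm <- 1.5
  sm <- smooth_map(pet_volume(delta, rep(voxmm, 3)), fwhm)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxmm
  axis_mass <- function(k) {
    stats::pnorm((k + 0.5) / sigma) - stats::pnorm((k - 0.5) / sigma)
  }
  idx <- as.matrix(expand.grid(1:17, 1:17, 1:17)) - 9
  oracle <- axis_mass(idx[, 1]) * axis_mass(idx[, 2]) * axis_mass(idx[, 3])
  expect_lt(max(abs(as.numeric(sm) - oracle)), 1e-6)
  expect_equal(sum(sm), 1, tolerance = 1e-6) # mass conservation
  expect_error(smooth_map(sm, -1), ">= 0")
})

test_that("smoothing excludes missing voxels by renormalization", {
  x <- array(5, c(9, 9, 9)); x[4, 4, 4] <- NA
  sm <- smooth_map(pet_volume(x, c(2, 2, 2)), 6)
  expect_true(is.na(sm[4, 4, 4]))
  vals <- as.numeric(sm)
  expect_equal(vals[!is.na(vals)], rep(5, 9^3 - 1), tolerance = 1e-12)
})

test_that("voxelwise Patlak map is constant on a constant-TAC phantom", {
  tis <- simulate_irreversible_tac(ref_fmt, Ki = 0.015, V = 0.5)
  d <- c(3, 3, 2)
  dyn <- array(rep(tis$activity, each = prod(d)), c(d, 25))
  km <- fit_parametric_map(dyn, ref_fmt, "patlak", t_star = 25)
  expect_equal(as.numeric(km), rep(0.015, prod(d)), tolerance = 1e-9)
  empty <- fit_parametric_map(array(0, c(d, 25)), ref_fmt, "patlak")
  expect_true(all(is.na(empty)))
})

test_that("voxelwise SRTM map recovers two-region truth", {
  bps <- c(1.5, 3.0)
  t1 <- simulate_srtm_tac(ref_rac, 1, 0.3, bps[1])
  t2 <- simulate_srtm_tac(ref_rac, 1, 0.3, bps[2])
  d <- c(4, 2, 1)
  dyn <- array(NA_real_, c(d, 19))
  lab <- array(0L, d); lab[1:2, , ] <- 1L; lab[3:4, , ] <- 2L
  for (f in 1:19) {
    sl <- array(0, d)
    sl[lab == 1L] <- t1$activity[f]
    sl[lab == 2L] <- t2$activity[f]
    dyn[, , , f] <- sl
  }
  bm <- fit_parametric_map(dyn, ref_rac, "srtm", theta3 = theta3_grid(64))
  labs <- pet_volume(lab, c(1, 1, 1), "labels")
  for (i in 1:2) {
    got <- extract_roi(bm, labs, i)$value
    expect_lt(abs(got - bps[i]) / bps[i], 0.01)
  }
})

test_that("group t-maps match closed-form t and the paired identity", {
  mk <- function(vals) pet_volume(array(vals, c(1, 1, 1)), c(1, 1, 1))
  tm <- group_tmap(lapply(c(1, 2, 3), mk))
  expect_equal(as.numeric(tm), 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(attr(tm, "df"), 2L)
  set.seed(8)
  a <- lapply(1:6, function(i) {
    pet_volume(array(stats::rnorm(27), c(3, 3, 3)), c(1, 1, 1))
  })
  b <- lapply(1:6, function(i) {
    pet_volume(array(stats::rnorm(27), c(3, 3, 3)), c(1, 1, 1))
  })
  paired <- group_tmap(a, b, mode = "paired")
  diffs <- Map(function(x, y) {
    pet_volume(unclass(x) - unclass(y), voxdim(x))
  }, a, b)
  expect_equal(unclass(group_tmap(diffs)), unclass(paired))
  # zero variance -> missing
  expect_true(is.na(as.numeric(group_tmap(lapply(c(2, 2, 2), mk)))))
  expect_error(group_tmap(a[1]), "at least 2")
})

test_that("cluster-extent thresholding enforces k and connectivity", {
  df <- 20
  d <- c(60, 5, 3)
  tv <- array(0, d)
  tv[1:54, 2, 1] <- 10   # component of 54 voxels
  tv[1:55, 2, 3] <- 10   # component of 55 voxels
  tm <- pet_volume(tv, c(1, 1, 1), "t")
  res <- threshold_clusters(tm, cluster_config(p = 0.001, df = df, k = 55))
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$size, 55)
  expect_equal(sum(res$mask), 55)
  # all-zero map -> empty
  zero <- pet_volume(array(0, c(4, 4, 4)), c(1, 1, 1), "t")
  expect_equal(nrow(threshold_clusters(
    zero, cluster_config(df = df))$table), 0L)
  # diagonal adjacency
  dv <- array(0, c(4, 4, 4)); dv[1, 1, 1] <- 10; dv[2, 2, 2] <- 10
  dtm <- pet_volume(dv, c(1, 1, 1), "t")
  c6 <- threshold_clusters(dtm, cluster_config(df = df, k = 1,
                                               connectivity = 6))
  c26 <- threshold_clusters(dtm, cluster_config(df = df, k = 1,
                                                connectivity = 26))
  expect_equal(nrow(c6$table), 2L)
  expect_equal(nrow(c26$table), 1L)
})

test_that("cluster-extent Monte Carlo is seeded, calibrated, and monotone", {
  msk <- pet_volume(array(1, c(8, 8, 4)), c(2, 2, 2), "mask")
  k1 <- cluster_extent_mc(msk, fwhm_mm = 4, p_thresh = 0.01, n_iter = 120,
                          seed = 31)
  k2 <- cluster_extent_mc(msk, fwhm_mm = 4, p_thresh = 0.01, n_iter = 120,
                          seed = 31)
  expect_identical(as.integer(k1), as.integer(k2))
  expect_identical(attr(k1, "max_sizes"), attr(k2, "max_sizes"))
  # alpha = 1: any cluster passes
  expect_equal(as.integer(cluster_extent_mc(msk, 0, alpha = 1,
                                            n_iter = 100, seed = 1)), 1L)
  # monotone: larger smoothing and stricter alpha both raise k
  ks <- vapply(c(0, 4, 8), function(fw) {
    as.integer(cluster_extent_mc(msk, fw, p_thresh = 0.01, n_iter = 120,
                                 seed = 7))
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
  ka <- vapply(c(0.2, 0.05), function(al) {
    as.integer(cluster_extent_mc(msk, 4, p_thresh = 0.01, alpha = al,
                                 n_iter = 120, seed = 7))
  }, integer(1))
  expect_true(ka[2] >= ka[1])
})

test_that("unsmoothed Monte-Carlo null matches a from-scratch re-simulation", {
  d <- c(8, 8, 4)
  msk <- pet_volume(array(1, d), c(2, 2, 2), "mask")
  n_iter <- 120; p <- 0.01; seed <- 13
  got <- cluster_extent_mc(msk, fwhm_mm = 0, p_thresh = p, alpha = 0.05,
                           n_iter = n_iter, seed = seed)
  zcrit <- stats::qnorm(1 - p / 2)
  oracle_sizes <- withr::with_seed(seed, vapply(seq_len(n_iter), function(i) {
    noise <- array(stats::rnorm(prod(d)), d)
    z <- (noise - mean(noise)) / stats::sd(as.numeric(noise))
    supra <- abs(z) > zcrit
    if (!any(supra)) 0L else oracle_max_cluster(supra, 6)
  }, integer(1)))
  expect_identical(attr(got, "max_sizes"), oracle_sizes)
  k <- 1L
  while (mean(oracle_sizes >= k) > 0.05) k <- k + 1L
  expect_identical(as.integer(got), k)
})

test_that("mask algebra: intersection, dice, posterior cerebellum", {
  d <- c(20, 20, 20)
  full <- pet_volume(array(1, d), c(1, 1, 1), "mask")
  sub <- array(0, d); sub[which(array(TRUE, d))[1:7097]] <- 1
  subm <- pet_volume(sub, c(1, 1, 1), "mask")
  both <- intersect_masks(list(subm, full))
  expect_equal(both$volume_mm3, 7097)
  expect_equal(unclass(intersect_masks(list(subm, subm))$mask), unclass(subm))
  disj <- pet_volume(1 - sub, c(1, 1, 1), "mask")
  expect_equal(intersect_masks(list(subm, disj))$volume_mm3, 0)

  expect_equal(dice_coefficient(subm, subm), 1)
  expect_equal(dice_coefficient(subm, disj), 0)
  a <- array(0, c(10, 10, 2)); a[1:100] <- 1
  b <- array(0, c(10, 10, 2)); b[21:120] <- 1 # |A|=|B|=100, overlap 80
  expect_equal(dice_coefficient(pet_volume(a, c(1, 1, 1)),
                                pet_volume(b, c(1, 1, 1))), 0.8)

  # synthetic cerebellum spanning 8 coronal slices
  lab <- array(0L, c(6, 12, 6)); lab[2:5, 3:10, 2:5] <- 1L
  labv <- pet_volume(lab, c(2, 2, 2), "labels")
  kept <- posterior_cerebellum_mask(labv, 1L, fraction = 0.25)
  expect_equal(sum(apply(unclass(kept) > 0, 2, any)), 6) # 2 of 8 removed
  expect_true(!any(kept[, 3:4, ] > 0)) # the two anterior slices cleared
  expect_equal(unclass(posterior_cerebellum_mask(labv, 1L, 0)),
               unclass(pet_volume((lab == 1L) + 0, c(2, 2, 2))),
               ignore_attr = TRUE)
  n20 <- sum(posterior_cerebellum_mask(labv, 1L, 0.20))
  n25 <- sum(posterior_cerebellum_mask(labv, 1L, 0.25))
  expect_lte(n25, n20)
  expect_error(posterior_cerebellum_mask(labv, 9L), "absent")
})

test_that("ROI extraction averages maps and dynamic volumes", {
  lab <- array(0L, c(4, 4, 1)); lab[1:2, 1, 1] <- 1L
  labs <- pet_volume(lab, c(2, 2, 2), "labels")
  m <- array(NA_real_, c(4, 4, 1)); m[1, 1, 1] <- 1; m[2, 1, 1] <- 3
  got <- extract_roi(pet_volume(m, c(2, 2, 2)), labs, 1L)
  expect_equal(got$value, 2)
  expect_equal(got$volume_mm3, 2 * 8)
  expect_error(extract_roi(pet_volume(m, c(2, 2, 2)), labs, 5L), "absent")
  # dynamic round trip: homogeneous ROI reproduces the generating TAC
  tis <- simulate_srtm_tac(ref_rac, 1, 0.3, 2)
  dyn <- array(0, c(4, 4, 1, 19))
  for (f in 1:19) dyn[1:2, 1, 1, f] <- tis$activity[f]
  rt <- extract_roi(dyn, labs, 1L, schedule = ref_rac$schedule)
  expect_equal(rt$activity, tis$activity, tolerance = 1e-12)
})

test_that("volumes round-trip through NIfTI with voxel dimensions", {
  v <- pet_volume(array(stats::rnorm(60), c(5, 4, 3)), c(2, 2.5, 3), "BPnd")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, path)
  back <- read_volume_nifti(path, "BPnd")
  expect_equal(unclass(back), unclass(v), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(voxdim(back), voxdim(v), tolerance = 1e-6)
})
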