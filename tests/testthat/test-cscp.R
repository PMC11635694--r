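test_that("connectivity profiles recover planted correlation structure", {
  set.seed(1)
  n <- 10000
  roi <- rnorm(n)
  # voxel = roi + noise of 3x the variance: population r = 1/sd = 0.5
  vox <- roi + rnorm(n, sd = sqrt(3))
  cort <- roi_timeseries(cbind(r1 = roi, r2 = rnorm(n)), tr_seconds = 2)
  str <- voxel_timeseries(cbind(vox), cbind(1L, 1L, 1L), 2)
  p <- connectivity_profile(str, cort)
  expect_equal(p$z[1, 1], atanh(0.5), tolerance = 0.05)
  expect_equal(p$z[1, 1], atanh(cor(vox, roi)), tolerance = 1e-12)

  # anti-correlated construction gives negative z
  stra <- voxel_timeseries(cbind(-roi + rnorm(n)), cbind(1L, 1L, 1L), 2)
  expect_lt(connectivity_profile(stra, cort)$z[1, 1], 0)

  # perfectly dependent series stay finite via the clipping rule
  strd <- voxel_timeseries(cbind(roi), cbind(1L, 1L, 1L), 2)
  expect_true(is.finite(connectivity_profile(strd, cort)$z[1, 1]))

  # zero-variance voxel flagged as NA with a warning
  strz <- voxel_timeseries(cbind(vox, 0 * vox), rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)), 2)
  expect_warning(pz <- connectivity_profile(strz, cort), "zero-variance")
  expect_true(all(is.na(pz$z[2, ])))
})

test_that("independent voxel-ROI pairs give near-zero z at 235 frames", {
  set.seed(2)
  mz <- replicate(50, {
    cort <- roi_timeseries(matrix(rnorm(235 * 3), 235, 3), tr_seconds = 2)
    str <- voxel_timeseries(matrix(rnorm(235), 235, 1), cbind(1L, 1L, 1L), 2)
    mean(abs(connectivity_profile(str, cort)$z))
  })
  expect_lt(mean(mz), 0.1)
})

test_that("aggregate divergence: identity, hand sum, homogeneity", {
  pa <- mk_profile(rbind(c(0.9, 0.5), c(0.2, 0.1)))
  expect_equal(aggregate_divergence(pa, pa)$values, c(0, 0))
  pb <- mk_profile(rbind(c(0.5, 0.9), c(0.2, 0.1)))
  expect_equal(aggregate_divergence(pa, pb)$values[1], 0.8)  # |0.4| + |-0.4|
  c_ <- 2.5
  sa <- mk_profile(pa$z * c_); sb <- mk_profile(pb$z * c_)
  expect_equal(aggregate_divergence(sa, sb)$values,
               c_ * aggregate_divergence(pa, pb)$values)
  expect_error(aggregate_divergence(pa, mk_profile(matrix(0.1, 1, 3))), "shapes")
})

test_that("ROR matches exhaustive rank enumeration and known hand cases", {
  pa <- mk_profile(rbind(c(0.9, 0.5, 0.1)))
  pb <- mk_profile(rbind(c(0.1, 0.5, 0.9)))
  expect_equal(rank_order_rearrangement(pa, pa)$values, 0)
  expect_equal(rank_order_rearrangement(pa, pb)$values, 4)  # (1,2,3) vs (3,2,1)

  # swapping the two weakest of K ROIs gives ROR = 2 regardless of K
  for (K in 3:10) {
    za <- matrix(rev(seq_len(K)) / K, 1)   # strictly decreasing
    zb <- za
    zb[1, c(K - 1, K)] <- zb[1, c(K, K - 1)]
    expect_equal(rank_order_rearrangement(mk_profile(za), mk_profile(zb))$values, 2)
  }

  # oracle: explicit rank-by-sorting enumeration on random profiles
  set.seed(3)
  for (i in 1:50) {
    K <- sample(2:10, 1)
    za <- matrix(rnorm(K), 1); zb <- matrix(rnorm(K), 1)
    got <- rank_order_rearrangement(mk_profile(za), mk_profile(zb))$values
    ra <- match(seq_len(K), order(za[1, ], decreasing = TRUE))
    rb <- match(seq_len(K), order(zb[1, ], decreasing = TRUE))
    expect_equal(got, sum(abs(ra - rb)))
  }
})

test_that("ROR is rank-invariant under monotone transforms; AD is not", {
  set.seed(4)
  za <- matrix(rnorm(8), 1); zb <- matrix(rnorm(8), 1)
  mono <- function(x) x^3 + 2 * x   # strictly increasing
  r1 <- rank_order_rearrangement(mk_profile(za), mk_profile(zb))$values
  r2 <- rank_order_rearrangement(mk_profile(mono(za)), mk_profile(mono(zb)))$values
  expect_equal(r1, r2)
  a1 <- aggregate_divergence(mk_profile(za), mk_profile(zb))$values
  a2 <- aggregate_divergence(mk_profile(mono(za)), mk_profile(mono(zb)))$values
  expect_false(isTRUE(all.equal(a1, a2)))
})

test_that("ROR upper bound floor(K^2/2): reversal attains it, nothing exceeds it", {
  # exhaustive permutation search for small K
  for (K in 2:6) {
    za <- matrix(rev(seq_len(K)), 1)
    perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
    vals <- apply(perms, 1, function(p)
      rank_order_rearrangement(mk_profile(za), mk_profile(za[, p, drop = FALSE]))$values)
    expect_equal(max(vals), floor(K^2 / 2))
  }
  # reversal attains the bound, random permutations respect it, K up to 10
  set.seed(5)
  for (K in 7:10) {
    za <- matrix(rev(seq_len(K)), 1)
    rev_val <- rank_order_rearrangement(
      mk_profile(za), mk_profile(za[, K:1, drop = FALSE]))$values
    expect_equal(rev_val, floor(K^2 / 2))
    for (i in 1:30) {
      p <- sample.int(K)
      expect_lte(rank_order_rearrangement(
        mk_profile(za), mk_profile(za[, p, drop = FALSE]))$values, floor(K^2 / 2))
    }
  }
})

test_that("entropy shift: identity, ln K maximum, dominant-connection case", {
  K <- 6
  uni <- mk_profile(matrix(0.4, 1, K))
  expect_equal(entropy_shift(uni, uni)$values, 0)
  expect_equal(capdyn:::profile_entropy(uni$z), log(K), tolerance = 1e-9)

  dom <- matrix(c(10, rep(1e-4, K - 1)), 1)
  es <- entropy_shift(mk_profile(dom), uni)$values
  expect_equal(es, log(K) - capdyn:::profile_entropy(dom), tolerance = 1e-9)
  expect_gt(es, 0)
  # all-zero row falls back to ln K via the eps floor
  expect_equal(capdyn:::profile_entropy(matrix(0, 1, K)), log(K), tolerance = 1e-6)
})

test_that("split-half profiles: frame arithmetic, identical halves, noise floor", {
  set.seed(6)
  cort <- roi_timeseries(matrix(rnorm(235 * 4), 235, 4), tr_seconds = 2)
  str <- voxel_timeseries(matrix(rnorm(235 * 2), 235, 2),
                          rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)), 2)
  halves <- split_half_profiles(str, cort)
  expect_equal(nrow(halves$first$z), 2L)
  expect_equal(halves$first$n_frames, 117L)   # 235 frames split as 117 + 118
  expect_equal(halves$second$n_frames, 118L)
  expect_error(split_half_profiles(
    voxel_timeseries(matrix(rnorm(19 * 2), 19, 2), rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)), 2),
    roi_timeseries(matrix(rnorm(19 * 4), 19, 4), tr_seconds = 2)), ">= 20 frames")

  dup <- rbind(cort$values[1:50, ], cort$values[1:50, ])
  dupv <- rbind(str$values[1:50, ], str$values[1:50, ])
  h <- split_half_profiles(voxel_timeseries(dupv, str$voxel_coords, 2),
                           roi_timeseries(dup, tr_seconds = 2))
  expect_equal(aggregate_divergence(h$first, h$second)$values, c(0, 0))
  expect_equal(rank_order_rearrangement(h$first, h$second)$values, c(0, 0))
})

test_that("subject scores average voxels, skip NA, and respect node partitions", {
  m <- mk_map(c(1, 2, 3))
  expect_equal(subject_cscp_score(m), 2)
  expect_equal(subject_cscp_score(m, m$voxel_coords[1:2, ]), 1.5)
  mna <- mk_map(c(1, NA, 3))
  expect_equal(subject_cscp_score(mna), 2)
  expect_error(subject_cscp_score(m, rbind(c(99L, 99L, 99L))), "not in the map")

  # whole-striatum score = size-weighted mean of node scores over a partition
  set.seed(7)
  vals <- rnorm(20)
  mm <- mk_map(vals)
  part <- list(1:7, 8:12, 13:20)
  node_scores <- vapply(part, function(ix)
    subject_cscp_score(mm, mm$voxel_coords[ix, ]), numeric(1))
  sizes <- lengths(part)
  expect_equal(subject_cscp_score(mm), sum(node_scores * sizes) / sum(sizes))
})

test_that("voxelwise paired test recovers a planted block and matches the t formula", {
  set.seed(8)
  # 4x4x4 grid; 10-voxel 6-connected block gets a +1 shift in every subject
  grid <- as.matrix(expand.grid(i = 1:4, j = 1:4, k = 1:4))
  nvox <- nrow(grid)
  block <- which(grid[, "k"] == 1 &
                   (grid[, "j"] <= 2 | (grid[, "j"] == 3 & grid[, "i"] <= 2)))
  stopifnot(length(block) == 10L)
  n <- 20
  maps_a <- maps_b <- vector("list", n)
  for (s in seq_len(n)) {
    base <- rnorm(nvox, sd = 0.1)
    av <- base + rnorm(nvox, sd = 0.1)
    av[block] <- av[block] + 1
    maps_a[[s]] <- mk_map(av, grid)
    maps_b[[s]] <- mk_map(base + rnorm(nvox, sd = 0.1), grid)
  }
  ns <- voxelwise_paired_test(maps_a, maps_b, p_threshold = 0.001, min_extent = 5)
  expect_equal(length(ns$nodes), 1L)
  got <- ns$nodes[[1]]$coords
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               grid[block, ][order(grid[block, 1], grid[block, 2], grid[block, 3]), ],
               ignore_attr = TRUE)

  # per-voxel t equals mean(diff) / (sd(diff)/sqrt(n))
  D <- do.call(rbind, lapply(seq_len(n), function(s)
    maps_a[[s]]$values - maps_b[[s]]$values))
  expect_equal(ns$t, colMeans(D) / (apply(D, 2, sd) / sqrt(n)), tolerance = 1e-12)

  # identical maps: empty node set
  ns0 <- voxelwise_paired_test(maps_a, maps_a, 0.001, 5)
  expect_equal(length(ns0$nodes), 0L)
  expect_error(voxelwise_paired_test(maps_a[1:2], maps_b[1:2]), ">= 3 subjects")
})

test_that("6-connectivity clustering separates diagonal-only neighbours", {
  coords <- rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(3L, 2L, 1L), c(3L, 2L, 2L))
  comp <- capdyn:::cluster_6conn(coords)
  expect_equal(comp[1], comp[2])       # face neighbours
  expect_equal(comp[3], comp[4])
  expect_false(comp[1] == comp[3])     # diagonal gap splits clusters
})

test_that("rank-shift summaries report planted shifts and honour min_shift", {
  K <- 10
  za <- matrix(rep(seq(K, 1), each = 3), 3, K)     # ranks 1..K for every voxel
  rb <- c(2, 3, 4, 5, 6, 7, 1, 8, 9, 10)           # ROI 7 climbs 6 ranks under b
  zb <- matrix(rep(K + 1 - rb, each = 3), 3, K)
  pa <- mk_profile(za); pb <- mk_profile(zb)
  node <- list(coords = pa$voxel_coords, size = 3L)
  tab <- rank_shift_summary(node, pa, pb, min_shift = 5)
  expect_equal(nrow(tab), 1L)
  expect_equal(abs(tab$mean_rank_change), 6)
  expect_equal(nrow(rank_shift_summary(node, pa, pa, min_shift = 5)), 0L)
  tab0 <- rank_shift_summary(node, pa, pb, min_shift = 0)
  expect_equal(nrow(tab0), K)
})

test_that("with equalized run lengths and no planted effects the drug pair matches the null", {
  cfg <- simulation_config(n_subjects = 12, n_rois = 53, n_cortical_rois = 53,
                           n_striatal_voxels = 40, mph_boost = 1,
                           mph_fpn_damp = 1, hal_boost = 1, perm_frac = 0,
                           seed = 91)
  sim <- simulate_cohort(cfg)
  eq <- cohort_cscp(sim$cohort, "ROR", equalize_null_length = TRUE)$scores
  m <- tapply(eq$score, eq$condition_pair, mean)
  expect_lt(abs(m[["MPH-PBO"]] / m[["PBO-split"]] - 1), 0.1)

  # full-length drug profiles are less noisy than half-length ones, so the
  # unequalized drug-pair ROR sits below the split-half null
  fl <- cohort_cscp(sim$cohort, "ROR")$scores
  mf <- tapply(fl$score, fl$condition_pair, mean)
  expect_lt(mf[["MPH-PBO"]], mf[["PBO-split"]])
})
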