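test_that("centroids are standardized, distinct, and seed-reproducible", {
  cen <- make_centroids(8, 129, seed = 1)
  expect_equal(dim(cen$values), c(8L, 129L))
  expect_equal(rowMeans(cen$values), rep(0, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(cen$values, 1, sd), rep(1, 8),
               tolerance = 1e-12, ignore_attr = TRUE)
  cc <- cor(t(cen$values))
  expect_true(all(abs(cc[upper.tri(cc)]) <= 0.5))

  # n_rois = 2 is degenerate (standardized rows correlate at +-1): the
  # construction still guarantees distinct rows, i.e. correlation below +1
  small <- make_centroids(2, 2, seed = 7)
  expect_false(identical(small$values[1, ], small$values[2, ]))
  expect_lt(cor(small$values[1, ], small$values[2, ]), 1)

  expect_identical(make_centroids(8, 129, seed = 3)$values,
                   make_centroids(8, 129, seed = 3)$values)
  expect_error(make_centroids(10, 5), "invalid configuration")
})

test_that("state sequences follow the chain: absorbing, stationary, reproducible", {
  expect_equal(simulate_state_sequence(diag(3), 50, seed = 9),
               rep(simulate_state_sequence(diag(3), 1, seed = 9), 50))

  # stationary occupancy matches the eigenvector oracle
  P2 <- matrix(0.5, 2, 2)
  s <- simulate_state_sequence(P2, 1e5, seed = 4)
  expect_equal(mean(s == 1), 0.5, tolerance = 0.01)

  set.seed(21)
  P3 <- matrix(runif(9, 0.1, 1), 3, 3)
  P3 <- P3 / rowSums(P3)
  pi3 <- stationary_distribution(P3)
  expect_equal(as.numeric(pi3 %*% P3), as.numeric(pi3), tolerance = 1e-10)
  s3 <- simulate_state_sequence(P3, 1e5, seed = 5)
  expect_lt(max(abs(tabulate(s3, 3) / 1e5 - as.numeric(pi3))), 0.01)

  expect_identical(simulate_state_sequence(P3, 500, seed = 2),
                   simulate_state_sequence(P3, 500, seed = 2))
  bad <- rbind(c(0.5, 0.6), c(0.5, 0.5))
  expect_error(simulate_state_sequence(bad, 10), "row 1")
})

test_that("zero-noise runs reproduce centroids and round-trip through assignment", {
  cen <- make_centroids(5, 40, seed = 11)
  labs <- simulate_state_sequence(capdyn:::base_transition_matrix(5), 80, seed = 12)
  run <- simulate_subject_run(cen, labs, noise_sd = 0)
  expect_equal(run$values, cen$values[labs, ], ignore_attr = TRUE)
  expect_identical(assign_frames(run, cen)$labels, labs)
  # full round trip: dwell metrics from assigned labels equal planted ones
  expect_identical(dwell_metrics(assign_frames(run, cen)$labels, 2, 5),
                   dwell_metrics(labs, 2, 5))
  expect_error(simulate_subject_run(cen, c(1L, 6L), 0), "out of centroid range")
})

test_that("assignment stays accurate at the calibrated noise level", {
  cen <- make_centroids(8, 129, seed = 1)
  P <- capdyn:::base_transition_matrix(8)
  acc <- vapply(1:5, function(sd_seed) {
    labs <- simulate_state_sequence(P, 235, seed = sd_seed)
    run <- simulate_subject_run(cen, labs, noise_sd = 0.5, seed = sd_seed + 100)
    mean(assign_frames(run, cen)$labels == labs)
  }, numeric(1))
  expect_true(all(acc >= 0.95))
})

test_that("striatal mixtures honour weights: one-hot identity and planted permutation", {
  cen <- make_centroids(4, 12, seed = 2)
  labs <- simulate_state_sequence(capdyn:::base_transition_matrix(4), 60, seed = 3)
  cort <- simulate_subject_run(cen, labs, noise_sd = 0.3, seed = 4)
  W <- matrix(0, 2, 12); W[1, 5] <- 1; W[2, 2] <- 1
  st <- simulate_striatal_run(cort, W, noise_sd = 0)
  expect_equal(st$values[, 1], cort$values[, 5], ignore_attr = TRUE)
  expect_error(simulate_striatal_run(cort, W[, 1:5], 0), "columns")

  # permuting a voxel's weights between conditions yields positive ROR there
  set.seed(6)
  Wp <- capdyn:::make_weight_profiles(4, 12)
  perm <- sample.int(12)
  ror_hits <- vapply(1:20, function(s) {
    labs <- simulate_state_sequence(capdyn:::base_transition_matrix(4), 120)
    cort <- simulate_subject_run(cen, labs, noise_sd = 0.2)
    a <- simulate_striatal_run(cort, Wp, noise_sd = 0.05)
    Wb <- Wp; Wb[2, ] <- Wb[2, perm]
    b <- simulate_striatal_run(cort, Wb, noise_sd = 0.05)
    pa <- connectivity_profile(a, cort)
    pb <- connectivity_profile(b, cort)
    rank_order_rearrangement(pa, pb)$values[2] > 0
  }, logical(1))
  expect_gte(mean(ror_hits), 0.95)
})

test_that("cohort bookkeeping: one run per subject per condition, documented covariates", {
  cfg <- simulation_config(n_subjects = 59, n_rois = 12, n_cortical_rois = 6,
                           n_striatal_voxels = 0, n_frames = 40, seed = 10)
  sim <- simulate_cohort(cfg)
  man <- sim$cohort$manifest
  expect_equal(length(sim$cohort$roi_ts), 177L)  # 59 x 3 records
  expect_true(all(table(man$subject, man$condition) == 1L))
  expect_true(all(man$age >= 18 & man$age <= 55))
  expect_true(all(man$sex %in% c("M", "F")))
  for (cond in names(sim$truth$expected_dwell))
    expect_equal(sum(sim$truth$expected_dwell[[cond]]), 1, tolerance = 1e-9)
  # seeded determinism of the whole cohort
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$cohort$roi_ts[["sub001_MPH"]]$values,
                   sim2$cohort$roi_ts[["sub001_MPH"]]$values)
  expect_identical(sim$truth$state_sequences, sim2$truth$state_sequences)
})

test_that("cohort write/read round-trips through the text formats", {
  cfg <- simulation_config(n_subjects = 2, n_rois = 8, n_cortical_rois = 4,
                           n_striatal_voxels = 5, n_frames = 25, seed = 5)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest$subject, sim$cohort$manifest$subject)
  key <- "sub002_HAL"
  expect_equal(back$roi_ts[[key]]$values, sim$cohort$roi_ts[[key]]$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$striatal_ts[[key]]$voxel_coords,
               sim$cohort$striatal_ts[[key]]$voxel_coords,
               ignore_attr = TRUE)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation and marginal sd", {
  cen <- make_centroids(2, 40, seed = 51)
  labs <- rep(1L, 4000)   # constant state isolates the noise process
  run <- simulate_subject_run(cen, labs, noise_sd = 0.8, noise_ar = 0.5,
                              seed = 52)
  noise <- sweep(run$values, 2L, cen$values[1, ])
  ac <- mean(apply(noise, 2, function(e) cor(e[-1], e[-length(e)])))
  expect_equal(ac, 0.5, tolerance = 0.05)
  expect_equal(mean(apply(noise, 2, sd)), 0.8, tolerance = 0.05)
  # default stays i.i.d.
  run0 <- simulate_subject_run(cen, labs, noise_sd = 0.8, seed = 52)
  noise0 <- sweep(run0$values, 2L, cen$values[1, ])
  ac0 <- mean(apply(noise0, 2, function(e) cor(e[-1], e[-length(e)])))
  expect_lt(abs(ac0), 0.05)
})
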