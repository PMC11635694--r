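test_that("dwell metrics reproduce the four-entries, 5 s persistence, 20 s example", {
  # state 1 runs of lengths {2, 3, 2, 3} frames at TR = 2 s inside 20 frames
  labs <- c(1, 1, 2, 2, 1, 1, 1, 2, 2, 2, 1, 1, 2, 1, 1, 1, 2, 2, 2, 2)
  dm <- dwell_metrics(labs, tr_seconds = 2, n_states = 2)
  expect_equal(dm$transitions[1], 4)
  expect_equal(dm$persistence_s[1], 5)
  expect_equal(dm$total_time_s[1], 20)
})

test_that("dwell metrics handle single-run and never-visited states", {
  dm <- dwell_metrics(rep(1L, 12), tr_seconds = 2, n_states = 3)
  expect_equal(dm$transitions, c(1, 0, 0))
  expect_equal(dm$total_time_s, c(24, 0, 0))
  expect_equal(dm$persistence_s, c(24, NA, NA))
})

test_that("conservation and total = transitions x persistence hold on random sequences", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:100, 1)
    k <- sample(2:8, 1)
    tr <- runif(1, 0.5, 3)
    labs <- sample.int(k, n, replace = TRUE)
    dm <- dwell_metrics(labs, tr, k)
    expect_equal(sum(dm$total_time_s), n * tr, tolerance = 1e-12)
    # frame-count bookkeeping is exact
    expect_identical(round(sum(dm$total_time_s / tr)), as.numeric(n))
    v <- dm$transitions > 0
    expect_equal(dm$total_time_s[v], dm$transitions[v] * dm$persistence_s[v],
                 tolerance = 1e-12)
    expect_identical(sum(dm$transitions), as.numeric(length(rle(labs)$lengths)))
  }
})

test_that("dwell metrics agree with the naive run-length oracle", {
  set.seed(7)
  for (i in 1:200) {
    labs <- sample.int(5, sample(3:60, 1), replace = TRUE)
    dm <- dwell_metrics(labs, 2, 5)
    or <- naive_dwell(labs, 2, 5)
    expect_equal(dm$total_time_s, or$total_time_s)
    expect_equal(dm$transitions, or$transitions)
    expect_equal(dm$persistence_s, or$persistence_s)
  }
})

test_that("frame duplication with halved TR leaves total time and persistence unchanged", {
  set.seed(9)
  labs <- sample.int(4, 50, replace = TRUE)
  a <- dwell_metrics(labs, 2, 4)
  b <- dwell_metrics(rep(labs, each = 2), 1, 4)
  expect_equal(b$total_time_s, a$total_time_s)
  expect_equal(b$persistence_s, a$persistence_s)
  expect_equal(b$transitions, a$transitions)
})

test_that("frame assignment: identity, tie-break to lowest index, brute-force oracle", {
  cen <- make_centroids(3, 10, seed = 5)
  ts <- roi_timeseries(cen$values[c(2, 1, 3, 3, 1), ], colnames(cen$values), 2)
  expect_identical(assign_frames(ts, cen)$labels, c(2L, 1L, 3L, 3L, 1L))

  # frames equally correlated with states 2 and 5 resolve to 2
  base <- make_centroids(5, 12, seed = 6)$values
  base[5, ] <- base[2, ]
  cen5 <- centroid_set(base, paste0("s", 1:5))
  planted <- c(2L, 5L, 1L, 3L, 4L, 2L, 5L, 1L, 4L, 3L)
  labs <- assign_frames(roi_timeseries(base[planted, ], tr_seconds = 2), cen5)$labels
  expect_identical(labs, ifelse(planted == 5L, 2L, planted))

  # exhaustive correlation loop oracle on random data
  set.seed(8)
  X <- matrix(rnorm(100), 10, 10)
  cen3 <- make_centroids(3, 10, seed = 9)
  ts <- roi_timeseries(X, tr_seconds = 2)
  got <- assign_frames(ts, cen3)$labels
  Z <- scale(X)
  oracle <- integer(10)
  for (t in 1:10) {
    cors <- numeric(3)
    for (s in 1:3) cors[s] <- cor(Z[t, ], cen3$values[s, ])
    oracle[t] <- which.max(cors)
  }
  expect_identical(got, oracle)
})

test_that("zero-variance frames are flagged and assigned by tie-break", {
  cen <- make_centroids(3, 6, seed = 2)
  # identical ROI columns: every frame is constant after z-scoring, so no
  # correlation is defined and the tie-break rule sends all frames to state 1
  X <- matrix(rep(c(1, 5, 2, 4), 6), 4, 6)
  expect_warning(labs <- assign_frames(roi_timeseries(X, tr_seconds = 2), cen),
                 "tie-break")
  expect_identical(labs$labels, rep(1L, 4))
})

test_that("beta series equal the closed-form simple-regression slope", {
  set.seed(3)
  map <- rnorm(6)
  beta <- rnorm(5)
  X <- outer(beta, map) + 1.7          # frames = beta * map + constant
  ts <- roi_timeseries(X, tr_seconds = 2)
  expect_equal(network_beta_series(ts, map), beta, tolerance = 1e-10)

  # orthogonal (zero-covariance) map
  Xo <- matrix(rnorm(30), 5, 6)
  mc <- map - mean(map)
  Xo <- Xo - (Xo %*% mc) %*% t(mc) / sum(mc^2)  # project out the map
  expect_equal(network_beta_series(roi_timeseries(Xo, tr_seconds = 2), map),
               rep(0, 5), tolerance = 1e-10)

  # hand-computed cov/var oracle on random data
  Xr <- matrix(rnorm(30), 5, 6)
  got <- network_beta_series(roi_timeseries(Xr, tr_seconds = 2), map)
  oracle <- apply(Xr, 1, function(f) cov(f, map) / var(map))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(network_beta_series(roi_timeseries(Xr, tr_seconds = 2), rep(1, 6)),
               "zero variance")
})

test_that("anticorrelation z is atanh(r) with sane sign and null behaviour", {
  set.seed(4)
  a <- rnorm(235)
  b <- -a + rnorm(235, sd = 0.5)
  expect_lt(anticorrelation_z(a, b), 0)

  # hand-built pair with r = 0.5 exactly: x = (-1,0,1), y = x + (1,-2,1)
  # has cov 1, sds 1 and 2, so r = 0.5 and z = atanh(0.5) ~ 0.5493
  x <- c(-1, 0, 1)
  y <- c(0, -2, 2)
  expect_equal(cor(x, y), 0.5, tolerance = 1e-15)
  expect_equal(anticorrelation_z(x, y), atanh(0.5), tolerance = 1e-12)
  expect_equal(anticorrelation_z(x, y), 0.5493, tolerance = 1e-4)

  u <- rnorm(10000); v <- rnorm(10000)
  expect_lt(abs(anticorrelation_z(u, v)), 0.05)

  expect_error(anticorrelation_z(1:5, rep(2, 5)), "zero variance")
  expect_error(anticorrelation_z(1:5, 2 * (1:5)), "\\|r\\| = 1")
})

test_that("emergent DMN-DAN anticorrelation strengthens with time in DMN+DAN", {
  # frames spent in DMN vs DAN push the two beta series in opposite
  # directions, so more combined time in the two states (at opposing
  # times) should strengthen their anticorrelation
  cen <- make_centroids(8, 129, seed = 31)
  P0 <- capdyn:::base_transition_matrix(8)
  Pb <- boost_transitions(P0, c(3, 4), 2.2)
  set.seed(32)
  z0 <- replicate(15, {
    labs <- simulate_state_sequence(P0, 235)
    run <- simulate_subject_run(cen, labs, 0.5)
    anticorrelation_z(network_beta_series(run, cen$values[3, ]),
                      network_beta_series(run, cen$values[4, ]))
  })
  zb <- replicate(15, {
    labs <- simulate_state_sequence(Pb, 235)
    run <- simulate_subject_run(cen, labs, 0.5)
    anticorrelation_z(network_beta_series(run, cen$values[3, ]),
                      network_beta_series(run, cen$values[4, ]))
  })
  expect_lt(mean(zb), mean(z0))
})
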