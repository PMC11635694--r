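# Synthetic cohort generator: Markov state sequences over the eight
# transient network states, frame vectors as centroid + Gaussian noise, and
# striatal voxels as weighted cortical mixtures with planted rank
# permutations under the simulated drug. Every generator draws from the
# current RNG stream unless given an explicit seed, so one cohort seed
# reproduces the whole dataset bit-for-bit.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to one.
#'
#' @param P row-stochastic square matrix.
#' @return numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  validate_transition_matrix(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-9)) stopf("chain has no nonnegative stationary vector (reducible?)")
  pmax(v, 0) / sum(pmax(v, 0))
}

validate_transition_matrix <- function(P, tol = 1e-9) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stopf("transition matrix must be square")
  if (any(P < 0)) stopf("transition matrix has negative entries")
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stopf("transition matrix row %d sums to %.12g, not 1", bad[1L], rs[bad[1L]])
  invisible(P)
}

#' Generate synthetic CAP state centroids
#'
#' Mutually distinct unit-variance spatial maps standing in for empirically
#' derived CAP states: i.i.d. Gaussian rows standardized to mean 0, sd 1,
#' with any row whose absolute correlation to an earlier row exceeds 0.5
#' redrawn (essentially never triggered at realistic `n_rois`).
#'
#' @param n_states number of states (>= 2).
#' @param n_rois number of ROIs (>= n_states).
#' @param seed integer seed, or NULL to draw from the current stream.
#' @return A [centroid_set()].
#' @export
make_centroids <- function(n_states = 8L, n_rois = 129L, seed = NULL) {
  if (n_states < 2L) stopf("need n_states >= 2")
  if (n_states > n_rois) stopf("invalid configuration: n_states (%d) > n_rois (%d)",
                               n_states, n_rois)
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_states * n_rois), n_states, n_rois)
    for (i in seq_len(n_states)) {
      # redraw rows too similar to earlier ones; at n_rois = 2 every
      # standardized row pair has |cor| = 1, so relax to distinctness
      # (cor < 1) once bounded low-correlation attempts are exhausted
      accepted <- FALSE
      for (strict in c(TRUE, FALSE)) {
        for (attempt in 1:200) {
          row <- (m[i, ] - mean(m[i, ])) / stats::sd(m[i, ])
          cc <- if (i == 1L) 0 else
            stats::cor(row, t(m[seq_len(i - 1L), , drop = FALSE]))
          ok <- if (strict) all(abs(cc) <= 0.5) else all(cc < 1 - 1e-12)
          if (ok) {
            m[i, ] <- row
            accepted <- TRUE
            break
          }
          m[i, ] <- stats::rnorm(n_rois)
        }
        if (accepted) break
      }
      if (!accepted) stopf("could not draw distinct centroid rows")
    }
    colnames(m) <- paste0("ROI", seq_len(n_rois))
    centroid_set(m, default_state_names(n_states))
  })
}

#' Simulate a Markov state-label sequence
#'
#' The initial state is drawn from the chain's stationary distribution so
#' expected occupancy matches the stationary eigenvector from frame 1.
#'
#' @param P row-stochastic transition matrix (rows sum to 1 within 1e-9).
#' @param n_frames sequence length (>= 1).
#' @param seed integer seed, or NULL.
#' @return integer vector of state labels in `1..nrow(P)`.
#' @export
simulate_state_sequence <- function(P, n_frames, seed = NULL) {
  validate_transition_matrix(P)
  if (n_frames < 1L) stopf("n_frames must be >= 1")
  k <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  pi0 <- stationary_distribution(P)
  with_seed(seed, {
    u <- stats::runif(n_frames)
    s <- integer(n_frames)
    s[1L] <- 1L + sum(u[1L] > cumsum(pi0))
    if (n_frames > 1L)
      for (t in 2:n_frames) s[t] <- 1L + sum(u[t] > cum[s[t - 1L], ])
    pmin(s, k)
  })
}

#' Simulate one subject run from a state sequence
#'
#' Frame `t` is the centroid of `labels[t]` plus i.i.d. Gaussian noise per
#' ROI.
#'
#' @param centroids a [centroid_set()].
#' @param labels integer state labels indexing centroid rows.
#' @param noise_sd Gaussian noise standard deviation (signal units; centroid
#'   rows have sd 1 across ROIs).
#' @param tr_seconds repetition time in seconds.
#' @param noise_ar AR(1) coefficient of the noise across frames (default 0:
#'   i.i.d. noise); the marginal sd stays `noise_sd`.
#' @param seed integer seed, or NULL.
#' @return A [roi_timeseries()].
#' @export
simulate_subject_run <- function(centroids, labels, noise_sd = 0.5,
                                 tr_seconds = 2, noise_ar = 0, seed = NULL) {
  k <- nrow(centroids$values)
  if (any(labels < 1L | labels > k)) stopf("label out of centroid range 1..%d", k)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (abs(noise_ar) >= 1) stopf("noise_ar must be in (-1, 1)")
  x <- centroids$values[labels, , drop = FALSE]
  with_seed(seed, {
    if (noise_sd > 0) {
      e <- matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x), ncol(x))
      if (noise_ar != 0) {
        # innovation sd scaled so the stationary marginal sd is noise_sd
        e <- e * sqrt(1 - noise_ar^2)
        e[1L, ] <- e[1L, ] / sqrt(1 - noise_ar^2)
        for (t in 2:nrow(e)) e[t, ] <- noise_ar * e[t - 1L, ] + e[t, ]
      }
      x <- x + e
    }
    roi_timeseries(x, colnames(centroids$values), tr_seconds)
  })
}

#' Simulate striatal voxel time series as weighted cortical mixtures
#'
#' Voxel `v`'s time course is the weighted sum of cortical ROI time courses
#' under that voxel's weight vector, plus Gaussian noise.
#'
#' @param cortical_ts a [roi_timeseries()] of cortical ROI signals.
#' @param weights voxels x ROIs weight matrix (columns match cortical ROIs).
#' @param noise_sd Gaussian noise sd.
#' @param voxel_coords optional voxels x 3 integer coordinates; defaults to
#'   a line of voxels along i.
#' @param seed integer seed, or NULL.
#' @return A [voxel_timeseries()].
#' @export
simulate_striatal_run <- function(cortical_ts, weights, noise_sd = 0.5,
                                  voxel_coords = NULL, seed = NULL) {
  weights <- as.matrix(weights)
  if (any(!is.finite(weights))) stopf("weights must be finite")
  if (ncol(weights) != ncol(cortical_ts$values))
    stopf("weights have %d columns but cortical series has %d ROIs",
          ncol(weights), ncol(cortical_ts$values))
  nv <- nrow(weights)
  if (is.null(voxel_coords)) voxel_coords <- cbind(seq_len(nv), 1L, 1L)
  x <- cortical_ts$values %*% t(weights)
  with_seed(seed, {
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
    voxel_timeseries(x, voxel_coords, cortical_ts$tr_seconds)
  })
}

#' Rescale transition probabilities into target states
#'
#' Multiplies the columns named by `into` by `factor` and renormalizes each
#' row, modelling a drug that makes entries into those states more (or
#' less) likely.
#'
#' @param P row-stochastic matrix.
#' @param into target state indices.
#' @param factor positive multiplier(s), recycled over `into`.
#' @return row-stochastic matrix.
#' @export
boost_transitions <- function(P, into, factor) {
  validate_transition_matrix(P)
  factor <- rep_len(factor, length(into))
  for (i in seq_along(into)) P[, into[i]] <- P[, into[i]] * factor[i]
  P / rowSums(P)
}

base_transition_matrix <- function(n_states, p_stay = 0.55) {
  off <- (1 - p_stay) / (n_states - 1L)
  P <- matrix(off, n_states, n_states)
  diag(P) <- p_stay
  P
}

make_weight_profiles <- function(n_voxels, n_cortical, tau = 8) {
  base <- exp(-(seq_len(n_cortical) - 1L) / tau)
  base <- base / sum(base)
  t(vapply(seq_len(n_voxels),
           function(v) base[sample.int(n_cortical)],
           numeric(n_cortical)))
}

#' Configuration for a synthetic three-condition cohort
#'
#' Defaults mirror the study geometry the pipeline targets: 59 subjects,
#' conditions PBO / MPH / HAL, 235 retained frames at TR = 2 s, 129 ROIs of
#' which the first 53 are cortical, and an 8-state chain. The simulated MPH
#' raises entry probabilities into the DMN and DAN states and damps the FPN
#' state; the simulated HAL raises entries into the SM-DMN state; both also
#' act on corticostriatal structure: MPH permutes the cortical weight
#' ranking at `perm_frac` of striatal voxels, HAL leaves weights unchanged.
#' `mph_boost` is calibrated so the planted DMN dwell-time increase has a
#' paired effect size d of about 0.7 at these defaults.
#'
#' @param n_subjects cohort size.
#' @param n_states,n_rois,n_cortical_rois,n_striatal_voxels,n_frames
#'   geometry counts.
#' @param tr_seconds repetition time (s).
#' @param noise_sd frame noise sd (signal units).
#' @param p_stay baseline self-transition probability.
#' @param mph_boost multiplier on entries into DMN/DAN under MPH.
#' @param mph_fpn_damp multiplier on entries into FPN under MPH.
#' @param hal_boost multiplier on entries into SM-DMN under HAL.
#' @param perm_frac fraction of striatal voxels whose cortical weight
#'   ranking is permuted under MPH.
#' @param coupling if TRUE, each subject gets a drug-effect multiplier
#'   applied both to the transition-matrix shift and to the number of
#'   permuted voxels, planting a positive dynamics-reconfiguration coupling.
#' @param timeseries if FALSE, only state-label sequences are generated
#'   (no ROI or striatal signals) for large Monte-Carlo runs on dwell
#'   metrics alone.
#' @param seed integer seed governing all randomness.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 59L, n_states = 8L, n_rois = 129L,
                              n_cortical_rois = 53L, n_striatal_voxels = 300L,
                              n_frames = 235L, tr_seconds = 2, noise_sd = 0.5,
                              p_stay = 0.55, mph_boost = 1.26,
                              mph_fpn_damp = 0.8, hal_boost = 1.17,
                              perm_frac = 0.5, coupling = FALSE,
                              timeseries = TRUE, seed = 1L) {
  if (n_frames < 2L) stopf("n_frames must be >= 2")
  if (tr_seconds <= 0) stopf("tr_seconds must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  states <- default_state_names(n_states)
  dmn <- match("DMN", states); dan <- match("DAN", states)
  fpn <- match("FPN", states); smdmn <- match("SM-DMN", states)
  if (anyNA(c(dmn, dan, fpn, smdmn))) { dmn <- 3L; dan <- 4L; fpn <- 2L; smdmn <- 7L }
  P0 <- base_transition_matrix(n_states, p_stay)
  Pm <- boost_transitions(P0, c(dmn, dan, fpn), c(mph_boost, mph_boost, mph_fpn_damp))
  Ph <- boost_transitions(P0, smdmn, hal_boost)
  structure(list(
    n_subjects = as.integer(n_subjects), n_states = as.integer(n_states),
    n_rois = as.integer(n_rois), n_cortical_rois = as.integer(n_cortical_rois),
    n_striatal_voxels = as.integer(n_striatal_voxels),
    n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
    noise_sd = noise_sd, state_names = states,
    sig_states = states[c(fpn, dmn, dan)],
    condition_transition_matrices = list(PBO = P0, MPH = Pm, HAL = Ph),
    perm_frac = perm_frac, coupling = isTRUE(coupling),
    timeseries = isTRUE(timeseries), seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a multi-subject three-condition cohort with ground truth
#'
#' One run per subject per condition (PBO, MPH, HAL). Ages are drawn
#' Normal(39.3, 11.25) truncated to 18-55 and sex 17:42 male:female; all
#' randomness flows from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `cohort` (manifest data.frame, `roi_ts` and
#'   `striatal_ts` keyed by `"<subject>_<condition>"`, `centroids`,
#'   `cortical_idx`) and `truth` (state sequences, per-condition stationary
#'   occupancy, weight profiles, planted rank permutations, per-subject
#'   effect multipliers).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  conditions <- names(config$condition_transition_matrices)
  subjects <- sprintf("sub%03d", seq_len(ns))

  age <- stats::rnorm(ns, 39.3, 11.25)
  while (any(age < 18 | age > 55))
    age[age < 18 | age > 55] <- stats::rnorm(sum(age < 18 | age > 55), 39.3, 11.25)
  sex <- sample(c("M", "F"), ns, replace = TRUE, prob = c(17, 42) / 59)
  manifest <- data.frame(subject = rep(subjects, each = length(conditions)),
                         condition = rep(conditions, ns),
                         age = rep(round(age, 1), each = length(conditions)),
                         sex = rep(sex, each = length(conditions)),
                         stringsAsFactors = FALSE)

  centroids <- if (config$timeseries) make_centroids(config$n_states, config$n_rois)
               else NULL
  cortical_idx <- seq_len(config$n_cortical_rois)

  nv <- config$n_striatal_voxels
  vox_coords <- NULL
  weights_pbo <- NULL
  if (config$timeseries && nv > 0L) {
    side <- ceiling(nv^(1 / 3))
    grid <- as.matrix(expand.grid(i = seq_len(side), j = seq_len(side), k = seq_len(side)))
    vox_coords <- grid[seq_len(nv), , drop = FALSE]
    weights_pbo <- make_weight_profiles(nv, config$n_cortical_rois)
  }

  effect <- if (config$coupling) stats::runif(ns, 0.25, 1.75) else rep(1, ns)

  # per-subject permuted voxels and weight permutations under MPH
  perms <- NULL
  if (!is.null(weights_pbo)) {
    perms <- lapply(seq_len(ns), function(s) {
      npv <- min(nv, round(config$perm_frac * effect[s] * nv))
      vsel <- if (npv > 0L) sort(sample.int(nv, npv)) else integer(0)
      pv <- vector("list", nv)
      for (v in vsel) pv[[v]] <- sample.int(config$n_cortical_rois)
      pv
    })
  }

  P_pbo <- config$condition_transition_matrices$PBO
  subject_P <- function(cond, s) {
    P <- config$condition_transition_matrices[[cond]]
    if (cond == "PBO" || !config$coupling) return(P)
    Ps <- P_pbo + effect[s] * (P - P_pbo)
    Ps[Ps < 0] <- 0
    Ps / rowSums(Ps)
  }

  roi_ts <- list(); striatal_ts <- list(); seqs <- list()
  for (s in seq_len(ns)) {
    for (cond in conditions) {
      key <- paste0(subjects[s], "_", cond)
      labs <- simulate_state_sequence(subject_P(cond, s), config$n_frames)
      seqs[[key]] <- labs
      if (config$timeseries) {
        run <- simulate_subject_run(centroids, labs, config$noise_sd,
                                    config$tr_seconds)
        roi_ts[[key]] <- run
        if (!is.null(weights_pbo)) {
          W <- weights_pbo
          if (cond == "MPH") {
            pv <- perms[[s]]
            for (v in seq_len(nv)) if (!is.null(pv[[v]])) W[v, ] <- W[v, pv[[v]]]
          }
          cort <- roi_timeseries(run$values[, cortical_idx, drop = FALSE],
                                 run$roi_names[cortical_idx], config$tr_seconds)
          striatal_ts[[key]] <- simulate_striatal_run(
            cort, W, config$noise_sd, vox_coords)
        }
      }
    }
  }

  expected_dwell <- lapply(config$condition_transition_matrices,
                           stationary_distribution)
  list(
    cohort = list(manifest = manifest, roi_ts = roi_ts,
                  striatal_ts = striatal_ts, centroids = centroids,
                  cortical_idx = cortical_idx, config = config),
    truth = list(state_sequences = seqs, expected_dwell = expected_dwell,
                 weight_profiles = weights_pbo,
                 planted_rank_permutations = perms,
                 effect_multipliers = effect))
}

#' Write / read a simulated cohort as a directory of text files
#'
#' `manifest.tsv` plus one `<subject>_<condition>_roi.tsv` and (when
#' present) `<subject>_<condition>_striatal.tsv` per run; ground truth is
#' not serialized (it lives with the in-memory object).
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- sim$cohort
  utils::write.table(co$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(co$centroids)) write_centroids(co$centroids, file.path(dir, "centroids.tsv"))
  for (key in names(co$roi_ts))
    write_roi_timeseries(co$roi_ts[[key]], file.path(dir, paste0(key, "_roi.tsv")))
  for (key in names(co$striatal_ts))
    write_voxel_timeseries(co$striatal_ts[[key]], file.path(dir, paste0(key, "_striatal.tsv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @param tr_seconds repetition time used when reading runs back.
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  cen_path <- file.path(dir, "centroids.tsv")
  centroids <- if (file.exists(cen_path)) read_centroids(cen_path) else NULL
  keys <- paste0(manifest$subject, "_", manifest$condition)
  roi_ts <- list(); striatal_ts <- list()
  for (key in keys) {
    rp <- file.path(dir, paste0(key, "_roi.tsv"))
    if (file.exists(rp)) roi_ts[[key]] <- read_roi_timeseries(rp, tr_seconds)
    sp <- file.path(dir, paste0(key, "_striatal.tsv"))
    if (file.exists(sp)) striatal_ts[[key]] <- read_voxel_timeseries(sp, tr_seconds)
  }
  list(manifest = manifest, roi_ts = roi_ts, striatal_ts = striatal_ts,
       centroids = centroids)
}
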