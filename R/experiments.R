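# Monte-Carlo validation experiments over synthetic cohorts: detection
# power for the planted drug effect, the ROR-above-null ordering, recovery
# of the planted dynamics-reconfiguration coupling, and type-I calibration
# with no planted effects. These back both the test suite and the
# reproducibility script; problem sizes are the package's study defaults.

#' Detection power for the planted MPH dwell-time increase
#'
#' Simulates label-only cohorts under the default planted conditions
#' (DMN dwell effect d of about 0.7 at n = 59) and runs the post hoc
#' paired t (MPH vs PBO on DMN total time) on each; power is the fraction
#' of seeds detected at the Bonferroni-corrected one-sided-free threshold
#' alpha = 0.025.
#'
#' @param n_seeds number of cohort replicates.
#' @param n_subjects cohort size per replicate.
#' @param alpha detection threshold on the raw two-sided p.
#' @param seed base seed; replicate i uses seed + i.
#' @return list: `per_seed` (data.frame seed, t, p, d), `power`, `mean_d`.
#' @export
power_dwell_experiment <- function(n_seeds = 100L, n_subjects = 59L,
                                   alpha = 0.025, seed = 1L) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(n_subjects = n_subjects, timeseries = FALSE,
                             seed = seed + i)
    sim <- simulate_cohort(cfg)
    dmn <- match("DMN", cfg$state_names)
    tt_state <- function(cond) vapply(
      sprintf("sub%03d_%s", seq_len(n_subjects), cond),
      function(k) dwell_metrics(sim$truth$state_sequences[[k]],
                                cfg$tr_seconds, cfg$n_states)$total_time_s[dmn],
      numeric(1))
    res <- paired_t(tt_state("MPH"), tt_state("PBO"))
    rows[[i]] <- data.frame(seed = seed + i, t = res$t, p = res$p, d = res$d)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       power = mean(per_seed$p < alpha & per_seed$t > 0),
       mean_d = mean(per_seed$d))
}

#' Drug-pair ROR against the within-session placebo null
#'
#' Per seed, one subject's PBO and MPH runs are generated with the default
#' planted weight permutations; the mean striatal ROR of the MPH-PBO
#' profile pair is compared with the subject's own split-half placebo
#' null.
#'
#' @param n_seeds replicates.
#' @param n_voxels striatal voxels per subject.
#' @param seed base seed.
#' @return list: `per_seed` (drug and null mean ROR), `exceed_rate`.
#' @export
ror_null_experiment <- function(n_seeds = 50L, n_voxels = 50L, seed = 1L) {
  n_cort <- 53L
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    set.seed(seed + 10000L + i)
    cfg <- simulation_config()
    cen <- make_centroids(cfg$n_states, n_cort)
    W <- make_weight_profiles(n_voxels, n_cort)
    Wm <- W
    perm_vox <- sample.int(n_voxels, round(cfg$perm_frac * n_voxels))
    for (v in perm_vox) Wm[v, ] <- Wm[v, sample.int(n_cort)]
    run <- function(P, Wv) {
      labs <- simulate_state_sequence(P, cfg$n_frames)
      cort <- simulate_subject_run(cen, labs, cfg$noise_sd, cfg$tr_seconds)
      list(cort = cort,
           str = simulate_striatal_run(cort, Wv, cfg$noise_sd))
    }
    pbo <- run(cfg$condition_transition_matrices$PBO, W)
    mph <- run(cfg$condition_transition_matrices$MPH, Wm)
    p_pbo <- connectivity_profile(pbo$str, pbo$cort, "PBO")
    p_mph <- connectivity_profile(mph$str, mph$cort, "MPH")
    halves <- split_half_profiles(pbo$str, pbo$cort)
    drug <- subject_cscp_score(rank_order_rearrangement(p_mph, p_pbo))
    null <- subject_cscp_score(rank_order_rearrangement(halves$first, halves$second))
    rows[[i]] <- data.frame(seed = seed + 10000L + i, drug_ror = drug,
                            null_ror = null)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       exceed_rate = mean(per_seed$drug_ror > per_seed$null_ror))
}

#' Recovery of the planted dynamics-reconfiguration coupling
#'
#' Cohorts are generated with `coupling = TRUE`, so subjects with larger
#' drug-effect multipliers receive both larger transition-matrix shifts
#' and more permuted striatal weight profiles. Per seed the correlation
#' between subject-wise whole-striatum MPH-PBO ROR and the absolute
#' time-change score is computed; recovery means r > 0.
#'
#' @param n_seeds replicates.
#' @param n_subjects cohort size.
#' @param n_voxels striatal voxels.
#' @param seed base seed.
#' @return list: `per_seed` (r, p), `positive_rate`, `mean_r`.
#' @export
coupling_experiment <- function(n_seeds = 100L, n_subjects = 59L,
                                n_voxels = 100L, seed = 1L) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(n_subjects = n_subjects, n_rois = 53L,
                             n_cortical_rois = 53L,
                             n_striatal_voxels = n_voxels,
                             coupling = TRUE, seed = seed + 20000L + i)
    sim <- simulate_cohort(cfg)
    cohort <- sim$cohort
    idx <- cohort$cortical_idx
    subjects <- unique(cohort$manifest$subject)
    ror <- tchange <- numeric(length(subjects))
    for (s in seq_along(subjects)) {
      keym <- paste0(subjects[s], "_MPH"); keyp <- paste0(subjects[s], "_PBO")
      cort <- function(k) {
        ts <- cohort$roi_ts[[k]]
        roi_timeseries(ts$values[, idx, drop = FALSE], ts$roi_names[idx],
                       ts$tr_seconds)
      }
      pm <- connectivity_profile(cohort$striatal_ts[[keym]], cort(keym))
      pp <- connectivity_profile(cohort$striatal_ts[[keyp]], cort(keyp))
      ror[s] <- subject_cscp_score(rank_order_rearrangement(pm, pp))
      dm <- dwell_metrics(sim$truth$state_sequences[[keym]], cfg$tr_seconds,
                          cfg$n_states)
      dp <- dwell_metrics(sim$truth$state_sequences[[keyp]], cfg$tr_seconds,
                          cfg$n_states)
      tchange[s] <- abs_time_change_score(dm, dp, normalize = TRUE)
    }
    ct <- dynamics_cscp_correlation(tchange, ror)
    rows[[i]] <- data.frame(seed = cfg$seed, r = ct$r, p = ct$p)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, positive_rate = mean(per_seed$r > 0),
       mean_r = mean(per_seed$r))
}

#' Type-I calibration with no planted effects
#'
#' Cohorts with identical transition matrices in all conditions: the drug
#' x state interaction and the dynamics-CSCP correlation should reject at
#' about the nominal 5% rate.
#'
#' @param n_seeds replicates.
#' @param n_subjects cohort size.
#' @param alpha nominal level.
#' @param seed base seed.
#' @return list: `per_seed` (interaction p, correlation p),
#'   `interaction_rejection_rate`, `correlation_rejection_rate`.
#' @export
null_calibration_experiment <- function(n_seeds = 100L, n_subjects = 59L,
                                        alpha = 0.05, seed = 1L) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(n_subjects = n_subjects, mph_boost = 1,
                             mph_fpn_damp = 1, hal_boost = 1,
                             timeseries = FALSE, seed = seed + 30000L + i)
    sim <- simulate_cohort(cfg)
    dwell <- cohort_dwell_table(sim$cohort,
                                label_sequences = sim$truth$state_sequences,
                                tr_seconds = cfg$tr_seconds)
    a <- rm_anova(dwell, "total_time_s", c("condition", "state_name"))
    p_int <- a$p[a$effect == "condition:state_name"]

    # dynamics-CSCP null: time-change scores against independently drawn
    # scores, so any association is spurious by construction
    y <- cohort_time_change_scores(dwell, normalize = TRUE)$score
    set.seed(cfg$seed + 500000L)
    x <- stats::rnorm(n_subjects)
    p_cor <- dynamics_cscp_correlation(y, x)$p
    rows[[i]] <- data.frame(seed = cfg$seed, p_interaction = p_int,
                            p_correlation = p_cor)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       interaction_rejection_rate = mean(per_seed$p_interaction < alpha),
       correlation_rejection_rate = mean(per_seed$p_correlation < alpha))
}

#' Frame-assignment accuracy at a given noise level
#'
#' @param n_seeds replicates (one run each).
#' @param noise_sd frame noise sd.
#' @param seed base seed.
#' @return list: `per_seed` accuracies, `mean_accuracy`.
#' @export
assignment_accuracy_experiment <- function(n_seeds = 20L, noise_sd = 0.5,
                                           seed = 1L) {
  cfg <- simulation_config()
  cen <- make_centroids(cfg$n_states, cfg$n_rois, seed = seed)
  P <- cfg$condition_transition_matrices$PBO
  acc <- vapply(seq_len(n_seeds), function(i) {
    set.seed(seed + 40000L + i)
    labs <- simulate_state_sequence(P, cfg$n_frames)
    run <- simulate_subject_run(cen, labs, noise_sd, cfg$tr_seconds)
    mean(assign_frames(run, cen)$labels == labs)
  }, numeric(1))
  list(per_seed = acc, mean_accuracy = mean(acc))
}
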