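test_that("configuration invariants are enforced", {
  expect_s3_class(synth_config(), "avp_synth_config")
  expect_error(synth_config(duration = 0), "positive")
  expect_error(synth_config(duration = 4, fs = 250), ">= 2000")
  expect_error(synth_config(band_center = 2, band_halfwidth = 3), "band_center")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(gains = c(redundant = 1)), "must name")
  expect_error(synth_config(av_coupling = 1.5), "av_coupling")
})

test_that("stimulus pairs are deterministic, positive, and band-structured", {
  cfg <- quick_config(duration = 60, seed = 51)
  s1 <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 52)
  s2 <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 52)
  expect_identical(s1$audio_env$values, s2$audio_env$values)
  expect_identical(s1$lip_area$values, s2$lip_area$values)

  expect_true(all(s1$audio_env$values > 0))
  expect_true(all(s1$lip_area$values > 0))
  expect_length(s1$audio_env$values, 60 * 250)

  # a different seed gives a different realisation
  s3 <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 53)
  expect_false(identical(s1$audio_env$values, s3$audio_env$values))
})

test_that("matched pairs peak in band; unmatched pairs stay below a shift null", {
  cfg <- quick_config(duration = 60, seed = 54)
  peaks <- vapply(1:10, function(i) {
    s <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 540 + i)
    prof <- spectral_mi_profile(s$audio_env, s$lip_area)
    prof$frequency[which.max(prof$mi)]
  }, numeric(1))
  expect_true(all(peaks >= 3 & peaks <= 7))

  # unmatched: at every tested frequency the MI stays inside the range of a
  # per-frequency time-shift null (the null floor varies by band because
  # narrow bands have fewer effective samples)
  un <- gen_stimulus_pair(cfg, matched = FALSE, rng_seed = 55)
  centers <- c(3, 5, 8, 12, 16)
  prof_un <- spectral_mi_profile(un$audio_env, un$lip_area, centers = centers)
  null_mi <- vapply(1:16, function(i) {
    sh <- time_shift_surrogate(un$audio_env, un$lip_area,
      shift_a_s = 1.7 * i, shift_v_s = 29 + i
    )
    spectral_mi_profile(sh$audio_env, un$lip_area, centers = centers)$mi
  }, numeric(length(centers)))
  null_max <- apply(null_mi, 1, max)
  expect_true(all(prof_un$mi < null_max + 0.005))
  # while the matched pair at the band center clears the same null easily
  ma <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 55)
  expect_gt(
    spectral_mi_profile(ma$audio_env, ma$lip_area, centers = 5)$mi,
    10 * max(null_mi)
  )
})

test_that("node generation validates kinds and is seed-deterministic", {
  cfg <- quick_config(duration = 60, seed = 56)
  stim <- gen_stimulus_pair(cfg, rng_seed = 57)
  expect_error(
    gen_neural_node(stim$audio_env, stim$lip_area, "fancy"),
    "unknown node kind"
  )
  n1 <- gen_neural_node(stim$audio_env, stim$lip_area, "redundant", rng_seed = 58)
  n2 <- gen_neural_node(stim$audio_env, stim$lip_area, "redundant", rng_seed = 58)
  expect_identical(n1$values, n2$values)
  expect_identical(attr(n1, "kind"), "redundant")
})

test_that("null nodes decompose to chance-level terms", {
  cfg <- quick_config(duration = 80, seed = 59)
  stim <- gen_stimulus_pair(cfg, rng_seed = 60)
  node <- gen_neural_node(stim$audio_env, stim$lip_area, "null",
    gain = 5, noise_sd = 1, rng_seed = 61
  )
  p <- avpid:::pid_for_node(stim$audio_env, stim$lip_area, node,
    5, 2, 100, 1e4,
    rng_seed = 62
  )
  for (term in c(p$red, p$uni_a, p$uni_v, p$syn)) {
    expect_lt(abs(term), 3 * p$mc_se + 0.01)
  }
})

test_that("planted redundant and synergistic couplings order the PID terms", {
  cfg <- quick_config(duration = 120, seed = 63)
  stim <- gen_stimulus_pair(cfg, rng_seed = 64)
  pid_of <- function(kind, gain) {
    node <- gen_neural_node(stim$audio_env, stim$lip_area, kind,
      gain = gain, noise_sd = 1, rng_seed = 65
    )
    avpid:::pid_for_node(stim$audio_env, stim$lip_area, node, 5, 2, 100, 1e4,
      rng_seed = 66
    )
  }
  pr <- pid_of("redundant", gain = 3)
  expect_gt(pr$red, pr$syn)
  ps <- pid_of("synergistic", gain = 1)
  expect_gt(ps$syn, ps$red)
})

test_that("cohorts are reproducible, sized, and behaviorally linked", {
  expect_error(gen_cohort(synth_config(n_subjects = 2)), ">= 3")

  cfg <- synth_config(n_subjects = 5, duration = 8, rng_seed = 67)
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  expect_length(c1, 5)
  expect_identical(c1[[3]]$nodes$redundant$values, c2[[3]]$nodes$redundant$values)
  expect_identical(cohort_scores(c1), cohort_scores(c2))
  expect_true(all(cohort_scores(c1)$comprehension >= 0 &
    cohort_scores(c1)$comprehension <= 1))
  # default cohort size matches the study
  expect_identical(synth_config()$n_subjects, 44L)
})

test_that("a zero behavior slope decouples gains from scores", {
  # null calibration: across replicate cohorts the gain-score correlation is
  # only spuriously significant at ~ the nominal rate
  pvals <- vapply(1:100, function(i) {
    cfg <- synth_config(
      n_subjects = 10, duration = 8, behavior_slope = 0,
      rng_seed = 700 + i
    )
    coh <- gen_cohort(cfg)
    g <- vapply(coh, function(s) s$gains[["redundant"]], numeric(1))
    behavior_correlation(g, cohort_scores(coh)$comprehension)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("a strong behavior link is recovered with the right sign", {
  signs <- vapply(1:40, function(i) {
    cfg <- synth_config(
      n_subjects = 44, duration = 8, behavior_slope = 0.5,
      behavior_noise_sd = 0.02, rng_seed = 800 + i
    )
    coh <- gen_cohort(cfg)
    g <- vapply(coh, function(s) s$gains[["redundant"]], numeric(1))
    ct <- behavior_correlation(g, cohort_scores(coh)$comprehension)
    ct$estimate > 0 && ct$p.value < 0.05
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})
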