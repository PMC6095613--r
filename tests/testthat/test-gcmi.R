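test_that("copula normalisation maps ranks to Gaussian quantiles", {
  # three points land on the 25/50/75% standard-normal quantiles
  expect_equal(
    as.numeric(copula_normalise(c(1, 2, 3))),
    qnorm(c(0.25, 0.5, 0.75)),
    tolerance = 1e-12
  )
  expect_equal(round(as.numeric(copula_normalise(c(1, 2, 3))), 4),
               c(-0.6745, 0, 0.6745))

  # strictly monotone transforms leave the output bit-identical
  set.seed(1)
  x <- rnorm(500)
  expect_identical(
    as.numeric(copula_normalise(x)),
    as.numeric(copula_normalise(exp(x)))
  )

  # a standard-normal column is nearly reproduced at large n
  set.seed(2)
  g <- rnorm(10000)
  expect_gt(cor(g, as.numeric(copula_normalise(g))), 0.99)

  expect_error(copula_normalise(rep(1, 50)), "constant column")
  expect_error(copula_normalise(c(1, NA, 3)), "non-finite")
})

test_that("mi_gg matches the Gaussian closed form and is symmetric", {
  z <- rho_pair(50000, 0.5, seed = 3)
  expect_lt(abs(mi_gg(z[, 1], z[, 2]) - gauss_mi_rho(0.5)), 0.01)

  # symmetry of the formula (to numerical precision of the factorisation)
  set.seed(4)
  a <- matrix(rnorm(2000), ncol = 2)
  b <- matrix(rnorm(2000), ncol = 2)
  expect_equal(mi_gg(a, b), mi_gg(b, a), tolerance = 1e-12)

  # duplicated column -> singular joint covariance
  expect_error(mi_gg(cbind(a[, 1], a[, 1]), b), "singular")
})

test_that("mi_gg null estimates are centred near zero", {
  set.seed(5)
  nulls <- replicate(200, mi_gg(rnorm(5000), rnorm(5000)))
  expect_gte(mean(abs(nulls) < 0.01), 0.95)
})

test_that("mi_gg respects its lower-bound character for Gaussian data", {
  set.seed(6)
  for (rho in c(0.3, 0.6)) {
    est <- replicate(30, {
      z <- rho_pair(2000, rho)
      mi_gg(z[, 1], z[, 2])
    })
    se <- sd(est) / sqrt(length(est))
    expect_lt(mean(est), gauss_mi_rho(rho) + 3 * se)
  }
})

test_that("mi estimates are invariant to monotone transforms of inputs", {
  set.seed(7)
  z <- rho_pair(3000, 0.4)
  expect_identical(
    mi_gg(z[, 1], z[, 2]),
    mi_gg(exp(z[, 1]), z[, 2]^3)
  )
})

test_that("phase MI detects self-dependence and ignores phase offsets", {
  set.seed(8)
  s <- bandpass_analytic(avp_ts(avpid:::narrowband_noise(20000, 250, 5, 2), 250), 5, 2)
  p <- phase_2d(s)
  # a (near-)copy of the same phase signal: MI is large; an exact copy makes
  # the fitted Gaussian singular, which is reported as an explicit error
  near <- phase_2d(avp_analytic(s$values * exp(1i * rnorm(20000, sd = 0.05)), 250, 5, 2))
  expect_gt(mi_phase(p, near), 1)
  expect_error(mi_phase(p, p), "singular")

  # a constant rotation of the unit circle preserves the dependence; the
  # semi-parametric estimator tracks this closely at the moderate dependence
  # levels of stimulus-brain coupling (rank normalisation is per-coordinate,
  # so the bound is only approximately rotation-invariant)
  s2 <- bandpass_analytic(
    avp_ts(
      0.5 * Re(s$values) / sd(Re(s$values)) +
        sqrt(0.75) * avpid:::narrowband_noise(20000, 250, 5, 2), 250
    ), 5, 2
  )
  p2 <- phase_2d(s2)
  rot <- avp_analytic(s$values * exp(1i * pi / 4), s$fs, 5, 2)
  pr <- phase_2d(rot)
  expect_lt(abs(mi_phase(p, p2) - mi_phase(pr, p2)), 0.01)

  # independent narrowband signals sit at the null level
  q <- phase_2d(bandpass_analytic(avp_ts(avpid:::narrowband_noise(20000, 250, 5, 2), 250), 5, 2))
  expect_lt(abs(mi_phase(p, q)), 0.02)

  expect_error(
    mi_phase(phase_2d(s$values[1:5]), phase_2d(s$values[1:5])),
    "fewer than 10"
  )
})

test_that("noise cannot increase phase MI (data-processing sanity)", {
  cfg <- quick_config(seed = 9)
  stim <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 90)
  noisy <- avp_ts(stim$lip_area$values + 5 * sd(stim$lip_area$values) * rnorm(length(stim$lip_area)),
    stim$lip_area$fs
  )
  f <- function(v) {
    mi_phase(
      phase_2d(bandpass_analytic(stim$audio_env, 5, 2)),
      phase_2d(bandpass_analytic(v, 5, 2))
    )
  }
  set.seed(10)
  expect_gt(f(stim$lip_area), f(noisy))
})

test_that("spectral MI profile peaks at the planted band and is flat otherwise", {
  cfg <- quick_config(duration = 80, seed = 11)
  stim <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 42)
  prof <- spectral_mi_profile(stim$audio_env, stim$lip_area)
  peak <- prof$frequency[which.max(prof$mi)]
  expect_gte(peak, 3)
  expect_lte(peak, 7)

  un <- gen_stimulus_pair(cfg, matched = FALSE, rng_seed = 43)
  pu <- spectral_mi_profile(un$audio_env, un$lip_area)
  expect_lt(max(pu$mi), 0.02)

  # one-center profile agrees with the direct phase-MI computation
  one <- spectral_mi_profile(stim$audio_env, stim$lip_area, centers = 5)
  direct <- mi_phase(
    phase_2d(avpid:::trim_analytic(bandpass_analytic(stim$audio_env, 5, 2))),
    phase_2d(avpid:::trim_analytic(bandpass_analytic(stim$lip_area, 5, 2)))
  )
  expect_equal(one$mi, direct)

  expect_error(
    spectral_mi_profile(stim$audio_env, stim$lip_area, centers = c(1, 5)),
    "within"
  )
})

test_that("delayed MI localises a planted 100 ms delay on the default 26-lag grid", {
  cfg <- quick_config(duration = 80, seed = 12)
  stim <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 13)
  node <- gen_neural_node(stim$audio_env, stim$lip_area, "redundant",
    gain = 3, noise_sd = 1, lag_ms = 100, rng_seed = 14
  )
  dm <- delayed_mi(stim$audio_env, node)
  expect_identical(nrow(dm), 26L)
  expect_identical(dm$lag_ms, seq(0, 500, by = 20))
  expect_equal(dm$lag_ms[which.max(dm$mi)], 100)
  expect_equal(attr(dm, "mean_mi"), mean(dm$mi))

  set.seed(15)
  ind <- delayed_mi(
    avp_ts(avpid:::narrowband_noise(20000, 250, 5, 2), 250),
    avp_ts(avpid:::narrowband_noise(20000, 250, 5, 2), 250)
  )
  expect_true(all(abs(ind$mi) < 0.01))
})

test_that("plug-in discrete MI of a fair coin with itself is exactly one bit", {
  coin <- rep(c(0, 1), 50)
  expect_identical(mi_plugin_discrete(coin, coin), 1)
  expect_equal(mi_plugin_discrete(coin, 1 - coin), 1)
  set.seed(16)
  expect_lt(mi_plugin_discrete(sample(0:1, 4000, TRUE), sample(0:1, 4000, TRUE)), 0.01)
})
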