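test_that("interaction information is the joint-minus-marginals difference", {
  expect_equal(interaction_information(0.3, 0.3, 0.6), 0)
  expect_equal(interaction_information(0.3, 0.3, 0.4), -0.2) # net redundant
  expect_equal(interaction_information(0.1, 0.1, 0.5), 0.3) # net synergistic
})

test_that("max-ent surrogate is the conditional-independence closed form", {
  C <- random_corr(6, seed = 21)
  m <- new_gauss_model(C, c(2, 2, 2))
  me <- maxent_surrogate(m)
  ix <- avpid:::block_idx(m$dims)

  # (M,A) and (M,V) blocks preserved exactly
  keep <- c(ix$m, ix$a)
  expect_lt(max(abs(me$cov_tilde[keep, keep] - C[keep, keep])), 1e-10)
  keep <- c(ix$m, ix$v)
  expect_lt(max(abs(me$cov_tilde[keep, keep] - C[keep, keep])), 1e-10)

  # entropy (determinant) never decreases
  expect_gte(det(me$cov_tilde), det(C) - 1e-12)
  expect_gte(me$entropy_gain, 0)

  # A-V partial covariance given M vanishes
  S <- me$cov_tilde
  part <- S[ix$a, ix$v] - S[ix$a, ix$m] %*% solve(S[ix$m, ix$m], S[ix$m, ix$v])
  expect_lt(max(abs(part)), 1e-8)

  # a model already conditionally independent is a fixed point
  m2 <- new_gauss_model(me$cov_tilde, c(2, 2, 2))
  me2 <- maxent_surrogate(m2)
  expect_lt(max(abs(me2$cov_tilde - me$cov_tilde)), 1e-12)
  expect_lt(me2$entropy_gain, 1e-12)
})

test_that("closed-form max-ent matches a numerical log-det maximiser", {
  for (seed in 1:5) {
    for (dims in list(c(2, 2, 2), c(1, 1, 1))) {
      C <- random_corr(sum(dims), seed = 100 + seed + sum(dims))
      me <- maxent_surrogate(new_gauss_model(C, dims))
      oracle <- maxent_numeric_oracle(C, dims)
      expect_lt(max(abs(me$cov_tilde - oracle)), 1e-6)
    }
  }
})

test_that("Iccs redundancy vanishes for independent variables", {
  m <- new_gauss_model(diag(6), c(2, 2, 2))
  r <- iccs_redundancy(m, n_mc = 2e4, rng_seed = 31)
  expect_lt(abs(r$red), 3 * r$mc_se + 1e-12)
})

test_that("Iccs Monte-Carlo error scales as one over root n", {
  C <- random_corr(3, seed = 32)
  m <- new_gauss_model(C, c(1, 1, 1))
  me <- maxent_surrogate(m)
  est <- function(n_mc) {
    vapply(1:50, function(s) iccs_redundancy(m, me, n_mc = n_mc, rng_seed = 1000 + s)$red,
      numeric(1)
    )
  }
  e1 <- est(1e4)
  e2 <- est(2e4)
  ratio <- sd(e1) / sd(e2)
  expect_gt(ratio, sqrt(2) * 0.8)
  expect_lt(ratio, sqrt(2) * 1.2)
  # the reported mc_se agrees with the spread over reseeds
  se_rep <- mean(vapply(1:10, function(s) {
    iccs_redundancy(m, me, n_mc = 1e4, rng_seed = s)$mc_se
  }, numeric(1)))
  expect_gt(sd(e1) / se_rep, 0.7)
  expect_lt(sd(e1) / se_rep, 1.4)

  expect_error(iccs_redundancy(m, me, n_mc = 100), "10,000")
})

test_that("Iccs is seeded-deterministic", {
  C <- random_corr(6, seed = 33)
  m <- new_gauss_model(C, c(2, 2, 2))
  r1 <- iccs_redundancy(m, n_mc = 1e4, rng_seed = 7)
  r2 <- iccs_redundancy(m, n_mc = 1e4, rng_seed = 7)
  expect_identical(r1, r2)
})

test_that("PID identities hold to machine precision and match Eq-1 interaction", {
  set.seed(34)
  n <- 3000
  z <- rnorm(n)
  a <- cbind(z + rnorm(n), rnorm(n))
  v <- cbind(z + rnorm(n), rnorm(n))
  m <- cbind(z + rnorm(n), 0.3 * a[, 1] + rnorm(n))
  p <- pid_decompose(m, a, v, n_mc = 1e4, rng_seed = 35)

  expect_lt(abs(p$red + p$uni_a - p$mi_a), 1e-12)
  expect_lt(abs(p$red + p$uni_v - p$mi_v), 1e-12)
  expect_lt(abs(p$red + p$uni_a + p$uni_v + p$syn - p$mi_av), 1e-12)
  expect_lt(
    abs((p$syn - p$red) - interaction_information(p$mi_a, p$mi_v, p$mi_av)),
    1e-12
  )

  # deterministic under identical seeds
  p2 <- pid_decompose(m, a, v, n_mc = 1e4, rng_seed = 35)
  expect_identical(unclass(p), unclass(p2))
})

test_that("an additive target of independent predictors is net synergistic", {
  set.seed(36)
  n <- 5000
  a <- rnorm(n)
  v <- rnorm(n)
  m <- a + v + rnorm(n)
  p <- pid_decompose(m, a, v, n_mc = 1e4, rng_seed = 37)
  net <- interaction_information(p$mi_a, p$mi_v, p$mi_av)
  expect_gt(net, 0)
  expect_equal(p$syn - p$red, net, tolerance = 1e-12)
  expect_gt(p$syn, p$red)
})

test_that("redundancy is invariant to the A-V cross block of the source model", {
  C <- random_corr(6, seed = 38)
  m <- new_gauss_model(C, c(2, 2, 2))
  # perturb only the A-V cross block, keeping positive definiteness
  ix <- avpid:::block_idx(m$dims)
  C2 <- C
  C2[ix$a, ix$v] <- 0.9 * C2[ix$a, ix$v]
  C2[ix$v, ix$a] <- t(C2[ix$a, ix$v])
  m2 <- new_gauss_model(C2, c(2, 2, 2))
  r1 <- iccs_redundancy(m, n_mc = 5e4, rng_seed = 39)
  r2 <- iccs_redundancy(m2, n_mc = 5e4, rng_seed = 40)
  expect_lt(abs(r1$red - r2$red), 3 * (r1$mc_se + r2$mc_se))
  # and mi_a, mi_v are untouched by construction
  expect_equal(gauss_block_mi(m, "a"), gauss_block_mi(m2, "a"))
  expect_equal(gauss_block_mi(m, "v"), gauss_block_mi(m2, "v"))
})

test_that("local p*i maps decompose the global quantities over median cells", {
  r <- 0.6
  C <- matrix(c(
    1, r, r,
    r, 1, 0.5,
    r, 0.5, 1
  ), 3, 3)
  m <- new_gauss_model(C, c(1, 1, 1))
  lm <- local_pid_map(m, n_mc = 1e5, rng_seed = 41)
  expect_identical(nrow(lm), 8L)
  expect_equal(sum(lm$p_cell), 1, tolerance = 1e-12)
  # cells sum to the model's joint MI within Monte-Carlo error
  expect_equal(sum(lm$pi_mi), gauss_block_mi(m, "av"),
    tolerance = 4 * attr(lm, "mc_se_mi") / gauss_block_mi(m, "av")
  )
  expect_equal(sum(lm$pi_red), attr(lm, "red_total"), tolerance = 1e-12)

  # independent model: every cell near zero
  l0 <- local_pid_map(new_gauss_model(diag(3), c(1, 1, 1)), n_mc = 5e4, rng_seed = 42)
  expect_lt(max(abs(l0$pi_mi)), 0.005)
  expect_lt(max(abs(l0$pi_red)), 0.005)

  # near-duplicated predictors: opposite-sign (a, v) cells carry ~no mass
  Cd <- matrix(c(
    1, r, r,
    r, 1, 0.98,
    r, 0.98, 1
  ), 3, 3)
  ld <- local_pid_map(new_gauss_model(Cd, c(1, 1, 1)), n_mc = 5e4, rng_seed = 43)
  off <- ld$a_bin != ld$v_bin
  expect_lt(sum(ld$p_cell[off]), 0.07)
  expect_lt(sum(abs(ld$pi_mi[off])), 0.05 * sum(abs(ld$pi_mi)))

  expect_error(local_pid_map(new_gauss_model(diag(6), c(2, 2, 2))), "1-dimensional")
})

test_that("region-pair PID about a stimulus recovers shared and absent coupling", {
  set.seed(44)
  n <- 4000
  s <- cbind(rnorm(n), rnorm(n))
  node1 <- s + 0.8 * matrix(rnorm(2 * n), ncol = 2)
  node2 <- s + 0.8 * matrix(rnorm(2 * n), ncol = 2)
  p <- pid_regions_to_stimulus(node1, node2, s, n_mc = 2e4, rng_seed = 45)
  expect_gt(p$red, p$uni_a)
  expect_gt(p$red, p$uni_v)
  expect_gt(p$red, p$syn)

  # stimulus independent of both nodes: all terms at chance
  s0 <- matrix(rnorm(2 * n), ncol = 2)
  p0 <- pid_regions_to_stimulus(node1, node2, s0, n_mc = 2e4, rng_seed = 46)
  expect_lt(max(abs(c(p0$red, p0$uni_a, p0$uni_v, p0$syn))), 0.01)
})

test_that("model validation rejects malformed covariances", {
  expect_error(new_gauss_model(diag(5), c(2, 2, 2)), "block sizes")
  bad <- diag(6)
  bad[1, 2] <- 0.5 # asymmetric
  expect_error(new_gauss_model(bad, c(2, 2, 2)), "symmetric")
  sing <- matrix(1, 3, 3)
  expect_error(new_gauss_model(sing, c(1, 1, 1)), "positive definite")
  scaled <- diag(6) * 2
  expect_error(new_gauss_model(scaled, c(2, 2, 2)), "unit diagonal")
})

test_that("tidy and glance expose the decomposition as tibbles", {
  set.seed(47)
  z <- rnorm(500)
  p <- pid_decompose(z + rnorm(500), z + rnorm(500), z + rnorm(500),
    n_mc = 1e4, rng_seed = 48
  )
  td <- tidy(p)
  expect_identical(td$term, c("red", "uni_a", "uni_v", "syn"))
  expect_equal(td$estimate[1], p$red)
  gl <- glance(p)
  expect_equal(gl$interaction, p$mi_av - p$mi_a - p$mi_v)
})
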