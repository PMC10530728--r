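test_that("synthetic mean-abundance profiles pin, sort and normalize", {
  set.seed(401)
  pin <- c(0.105, 0.062, 0.054, 0.050, 0.049)
  prof <- synthesize_mean_abundances(856, pinned_top = pin)
  expect_identical(prof$pi_bar[1:5], pin)
  expect_equal(sum(prof$pi_bar), 1, tolerance = 1e-12)
  expect_true(all(diff(prof$pi_bar) <= 0))

  # normalization forces the remainder
  prof2 <- synthesize_mean_abundances(2, pinned_top = 0.9)
  expect_equal(prof2$pi_bar, c(0.9, 0.1))

  for (J in c(20, 57, 200)) {
    p <- synthesize_mean_abundances(J, pinned_top = pin)$pi_bar
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0))
  }
  expect_error(synthesize_mean_abundances(10, pinned_top = c(0.6, 0.5)),
               "sum to less than 1")
})

test_that("Dirichlet baselines have the configured mean and overdispersion", {
  set.seed(402)
  prof <- synthesize_mean_abundances(50, pinned_top = c(0.2, 0.1))

  # vanishing overdispersion: every draw collapses to pi_bar
  tiny <- community_profile(prof$pi_bar, overdispersion = 1e-8)
  Pi <- draw_baseline_abundances(tiny, 5)
  expect_equal(Pi, matrix(prof$pi_bar, 5, 50, byrow = TRUE),
               tolerance = 1e-3)

  set.seed(403)
  Pi <- draw_baseline_abundances(prof, 10000)
  expect_equal(rowSums(Pi), rep(1, 10000), tolerance = 1e-12)
  # per-taxon means within 3 sd of pi_bar
  sds <- sqrt(prof$pi_bar * (1 - prof$pi_bar) * 0.02 / 10000)
  expect_true(all(abs(colMeans(Pi) - prof$pi_bar) < 3.5 * sds))

  set.seed(404)
  Pi2 <- draw_baseline_abundances(prof, 1000)
  expect_equal(round(estimate_overdispersion(Pi2), 2), 0.02)
})

test_that("causal and confounder sets follow the M1/M2 schemes", {
  set.seed(405)
  prof <- synthesize_mean_abundances(200,
    pinned_top = c(0.105, 0.062, 0.054, 0.050, 0.049), sdlog = 1)
  expect_identical(select_causal_taxa(prof, "M2"), 1:5)

  # make the M1 pool comfortable
  prof_flat <- community_profile(rep(1 / 100, 100))
  for (r in 1:5) {
    cs <- select_causal_taxa(prof_flat, "M1")
    expect_length(cs, 20)
    expect_false(which.max(prof_flat$pi_bar) %in% cs)
    expect_true(all(prof_flat$pi_bar[cs] > 0.005))
    expect_false(anyDuplicated(cs) > 0)
  }
  # pool exhaustion is an error
  small <- community_profile(c(rep(0.09, 10), rep(0.1 / 90, 90)))
  expect_error(select_causal_taxa(small, "M1"), "pool")

  set.seed(406)
  causal <- 1:20
  nulls <- 21:100
  conf1 <- select_confounder_taxa(causal, nulls, "M1")
  expect_length(conf1, 20)
  expect_length(intersect(conf1, causal), 10)
  conf2 <- select_confounder_taxa(1:5, 6:50, "M2")
  expect_length(conf2, 5)
  expect_length(intersect(conf2, 1:5), 2)
})

test_that("traits and confounders follow the stated designs", {
  set.seed(407)
  tr <- draw_traits(100, "binary")
  expect_identical(sum(tr$trait), 50L)
  expect_null(tr$confounder)

  tr2 <- draw_traits(10000, "binary", confounded = TRUE)
  expect_lt(abs(mean(tr2$confounder[tr2$trait == 1]) - 0.8), 0.02)
  expect_lt(abs(mean(tr2$confounder[tr2$trait == 0]) - 0.2), 0.02)

  tr3 <- draw_traits(1e5, "continuous")
  # U[-1,1]: mean 0, sd 1/sqrt(3)
  expect_lt(abs(mean(tr3$trait)), 3 / sqrt(3 * 1e5))

  expect_error(draw_traits(99, "binary"), "even")
  expect_error(draw_traits(10, "continuous", confounded = TRUE),
               "binary trait")
})

test_that("spike-in tilt acts on absolute abundances and cancels in ratios", {
  set.seed(408)
  Pi0 <- draw_baseline_abundances(community_profile(rep(0.1, 10)), 6)
  eff0 <- effect_spec(10, causal_set = 1:2, beta = 0)
  expect_identical(true_abundances(Pi0, eff0, rep(1, 6)), Pi0)

  # two-taxon hand case: (0.5, 0.5), beta = ln 2 on taxon 1
  eff <- effect_spec(2, causal_set = 1, beta = log(2))
  Pi <- true_abundances(matrix(0.5, 1, 2), eff, trait = 1)
  expect_equal(as.vector(Pi), c(2 / 3, 1 / 3))

  # ratios between null taxa are invariant to beta
  eff2 <- effect_spec(10, causal_set = 1:2, beta = 1.5)
  tr <- rep(c(0, 1), 3)
  Pi <- true_abundances(Pi0, eff2, tr)
  expect_equal(Pi[, 5] / Pi[, 7], Pi0[, 5] / Pi0[, 7], tolerance = 1e-12)
})

test_that("observed abundances obey the main-effect ratio identity", {
  set.seed(409)
  J <- 8
  Pi0 <- draw_baseline_abundances(community_profile(rep(1 / J, J)), 5)
  eff <- effect_spec(J, causal_set = 1, beta = 0.7)
  tr <- c(0, 1, 0, 1, 0)
  Pi <- true_abundances(Pi0, eff, tr)
  gamma <- rnorm(J)

  # no bias reproduces the truth exactly
  obs0 <- observed_abundances(Pi0, Pi, rep(0, J), NULL, eff, tr)
  expect_identical(obs0$P, Pi)
  expect_identical(obs0$eta, matrix(0, 5, J))

  # with theta = 0, observed/baseline log-ratio differences equal gamma
  # differences for every sample, independent of beta
  obs <- observed_abundances(Pi0, Pi, gamma, NULL, eff, tr)
  for (j in c(2, 5)) {
    for (k in c(3, 8)) {  # null taxa: beta1 is zero there
      lhs <- log(obs$P[, j] / obs$P[, k]) - log(Pi0[, j] / Pi0[, k])
      expect_equal(lhs, rep(gamma[j] - gamma[k], 5), tolerance = 1e-12)
    }
  }

  # two-taxon hand case: gamma = (ln 2, 0)
  eff0 <- effect_spec(2, causal_set = integer(0), beta = 0)
  obs2 <- observed_abundances(matrix(0.5, 1, 2), matrix(0.5, 1, 2),
                              c(log(2), 0), NULL, eff0, trait = 0)
  expect_equal(as.vector(obs2$P), c(2 / 3, 1 / 3))
  expect_equal(obs2$log_norm, log(1.5), tolerance = 1e-12)
})

test_that("vectorized observed abundances match a scalar-loop oracle", {
  set.seed(410)
  for (rep in 1:5) {
    J <- sample(2:4, 1)
    n <- sample(1:3, 1)
    Pi0 <- draw_baseline_abundances(community_profile(rep(1 / J, J)), n)
    gamma <- rnorm(J)
    eps <- draw_epsilon(J, "S-nondiff")
    theta <- build_interaction_matrix(gamma, 1.3, eps)
    causal <- sample(J, 1)
    eff <- effect_spec(J, causal, beta = 0.8,
                       confounder_set = sample(J, 1),
                       beta_confounder = -0.4)
    tr <- rbinom(n, 1, 0.5)
    cf <- rbinom(n, 1, 0.5)
    Pi <- true_abundances(Pi0, eff, tr, cf)
    obs <- observed_abundances(Pi0, Pi, gamma, theta, eff, tr, cf)
    expect_equal(obs$P,
                 oracle_observed(Pi0, Pi, gamma, theta, eff$beta1,
                                 eff$beta2, tr, cf),
                 tolerance = 1e-12)
  }
})

test_that("library sizes are truncated-normal with the closed-form mean", {
  set.seed(411)
  libs <- draw_library_sizes(1e5)
  expect_true(min(libs) >= 2000)
  mu <- 10000
  sigma <- 10000 / 3
  a <- (2000 - mu) / sigma
  trunc_mean <- mu + sigma * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(libs), trunc_mean, tolerance = 0.01)
  expect_gt(mean(libs), mu)  # truncation shifts the mean up

  expect_identical(draw_library_sizes(5, sd = 0), rep(10000, 5))
})

test_that("multinomial counts respect library sizes and probabilities", {
  set.seed(412)
  P <- matrix(c(0.5, 0.3, 0.2, 1, 0, 0), 2, 3, byrow = TRUE)
  counts <- draw_counts(P, c(100, 50))
  expect_equal(rowSums(counts), c(100, 50))
  expect_equal(counts[2, ], c(50L, 0L, 0L))

  # moments over replicate draws
  reps <- t(replicate(10000, draw_counts(P[1, , drop = FALSE], 1000)[1, ]))
  expected <- 1000 * P[1, ]
  sds <- sqrt(1000 * P[1, ] * (1 - P[1, ]))
  expect_true(all(abs(colMeans(reps) - expected) <
                    3.5 * sds / sqrt(10000)))
})

test_that("simulate_replicate is deterministic and closes compositions", {
  cfg <- tiny_config(beta = 1, phi = 1, scenario = "S-diff-half")
  ds1 <- simulate_replicate(cfg, 11)
  ds2 <- simulate_replicate(cfg, 11)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$P, ds2$P)
  expect_identical(ds1$gamma, ds2$gamma)

  for (m in list(ds1$Pi0, ds1$Pi, ds1$P)) {
    expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-10)
  }
  expect_identical(unname(rowSums(ds1$counts)), ds1$library_sizes)
  expect_true(all(ds1$counts[ds1$P == 0] == 0))

  # all distortions off: observed equals baseline rowwise
  cfg0 <- tiny_config(beta = 0, phi = 0, sigma_gamma = 0)
  ds0 <- simulate_replicate(cfg0, 3)
  expect_identical(ds0$P, ds0$Pi0)

  # different seeds give different data
  expect_false(identical(simulate_replicate(cfg, 12)$counts, ds1$counts))
})

test_that("trait fold change on a causal taxon is recoverable", {
  beta <- 0.5
  cfg <- tiny_config(beta = beta)
  ratios <- vapply(1:40, function(r) {
    ds <- simulate_replicate(cfg, r)
    cs <- ds$causal_set[1]
    nt <- setdiff(seq_len(ncol(ds$Pi)), which(ds$beta1 != 0))[1]
    # causal-to-null true-abundance ratio: the tilt normalization cancels
    g1 <- exp(mean(log(ds$Pi[ds$trait == 1, cs] / ds$Pi[ds$trait == 1, nt])))
    g0 <- exp(mean(log(ds$Pi[ds$trait == 0, cs] / ds$Pi[ds$trait == 0, nt])))
    g1 / g0
  }, numeric(1))
  expect_equal(mean(log(ratios)), beta, tolerance = 0.1)
})
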