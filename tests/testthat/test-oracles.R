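test_that("SI fixation-time closed form matches hand enumeration", {
  expect_identical(expected_si_fixation_time(2, 1), 1)
  # N = 3: 1/(1*2) + 1/(2*1)
  expect_identical(expected_si_fixation_time(3, 1), 1)
  # N = 10, beta = 0.5: 2*H9/(0.5*10), frozen from the harmonic sum
  expect_equal(expected_si_fixation_time(10, 0.5), 1.131587301587302,
               tolerance = 1e-12)
  expect_error(expected_si_fixation_time(10, 0), "beta")
})

test_that("SI fixation time decreases in beta and (for N >= 3) in N", {
  betas <- c(0.1, 0.5, 1, 2, 10)
  v <- vapply(betas, function(b) expected_si_fixation_time(20, b), 1)
  expect_true(all(diff(v) < 0))
  Ns <- 3:60
  w <- vapply(Ns, function(n) expected_si_fixation_time(n, 1), 1)
  expect_true(all(diff(w) < 0))
})

test_that("Moran fixation probability matches closed form and linear solve", {
  expect_identical(moran_fixation_probability(20, 0), 1 / 20)
  expect_equal(moran_fixation_probability(2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(moran_fixation_probability(100, 0.1), 0.09091568827109701,
               tolerance = 1e-12)
  expect_error(moran_fixation_probability(10, -1.5), "fitness")

  # independent oracle: first-step absorbing-chain solve for h_1.
  # h_i = p_i h_{i+1} + q_i h_{i-1} + (1 - p_i - q_i) h_i with
  # p_i = r i (N - i) / ((r i + N - i) N), q_i = (N - i) i / ((r i + N - i) N)
  chain_fixation <- function(N, s) {
    r <- 1 + s
    i <- 1:(N - 1)
    p <- r * i * (N - i) / ((r * i + N - i) * N)
    q <- (N - i) * i / ((r * i + N - i) * N)
    A <- matrix(0, N - 1, N - 1)
    b <- numeric(N - 1)
    for (k in i) {
      A[k, k] <- p[k] + q[k]
      if (k > 1) A[k, k - 1] <- -q[k]
      if (k < N - 1) A[k, k + 1] <- -p[k]
    }
    b[N - 1] <- p[N - 1]
    solve(A, b)[1]
  }
  for (N in c(5, 17, 50)) {
    for (s in c(0.02, 0.1, 0.5)) {
      expect_equal(moran_fixation_probability(N, s), chain_fixation(N, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("Moran fixation probability increases strictly in s", {
  ss <- seq(-0.5, 1, by = 0.1)
  v <- vapply(ss, function(s) moran_fixation_probability(30, s), 1)
  expect_true(all(diff(v) > 0))
})

test_that("SIR final size solves z = 1 - exp(-R0 z)", {
  expect_identical(sir_final_size(0.8), 0)
  expect_identical(sir_final_size(1), 0)
  # frozen via 200 fixed-point iterations of z <- 1 - exp(-R0 z)
  expect_equal(sir_final_size(2), 0.7968121300200199, tolerance = 1e-10)
  expect_gt(sir_final_size(20), 0.999)
  # continuity near 1 and monotonicity above it
  expect_lt(sir_final_size(1.001), 0.01)
  r0 <- seq(1.05, 8, by = 0.05)
  v <- vapply(r0, sir_final_size, 1)
  expect_true(all(diff(v) > 0))
  # each value satisfies the relation itself
  expect_true(all(abs(v - (1 - exp(-r0 * v))) < 1e-9))
})

test_that("polymorphism index counts discordant pairs", {
  all_same <- tidyr::expand_grid(entity = 1:4, product_id = 1:2)
  expect_identical(polymorphism_index(all_same, n_entities = 4), 0)
  all_diff <- data.frame(entity = 1:4, product_id = 1:4)
  expect_identical(polymorphism_index(all_diff, n_entities = 4), 1)
  # 2 + 2 split between two genotypes: 4 discordant of 6 pairs
  split22 <- data.frame(entity = c(1, 2, 3, 4), product_id = c(1, 1, 2, 2))
  expect_equal(polymorphism_index(split22, n_entities = 4), 2 / 3)
  expect_error(polymorphism_index(all_same[all_same$entity == 1, ],
                                  n_entities = 1), "2 entities")
})

test_that("polymorphism index is invariant under relabeling", {
  h <- data.frame(entity = c(1, 1, 2, 3, 3, 4), product_id = c(1, 2, 2, 1, 3, 3))
  base <- polymorphism_index(h, n_entities = 5)
  perm_e <- c(3, 5, 1, 2, 4)  # entity relabeling
  h2 <- transform(h, entity = perm_e[entity])
  expect_identical(polymorphism_index(h2, n_entities = 5), base)
  perm_p <- c(2, 3, 1)        # product relabeling
  h3 <- transform(h, product_id = perm_p[product_id])
  expect_identical(polymorphism_index(h3, n_entities = 5), base)
})

test_that("mean fitness floors each entity at zero", {
  # one entity with effects {+0.1, -0.05}, one empty: (1.05 + 1)/2
  cfg <- sim_config(N = 2, lambda_stim = 0, beta = 0, t_max = 1,
                    seed_products = data.frame(effect_size = c(0.1, -0.05),
                                               entity = c(1L, 1L)), seed = 1)
  expect_equal(mean_fitness(sim_run(cfg)), 1.025)
  # effects summing to -1.5 contribute 0, not -0.5
  cfg2 <- sim_config(N = 2, lambda_stim = 0, beta = 0, t_max = 1,
                     seed_products = data.frame(effect_size = -1.5, entity = 1L),
                     seed = 1)
  expect_equal(mean_fitness(sim_run(cfg2)), 0.5)
  expect_identical(mean_fitness(data.frame(fitness = c(1, 1))), 1)
})

test_that("regime classification follows the ratio thresholds", {
  cfg <- sim_config(N = 20, beta = 1, lambda_stim = 0, t_max = 5, seed = 1)
  traj <- data.frame(monomorphic = c(1, 1, 0, 1))
  r0 <- classify_regime(cfg, traj)
  expect_identical(r0$regime_ratio, 0)
  expect_identical(r0$classified_regime, "community_based")  # by convention
  expect_equal(r0$observed_monomorphic_fraction, 0.75)

  tfix <- expected_si_fixation_time(20, 1)
  cfg$lambda_stim <- 0.01 / tfix
  expect_identical(classify_regime(cfg, traj)$classified_regime, "community_based")
  cfg$lambda_stim <- 100 / tfix
  expect_identical(classify_regime(cfg, traj)$classified_regime, "individual_based")
  cfg$lambda_stim <- 1 / tfix
  expect_identical(classify_regime(cfg, traj)$classified_regime, "marginal")
})
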