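make_pair <- function() {
  toy <- make_two_state_toy(n_domains = 2, beads_per_domain = 60, seed = 21)
  q <- toy_q_grid(80)
  list(toy = toy, q = q,
       closed = debye_intensity(toy$closed, q),
       open = debye_intensity(toy$open, q))
}

test_that("optimal scale is exact for rescaled data and matches a grid search", {
  pp <- make_pair()
  calc <- pp$closed
  exp_prof <- saxs_profile(pp$q, calc$intensity,
                           sigma = pmax(calc$intensity * 0.02, 1e-12))
  expect_equal(optimal_scale(exp_prof, calc), 1, tolerance = 1e-12)

  scaled <- saxs_profile(pp$q, calc$intensity / 7,
                         sigma = pmax(calc$intensity * 0.02, 1e-12))
  calc7 <- saxs_profile(pp$q, calc$intensity / 7)
  expect_equal(optimal_scale(exp_prof, calc7), 7, tolerance = 1e-9)

  # brute-force 1-D grid search oracle
  noisy <- simulate_profile(pp$toy$closed, pp$q, noise_level = 0.02, seed = 3)
  c_formula <- optimal_scale(noisy, calc)
  cs <- seq(0.8, 1.2, by = 1e-4)
  ssr <- vapply(cs, function(cc)
    sum(((noisy$intensity - cc * calc$intensity) / noisy$sigma)^2), numeric(1))
  expect_equal(c_formula, cs[which.min(ssr)], tolerance = 1e-3)
})

test_that("chi2 is zero for self, ~1 under consistent noise, and scale-invariant", {
  pp <- make_pair()
  self <- saxs_profile(pp$q, pp$closed$intensity,
                       sigma = pmax(pp$closed$intensity * 0.01, 1e-12))
  expect_lt(chi2(self, pp$closed), 1e-18)

  x2 <- vapply(1:10, function(s) as.numeric(
    chi2(simulate_profile(pp$toy$closed, pp$q, noise_level = 0.01, seed = s),
         pp$closed)), numeric(1))
  expect_gt(mean(x2), 0.8)
  expect_lt(mean(x2), 1.2)

  noisy <- simulate_profile(pp$toy$closed, pp$q, noise_level = 0.01, seed = 5)
  rescaled <- saxs_profile(noisy$q, noisy$intensity * 3.5,
                           sigma = noisy$sigma * 3.5)
  expect_equal(as.numeric(chi2(rescaled, pp$closed)),
               as.numeric(chi2(noisy, pp$closed)), tolerance = 1e-9)
})

test_that("best single state finds the generating model, order-independently", {
  pp <- make_pair()
  obs <- simulate_profile(pp$toy$open, pp$q, noise_level = 0.01, seed = 8)
  pool <- list(closed = pp$closed, open = pp$open)
  bs <- best_single_state(obs, pool)
  expect_equal(bs$member_ids, "open")
  expect_lt(bs$chi2, 2)
  expect_gt(bs$chi2, 0.5)
  bs2 <- best_single_state(obs, rev(pool))
  expect_equal(bs2$member_ids, bs$member_ids)
  expect_equal(bs2$chi2, bs$chi2)
})

test_that("two-state fit recovers known mixtures and degenerate weights", {
  pp <- make_pair()
  pool <- list(closed = pp$closed, open = pp$open)

  # pure state: weight concentrates on the true member
  pure <- saxs_profile(pp$q, pp$open$intensity,
                       sigma = pmax(pp$open$intensity * 0.01, 1e-12))
  ms <- multi_state_fit(pure, pool, k = 2)
  expect_gte(ms$weights[match("open", ms$member_ids)], 0.95)

  # 0.6/0.4 mixture at 1% noise: weights within 0.05
  mix <- simulate_mixture(list(pp$toy$closed, pp$toy$open), c(0.6, 0.4),
                          pp$q, noise_level = 0.01, seed = 12)
  ms2 <- multi_state_fit(mix, pool, k = 2)
  expect_equal(ms2$weights[match("closed", ms2$member_ids)], 0.6,
               tolerance = 0.085)
  expect_equal(sum(ms2$weights), 1, tolerance = 1e-9)
})

test_that("model nesting: chi2 never increases with k or with a larger pool", {
  pp <- make_pair()
  toy3 <- make_two_state_toy(n_domains = 2, beads_per_domain = 60, seed = 99)
  third <- debye_intensity(toy3$open, pp$q)
  obs <- simulate_mixture(list(pp$toy$closed, pp$toy$open), c(0.5, 0.5),
                          pp$q, noise_level = 0.02, seed = 30)
  pool2 <- list(closed = pp$closed, open = pp$open)
  pool3 <- c(pool2, list(other = third))
  expect_lte(multi_state_fit(obs, pool2, k = 2)$chi2,
             best_single_state(obs, pool2)$chi2 + 1e-9)
  expect_lte(best_single_state(obs, pool3)$chi2,
             best_single_state(obs, pool2)$chi2 + 1e-9)
  expect_lte(multi_state_fit(obs, pool3, k = 3)$chi2,
             multi_state_fit(obs, pool3, k = 2)$chi2 * 1.02 + 1e-9)
})

test_that("weight recovery is unbiased over 20 seeds", {
  pp <- make_pair()
  pool <- list(closed = pp$closed, open = pp$open)
  w <- vapply(1:20, function(s) {
    mix <- simulate_mixture(list(pp$toy$closed, pp$toy$open), c(0.6, 0.4),
                            pp$q, noise_level = 0.01, seed = 100 + s)
    ms <- multi_state_fit(mix, pool, k = 2)
    ms$weights[match("closed", ms$member_ids)]
  }, numeric(1))
  expect_lt(abs(mean(w) - 0.6), 0.02)
  expect_lt(sqrt(mean((w - 0.6)^2)), 0.05)
})
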