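test_that("Guinier fit recovers exact parameters from an ideal curve", {
  q <- seq(0.005, 0.05, length.out = 60)
  I <- 2.0 * exp(-q^2 * 30^2 / 3)
  p <- saxs_profile(q, I, sigma = I * 0.01)
  gf <- guinier_fit(p)
  expect_equal(gf$rg, 30.00, tolerance = 1e-6)
  expect_equal(gf$i0, 2.00, tolerance = 1e-6)
  expect_false(gf$curvature_corrected)
  expect_lte(gf$q_window[2] * gf$rg, gf$qrg_limit + 1e-9)
})

test_that("Guinier Rg for a uniform sphere is within 1% of sqrt(3/5) R", {
  p <- sphere_profile(R = 50)
  gf <- guinier_fit(p)
  expect_equal(gf$rg, sqrt(3 / 5) * 50, tolerance = 0.01)
})

test_that("Guinier fit fails loudly on non-Guinier data and short windows", {
  q <- seq(0.005, 0.05, length.out = 30)
  I <- 1 + q  # increasing: rg^2 <= 0
  expect_error(guinier_fit(saxs_profile(q, I, sigma = rep(0.01, 30))),
               "non-Guinier")
  p <- sphere_profile(R = 50, q = seq(0.1, 0.3, length.out = 30))
  expect_error(guinier_fit(p), "fewer than 5|window")
})

test_that("dimensionless Kratky peaks at the Guinier-Kratky point for an ideal globule", {
  # analytic: x^2 exp(-x^2/3) has maximum at x = sqrt(3), value 3/e
  q <- seq(0.002, 0.2, length.out = 400)
  rg <- 30
  I <- 5 * exp(-q^2 * rg^2 / 3)
  p <- saxs_profile(q, I, sigma = I * 0.01)
  gf <- guinier_fit(p)
  kr <- dimensionless_kratky(p, gf)
  expect_identical(unname(kr$reference), c(sqrt(3), 3 * exp(-1)))
  imax <- which.max(kr$y)
  expect_equal(kr$x[imax], sqrt(3), tolerance = 0.01)
  expect_equal(kr$y[imax], 3 / exp(1), tolerance = 0.01)
})

test_that("Kratky transform of a Debye random coil plateaus at 2", {
  q <- seq(0.001, 1.2, length.out = 2000)
  rg <- 30
  u <- (q * rg)^2
  I <- 2 * (exp(-u) + u - 1) / u^2
  p <- saxs_profile(q, I, sigma = pmax(I, 1e-8) * 0.01)
  gf <- guinier_fit(p)
  expect_equal(gf$rg, 30, tolerance = 0.02)
  kr <- dimensionless_kratky(p, gf)
  plateau <- mean(kr$y[kr$x > 25])
  expect_equal(plateau, 2, tolerance = 0.03)
})

test_that("Kratky curve is invariant under intensity rescaling", {
  p <- sphere_profile(R = 40)
  k1 <- dimensionless_kratky(p, guinier_fit(p))
  p2 <- saxs_profile(p$q, p$intensity * 7.3, sigma = p$sigma * 7.3)
  k2 <- dimensionless_kratky(p2, guinier_fit(p2))
  expect_equal(k1$x, k2$x, tolerance = 1e-9)
  expect_equal(k1$y, k2$y, tolerance = 1e-9)
})

test_that("Moore P(r) of a sphere matches the Monte-Carlo pair-distance oracle", {
  p <- sphere_profile(R = 50)
  pr <- moore_pr(p, dmax = 100)
  # sine basis pins both ends to zero
  expect_identical(pr$p[1], 0)
  expect_identical(pr$p[length(pr$p)], 0)

  # MC oracle: histogram of 1e5 uniform point-pair distances in the sphere
  A <- runif_sphere(1e5, 50, seed = 31)
  B <- runif_sphere(1e5, 50, seed = 32)
  d <- sqrt(rowSums((A - B)^2))
  h <- hist(d, breaks = seq(0, 100, length.out = 41), plot = FALSE)
  p_fit <- approx(pr$r, pr$p, xout = h$mids)$y
  p_fit <- p_fit / pracma::trapz(h$mids, p_fit)
  p_mc <- h$density / pracma::trapz(h$mids, h$density)
  expect_lt(sqrt(mean((p_fit - p_mc)^2)) / max(p_mc), 0.02)
})

test_that("P(r)-derived Rg and I(0) agree with Guinier on noise-free data", {
  p <- sphere_profile(R = 50, i0 = 3.7)
  gf <- guinier_fit(p)
  pr <- moore_pr(p, dmax = 100)
  expect_equal(pr$rg_real, gf$rg, tolerance = 0.02)
  expect_equal(pr$i0_real, gf$i0, tolerance = 0.02)
  expect_equal(pr$rg_real, sqrt(3 / 5) * 50, tolerance = 0.01)
})

test_that("Moore fit reproduces the measured curve at chi2 ~ 1 under consistent noise", {
  x2 <- vapply(1:5, function(s) {
    p <- sphere_profile(R = 50, noise_seed = s)
    moore_pr(p, dmax = 100)$chi2_fit
  }, numeric(1))
  expect_gt(mean(x2), 0.7)
  expect_lt(mean(x2), 1.3)
  # and the stored forward transform matches pr_intensity on the same grid
  p <- sphere_profile(R = 50)
  pr <- moore_pr(p, dmax = 100)
  expect_equal(pr_intensity(pr, p$q), pr$fit_intensity, tolerance = 1e-9)
})

test_that("moore_pr flags ill-conditioned systems", {
  p <- sphere_profile(R = 50, q = seq(0.004, 0.05, length.out = 40))
  expect_error(moore_pr(p, dmax = 100, n_terms = 30), "ill-conditioned")
})

test_that("dmax estimation recovers the true maximum dimension", {
  # sphere: true dmax = 2R = 100
  p <- sphere_profile(R = 50, noise_seed = 7)
  ed <- estimate_dmax(p, seq(70, 160, by = 5))
  expect_lt(abs(ed$dmax - 100), 5 + 1e-9)

  # two-bead dumbbell: separation 80, bead radius 10 -> dmax = 100
  A <- runif_sphere(600, 10, seed = 1)
  B <- sweep(runif_sphere(600, 10, seed = 2), 2, c(-80, 0, 0))
  bm <- bead_model(rbind(A, B))
  q <- seq(0.006, 0.25, length.out = 200)
  pd <- simulate_profile(bm, q, noise_level = 0.01, seed = 3)
  ed2 <- estimate_dmax(pd, seq(70, 150, by = 5))
  expect_lt(abs(ed2$dmax - 100), 5 + 1e-9)

  # intensity scale invariance of the selection
  p2 <- saxs_profile(p$q, 2 * p$intensity, sigma = 2 * p$sigma)
  ed3 <- estimate_dmax(p2, seq(70, 160, by = 5))
  expect_equal(ed3$dmax, ed$dmax)
})

test_that("Porod volume of a sphere is within 10% and scale-invariant", {
  p <- sphere_profile(R = 50)
  gf <- guinier_fit(p)
  v <- porod_volume(p, gf, q_cut = 0.25)
  expect_equal(as.numeric(v), 4 / 3 * pi * 50^3, tolerance = 0.10)

  p2 <- saxs_profile(p$q, 5 * p$intensity, sigma = 5 * p$sigma)
  v2 <- porod_volume(p2, guinier_fit(p2), q_cut = 0.25)
  expect_equal(as.numeric(v2), as.numeric(v), tolerance = 1e-6)

  expect_error(porod_volume(p, gf, q_cut = 0.5), "q_cut")
})
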