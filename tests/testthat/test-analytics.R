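test_that("the mean extinction-time approximation evaluates correctly", {
  expect_equal(tau_approx(0), 0)
  expect_equal(tau_approx(0.5), 3 * log(0.5) / (0.25 - 3))
  expect_equal(tau_approx(0.5), 0.7561605606, tolerance = 1e-9)
  # leading order tau ~ fe at small fe
  expect_equal(tau_approx(1e-6), 1e-6, tolerance = 1e-5)
  # divergence toward fe = 1, strictly increasing
  fe <- seq(0, 0.999, by = 0.001)
  expect_true(all(diff(tau_approx(fe)) > 0))
  expect_gt(tau_approx(1 - 1e-9), 3 * log(1e9) / 2 - 1)
  expect_error(tau_approx(1), "fe")
  expect_error(tau_approx(-0.1), "fe")
})

test_that("the no-ecology mutant number evaluates and limits correctly", {
  expect_equal(n_mut_noeco(1e4, 1e-4, 0.25), -log(0.25) / 0.75 - 1)
  expect_equal(n_mut_noeco(1e4, 1e-4, 0.25), 0.848392, tolerance = 1e-6)
  expect_equal(n_mut_noeco(1e4, 1e-4, 0.5), 0.386294, tolerance = 1e-6)
  # fc -> 1 limit is 0 (L'Hopital)
  expect_equal(n_mut_noeco(1e4, 1e-4, 1), 0)
  expect_lt(n_mut_noeco(1e4, 1e-4, 1 - 1e-9), 1e-8)
  # decreasing in the cost
  fc <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(n_mut_noeco(1, 0.5, fc)) < 0))
  expect_error(n_mut_noeco(1e4, 1e-4, 0), "fc")
})

test_that("no-ecology formula matches an independent branching simulation", {
  sizes <- branching_noeco_sizes(2e5, fc = 0.25, seed = 31)
  target <- n_mut_noeco(1e6, 1e-6, 0.25) # N mu = 1, so this is E[fi/(1-fi)]
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - target), 3 * se)
})

test_that("small-mu ecological mutant number and its identities hold", {
  expect_equal(n_mut_eco_small_mu(1e4, 1e-4, 0.99), 3.651687, tolerance = 1e-6)
  expect_warning(n_mut_eco_small_mu(10, 0.01, 0.5), "mu << 1", fixed = TRUE)
  # exact substitution symmetry with the no-ecology formula
  for (fmax in c(0.2, 0.5, 0.75, 0.99)) {
    expect_equal(n_mut_eco_small_mu(1e5, 1e-5, fmax),
                 n_mut_noeco(1e5, 1e-5, 1 - fmax), tolerance = 1e-12)
  }
  # the eco/no-eco ratio is independent of N mu
  r1 <- n_mut_eco_small_mu(1e4, 1e-6, 0.99) / n_mut_noeco(1e4, 1e-6, 0.25)
  r2 <- n_mut_eco_small_mu(1e7, 1e-4, 0.99) / n_mut_noeco(1e7, 1e-4, 0.25)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(n_mut_eco_small_mu(1e4, 1e-4, 1), "fmax")
})

test_that("the Lambert-W mutant number is consistent and monotone", {
  # small-mu consistency
  for (mu in c(1e-8, 1e-7)) {
    a <- n_mut_eco(1e3, mu, 0.25, 0.99, method = "lambert")
    b <- n_mut_eco(1e3, mu, 0.25, 0.99, method = "small_mu")
    expect_lt(abs(a - b) / b, 0.01)
  }
  # automatic switch below mu = 1e-6
  expect_equal(n_mut_eco(1e3, 1e-7, 0.25, 0.99),
               n_mut_eco(1e3, 1e-7, 0.25, 0.99, method = "small_mu"))
  # monotone nondecreasing in mu, positive everywhere on a parameter grid
  for (fc in c(0.1, 0.25, 0.6)) {
    for (fmax in c(0.3, 0.8, 0.99)) {
      mus <- 10^seq(-6, -1, by = 0.5)
      vals <- n_mut_eco(1e3, mus, fc, fmax, method = "lambert")
      expect_true(all(vals > 0))
      expect_true(all(diff(vals) > 0))
    }
  }
  expect_error(n_mut_eco(1e3, 0.5, 0.25, 0.99), "mu")
  expect_error(n_mut_eco(1e3, 1e-3, 0.25, 1), "fmax")
})

test_that("lambert W evaluation agrees with pracma on overlapping range", {
  for (rho in c(-5, 0, 3, 100, 499)) {
    expect_equal(ecoresist:::lambert_w0_log(rho), pracma::lambertWp(exp(rho)),
                 tolerance = 1e-10)
  }
  # large-argument branch: w + log(w) = rho must hold
  for (rho in c(600, 1e4, 1e6)) {
    w <- ecoresist:::lambert_w0_log(rho)
    expect_equal(w + log(w), rho, tolerance = 1e-10)
  }
})

test_that("the stationary density has the stated form and integral", {
  expect_equal(stationary_density(0, 1e-3), 0)
  dee <- effect_dist_uniform(0, 0.99)
  expect_equal(stationary_density(0.5, 1e-3, dee), 1.0101010101e-3,
               tolerance = 1e-9)
  # integral identity with the small-mu mutant number
  for (fmax in c(0.5, 0.9, 0.99)) {
    d <- effect_dist_uniform(0, fmax)
    total <- integrate(function(x) stationary_density(x, 1e-4, d), 0, fmax,
                       rel.tol = 1e-10)$value
    expect_equal(total, n_mut_eco_small_mu(1, 1e-4, fmax), tolerance = 1e-8)
  }
  expect_error(stationary_density(1, 1e-3), "fe")
})

test_that("regimes are classified by the two expected mutant counts", {
  # N mu = 1e-3: neither count reaches 1
  r1 <- classify_regime(1e5, 1e-8, 0.25, 0.99)
  expect_equal(r1$regime, "small-Nmu")
  expect_equal(r1$n_mut_noeco, 0.000848, tolerance = 1e-3)
  expect_equal(r1$n_mut_eco, 0.00365, tolerance = 1e-3)
  # N mu = 0.5: ecology alone pushes the count past 1
  r2 <- classify_regime(5e5, 1e-6, 0.25, 0.99)
  expect_equal(r2$regime, "rare-mutant")
  expect_lt(r2$n_mut_noeco, 1); expect_gt(r2$n_mut_eco, 1)
  expect_equal(r2$n_mut_eco, 1.826, tolerance = 1e-3)
  # N mu = 2: mutants are common regardless
  r3 <- classify_regime(2e6, 1e-6, 0.25, 0.99)
  expect_equal(r3$regime, "many-mutant")
  expect_equal(r3$n_mut_noeco, 1.697, tolerance = 1e-3)
  # ecology can only suppress below 1 when fmax < 1 - fc (flagged)
  expect_warning(r4 <- classify_regime(1e6, 1e-6, 0.05, 0.3), "fmax < 1 - fc",
                 fixed = TRUE)
  expect_equal(r4$regime, "small-Nmu")
})

test_that("the regime map covers all three phases", {
  rm <- regime_map(10^seq(-2, 1, by = 0.25), fc = c(0.1, 0.25, 0.5), fmax = 0.99)
  expect_setequal(unique(rm$regime), c("small-Nmu", "rare-mutant", "many-mutant"))
  # at fixed fc the regime boundaries are monotone in N mu
  one_fc <- rm[rm$fc == 0.25, ]
  expect_true(all(diff(as.integer(factor(
    one_fc$regime, levels = c("small-Nmu", "rare-mutant", "many-mutant")
  ))) >= 0))
})

test_that("coexistence fixed points exist exactly when fe exceeds 1", {
  expect_equal(coexistence_fixed_point(fitness_profile(0.8, 1.1)), 2 / 3)
  # different profiles, same equilibrium: cost and fe combine
  expect_equal(coexistence_fixed_point(fitness_profile(0.9, 1.05)), 2 / 3)
  expect_true(is.na(coexistence_fixed_point(fitness_profile(0.75, 0.99))))
  expect_true(is.na(coexistence_fixed_point(fitness_profile(0.5, 1))))
  # the fixed point solves mutant_fitness = 1 and lies in (0, 1)
  p <- fitness_profile(0.3, 1.4)
  xs <- coexistence_fixed_point(p)
  expect_gt(xs, 0); expect_lt(xs, 1)
  expect_equal(mutant_fitness(p, xs), 1)
})
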