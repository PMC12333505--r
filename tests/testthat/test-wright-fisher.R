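test_that("population size is conserved and the seed fixes the run", {
  p <- wf_params(500, 1e-3, 400, fc = 0.25, dee = effect_dist_uniform(0, 0.99))
  r1 <- wf_run(p, seed = 3, totals_every = 1L)
  expect_true(all(r1$totals$ancestor + r1$totals$mutants == 500))
  expect_equal(r1$final_ancestor + sum(r1$lineages$censored * 0) +
                 (500 - r1$final_ancestor), 500)
  r2 <- wf_run(p, seed = 3, totals_every = 1L)
  expect_identical(r1$lineages, r2$lineages)
  expect_identical(r1$totals, r2$totals)
  r3 <- wf_run(p, seed = 4, totals_every = 1L)
  expect_false(identical(r1$lineages, r3$lineages))
})

test_that("without mutation an all-ancestor population never changes", {
  p <- wf_params(200, 0, 100)
  r <- wf_run(p, seed = 1, totals_every = 1L)
  expect_equal(r$n_lineages_total, 0)
  expect_true(all(r$totals$mutants == 0))
  expect_true(all(r$totals$ancestor == 200))
})

test_that("every emerged lineage is recorded, including zero-survivors", {
  p <- wf_params(1000, 1e-3, 500, fc = 0.25, dee = effect_dist_uniform(0, 0.99))
  r <- wf_run(p, seed = 12)
  lin <- r$lineages
  expect_equal(nrow(lin), r$n_lineages_total)
  expect_equal(sum(lin$censored), r$n_censored)
  # most freshly emerged deleterious mutants die in their first selection step
  expect_gt(sum(lin$tau == 0, na.rm = TRUE), 0.3 * nrow(lin))
  expect_true(all(lin$tau[!lin$censored] >= 0))
  # expected lineage count ~ N mu generations (ancestor fraction near 1)
  expected <- 1000 * 1e-3 * 500
  expect_lt(abs(r$n_lineages_total - expected), 5 * sqrt(expected))
})

test_that("a neutral single mutant fixes with probability 1/N", {
  fx <- wf_fixation_prob(100, fitness_profile(1 - 1e-12, 1), s0 = 1,
                         reps = 3e4, seed = 5)
  expect_equal(fx$n_censored, 0)
  expect_lt(abs(fx$p_fix - 0.01), 3 * sqrt(0.01 * 0.99 / 3e4))
})

test_that("binned extinction times follow the closed-form curve", {
  p <- wf_params(1e4, 1e-4, 8e4, fc = 0, dee = effect_dist_uniform(0, 1))
  r <- wf_run(p, seed = 21, totals_every = 0L)
  cur <- wf_extinction_curve(r, breaks = seq(0, 1, by = 0.01))
  # top bin [0.99, 1): mean tau within 3 SE of the bin-averaged approximation
  top <- cur[abs(cur$bin_lo - 0.99) < 1e-9, ]
  expect_gt(top$n, 100)
  expect_lt(abs(top$mean_tau - tau_bin_average(0.99, 1)), 3 * top$se_tau)
  # smallest-fe bin: tau is approximately fe itself (tiny)
  bottom <- cur[1, ]
  expect_lt(bottom$mean_tau, 0.05)
  # monotone nondecreasing up to sampling noise: isotonic-regression residuals
  ok <- is.finite(cur$mean_tau) & is.finite(cur$se_tau) & cur$se_tau > 0
  iso <- isoreg(cur$fe_mid[ok], cur$mean_tau[ok])
  z2 <- ((cur$mean_tau[ok] - iso$yf) / cur$se_tau[ok])^2
  expect_lt(mean(z2), 2)
})

test_that("the extinction-time curve depends only on ecological fitness", {
  # vary N, fc and mu jointly; curves must collapse within sampling error
  configs <- list(
    list(N = 1e3, mu = 1e-4, fc = 0, gens = 3e5),
    list(N = 1e4, mu = 1e-4, fc = 0.5, gens = 4e4),
    list(N = 1e3, mu = 1e-3, fc = 0.25, gens = 4e4)
  )
  breaks <- seq(0, 0.9, length.out = 11)
  curves <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    p <- wf_params(cf$N, cf$mu, cf$gens, fc = cf$fc,
                   dee = effect_dist_uniform(0, 1))
    wf_extinction_curve(wf_run(p, seed = 300 + i, totals_every = 0L), breaks)
  })
  for (i in 2:3) {
    dz <- abs(curves[[1]]$mean_tau - curves[[i]]$mean_tau) /
      sqrt(curves[[1]]$se_tau^2 + curves[[i]]$se_tau^2)
    expect_lt(max(dz, na.rm = TRUE), 4)
  }
})

test_that("stationary fe histogram matches the mutation-selection density", {
  # mu = 1e-4 sits squarely in the mu << 1 domain of the closed form;
  # chi-square over replicate means on bins with fe <= 0.95 at alpha 0.01
  mu <- 1e-4
  p <- wf_params(1e3, mu, 1.2e5, fc = 0.25, dee = effect_dist_uniform(0, 0.99),
                 burn_in = 2e4, replicates = 24)
  reps <- wf_replicates(p, seed = 88)
  h <- reps$fe_hist
  sel <- h$bin_hi <= 0.95 & h$se_count > 0 & h$mean_count > 0
  expected <- stationary_density(h$mid[sel], mu, p$dee) * 1e3 *
    (h$bin_hi[sel] - h$bin_lo[sel])
  expected <- expected * sum(h$mean_count[sel]) / sum(expected)
  chi2 <- sum(((h$mean_count[sel] - expected) / h$se_count[sel])^2)
  df <- sum(sel) - 1
  expect_gt(pchisq(chi2, df, lower.tail = FALSE), 0.01)
})

test_that("a gaussian DEE still leaves high-fe mutants dominant", {
  dee <- effect_dist_gaussian(0.5, 0.15, 0, 0.99)
  p <- wf_params(1e3, 1e-3, 7e4, fc = 0.25, dee = dee,
                 burn_in = 1e4, replicates = 8)
  reps <- wf_replicates(p, seed = 99)
  h <- reps$fe_hist
  # under the gaussian DEE mutants with fe > 0.8 are rare at birth
  # (~2% of draws) yet dominate the stationary population far beyond
  # that share: the survival factor fe/(1-fe) outweighs their rarity
  birth_share <- integrate(function(x) dist_density(dee, x), 0.8, 0.99)$value
  stat_share <- sum(h$mean_count[h$mid > 0.8]) / sum(h$mean_count)
  expect_lt(birth_share, 0.05)
  expect_gt(stat_share, 3 * birth_share)
  # and the per-mutant enrichment grows with fe
  enrich <- h$mean_count / dist_density(dee, h$mid)
  ok <- is.finite(enrich) & h$mean_count > 0 & h$mid < 0.98
  expect_gt(cor(h$mid[ok], enrich[ok], method = "spearman"), 0.8)
})

test_that("mutants with fe above 1 persist at intermediate frequency", {
  p <- wf_params(2e3, 1e-4, 4e3, fc = 0, dee = effect_dist_uniform(0, 1.10),
                 burn_in = 1e3)
  r <- wf_run(p, seed = 44, totals_every = 1L)
  # the mutant pool reaches a sustained intermediate share without sweeping
  late <- r$totals[r$totals$generation > 1e3, ]
  expect_gt(mean(late$mutants) / 2e3, 0.05)
  expect_true(all(late$ancestor > 0))
  # long-lived lineages are the fe > 1 ones
  lin <- r$lineages
  long_lived <- lin$censored | (!is.na(lin$tau) & lin$tau > 500)
  expect_gt(sum(long_lived & lin$fe > 1), 0)
  expect_gt(mean(lin$fe[long_lived]), 1)
})

test_that("stationarity diagnostics and histogram normalisation behave", {
  p <- wf_params(1e3, 1e-3, 5e4, fc = 0.25, dee = effect_dist_uniform(0, 0.99),
                 burn_in = 1e4)
  r <- wf_run(p, seed = 10, totals_every = 1L)
  h <- wf_stationary_fe(r)
  expect_true(isTRUE(attr(h, "stationary_ok")))
  expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1, tolerance = 1e-12)
  expect_equal(sum(h$mean_count), attr(h, "mean_mutants"), tolerance = 0.15)
})

test_that("by-lineage weighting counts each emerged lineage once", {
  p <- wf_params(1e3, 1e-3, 3e4, fc = 0.25, dee = effect_dist_uniform(0, 0.99),
                 burn_in = 5e3)
  r <- wf_run(p, seed = 55)
  by_lin <- wf_stationary_fe(r, weight = "lineages")
  # emergence is uniform over fe, so lineage counts are flat across bins
  # (unlike the individual-weighted histogram, which rises steeply)
  counts <- by_lin$mean_count * r$stationary$n_post
  expect_equal(sum(counts),
               sum(r$lineages$birth_generation > 5e3 & r$lineages$fe < 0.99))
  expect_lt(cor(by_lin$mid, counts), 0.3)
  by_ind <- wf_stationary_fe(r)
  expect_gt(cor(by_ind$mid, by_ind$mean_count, method = "spearman"), 0.6)
})

test_that("child seeds are stable when replicates are added", {
  expect_identical(child_seeds(42, 5), child_seeds(42, 8)[1:5])
  expect_true(all(child_seeds(2^30, 100) < 2^31))
  expect_true(all(child_seeds(1, 100) >= 0))
})
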