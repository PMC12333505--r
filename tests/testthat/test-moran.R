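test_that("expected payoffs follow the frequency-dependent game", {
  spec <- moran_spec(100, fc = 0.25, fe = 1.0)
  # a lone mutant only meets ancestors, so its payoff is fe
  expect_equal(moran_payoffs(spec, 1)$P_R, 1.0)
  # direct evaluation near fixation
  expect_equal(moran_payoffs(spec, 99)$P_R, (98 / 99) * 0.75 + (1 / 99) * 1.0)
  expect_equal(moran_payoffs(spec, 50)$P_A, 1)
  # neutral payoff matrix
  neutral <- moran_spec(100, fc = 0, fe = 1)
  expect_equal(moran_payoffs(neutral, c(1, 17, 99))$P_R, c(1, 1, 1))
  expect_error(moran_payoffs(spec, 0), "1, ..., N - 1", fixed = TRUE)
  expect_error(moran_payoffs(spec, 100), "1, ..., N - 1", fixed = TRUE)
})

test_that("transition probabilities are fitness-weighted and conserve mass", {
  neutral <- moran_spec(100, fc = 0, fe = 1)
  tr <- moran_transitions(neutral)
  s <- tr$s
  expect_equal(tr$birth, s * (100 - s) / 100^2)
  expect_equal(tr$death, s * (100 - s) / 100^2)
  # locally neutral first step when P_R(1) = 1: b_1 = d_1 = (1/100)(99/100)
  pos <- moran_transitions(moran_spec(100, fc = 0.25, fe = 1.0), 1)
  expect_equal(pos$birth, 0.0099)
  expect_equal(pos$death, 0.0099)
  # absorbing states
  ab <- moran_transitions(moran_spec(100, fc = 0.25, fe = 0.75), c(0, 100))
  expect_equal(ab$birth, c(0, 0))
  expect_equal(ab$death, c(0, 0))
  expect_equal(ab$stay, c(1, 1))
})

test_that("absorption probabilities reduce to s0/N in the neutral case", {
  for (s0 in c(1, 10, 37, 99)) {
    ab <- moran_absorption(moran_spec(100, fc = 0, fe = 1, s0 = s0))
    expect_equal(ab$p_fix, s0 / 100, tolerance = 1e-12)
    expect_equal(ab$p_ext + ab$p_fix, 1, tolerance = 1e-12)
  }
})

test_that("absorption probabilities match the dense first-step oracle", {
  # deleterious mutant: fixation is astronomically rare but well-defined
  ab <- moran_absorption(moran_spec(100, fc = 0.25, fe = 0.75, s0 = 1))
  expect_lt(abs(ab$p_fix - 1.065576111787e-13), 1e-15)
  # grid cross-check against the dense solve
  for (case in list(c(40, 0.25, 0.9, 1), c(40, 0.1, 1.05, 3), c(80, 0.4, 0.6, 2))) {
    spec <- moran_spec(case[1], case[2], case[3], case[4])
    orc <- moran_dense_oracle(case[1], case[2], case[3], case[4])
    ab <- moran_absorption(spec)
    expect_equal(ab$p_fix, orc$p_fix, tolerance = 1e-8)
    expect_equal(ab$p_ext, orc$p_ext, tolerance = 1e-8)
  }
  # fe = 0 blocks a lone mutant's reproduction entirely
  ab0 <- moran_absorption(moran_spec(50, 0.25, 0, s0 = 1))
  expect_equal(ab0$p_fix, 0)
})

test_that("extinction-time distribution matches the dense linear-algebra oracle", {
  for (case in list(c(60, 0.25, 0.75, 1), c(60, 0.25, 1.0, 1),
                    c(120, 0.1, 0.5, 4), c(200, 0.25, 0.9, 1))) {
    spec <- moran_spec(case[1], case[2], case[3], case[4])
    ext <- moran_extinction(spec)
    orc <- moran_dense_oracle(case[1], case[2], case[3], case[4])
    # conditional pmf normalises
    expect_lt(abs(sum(ext$pmf$probability) - 1), 1e-9)
    # exact-solve mean against the oracle
    expect_equal(ext$mean_steps, orc$cond_mean_ext, tolerance = 1e-8)
    # phase-type recursion mean agrees with the exact solve
    expect_equal(ext$mean_steps_pmf, ext$mean_steps, tolerance = 1e-6)
    expect_false(ext$truncated)
  }
})

test_that("pinned extinction-time values for the reference chain hold", {
  ext <- moran_extinction(moran_spec(100, fc = 0.25, fe = 0.75, s0 = 1))
  expect_equal(ext$mean_steps, 187.9686730547, tolerance = 1e-9)
  expect_equal(ext$mean_generations, ext$mean_steps / 100)
})

test_that("positive ecological interactions prolong extinction and add right skew", {
  neutral <- moran_extinction(moran_spec(100, fc = 0.25, fe = 0.75, s0 = 1))
  positive <- moran_extinction(moran_spec(100, fc = 0.25, fe = 1.0, s0 = 1))
  expect_gt(positive$mean_steps, neutral$mean_steps)
  expect_gt(ecoresist:::moran_skewness(positive),
            ecoresist:::moran_skewness(neutral))
  # negative interaction (fe < 1 - fc) shifts extinction earlier
  negative <- moran_extinction(moran_spec(100, fc = 0.25, fe = 0.5, s0 = 1))
  expect_lt(negative$mean_steps, neutral$mean_steps)
})

test_that("conditional mean extinction time is nondecreasing in fe", {
  means <- vapply(seq(0.1, 1.1, by = 0.2), function(fe) {
    moran_extinction(moran_spec(80, fc = 0.25, fe = fe, s0 = 1))$mean_steps
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("truncated horizons are flagged rather than silently accepted", {
  spec <- moran_spec(100, fc = 0.25, fe = 1.0, s0 = 1)
  expect_warning(ext <- moran_extinction(spec, horizon = 50), "captures only")
  expect_true(ext$truncated)
  expect_lt(ext$captured, 0.999)
})
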