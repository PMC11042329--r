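test_that("noiseless baseline data invert to the generating parameters", {
  d <- make_lop_data(60, beta = 10^-3.5, chi = 0.9, lmin = 300, lmax = 6000)
  f <- fitBaseline(d)
  expect_equal(f@beta, 10^-3.5, tolerance = 1e-4)
  expect_equal(f@chi, 0.9, tolerance = 1e-4)
  expect_lt(f@rss, 1e-12)
  expect_identical(f@nParams, 2L)
})

test_that("baseline predictions decrease with length for chi > 0", {
  d <- make_lop_data(50, noise_sd = 0.1, seed = 2)
  f <- fitBaseline(d)
  L <- seq(250, 9000, by = 250)
  pred <- 1 - f@beta * L^f@chi
  expect_true(all(diff(pred) < 0))
})

test_that("chi is recovered within 0.1 under noise across seeds", {
  errs <- vapply(1:20, function(i) {
    d <- make_lop_data(100, beta = 10^-3.5, chi = 0.9, noise_sd = 0.2,
                       seed = i, lmin = 300, lmax = 6000)
    abs(fitBaseline(d)@chi - 0.9)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("stress terms vanish when treated equals control", {
  d <- make_lop_data(100, noise_sd = 0.1, seed = 3)
  f <- fitStress(d, d)
  expect_lt(abs(f@mu), 0.02)
  expect_lt(abs(f@nu) * 8000, 0.02)
})

test_that("a pure per-molecule effect is attributed to mu, not nu", {
  recs <- vapply(1:10, function(i) {
    p <- make_pair(mu = 1, nu = 0, noise_sd = 0.2, seed = 100 + i)
    f <- fitStress(p$ctrl, p$trt)
    c(f@mu, f@nu)
  }, numeric(2))
  expect_lt(median(abs(recs[1, ] - 1)), 0.1)           # mu within 10%
  expect_lt(median(abs(recs[2, ]) * 2000), 0.05 * 1)   # nu*L_median negligible
})

test_that("the joint fit never has larger RSS than its reduced fits", {
  p <- make_pair(mu = 0.6, nu = 2e-5, noise_sd = 0.2, seed = 17)
  full <- fitStress(p$ctrl, p$trt)
  for (t in c("mu", "nu")) {
    red <- fitStress(p$ctrl, p$trt, terms = t)
    expect_lte(full@rss, red@rss + 1e-8)
  }
})

test_that("the nested F-test handles its degenerate cases", {
  p <- make_pair(seed = 5)
  full <- fitStress(p$ctrl, p$trt)
  # reduced = full: F = 0, p = 1
  same <- nestedFTest(full, full)
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  # an optimizer failure leaves the full fit with larger RSS: warning, F = 0
  red <- fitStress(p$ctrl, p$trt, terms = "nu")
  broken_full <- full
  broken_full@rss <- red@rss + 1
  expect_warning(bad <- nestedFTest(broken_full, red), "RSS")
  expect_equal(bad$f_statistic, 0)
  # a genuine per-molecule effect is sharply detected against the nu-only model
  ft <- nestedFTest(full, red)
  expect_identical(ft$df1, 1L)
  expect_identical(ft$df2, full@nPoints - 4L)
  expect_lt(ft$p_value, 1e-6)
})

test_that("effective size ratios follow the mass-power law", {
  expect_equal(effectiveSizeRatio(0.8, 0.8, chi = 0.9), 1)
  expect_equal(effectiveSizeRatio(0.9, 0.7, chi = 1), 3, tolerance = 1e-12)
  # dissolution gives k < 1, not an error
  expect_lt(effectiveSizeRatio(0.7, 0.9, chi = 1), 1)
  # scale-free: moving both pSups along the model-consistent trajectory
  # (multiplying both pelleted fractions by the same factor) preserves k
  k1 <- effectiveSizeRatio(0.9, 0.6, chi = 0.8)
  expect_equal(effectiveSizeRatio(1 - 0.05, 1 - 0.2, chi = 0.8),
               effectiveSizeRatio(1 - 0.1, 1 - 0.4, chi = 0.8),
               tolerance = 1e-12)
  expect_gt(k1, 1)
  expect_error(effectiveSizeRatio(1, 0.5, chi = 1), "strictly")
})

test_that("mRNP mass arithmetic reproduces the polysome-scale worked example", {
  expect_equal(mrnpMass(0, 0), 0)
  # five ribosomes on a 1.8 kb transcript: ~17 MDa
  expect_equal(mrnpMass(5, 1800), 17.04, tolerance = 1e-12)
  expect_lt(abs(mrnpMass(5, 1800) - 17), 0.1)
  # the bare 1.8 kb mRNA: ~0.54 MDa
  expect_equal(mrnpMass(0, 1800), 0.54, tolerance = 1e-12)
})

test_that("protein spacing arithmetic behaves linearly", {
  pars <- massModelParams()
  # target of exactly mRNA + one protein: spacing = L
  L <- 1200
  target <- mrnpMass(0, L) + pars$protein_mass_kda / 1000
  expect_equal(proteinSpacing(target, L), L, tolerance = 1e-9)
  # reaching 17 MDa on 1800 nt needs a 65 kDa protein every ~7 nt
  expect_equal(round(proteinSpacing(17, 1800)), 7)
  # doubling the protein mass doubles the spacing
  heavy <- massModelParams(protein_mass_kda = 130)
  expect_equal(proteinSpacing(17, 1800, heavy),
               2 * proteinSpacing(17, 1800), tolerance = 1e-12)
  expect_error(proteinSpacing(0.1, 1800), "exceed")
})

test_that("fixed-baseline stress fitting reuses the control fit", {
  p <- make_pair(mu = 1, noise_sd = 0.1, seed = 23)
  base <- fitBaseline(p$ctrl)
  f <- fitStress(p$ctrl, p$trt, share_baseline = FALSE, baseline = base)
  expect_equal(f@beta, base@beta)
  expect_equal(f@chi, base@chi)
  expect_lt(abs(f@mu - 1), 0.15)
})
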