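test_that("pSup arithmetic matches hand calculations", {
  fc <- FractionCounts(total = c(110, 150), sup = c(100, 50),
                       pellet = c(10, 100), transcript_id = c("a", "b"))
  sym <- new("MixingRatios", alphaS = 1, alphaP = 1, dispersion = 100,
             nUsed = 2L, method = "MAP", diagnostics = list())
  expect_equal(computePSup(fc, sym)$psup, c(100 / 110, 50 / 150),
               tolerance = 1e-12)

  asym <- new("MixingRatios", alphaS = 2, alphaP = 0.5, dispersion = 100,
              nUsed = 2L, method = "MAP", diagnostics = list())
  # (alphaS=2, alphaP=0.5, S=50, P=100) -> 100/150
  expect_equal(computePSup(fc, asym)$psup[2], 100 / 150, tolerance = 1e-12)
})

test_that("rows with empty sup+pellet are dropped with a message", {
  fc <- FractionCounts(total = c(50, 60), sup = c(40, 0),
                       pellet = c(8, 0), transcript_id = c("a", "b"))
  r <- new("MixingRatios", alphaS = 1, alphaP = 1, dispersion = 100,
           nUsed = 2L, method = "MAP", diagnostics = list())
  expect_message(out <- computePSup(fc, r), "dropped")
  expect_identical(out$transcript_id, "a")
})

test_that("pSup is scale-identifiable in the mixing ratios", {
  fc <- FractionCounts(total = c(110, 150), sup = c(100, 50),
                       pellet = c(10, 100), transcript_id = c("a", "b"))
  r1 <- new("MixingRatios", alphaS = 2, alphaP = 0.5, dispersion = 100,
            nUsed = 2L, method = "MAP", diagnostics = list())
  # scale all S by c while dividing alphaS by c: pSup unchanged
  cc <- 3.7
  fc2 <- FractionCounts(total = c(110, 150), sup = c(100, 50) * cc,
                        pellet = c(10, 100), transcript_id = c("a", "b"))
  r2 <- new("MixingRatios", alphaS = 2 / cc, alphaP = 0.5, dispersion = 100,
            nUsed = 2L, method = "MAP", diagnostics = list())
  expect_equal(computePSup(fc, r1)$psup, computePSup(fc2, r2)$psup,
               tolerance = 1e-12)
})

test_that("identity mixing ratios are recovered on undistorted data", {
  catal <- makeCatalog(5000, seed = 21)
  ps <- simulateTruePSup(catal, conditionSpec("mock", gene_noise_sd = 0.35),
                         seed = 22)
  fc <- simulateFractionCounts(catal, ps, alpha_s = 1, alpha_p = 1,
                               dispersion = 100, depth = 1e7, seed = 23)
  r <- estimateMixingRatios(fc)
  expect_gt(alphaS(r), 0.9); expect_lt(alphaS(r), 1.1)
  expect_gt(alphaP(r), 0.9); expect_lt(alphaP(r), 1.1)
  expect_true(r@diagnostics$converged)
})

test_that("the count filter is enforced before inference", {
  fc <- FractionCounts(total = rep(10, 100), sup = rep(10, 100),
                       pellet = rep(10, 100),
                       transcript_id = sprintf("t%d", 1:100))
  expect_error(estimateMixingRatios(fc), "exceed")
})

test_that("MAP and MCMC point estimates agree on well-conditioned data", {
  catal <- makeCatalog(800, seed = 31)
  ps <- simulateTruePSup(catal, conditionSpec("mock", gene_noise_sd = 0.35),
                         seed = 32)
  fc <- simulateFractionCounts(catal, ps, alpha_s = 1.5, alpha_p = 0.7,
                               dispersion = 100, depth = 5e6, seed = 33)
  rmap <- estimateMixingRatios(fc)
  rmc <- estimateMixingRatios(fc, method = "MCMC", seed = 34,
                              n_chains = 4, n_warmup = 400, n_keep = 600)
  ratio_map <- alphaS(rmap) / alphaP(rmap)
  ratio_mc <- alphaS(rmc) / alphaP(rmc)
  expect_lt(abs(ratio_map - ratio_mc) / ratio_map, 0.02)
  expect_true(all(rmc@diagnostics$rhat < 1.1))
})

test_that("the fixed-covariate regression backend runs and is attenuated", {
  catal <- makeCatalog(2000, seed = 41)
  ps <- simulateTruePSup(catal, conditionSpec("mock", gene_noise_sd = 0.35),
                         seed = 42)
  fc <- simulateFractionCounts(catal, ps, alpha_s = 2, alpha_p = 0.5,
                               dispersion = 100, depth = 5e6, seed = 43)
  r_eiv <- estimateMixingRatios(fc)
  r_reg <- estimateMixingRatios(fc, model = "regression")
  # regression conditions on noisy covariates: ratio biased toward smaller
  # values relative to the errors-in-variables fit
  expect_lt(alphaS(r_reg) / alphaP(r_reg), alphaS(r_eiv) / alphaP(r_eiv))
})

test_that("delta-delta-Cq pSup matches hand evaluation", {
  tab <- data.frame(target = c("x", "x", "spike", "spike"),
                    fraction = c("sup", "pellet", "sup", "pellet"),
                    cq = c(25, 25, 20, 20))
  # equal Cq after correction factor 1 -> 0.5
  expect_equal(qpcrPSup(tab, pellet_concentration_factor = 1,
                        spike_amount_ratio = 1)$psup, 0.5)
  # net correction factor 10 on the pellet -> 1/11
  expect_equal(qpcrPSup(tab, pellet_concentration_factor = 1,
                        spike_amount_ratio = 10)$psup, 1 / 11,
               tolerance = 1e-12)
  # protocol defaults (10 and 10) cancel
  expect_equal(qpcrPSup(tab)$psup, 0.5)
  expect_error(qpcrPSup(tab[tab$fraction == "sup", ]), "spike")
})
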