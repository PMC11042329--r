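test_that("catalog lengths respect bounds and the target median", {
  cat1 <- makeCatalog(1, seed = 1)
  expect_gte(cat1$length_nt, 200)
  expect_lte(cat1$length_nt, 15000)

  cat5k <- makeCatalog(5000, length_log_mean = log(1300),
                       length_log_sd = 0.6, seed = 7)
  expect_lt(abs(median(cat5k$length_nt) - 1300) / 1300, 0.2)
  expect_true(all(cat5k$length_nt >= 200 & cat5k$length_nt <= 15000))
  expect_true(all(cat5k$utr5_length_nt < cat5k$length_nt))
  # abundances on a fixed library scale
  expect_equal(sum(cat5k$base_abundance), 1e6)

  # the clip ceiling accommodates the heaviest unstressed yeast mRNP (12.4 kb)
  big <- makeCatalog(2000, length_log_mean = log(9000), length_log_sd = 0.5,
                     seed = 3)
  expect_gt(max(big$length_nt), 12400)
  expect_lte(max(big$length_nt), 15000)
})

test_that("catalog generation is deterministic and validates inputs", {
  expect_identical(makeCatalog(50, seed = 9), makeCatalog(50, seed = 9))
  expect_error(makeCatalog(10, regulon_fractions = c(a = 0.7, b = 0.6)),
               "sum")
  expect_error(makeCatalog(0), ">= 1")
})

test_that("true pSup follows the mass/condensation model exactly", {
  catal <- makeCatalog(200, seed = 2)
  ctrl <- conditionSpec("mock", gene_noise_sd = 0)
  ps <- simulateTruePSup(catal, ctrl, beta = 2e-4, chi = 0.8, seed = 1)
  expect_equal(unname(ps), 1 - 2e-4 * catal$length_nt^0.8, tolerance = 1e-12)

  # scalar oracle: beta=1e-3, chi=0.8, mu=0.5, L=1000
  cat1 <- data.frame(transcript_id = "x", length_nt = 1000,
                     utr5_length_nt = 50, regulon = "none",
                     base_abundance = 1)
  st <- conditionSpec("s", mu = 0.5, gene_noise_sd = 0)
  ps1 <- simulateTruePSup(cat1, st, beta = 1e-3, chi = 0.8, seed = 1)
  expect_equal(unname(ps1), 1 - 1e-3 * 1000^0.8 * exp(0.5), tolerance = 1e-12)

  # monotone non-increasing in length when noise-free and nu >= 0
  stn <- conditionSpec("s2", mu = 0.3, nu = 1e-5, gene_noise_sd = 0)
  ps2 <- simulateTruePSup(catal, stn, seed = 1)
  ord <- order(catal$length_nt)
  expect_true(all(diff(ps2[ord]) <= 1e-12))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("pelleted fraction >= 1 errors without clipping", {
  catal <- makeCatalog(50, length_log_mean = log(9000), seed = 5)
  hot <- conditionSpec("hot", mu = 3, gene_noise_sd = 0)
  expect_error(simulateTruePSup(catal, hot, clip = FALSE), "clip")
  ps <- simulateTruePSup(catal, hot, clip = TRUE)
  expect_true(all(ps > 0 & ps < 1))
})

test_that("fraction counts are reproducible and respect conservation of mass", {
  catal <- makeCatalog(5000, seed = 4)
  ps <- simulateTruePSup(catal, conditionSpec("mock", gene_noise_sd = 0.35),
                         seed = 5)
  fc1 <- simulateFractionCounts(catal, ps, alpha_s = 1.4, alpha_p = 0.6,
                                depth = 1e7, seed = 6)
  fc2 <- simulateFractionCounts(catal, ps, alpha_s = 1.4, alpha_p = 0.6,
                                depth = 1e7, seed = 6)
  expect_identical(assay(fc1, "counts"), assay(fc2, "counts"))

  # regression of T on alphaS*S + alphaP*P with the true alphas: slope ~ 1
  x <- 1.4 * supCounts(fc1) + 0.6 * pelletCounts(fc1)
  slope <- sum(x * totalCounts(fc1)) / sum(x^2)
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("Poisson-limit fraction split converges to true pSup", {
  catal <- makeCatalog(50, seed = 8)
  ps <- simulateTruePSup(catal, conditionSpec("mock", gene_noise_sd = 0),
                         seed = 8)
  acc <- matrix(0, 2, 50)
  for (r in 1:200) {
    fc <- simulateFractionCounts(catal, ps, dispersion = Inf, depth = 2e5,
                                 seed = 1000 + r)
    acc[1, ] <- acc[1, ] + supCounts(fc)
    acc[2, ] <- acc[2, ] + pelletCounts(fc)
  }
  est <- acc[1, ] / (acc[1, ] + acc[2, ])
  expect_lt(max(abs(est - ps)), 0.01)
})

test_that("polysome simulation encodes occupancy and recoverable distortions", {
  catal <- makeCatalog(400, seed = 9)
  occ <- setNames(runif(400), catal$transcript_id)
  occ[1] <- 0  # transcript with no ribosome binding
  tab <- simulatePolysome(catal, occ, spike_set_size = 20, seed = 9)
  expect_identical(tab, simulatePolysome(catal, occ, spike_set_size = 20,
                                         seed = 9))
  bound1 <- tab$tpm[tab$transcript_id == catal$transcript_id[1] &
                      tab$fraction == "bound"]
  free1 <- tab$tpm[tab$transcript_id == catal$transcript_id[1] &
                     tab$fraction == "free"]
  expect_lt(bound1 / free1, 0.01)   # only in Free, up to noise

  # per-fraction spike medians reproduce the injected distortion within 5%
  dist <- attr(tab, "distortion")
  sp <- tab[tab$is_spike, ]
  med <- tapply(sp$tpm, sp$fraction, median)
  for (f in c("free", "bound"))
    expect_lt(abs((med[[f]] / med[["total"]]) /
                    (dist[[f]] / dist[["total"]]) - 1), 0.05)

  expect_error(simulatePolysome(catal, occ, spike_set_size = 0), "spike")
})

test_that("image fields are deterministic with truth tables inside the masks", {
  f1 <- simulateFishField(n_cells = 6, spots_per_cell = 8,
                          granule_enrichment = 4, seed = 11)
  f2 <- simulateFishField(n_cells = 6, spots_per_cell = 8,
                          granule_enrichment = 4, seed = 11)
  expect_identical(f1$marker, f2$marker)
  expect_identical(f1$spots, f2$spots)
  # every spot centroid lies inside its own cell's mask
  expect_true(all(f1$mask[cbind(f1$spots$y_px, f1$spots$x_px)] ==
                    f1$spots$cell_id))
  # per-cell normalized intensities average to 1
  m <- tapply(f1$spots$normalized_intensity, f1$spots$cell_id, mean)
  expect_equal(as.numeric(m), rep(1, 6), tolerance = 1e-12)
  expect_error(simulateFishField(0), ">= 1")
  expect_error(simulateFishField(5, granule_enrichment = -1), ">= 0")
})

test_that("qPCR plate simulation round-trips through the delta-delta-Cq path", {
  truth <- c(HSP26 = 0.82, PMU1 = 0.35, PGK1 = 0.6)
  cq <- simulateCqTable(truth, cq_noise_sd = 0, seed = 1)
  est <- qpcrPSup(cq)
  expect_equal(est$psup[match(names(truth), est$transcript_id)],
               unname(truth), tolerance = 1e-10)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(makeCatalog(20, seed = 4))
  invisible(simulateFishField(2, seed = 9))
  expect_identical(runif(1), before)
})
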