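test_that("log-odds transform is exact, antisymmetric and guarded", {
  expect_equal(logOdds(0.5), 0)
  expect_equal(logOdds(0.9), log(9), tolerance = 1e-12)
  p <- seq(0.01, 0.99, by = 0.07)
  expect_equal(logOdds(p), -logOdds(1 - p), tolerance = 1e-12)
  # clamping keeps the ends finite
  expect_true(is.finite(logOdds(0)) && is.finite(logOdds(1)))
  expect_equal(logOdds(0), log(1e-4 / (1 - 1e-4)))
  expect_error(logOdds(1.2), "lie in")
  expect_error(logOdds(-0.1), "lie in")
})

test_that("windowed stats match a brute-force double loop", {
  set.seed(5)
  n <- 60
  lens <- round(exp(runif(n, log(300), log(9000))))
  lop <- rnorm(n)
  for (wf in c(0.02, 0.1, 0.3)) {
    ws <- suppressMessages(windowedStats(lop, lens, wf))
    bf <- brute_windowed(lop, lens, wf)
    expect_equal(ws$mu_L, bf[, 1], tolerance = 1e-12)
    expect_equal(ws$sigma_L, bf[, 2], tolerance = 1e-12)
  }
})

test_that("degenerate and centering properties of windowed stats hold", {
  # all transcripts the same length: window mean is the global mean
  lop <- rnorm(20)
  ws <- windowedStats(lop, rep(1000, 20), 0.02)
  expect_equal(ws$mu_L, rep(mean(lop), 20), tolerance = 1e-12)

  set.seed(6)
  lens <- round(exp(runif(500, log(250), log(12000))))
  lop <- 2 - 0.5 * log(lens) + rnorm(500, 0, 0.4)
  ws <- windowedStats(lop, lens, 0.05)
  expect_lt(abs(mean(lop - ws$mu_L)), 1e-2 * sd(lop))
})

test_that("deltaSed and eSed vanish when treatment equals control", {
  df <- make_psup_df(250)
  st <- scoreTable(df, "control")
  expect_true(all(deltaSed(st, st)$delta_sed == 0))
  expect_true(all(escapeSed(st, st)$e_sed == 0))
})

test_that("deltaSed and eSed match brute-force reimplementations", {
  df_c <- make_psup_df(250, seed = 1)
  df_t <- df_c
  set.seed(2)
  df_t$psup <- pmin(pmax(df_c$psup * runif(250, 0.4, 1), 1e-4), 1 - 1e-4)
  stc <- scoreTable(df_c, "control")
  stt <- scoreTable(df_t, "treated")

  lop_c <- log(pmin(pmax(df_c$psup, 1e-4), 1 - 1e-4) /
                 (1 - pmin(pmax(df_c$psup, 1e-4), 1 - 1e-4)))
  lop_t <- log(pmin(pmax(df_t$psup, 1e-4), 1 - 1e-4) /
                 (1 - pmin(pmax(df_t$psup, 1e-4), 1 - 1e-4)))
  bw_c <- brute_windowed(lop_c, df_c$length_nt, 0.02)
  bw_t <- brute_windowed(lop_t, df_t$length_nt, 0.02)
  sigma0 <- sd(lop_c - bw_c[, 1])

  ds <- deltaSed(stc, stt)
  es <- escapeSed(stc, stt)
  expect_equal(ds$delta_sed, (lop_c - lop_t) / sigma0, tolerance = 1e-12)
  expect_equal(es$e_sed,
               ((lop_t - bw_t[, 1]) - (lop_c - bw_c[, 1])) / sigma0,
               tolerance = 1e-12)
})

test_that("scores are invariant to a common shift of all log-odds values", {
  df_c <- make_psup_df(200, seed = 3)
  df_t <- make_psup_df(200, seed = 4)
  df_t$length_nt <- df_c$length_nt
  stc <- scoreTable(df_c, "control")
  stt <- scoreTable(df_t, "treated")
  shift <- 0.8
  stc2 <- stc; stc2$lopSup <- stc$lopSup + shift; stc2$mu_L <- stc$mu_L + shift
  stt2 <- stt; stt2$lopSup <- stt$lopSup + shift; stt2$mu_L <- stt$mu_L + shift
  expect_equal(deltaSed(stc, stt)$delta_sed,
               deltaSed(stc2, stt2)$delta_sed, tolerance = 1e-10)
  expect_equal(escapeSed(stc, stt)$e_sed,
               escapeSed(stc2, stt2)$e_sed, tolerance = 1e-10)
})

test_that("sedScore matches the brute-force sort/bin/z computation", {
  df <- make_psup_df(250, seed = 7)
  rs <- sedScore(df, bin_size = 100)
  bf <- brute_sed_score(df, bin_size = 100)
  expect_equal(rs$r_sed, unname(bf[rs$transcript_id]), tolerance = 1e-12)

  # replicate averaging
  df2 <- df
  set.seed(8)
  df2$psup <- pmin(pmax(df$psup + rnorm(250, 0, 0.02), 1e-4), 1 - 1e-4)
  rs2 <- sedScore(list(df, df2), bin_size = 100)
  bf2 <- (brute_sed_score(df) + brute_sed_score(df2)) / 2
  expect_equal(rs2$r_sed, unname(bf2[rs2$transcript_id]), tolerance = 1e-12)
})

test_that("sedScore guards degenerate inputs", {
  df <- make_psup_df(50, seed = 9)
  df$psup <- 0.7
  expect_message(rs <- sedScore(df, bin_size = 100), "single bin")
  expect_true(all(rs$r_sed == 0))
})

test_that("sedScore ranks agree with windowed length-relative z-scores", {
  catal <- makeCatalog(5000, seed = 42)
  ps <- simulateTruePSup(catal, conditionSpec("mock", gene_noise_sd = 0.35),
                         seed = 43)
  df <- data.frame(transcript_id = catal$transcript_id, psup = ps,
                   length_nt = catal$length_nt)
  st <- scoreTable(df, "c")
  wz <- (st$lopSup - st$mu_L) / st$sigma_L
  rs <- sedScore(df)
  rho <- cor(wz, rs$r_sed[match(st$transcript_id, rs$transcript_id)],
             method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("transcripts missing from one condition are dropped with a message", {
  df_c <- make_psup_df(100, seed = 10)
  df_t <- df_c[1:90, ]
  stc <- scoreTable(df_c, "control")
  stt <- scoreTable(df_t, "treated")
  expect_message(ds <- deltaSed(stc, stt), "dropped")
  expect_equal(nrow(ds), 90)
})
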