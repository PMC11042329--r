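# Shared fixture builders.  Everything is generated in code at test time.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# One condition's noiseless log-odds pSup over a log-spaced length grid,
# optionally with Gaussian noise, for the physical-model fits.
make_lop_data <- function(n = 100, beta = 2e-4, chi = 0.8, mu = 0, nu = 0,
                          noise_sd = 0, seed = 1,
                          lmin = 200, lmax = 8000) {
  L <- round(exp(seq(log(lmin), log(lmax), length.out = n)))
  q <- pmin(beta * L^chi * exp(mu + nu * L), 1 - 1e-9)
  lop <- log((1 - q) / q)
  if (noise_sd > 0) {
    set.seed(seed)
    lop <- lop + rnorm(n, 0, noise_sd)
  }
  data.frame(length_nt = L, lopSup = lop)
}

# A control/treated pair from the same baseline.
make_pair <- function(mu = 0.8, nu = 0, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  L <- round(exp(seq(log(200), log(8000), length.out = 100)))
  q0 <- 2e-4 * L^0.8
  qt <- pmin(q0 * exp(mu + nu * L), 1 - 1e-9)
  list(ctrl = data.frame(length_nt = L,
                         lopSup = log((1 - q0) / q0) + rnorm(100, 0, noise_sd)),
       trt = data.frame(length_nt = L,
                        lopSup = log((1 - qt) / qt) + rnorm(100, 0, noise_sd)))
}

# A small pSup table with lengths, for score-table oracles.
make_psup_df <- function(n = 250, seed = 1) {
  set.seed(seed)
  data.frame(transcript_id = sprintf("g%03d", seq_len(n)),
             psup = runif(n, 0.05, 0.98),
             length_nt = round(exp(runif(n, log(250), log(12000)))))
}

# Brute-force windowed mean/SD: literal double loop over transcripts.
brute_windowed <- function(lop, len, window_fraction) {
  logL <- log(len)
  half <- window_fraction * (max(logL) - min(logL)) / 2
  t(vapply(seq_along(lop), function(i) {
    idx <- which(abs(logL - logL[i]) <= half)
    if (length(idx) < 3) idx <- order(abs(logL - logL[i]))[1:3]
    c(mean(lop[idx]), sd(lop[idx]))
  }, numeric(2)))
}

# Brute-force binned z (sedScore): sort, consecutive bins, final partial bin
# merged backward, z within bin.
brute_sed_score <- function(psup_df, bin_size = 100, eps = 1e-4) {
  lop <- log(pmin(pmax(psup_df$psup, eps), 1 - eps) /
               (1 - pmin(pmax(psup_df$psup, eps), 1 - eps)))
  ord <- order(psup_df$length_nt)
  n <- nrow(psup_df)
  n_bins <- max(n %/% bin_size, 1)
  z <- numeric(n)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * bin_size + 1
    hi <- if (b == n_bins) n else b * bin_size
    idx <- ord[lo:hi]
    s <- sd(lop[idx])
    z[idx] <- if (!is.finite(s) || s == 0) 0 else
      (lop[idx] - mean(lop[idx])) / s
  }
  setNames(z, psup_df$transcript_id)
}
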