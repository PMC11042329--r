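## Synthetic-data generators: transcript catalogs, true pSup under the
## mass/condensation model, three-fraction NB counts, polysome tables with
## spike-ins, and qPCR plates.  Every generator is deterministic given its
## seed and leaves the caller's RNG state untouched.

#' Generate a yeast-like transcript catalog
#'
#' Draws transcript lengths log-normally (clipped to the 200--15000 nt span a
#' budding-yeast transcriptome occupies, up to the heaviest unstressed mRNP),
#' assigns regulon membership, 5' UTR lengths and base abundances on a
#' transcripts-per-million scale.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_log_mean,length_log_sd Mean and SD of log length in nt.
#'   Defaults centre the distribution near the ~1.3 kb median yeast transcript.
#' @param regulon_fractions Named numeric vector of regulon proportions
#'   (e.g. \code{c(hsf1 = 0.02)}); must sum to at most 1. Remaining transcripts
#'   get regulon \code{"none"}.
#' @param abundance_log_sd SD of log base abundance (lognormal; abundances are
#'   rescaled to sum to 1e6).
#' @param seed Integer seed.
#' @return A data.frame with columns \code{transcript_id}, \code{length_nt},
#'   \code{utr5_length_nt}, \code{regulon}, \code{base_abundance}.
#' @examples
#' cat5 <- makeCatalog(5, seed = 1)
#' range(cat5$length_nt)
#' @export
makeCatalog <- function(n_transcripts,
                        length_log_mean = log(1300),
                        length_log_sd = 0.6,
                        regulon_fractions = c(),
                        abundance_log_sd = 1.2,
                        seed = 1L) {
  if (n_transcripts < 1) stop("'n_transcripts' must be >= 1", call. = FALSE)
  if (length(regulon_fractions) &&
      (any(regulon_fractions < 0) || sum(regulon_fractions) > 1))
    stop("regulon fractions must be non-negative and sum to <= 1",
         call. = FALSE)
  with_seed(derive_seed(seed, 11), {
    len <- round(clamp(rlnorm(n_transcripts, length_log_mean, length_log_sd),
                       200, 15000))
    utr5 <- pmin(round(clamp(rlnorm(n_transcripts, log(60), 0.7), 10, 1000)),
                 pmax(len - 50, 10))
    regulon <- rep("none", n_transcripts)
    if (length(regulon_fractions)) {
      probs <- c(regulon_fractions, none = 1 - sum(regulon_fractions))
      regulon <- sample(names(probs), n_transcripts, replace = TRUE,
                        prob = probs)
    }
    ab <- rlnorm(n_transcripts, 0, abundance_log_sd)
    ab <- ab / sum(ab) * 1e6
    data.frame(
      transcript_id = sprintf("tx%05d", seq_len(n_transcripts)),
      length_nt = as.integer(len),
      utr5_length_nt = as.integer(utr5),
      regulon = regulon,
      base_abundance = ab,
      stringsAsFactors = FALSE)
  })
}

#' Describe an experimental condition
#'
#' Bundles the condensation parameters of a condition: a per-molecule term
#' \code{mu} and per-nucleotide term \code{nu} multiplying the pelleted
#' fraction by \eqn{e^{\mu + \nu L}}, transcriptional induction per regulon
#' (log2 fold changes), an additive escape shift on the log-odds pSup scale
#' for induced regulons, and transcript-level scatter of log-odds pSup.
#'
#' @param name Condition label.
#' @param mu Per-molecule condensation parameter (>= 0 under stress).
#' @param nu Per-nucleotide condensation parameter (per nt).
#' @param induction_log2fc Named vector: regulon -> log2 abundance fold change.
#' @param escape_effect Named vector: regulon -> additive log-odds pSup shift.
#' @param gene_noise_sd SD of transcript-level noise on log-odds pSup.
#' @return A list of class \code{"ConditionSpec"}.
#' @examples
#' ctrl <- conditionSpec("mock")
#' hs <- conditionSpec("heat42", mu = 1.5, induction_log2fc = c(hsf1 = 3),
#'                     escape_effect = c(hsf1 = 1.5))
#' @export
conditionSpec <- function(name, mu = 0, nu = 0,
                          induction_log2fc = c(), escape_effect = c(),
                          gene_noise_sd = 0.35) {
  stopifnot_scalar(mu, "mu"); stopifnot_scalar(nu, "nu")
  if (mu < 0 || nu < 0)
    stop("'mu' and 'nu' must be non-negative", call. = FALSE)
  if (gene_noise_sd < 0) stop("'gene_noise_sd' must be >= 0", call. = FALSE)
  structure(list(name = name, mu = mu, nu = nu,
                 induction_log2fc = induction_log2fc,
                 escape_effect = escape_effect,
                 gene_noise_sd = gene_noise_sd),
            class = "ConditionSpec")
}

#' Simulate true per-transcript pSup under the mass/condensation model
#'
#' Baseline (no condensation): \eqn{pSup = 1 - \beta L^\chi}. Under a
#' condensation-inducing condition the pelleted fraction is multiplied by
#' \eqn{e^{\mu + \nu L}}. Transcript-level noise of SD \code{gene_noise_sd}
#' and any regulon escape effect are added on the log-odds scale.
#'
#' @param catalog Catalog from \code{\link{makeCatalog}}.
#' @param condition A \code{\link{conditionSpec}}.
#' @param beta,chi Baseline power-law parameters; \eqn{\beta L^\chi} must stay
#'   below 1 over the catalog (or set \code{clip = TRUE}).
#' @param seed Integer seed (used only when \code{gene_noise_sd > 0}).
#' @param clip If \code{TRUE} (default) pelleted fractions are clipped just
#'   below 1; if \code{FALSE}, a pelleted fraction >= 1 is an error.
#' @return Named numeric vector of pSup values strictly inside (0, 1).
#' @examples
#' cat <- makeCatalog(100, seed = 2)
#' ps <- simulateTruePSup(cat, conditionSpec("mock", gene_noise_sd = 0),
#'                        beta = 2e-4, chi = 0.8, seed = 1)
#' all(ps > 0 & ps < 1)
#' @export
simulateTruePSup <- function(catalog, condition,
                             beta = 2e-4, chi = 0.8, seed = 1L,
                             clip = TRUE) {
  stopifnot_scalar(beta, "beta", positive = TRUE)
  stopifnot_scalar(chi, "chi", positive = TRUE)
  L <- catalog$length_nt
  q <- beta * L^chi * exp(condition$mu + condition$nu * L)
  if (any(q >= 1)) {
    if (!clip)
      stop("pelleted fraction >= 1 for some transcripts; enable 'clip' or ",
           "reduce beta/mu/nu", call. = FALSE)
    q <- pmin(q, 1 - 1e-6)
  }
  lop <- logit(1 - pmax(q, 1e-12))
  if (length(condition$escape_effect)) {
    hit <- match(catalog$regulon, names(condition$escape_effect))
    shift <- ifelse(is.na(hit), 0, condition$escape_effect[hit])
    lop <- lop + shift
  }
  if (condition$gene_noise_sd > 0)
    lop <- lop + with_seed(derive_seed(seed, 23),
                           rnorm(length(lop), 0, condition$gene_noise_sd))
  psup <- clamp(inv_logit(lop), 1e-6, 1 - 1e-6)
  names(psup) <- catalog$transcript_id
  psup
}

#' Simulate Total/Supernatant/Pellet counts for one experiment
#'
#' Latent per-transcript totals are proportional to catalog abundance (times
#' any regulon induction in \code{condition}) at the requested depth. The
#' supernatant and pellet expectations split the total by the true pSup and
#' are divided by the mixing ratios \code{alpha_s}, \code{alpha_p} (so that
#' \eqn{T \approx \alpha_S S + \alpha_P P} in expectation). All three observed
#' vectors are negative-binomially distributed around their expectations with
#' a shared dispersion.
#'
#' @param catalog Catalog from \code{\link{makeCatalog}}.
#' @param true_psup Named pSup vector (e.g. \code{\link{simulateTruePSup}}).
#' @param condition Optional \code{\link{conditionSpec}} supplying
#'   \code{induction_log2fc}; \code{NULL} means no induction.
#' @param alpha_s,alpha_p True mixing ratios (> 0).
#' @param dispersion NB size parameter shared by the three fractions;
#'   \code{Inf} gives Poisson noise.
#' @param depth Expected total-library depth (sum of Total expectations).
#' @param experiment_id Label stored in the result.
#' @param seed Integer seed.
#' @return A \linkS4class{FractionCounts} with simulation truth (true pSup,
#'   true ratios, dispersion, seed) in \code{metadata()}.
#' @examples
#' cat <- makeCatalog(50, seed = 3)
#' ps <- simulateTruePSup(cat, conditionSpec("mock", gene_noise_sd = 0),
#'                        seed = 3)
#' fc <- simulateFractionCounts(cat, ps, depth = 1e5, seed = 3)
#' fc
#' @export
simulateFractionCounts <- function(catalog, true_psup, condition = NULL,
                                   alpha_s = 1, alpha_p = 1,
                                   dispersion = 100, depth = 1e7,
                                   experiment_id = "sim", seed = 1L) {
  stopifnot_scalar(alpha_s, "alpha_s", positive = TRUE)
  stopifnot_scalar(alpha_p, "alpha_p", positive = TRUE)
  stopifnot_scalar(depth, "depth", positive = TRUE)
  if (!(is.infinite(dispersion) || dispersion > 0))
    stop("'dispersion' must be positive (or Inf for Poisson)", call. = FALSE)
  psup <- true_psup[catalog$transcript_id]
  if (any(is.na(psup)))
    stop("'true_psup' must cover every catalog transcript", call. = FALSE)
  ab <- catalog$base_abundance
  if (!is.null(condition) && length(condition$induction_log2fc)) {
    hit <- match(catalog$regulon, names(condition$induction_log2fc))
    ab <- ab * 2^ifelse(is.na(hit), 0, condition$induction_log2fc[hit])
  }
  t_mean <- depth * ab / sum(ab)
  s_mean <- t_mean * psup / alpha_s
  p_mean <- t_mean * (1 - psup) / alpha_p
  rnb <- function(mu) {
    if (is.infinite(dispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = dispersion)
  }
  with_seed(derive_seed(seed, 37), {
    fc <- FractionCounts(
      total = rnb(t_mean), sup = rnb(s_mean), pellet = rnb(p_mean),
      transcript_id = catalog$transcript_id,
      length_nt = catalog$length_nt,
      experiment_id = experiment_id,
      rowData = data.frame(regulon = catalog$regulon,
                           utr5_length_nt = catalog$utr5_length_nt),
      metadata = list(true_psup = psup, alpha_s_true = alpha_s,
                      alpha_p_true = alpha_p, dispersion_true = dispersion,
                      depth = depth, seed = as.integer(seed),
                      condition = if (is.null(condition)) NULL
                                  else condition$name))
    fc
  })
}

#' Simulate a spike-in anchored polysome fractionation experiment
#'
#' Emits Total/Free/Bound abundance tables in which each cellular transcript's
#' Free:Bound split follows a supplied ribosome occupancy, and a disjoint set
#' of foreign spike-in transcripts receives identical expected abundance in
#' every fraction (emulating a fixed mass of foreign total RNA added per
#' pooled fraction). Each fraction's reported abundances are multiplied by a
#' lognormal fraction-scale distortion (shared by spikes and cellular
#' transcripts, like library depth), plus per-entry lognormal measurement
#' noise. The injected distortions are returned for recoverability checks.
#'
#' @param catalog Catalog from \code{\link{makeCatalog}}.
#' @param occupancy Named vector in [0,1]: fraction of each transcript's
#'   molecules bound by at least one ribosome.
#' @param spike_set_size Number of spike-in transcripts (> 0).
#' @param spike_abundance Expected spike abundance (common to all fractions).
#' @param distortion_sdlog SD of the lognormal per-fraction scale distortion.
#' @param noise_sdlog SD of per-entry lognormal measurement noise (default
#'   0.01, the repeatability scale of quantifier TPM estimates for
#'   well-covered transcripts; the spike-median normalizer inherits the
#'   middle spike's noise, so this sets the accuracy of distortion recovery).
#' @param seed Integer seed.
#' @return A data.frame with columns \code{transcript_id}, \code{fraction}
#'   (total/free/bound), \code{tpm}, \code{est_counts}, \code{is_spike};
#'   the true per-fraction distortion factors are in
#'   \code{attr(, "distortion")} and the occupancy truth in
#'   \code{attr(, "occupancy")}.
#' @examples
#' cat <- makeCatalog(30, seed = 4)
#' occ <- stats::setNames(stats::runif(30), cat$transcript_id)
#' tab <- simulatePolysome(cat, occ, seed = 4)
#' head(tab)
#' @export
simulatePolysome <- function(catalog, occupancy, spike_set_size = 20,
                             spike_abundance = 50,
                             distortion_sdlog = 0.3, noise_sdlog = 0.01,
                             seed = 1L) {
  if (spike_set_size < 1)
    stop("'spike_set_size' must be >= 1", call. = FALSE)
  occ <- occupancy[catalog$transcript_id]
  if (any(is.na(occ)) || any(occ < 0 | occ > 1))
    stop("'occupancy' must cover the catalog with values in [0,1]",
         call. = FALSE)
  with_seed(derive_seed(seed, 53), {
    spike_id <- sprintf("spike%03d", seq_len(spike_set_size))
    spike_ab <- rlnorm(spike_set_size, log(spike_abundance), 0.5)
    ids <- c(catalog$transcript_id, spike_id)
    is_spike <- c(rep(FALSE, nrow(catalog)), rep(TRUE, spike_set_size))
    ab <- catalog$base_abundance
    expected <- list(
      total = c(ab, spike_ab),
      free  = c(ab * (1 - occ), spike_ab),
      bound = c(ab * occ, spike_ab))
    distortion <- stats::setNames(rlnorm(3, 0, distortion_sdlog),
                                  names(expected))
    rows <- lapply(names(expected), function(f) {
      mu <- expected[[f]] * distortion[[f]]
      tpm <- mu * rlnorm(length(mu), 0, noise_sdlog)
      data.frame(transcript_id = ids, fraction = f, tpm = tpm,
                 est_counts = round(tpm * 10), is_spike = is_spike,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "distortion") <- distortion
    attr(out, "occupancy") <- occ
    out
  })
}

#' Simulate a qPCR plate for fractionated samples with spike-in wells
#'
#' Builds Cq values for target transcripts in supernatant and pellet fractions
#' plus one spike-in well per fraction, consistent with given true pSup values
#' and the stated spike amounts / pellet concentration. Cq decreases by 1 per
#' doubling of template (efficiency 2).
#'
#' @param true_psup Named vector of true pSup values.
#' @param sup_spike_amount,pellet_spike_amount Spike masses added per fraction.
#' @param pellet_concentration_factor Fold concentration of the pellet sample
#'   relative to supernatant.
#' @param base_cq Spike-well Cq (anchor).
#' @param abundance Named vector of relative target abundances (default 1).
#' @param cq_noise_sd Gaussian noise on Cq values.
#' @param seed Integer seed.
#' @return Data.frame with columns \code{well}, \code{target},
#'   \code{fraction}, \code{cq}; spike wells have target \code{"spike"}.
#' @export
simulateCqTable <- function(true_psup,
                            sup_spike_amount = 0.1, pellet_spike_amount = 1,
                            pellet_concentration_factor = 10,
                            base_cq = 20, abundance = NULL,
                            cq_noise_sd = 0, seed = 1L) {
  targets <- names(true_psup)
  if (is.null(abundance))
    abundance <- stats::setNames(rep(1, length(targets)), targets)
  with_seed(derive_seed(seed, 67), {
    ## template present in each well, per original lysate volume
    sup_amt <- abundance[targets] * true_psup
    pel_amt <- abundance[targets] * (1 - true_psup) *
      pellet_concentration_factor
    cq_for <- function(amt, spike_amt)
      base_cq - log2(amt / spike_amt)
    rows <- rbind(
      data.frame(target = targets, fraction = "sup",
                 cq = cq_for(sup_amt, sup_spike_amount)),
      data.frame(target = targets, fraction = "pellet",
                 cq = cq_for(pel_amt, pellet_spike_amount)),
      data.frame(target = "spike", fraction = c("sup", "pellet"),
                 cq = base_cq))
    rows$cq <- rows$cq + rnorm(nrow(rows), 0, cq_noise_sd)
    rows$well <- sprintf("W%02d", seq_len(nrow(rows)))
    rows[, c("well", "target", "fraction", "cq")]
  })
}
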