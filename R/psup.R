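## Estimation of mixing ratios and per-transcript pSup from three-fraction
## count data, plus the qPCR (delta-delta-Cq) route used for reporters.
##
## The estimation model assumes conservation of mass for each mRNA in the
## original lysate (T = S* + P* on the true amounts, with observed
## S ~ NB(S*/alphaS, phi) and P ~ NB(P*/alphaP, phi)) with negative-binomial
## noise on every count measurement.  This is an errors-in-variables problem:
## the latent true amounts (S*, P*) of each transcript are profiled out by an
## inner vectorized Newton maximization, and the mixing ratios maximize the
## resulting profile posterior.  Treating S and P as fixed noise-free
## covariates instead (a plain NB regression of T on S and P) is available as
## model = "regression", but is attenuated by the noise in S and P and
## systematically underestimates the alphaS/alphaP ratio.

## Negative log profile posterior for theta = (log alphaS, log alphaP,
## log phi).  Per transcript, latent (u, v) = (log S*, log P*) maximize
## lnNB(S; e^u/aS, phi) + lnNB(P; e^v/aP, phi) + lnNB(T; e^u + e^v, phi)
## via a capped 2-d Newton iteration (vectorized over transcripts).  Priors:
## alphaS, alphaP ~ Gamma(1,1); half-Cauchy(0,3) on 1/sqrt(phi); Jacobians
## included.
.eiv_nlp <- function(theta, S, P, T, inner = 8) {
  aS <- exp(theta[1]); aP <- exp(theta[2]); phi <- exp(theta[3])
  u <- log(S * aS); v <- log(P * aP)
  g <- function(C, mu) C / mu - (C + phi) / (mu + phi)
  h <- function(C, mu) -C / mu^2 + (C + phi) / (mu + phi)^2
  for (k in seq_len(inner)) {
    muS <- exp(u) / aS; muP <- exp(v) / aP
    eu <- exp(u); ev <- exp(v); muT <- eu + ev
    du <- g(S, muS) * muS + g(T, muT) * eu
    dv <- g(P, muP) * muP + g(T, muT) * ev
    duu <- h(S, muS) * muS^2 + g(S, muS) * muS +
      h(T, muT) * eu^2 + g(T, muT) * eu
    dvv <- h(P, muP) * muP^2 + g(P, muP) * muP +
      h(T, muT) * ev^2 + g(T, muT) * ev
    duv <- h(T, muT) * eu * ev
    det <- duu * dvv - duv^2
    ok <- is.finite(det) & det > 0 & duu < 0
    su <- ifelse(ok, (dv * duv - du * dvv) / det, 0.1 * sign(du))
    sv <- ifelse(ok, (du * duv - dv * duu) / det, 0.1 * sign(dv))
    u <- u + clamp(su, -1, 1)
    v <- v + clamp(sv, -1, 1)
  }
  muS <- exp(u) / aS; muP <- exp(v) / aP; muT <- exp(u) + exp(v)
  ll <- sum(dnbinom(S, size = phi, mu = muS, log = TRUE) +
            dnbinom(P, size = phi, mu = muP, log = TRUE) +
            dnbinom(T, size = phi, mu = muT, log = TRUE))
  sig <- 1 / sqrt(phi)
  -(ll - aS - aP + theta[1] + theta[2] +
      log(2 / (pi * 3)) - log1p((sig / 3)^2) - theta[3] / 2)
}

## Fixed-covariate NB regression posterior (the displayed-likelihood reading):
## T_i ~ NB(mean = alphaS*S_i + alphaP*P_i, size = phi).
.reg_nlp <- function(theta, T, S, P) {
  aS <- exp(theta[1]); aP <- exp(theta[2]); phi <- exp(theta[3])
  mu <- aS * S + aP * P
  if (any(mu <= 0)) return(Inf)
  -(sum(dnbinom(T, size = phi, mu = mu, log = TRUE)) -
      aS - aP + theta[1] + theta[2] +
      log(2 / (pi * 3)) - log1p((1 / sqrt(phi) / 3)^2) - theta[3] / 2)
}

.mix_objective <- function(model, T, S, P) {
  if (model == "eiv") {
    ## dispersion: profiling two latent amounts out of three observations
    ## leaves one residual dimension, inflating the apparent NB size by a
    ## factor ~3 (Neyman-Scott); report the degrees-of-freedom-corrected value
    list(fn = function(th) .eiv_nlp(th, S, P, T),
         start = c(0, 0, log(50)),
         to_est = function(th) c(alphaS = exp(th[1]), alphaP = exp(th[2]),
                                 dispersion = exp(th[3]) / 3))
  } else {
    list(fn = function(th) .reg_nlp(th, T, S, P),
         start = c(0, 0, log(10)),
         to_est = function(th) c(alphaS = exp(th[1]), alphaP = exp(th[2]),
                                 dispersion = exp(th[3])))
  }
}

.map_fit <- function(obj) {
  o1 <- stats::optim(obj$start, obj$fn, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-12))
  o2 <- tryCatch(
    stats::optim(o1$par, obj$fn, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) o1)
  best <- if (o2$value <= o1$value) o2 else o1
  list(par = best$par, value = best$value, converged = best$convergence == 0)
}

## Adaptive random-walk Metropolis over the same (profile) posterior, with
## split-R-hat and acceptance-rate diagnostics.
.mcmc_fit <- function(obj, n_chains = 4, n_warmup = 400, n_keep = 600,
                      seed = 1L) {
  map <- .map_fit(obj)
  ## posterior is a narrow ridge in (log alphaS, log alphaP); shape the
  ## proposal with the curvature at the mode
  H <- tryCatch(stats::optimHess(map$par, obj$fn), error = function(e) NULL)
  L <- tryCatch(t(chol(solve(H))), error = function(e) NULL)
  if (is.null(L)) L <- diag(0.05, 3)
  draws <- array(NA_real_, dim = c(n_keep, n_chains, 3))
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    with_seed(derive_seed(seed, ch), {
      theta <- map$par + as.numeric(L %*% rnorm(3))
      lp <- -obj$fn(theta)
      scale <- 2.4 / sqrt(3)
      n_acc <- 0L
      for (it in seq_len(n_warmup + n_keep)) {
        prop <- theta + scale * as.numeric(L %*% rnorm(3))
        lp_prop <- -obj$fn(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop; lp <- lp_prop
          if (it > n_warmup) n_acc <- n_acc + 1L
          if (it <= n_warmup) scale <- scale * 1.03
        } else if (it <= n_warmup) scale <- scale * 0.99
        if (it > n_warmup) draws[it - n_warmup, ch, ] <- theta
      }
      accept[ch] <- n_acc / n_keep
    })
  }
  rhat <- vapply(1:3, function(j) .split_rhat(draws[, , j]), numeric(1))
  list(draws = draws, accept = accept, rhat = rhat, map = map)
}

## Split-R-hat (each chain halved) for an iterations x chains matrix.
.split_rhat <- function(x) {
  n <- nrow(x); half <- n %/% 2
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(half + 1):(2 * half), , drop = FALSE])
  nn <- nrow(splits)
  means <- colMeans(splits); vars <- apply(splits, 2, stats::var)
  B <- nn * stats::var(means); W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Estimate per-experiment mixing ratios from three-fraction counts
#'
#' Estimates the mixing ratios \eqn{(\alpha_S, \alpha_P)} that restore
#' conservation of mass \eqn{T_i = \alpha_S S_i + \alpha_P P_i} across the
#' Total, Supernatant and Pellet libraries of one experiment, over all
#' transcripts whose counts exceed \code{min_counts} in all three fractions.
#' Priors: \eqn{\alpha_S, \alpha_P \sim} Gamma(1,1) and half-Cauchy(0,3) on
#' the noise scale.
#'
#' The default model (\code{"eiv"}) honours negative-binomial noise on every
#' count measurement: each transcript's latent true supernatant and pellet
#' amounts are profiled out (inner Newton maximization, vectorized over
#' transcripts), and the ratios maximize the profile posterior. The reported
#' dispersion carries a degrees-of-freedom correction for the profiled
#' latents. The
#' \code{"regression"} model conditions on S and P as fixed covariates
#' (\eqn{T_i \sim NB(\alpha_S S_i + \alpha_P P_i, \phi)}); it is simpler but
#' attenuates the ratio when S and P are themselves noisy.
#'
#' Only the ratio \eqn{\alpha_S/\alpha_P} is identifiable up to the relative
#' depths of the libraries; pSup depends on the ratios only through products
#' with the counts, so this is the quantity that matters downstream.
#'
#' @param counts A \linkS4class{FractionCounts} object.
#' @param min_counts Count filter: transcripts must exceed this in all three
#'   fractions (default 20).
#' @param method \code{"MAP"} (default, deterministic posterior mode) or
#'   \code{"MCMC"} (adaptive random-walk chains; posterior mean, with
#'   split-R-hat and acceptance diagnostics).
#' @param model \code{"eiv"} (default) or \code{"regression"}; see Details.
#' @param seed Seed for the MCMC backend.
#' @param min_transcripts Minimum number of transcripts that must pass the
#'   filter (default 50).
#' @param ... Passed to the MCMC backend (\code{n_chains}, \code{n_warmup},
#'   \code{n_keep}).
#' @return A \linkS4class{MixingRatios}. Non-convergence is flagged in
#'   \code{diagnostics}, never silent.
#' @examples
#' cat <- makeCatalog(300, seed = 5)
#' ps <- simulateTruePSup(cat, conditionSpec("mock"), seed = 5)
#' fc <- simulateFractionCounts(cat, ps, depth = 3e5, seed = 5)
#' estimateMixingRatios(fc)
#' @export
setGeneric("estimateMixingRatios",
  function(counts, min_counts = 20, method = c("MAP", "MCMC"),
           model = c("eiv", "regression"), seed = 1L,
           min_transcripts = 50, ...)
    standardGeneric("estimateMixingRatios"))

#' @rdname estimateMixingRatios
setMethod("estimateMixingRatios", "FractionCounts",
  function(counts, min_counts = 20, method = c("MAP", "MCMC"),
           model = c("eiv", "regression"), seed = 1L,
           min_transcripts = 50, ...) {
    method <- match.arg(method)
    model <- match.arg(model)
    T <- totalCounts(counts); S <- supCounts(counts); P <- pelletCounts(counts)
    keep <- T > min_counts & S > min_counts & P > min_counts
    if (sum(keep) < min_transcripts)
      stop(sprintf(
        "only %d transcripts exceed %d counts in all fractions (need >= %d)",
        sum(keep), min_counts, min_transcripts), call. = FALSE)
    obj <- .mix_objective(model, T[keep], S[keep], P[keep])
    if (method == "MAP") {
      fit <- .map_fit(obj)
      if (!fit$converged)
        warning("MAP optimizer did not report convergence; see diagnostics")
      est <- obj$to_est(fit$par)
      new("MixingRatios",
          alphaS = unname(est["alphaS"]), alphaP = unname(est["alphaP"]),
          dispersion = unname(est["dispersion"]),
          nUsed = sum(keep), method = "MAP",
          diagnostics = list(converged = fit$converged, model = model,
                             neg_log_posterior = fit$value))
    } else {
      fit <- .mcmc_fit(obj, seed = seed, ...)
      theta_mean <- apply(fit$draws, 3, mean)
      est <- obj$to_est(theta_mean)
      conv <- all(fit$rhat < 1.05)
      if (!conv)
        warning("MCMC split-R-hat exceeds 1.05; see diagnostics")
      new("MixingRatios",
          alphaS = unname(est["alphaS"]), alphaP = unname(est["alphaP"]),
          dispersion = unname(est["dispersion"]),
          nUsed = sum(keep), method = "MCMC",
          diagnostics = list(converged = conv, model = model,
                             rhat = fit$rhat, accept_rate = fit$accept))
    }
  })

#' Compute per-transcript pSup from counts and mixing ratios
#'
#' \eqn{pSup_i = \alpha_S S_i / (\alpha_S S_i + \alpha_P P_i)}. Transcripts
#' with zero counts in both the supernatant and pellet fractions are dropped
#' (with a message).
#'
#' @param counts A \linkS4class{FractionCounts} object.
#' @param ratios A \linkS4class{MixingRatios} fitted on the same experiment.
#' @return Data.frame with \code{transcript_id}, \code{psup}, \code{total},
#'   \code{length_nt} (when available) and \code{experiment_id}.
#' @examples
#' fc <- FractionCounts(total = c(110, 120), sup = c(100, 50),
#'                      pellet = c(10, 100), transcript_id = c("a", "b"))
#' r <- new("MixingRatios", alphaS = 1, alphaP = 1, dispersion = 100,
#'          nUsed = 2L, method = "MAP", diagnostics = list())
#' computePSup(fc, r)$psup   # 100/110, 50/150
#' @export
computePSup <- function(counts, ratios) {
  stopifnot(is(counts, "FractionCounts"), is(ratios, "MixingRatios"))
  S <- supCounts(counts); P <- pelletCounts(counts)
  keep <- (S + P) > 0
  if (any(!keep))
    message(sum(!keep), " transcript(s) with sup + pellet = 0 dropped")
  num <- alphaS(ratios) * S[keep]
  den <- num + alphaP(ratios) * P[keep]
  out <- data.frame(
    transcript_id = names(S)[keep],
    psup = num / den,
    total = as.numeric(totalCounts(counts)[keep]),
    experiment_id = metadata(counts)$experiment_id,
    stringsAsFactors = FALSE)
  len <- transcriptLengths(counts)
  if (!is.null(len)) out$length_nt <- as.numeric(len[keep])
  rownames(out) <- NULL
  out
}

#' Compute pSup from a qPCR Cq table via the delta-delta-Cq method
#'
#' Relative abundance of each target in each fraction is
#' \eqn{2^{Cq_{spike} - Cq_{target}}} (amplification efficiency 2). Pellet
#' abundances are multiplied by \code{spike_amount_ratio} (the pellet received
#' that much more spike-in, understating its relative abundance) and divided
#' by \code{pellet_concentration_factor} (the pellet was resuspended that much
#' more concentrated). With the protocol defaults (10 and 10) the two cancel.
#'
#' @param cq_table Data.frame with columns \code{target}, \code{fraction}
#'   (\code{"sup"} / \code{"pellet"}) and \code{cq}; spike wells have target
#'   \code{"spike"}. Replicate wells are averaged on the Cq scale.
#' @param pellet_concentration_factor Fold concentration of the pellet sample
#'   relative to the supernatant (default 10).
#' @param spike_amount_ratio Ratio of spike mass added to the pellet vs the
#'   supernatant (default 10).
#' @return Data.frame with \code{transcript_id} and \code{psup}.
#' @examples
#' tab <- data.frame(target = c("x", "x", "spike", "spike"),
#'                   fraction = c("sup", "pellet", "sup", "pellet"),
#'                   cq = c(25, 25, 20, 20))
#' qpcrPSup(tab, pellet_concentration_factor = 1, spike_amount_ratio = 1)
#' @export
qpcrPSup <- function(cq_table, pellet_concentration_factor = 10,
                     spike_amount_ratio = 10) {
  need <- c("target", "fraction", "cq")
  if (!all(need %in% names(cq_table)))
    stop("cq_table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  spike <- cq_table[cq_table$target == "spike", ]
  if (!all(c("sup", "pellet") %in% spike$fraction))
    stop("missing spike-in well for one or both fractions", call. = FALSE)
  spike_cq <- tapply(spike$cq, spike$fraction, mean)
  targ <- cq_table[cq_table$target != "spike", ]
  rel <- function(frac) {
    rows <- targ[targ$fraction == frac, ]
    cq <- tapply(rows$cq, rows$target, mean)
    2^(spike_cq[[frac]] - cq)
  }
  sup_rel <- rel("sup"); pel_rel <- rel("pellet")
  ids <- intersect(names(sup_rel), names(pel_rel))
  if (!length(ids))
    stop("no targets measured in both fractions", call. = FALSE)
  pel_corr <- pel_rel[ids] * spike_amount_ratio / pellet_concentration_factor
  data.frame(transcript_id = ids,
             psup = as.numeric(sup_rel[ids] / (sup_rel[ids] + pel_corr)),
             stringsAsFactors = FALSE, row.names = NULL)
}
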