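## Mass-based sedimentation model on the log-odds pSup scale.  Baseline:
## pelleted fraction q(L) = beta * L^chi.  Under a condensation-inducing
## treatment q is multiplied by exp(mu + nu*L) (per-molecule mu,
## per-nucleotide nu, both >= 0 increasing pelleting).  Fits are non-linear
## least squares against observed log-odds pSup, with multi-start over a
## log-spaced beta grid.

.Q_CLAMP <- 1 - 1e-9

## Predicted log-odds pSup.  nu is passed per kb internally for optimizer
## conditioning.
.pred_lop <- function(L, lbeta, chi, mu = 0, nu_kb = 0) {
  q <- exp(lbeta) * L^chi * exp(mu + (nu_kb / 1000) * L)
  clamped <- q >= .Q_CLAMP
  q <- pmin(q, .Q_CLAMP)
  structure(logit(1 - q), clamped = any(clamped))
}

.rss_of <- function(par, L, lop, free, fixed) {
  p <- fixed; p[free] <- par
  pred <- .pred_lop(L, p["lbeta"], p["chi"], p["mu"], p["nu_kb"])
  if (p["chi"] <= 0) return(1e12)
  sum((lop - as.numeric(pred))^2)
}

.nls_multistart <- function(L, lop, free, fixed, starts) {
  best <- NULL
  for (s in starts) {
    o1 <- stats::optim(s, .rss_of, L = L, lop = lop, free = free,
                       fixed = fixed, method = "Nelder-Mead",
                       control = list(maxit = 800, reltol = 1e-13))
    o2 <- tryCatch(
      stats::optim(o1$par, .rss_of, L = L, lop = lop, free = free,
                   fixed = fixed, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) o1)
    o <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  best
}

## Linearized starting values: the pelleted fraction q satisfies
## log q = log(beta) + chi*log(L) (+ mu + nu*L under treatment), so a linear
## model on the observed q gives starts close to the optimum.
.lm_start <- function(control, treated = NULL) {
  obs_q <- function(d) clamp(1 - inv_logit(d$lopSup), 1e-6, 1 - 1e-6)
  if (is.null(treated)) {
    f <- stats::lm(log(obs_q(control)) ~ log(control$length_nt))
    cf <- stats::coef(f)
    c(lbeta = unname(cf[1]), chi = unname(cf[2]))
  } else {
    y <- c(log(obs_q(control)), log(obs_q(treated)))
    lL <- c(log(control$length_nt), log(treated$length_nt))
    L <- c(control$length_nt, treated$length_nt)
    trt <- rep(c(0, 1), c(nrow(control), nrow(treated)))
    f <- stats::lm(y ~ lL + trt + I(trt * L))
    cf <- stats::coef(f)
    c(lbeta = unname(cf[1]), chi = unname(cf[2]), mu = unname(cf[3]),
      nu_kb = unname(cf[4]) * 1000)
  }
}

.as_sedfit <- function(par_full, rss, n, n_params, converged, details) {
  new("SedFit",
      beta = unname(exp(par_full["lbeta"])), chi = unname(par_full["chi"]),
      mu = unname(par_full["mu"]), nu = unname(par_full["nu_kb"] / 1000),
      rss = rss, nPoints = as.integer(n), nParams = as.integer(n_params),
      converged = converged, details = details)
}

#' Fit the baseline mass-only sedimentation model
#'
#' Least-squares fit of \eqn{\mathrm{logit}(1 - \beta L^\chi)} to observed
#' log-odds pSup over length, with multi-start over a log-spaced \eqn{\beta}
#' grid. Intended input is the treatment-averaged (windowed mean) log-odds
#' pSup per length point; per-transcript tables work too.
#'
#' @param data Data.frame with columns \code{length_nt} and \code{lopSup}
#'   (or \code{psup}, converted via \code{\link{logOdds}}).
#' @param beta_grid Multi-start values for \eqn{\beta}.
#' @param chi_start Starting values for \eqn{\chi}.
#' @return A \linkS4class{SedFit} with \code{nParams = 2}.
#' @examples
#' L <- round(exp(seq(log(300), log(6000), length.out = 50)))
#' lop <- logOdds(1 - 10^-3.5 * L^0.9)
#' fitBaseline(data.frame(length_nt = L, lopSup = lop))
#' @export
fitBaseline <- function(data, beta_grid = 10^seq(-6, -2.5, length.out = 5),
                        chi_start = 0.8) {
  if (!"lopSup" %in% names(data)) {
    if (!"psup" %in% names(data))
      stop("'data' needs a 'lopSup' or 'psup' column", call. = FALSE)
    data$lopSup <- logOdds(data$psup)
  }
  if (nrow(data) < 10) stop("need >= 10 length points", call. = FALSE)
  L <- data$length_nt; lop <- data$lopSup
  starts <- list(.lm_start(data))
  for (b in beta_grid) for (ch in chi_start)
    starts <- c(starts, list(c(lbeta = log(b), chi = ch)))
  fixed <- c(lbeta = NA, chi = NA, mu = 0, nu_kb = 0)
  best <- .nls_multistart(L, lop, c("lbeta", "chi"), fixed, starts)
  if (is.null(best) || !is.finite(best$value))
    stop("no start converged; see data scaling", call. = FALSE)
  par <- c(best$par, mu = 0, nu_kb = 0)
  .as_sedfit(par, best$value, length(L), 2, best$convergence == 0,
             details = list(n_starts = length(starts)))
}

#' Fit the stress condensation model
#'
#' Models the treated pelleted fraction as
#' \eqn{\beta L^\chi e^{\mu + \nu L}} with \eqn{\mu = \nu = 0} in the
#' control. With \code{share_baseline = TRUE} (default), \eqn{(\beta, \chi)}
#' and the requested condensation terms are fitted jointly to the stacked
#' control + treated data; otherwise the baseline is fixed from
#' \code{baseline} (or fitted to the control first) and only the condensation
#' terms are fitted to the treated data.
#'
#' @param control,treated Data.frames with \code{length_nt} and \code{lopSup}
#'   (or \code{psup}).
#' @param terms Which condensation terms to fit: any of \code{"mu"},
#'   \code{"nu"}. \code{c("mu", "nu")} is the full model; a single term gives
#'   the reduced models used in nested testing.
#' @param share_baseline Fit \eqn{(\beta, \chi)} jointly with the condensation
#'   terms (default) or fix them from the control-only fit.
#' @param baseline Optional \linkS4class{SedFit} supplying a fixed baseline.
#' @return A \linkS4class{SedFit}; \code{nParams} counts all free parameters.
#'   If the predicted pelleted fraction hits 1 anywhere, residuals are
#'   computed on the clamped value and \code{details$clamped} is set.
#' @export
fitStress <- function(control, treated, terms = c("mu", "nu"),
                      share_baseline = TRUE, baseline = NULL) {
  terms <- match.arg(terms, c("mu", "nu"), several.ok = TRUE)
  prep <- function(d) {
    if (!"lopSup" %in% names(d)) d$lopSup <- logOdds(d$psup)
    d
  }
  control <- prep(control); treated <- prep(treated)
  term_par <- c(mu = "mu", nu = "nu_kb")[terms]
  if (share_baseline) {
    ## stack: control rows have the condensation factor switched off by
    ## fitting them with mu = nu = 0 through a combined objective
    rss_joint <- function(par) {
      lbeta <- par[1]; chi <- par[2]
      mu <- if ("mu" %in% terms) par[which(terms == "mu") + 2] else 0
      nu_kb <- if ("nu" %in% terms) par[which(terms == "nu") + 2] else 0
      if (chi <= 0) return(1e12)
      r1 <- control$lopSup -
        as.numeric(.pred_lop(control$length_nt, lbeta, chi, 0, 0))
      r2 <- treated$lopSup -
        as.numeric(.pred_lop(treated$length_nt, lbeta, chi, mu, nu_kb))
      sum(r1^2) + sum(r2^2)
    }
    ls4 <- .lm_start(control, treated)
    take <- c("lbeta", "chi", term_par)
    start0 <- unname(ls4[take])
    starts <- list(start0,
                   c(start0[1:2], rep(0.5, length(terms))),
                   c(start0[1] - 1, start0[2] + 0.2,
                     rep(1.5, length(terms))))
    if (length(terms) == 2) {
      ## nested-aware starts: each single-term solution, other term at zero,
      ## so the full fit never ends above a reduced fit's RSS
      starts <- c(starts,
                  list(c(start0[1:2], ls4["mu"] + log(pmax(
                    exp(ls4["nu_kb"] / 1000 * stats::median(
                      treated$length_nt)), 1e-12)), 0),
                    c(start0[1:2], 0, ls4["nu_kb"] + ls4["mu"] * 1000 /
                        stats::median(treated$length_nt))))
    }
    best <- NULL
    for (s in starts) {
      o1 <- stats::optim(s, rss_joint, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-13))
      o2 <- tryCatch(
        stats::optim(o1$par, rss_joint, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) o1)
      o <- if (o2$value <= o1$value) o2 else o1
      if (is.null(best) || o$value < best$value - 1e-10) best <- o
    }
    par <- c(lbeta = best$par[1], chi = best$par[2], mu = 0, nu_kb = 0)
    par[term_par] <- best$par[-(1:2)]
    n <- nrow(control) + nrow(treated)
    fit <- .as_sedfit(par, best$value, n, 2 + length(terms),
                      best$convergence == 0,
                      details = list(shared_baseline = TRUE, terms = terms))
  } else {
    if (is.null(baseline)) baseline <- fitBaseline(control)
    fixed <- c(lbeta = log(baseline@beta), chi = baseline@chi,
               mu = 0, nu_kb = 0)
    starts <- lapply(c(0.1, 0.5, 1.5), function(v)
      stats::setNames(rep(v, length(terms)), term_par))
    best <- .nls_multistart(treated$length_nt, treated$lopSup,
                            term_par, fixed, starts)
    par <- fixed; par[term_par] <- best$par
    fit <- .as_sedfit(par, best$value, nrow(treated), length(terms),
                      best$convergence == 0,
                      details = list(shared_baseline = FALSE, terms = terms,
                                     baseline_rss = baseline@rss))
    ## count the fixed baseline's parameters for bookkeeping consistency
    fit@nParams <- as.integer(2 + length(terms))
  }
  pred <- .pred_lop(treated$length_nt, log(fit@beta), fit@chi, fit@mu,
                    fit@nu * 1000)
  if (isTRUE(attr(pred, "clamped"))) {
    warning("predicted pelleted fraction clamped below 1 for some lengths")
    fit@details$clamped <- TRUE
  }
  fit
}

#' Nested-model F-test between sedimentation fits
#'
#' Standard extra-sum-of-squares test:
#' \eqn{F = [(RSS_r - RSS_f)/(p_f - p_r)] / [RSS_f/(n - p_f)]}, with the
#' p-value from the F distribution on \eqn{(p_f - p_r, n - p_f)} degrees of
#' freedom. Both fits must be on identical data with the reduced model nested
#' in the full one.
#'
#' @param fit_full,fit_reduced \linkS4class{SedFit} objects on the same data.
#' @return List with \code{f_statistic}, \code{df1}, \code{df2},
#'   \code{p_value}. If \eqn{RSS_f > RSS_r} (an optimizer-failure signal),
#'   returns \code{F = 0, p = 1} with a warning.
#' @export
nestedFTest <- function(fit_full, fit_reduced) {
  if (fit_full@nPoints != fit_reduced@nPoints)
    stop("fits are not on the same data (nPoints differ)", call. = FALSE)
  df1 <- fit_full@nParams - fit_reduced@nParams
  df2 <- fit_full@nPoints - fit_full@nParams
  if (df1 < 0) stop("full model has fewer parameters than reduced",
                    call. = FALSE)
  if (df1 == 0 || fit_full@rss > fit_reduced@rss + 1e-12) {
    if (fit_full@rss > fit_reduced@rss + 1e-12)
      warning("full-model RSS exceeds reduced-model RSS; returning F = 0")
    return(list(f_statistic = 0, df1 = max(df1, 0L), df2 = df2, p_value = 1))
  }
  f <- ((fit_reduced@rss - fit_full@rss) / df1) / (fit_full@rss / df2)
  list(f_statistic = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Effective size multiple implied by a pSup change
#'
#' Under the mass-only model (pelleting proportional to mass\eqn{^\chi}), a
#' transcript whose pSup drops from \code{psup_control} to
#' \code{psup_treated} sediments as if its mass were multiplied by
#' \eqn{k = [(1 - pSup_t)/(1 - pSup_c)]^{1/\chi}}.
#'
#' @param psup_control,psup_treated pSup values in (0, 1).
#' @param chi Power-law exponent (> 0).
#' @return The mass multiple \eqn{k} (below 1 indicates dissolution).
#' @examples
#' effectiveSizeRatio(0.9, 0.7, chi = 1)   # 3
#' @export
effectiveSizeRatio <- function(psup_control, psup_treated, chi) {
  if (any(psup_control <= 0 | psup_control >= 1) ||
      any(psup_treated <= 0 | psup_treated >= 1))
    stop("pSup values must lie strictly in (0, 1)", call. = FALSE)
  stopifnot_scalar(chi, "chi", positive = TRUE)
  ((1 - psup_treated) / (1 - psup_control))^(1 / chi)
}

#' Component masses for mRNP mass arithmetic
#'
#' @param ribosome_mass_mda Mass of one ribosome (MDa; default 3.3).
#' @param nt_mass_kda Mass per RNA nucleotide (kDa; default 0.30).
#' @param protein_mass_kda Mass of one RNA-binding protein (kDa; default 65,
#'   the poly(A)-binding protein).
#' @return Named list of masses.
#' @export
massModelParams <- function(ribosome_mass_mda = 3.3, nt_mass_kda = 0.30,
                            protein_mass_kda = 65) {
  if (ribosome_mass_mda <= 0 || nt_mass_kda <= 0 || protein_mass_kda <= 0)
    stop("all masses must be positive", call. = FALSE)
  list(ribosome_mass_mda = ribosome_mass_mda, nt_mass_kda = nt_mass_kda,
       protein_mass_kda = protein_mass_kda)
}

#' Mass of an mRNP carrying a given ribosome load
#'
#' @param n_ribosomes Number of bound ribosomes (>= 0).
#' @param length_nt Transcript length (nt, >= 0).
#' @param params \code{\link{massModelParams}}.
#' @return Mass in MDa.
#' @examples
#' mrnpMass(5, 1800)   # a five-ribosome polysome on a 1.8 kb mRNA, ~17 MDa
#' mrnpMass(0, 1800)   # the bare 1.8 kb mRNA, ~0.54 MDa
#' @export
mrnpMass <- function(n_ribosomes, length_nt, params = massModelParams()) {
  if (any(n_ribosomes < 0) || any(length_nt < 0))
    stop("'n_ribosomes' and 'length_nt' must be non-negative", call. = FALSE)
  n_ribosomes * params$ribosome_mass_mda +
    length_nt * params$nt_mass_kda / 1000
}

#' Protein spacing needed to reach a target mRNP mass
#'
#' How often an RNA-binding protein would have to bind along a transcript for
#' the mRNP to reach \code{target_mass_mda} by protein binding alone.
#'
#' @param target_mass_mda Target mRNP mass (MDa); must exceed the bare mRNA
#'   mass.
#' @param length_nt Transcript length (nt).
#' @param params \code{\link{massModelParams}}.
#' @return Spacing in nucleotides per bound protein.
#' @examples
#' proteinSpacing(17, 1800)   # ~7 nt per 65 kDa protein: unphysical
#' @export
proteinSpacing <- function(target_mass_mda, length_nt,
                           params = massModelParams()) {
  mrna <- length_nt * params$nt_mass_kda / 1000
  if (target_mass_mda <= mrna)
    stop("target mass must exceed the bare mRNA mass", call. = FALSE)
  n_proteins <- (target_mass_mda - mrna) / (params$protein_mass_kda / 1000)
  length_nt / n_proteins
}
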