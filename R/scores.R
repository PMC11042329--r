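## Length-controlled condensation statistics: log-odds pSup, sliding-window
## means/SDs over log length, differential sedimentation (deltaSed), escape
## (eSed), and the length-binned relative sedimentation z-score
## (sedScore / rSed).

#' Log-odds of pSup
#'
#' Natural-log odds \eqn{\ln(p/(1-p))}, after clamping pSup into
#' \eqn{[\epsilon, 1-\epsilon]} so that estimates of exactly 0 or 1 stay
#' finite.
#'
#' @param psup Numeric vector in [0, 1].
#' @param eps Clamping bound (default 1e-4).
#' @return Numeric vector of log-odds values.
#' @examples
#' logOdds(0.5)        # 0
#' logOdds(0.9)        # log(9)
#' @export
logOdds <- function(psup, eps = 1e-4) {
  if (any(!is.finite(psup)) || any(psup < 0 | psup > 1))
    stop("'psup' values must lie in [0, 1]", call. = FALSE)
  p <- clamp(psup, eps, 1 - eps)
  log(p / (1 - p))
}

#' Sliding-window mean and SD of log-odds pSup over log length
#'
#' For each transcript of length L, computes the mean and SD of \code{lopsup}
#' over all transcripts whose log length lies within a window of width
#' \code{window_fraction} of the full log-length range, centered on log L
#' (the focal transcript included). Windows holding fewer than 3 transcripts
#' are widened to the 3 nearest log-length neighbours.
#'
#' @param lopsup Numeric vector of log-odds pSup values.
#' @param length_nt Matching transcript lengths (nt).
#' @param window_fraction Window width as a fraction of the log-length range
#'   (default 0.02).
#' @return Data.frame with \code{mu_L}, \code{sigma_L} and \code{n_window},
#'   in input order.
#' @examples
#' ws <- windowedStats(rnorm(50), exp(runif(50, log(200), log(10000))))
#' head(ws)
#' @export
windowedStats <- function(lopsup, length_nt, window_fraction = 0.02) {
  n <- length(lopsup)
  if (n < 10) stop("need at least 10 transcripts", call. = FALSE)
  if (length(length_nt) != n)
    stop("'lopsup' and 'length_nt' lengths differ", call. = FALSE)
  logL <- log(length_nt)
  half <- window_fraction * (max(logL) - min(logL)) / 2
  ord <- order(logL)
  sL <- logL[ord]; sv <- lopsup[ord]
  cs <- cumsum(sv); cs2 <- cumsum(sv^2)
  lo <- findInterval(sL - half, sL, left.open = TRUE) + 1L
  hi <- findInterval(sL + half, sL)
  mu <- sig <- nw <- numeric(n)
  widened <- 0L
  for (k in seq_len(n)) {
    a <- lo[k]; b <- hi[k]
    if (b - a + 1L < 3L) {
      ## widen to the 3 nearest neighbours in log length (incl. focal)
      widened <- widened + 1L
      d <- abs(sL - sL[k])
      idx <- order(d)[1:3]
      a <- min(idx); b <- max(idx)
    }
    m <- b - a + 1L
    s1 <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    mu[k] <- s1 / m
    v <- (s2 - s1^2 / m) / (m - 1)
    sig[k] <- sqrt(max(v, 0))
    nw[k] <- m
  }
  if (widened > 0)
    message(widened, " window(s) widened to the nearest 3 neighbours")
  out <- data.frame(mu_L = mu, sigma_L = sig, n_window = nw)
  out <- out[order(ord), , drop = FALSE]   # back to input order
  rownames(out) <- NULL
  out
}

## Assemble one condition's score table (lopSup + windowed stats).
.condition_scores <- function(psup_df, condition, window_fraction = 0.02,
                              eps = 1e-4) {
  need <- c("transcript_id", "psup", "length_nt")
  if (!all(need %in% names(psup_df)))
    stop("pSup table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lop <- logOdds(psup_df$psup, eps = eps)
  ws <- windowedStats(lop, psup_df$length_nt, window_fraction)
  data.frame(transcript_id = psup_df$transcript_id,
             condition = condition,
             lopSup = lop, mu_L = ws$mu_L, sigma_L = ws$sigma_L,
             length_nt = psup_df$length_nt,
             stringsAsFactors = FALSE)
}

#' Build a per-condition score table
#'
#' Computes log-odds pSup and the sliding-window mean/SD over log length for
#' one condition.
#'
#' @param psup_df Data.frame with \code{transcript_id}, \code{psup},
#'   \code{length_nt} (e.g. from \code{\link{computePSup}} joined to lengths).
#' @param condition Condition label.
#' @param window_fraction Window width on the log-length scale (default 0.02).
#' @param eps pSup clamping bound before the log-odds transform.
#' @return Data.frame with \code{transcript_id}, \code{condition},
#'   \code{lopSup}, \code{mu_L}, \code{sigma_L}, \code{length_nt}.
#' @export
scoreTable <- function(psup_df, condition = "cond",
                       window_fraction = 0.02, eps = 1e-4)
  .condition_scores(psup_df, condition, window_fraction, eps)

## Residual SD of the control: SD over transcripts of (lopSup - mu_L).
.sigma_control <- function(control) stats::sd(control$lopSup - control$mu_L)

.match_conditions <- function(control, treated) {
  ids <- intersect(control$transcript_id, treated$transcript_id)
  dropped <- length(unique(c(control$transcript_id,
                             treated$transcript_id))) - length(ids)
  if (dropped > 0)
    message(dropped, " transcript(s) absent from one condition dropped")
  list(control = control[match(ids, control$transcript_id), ],
       treated = treated[match(ids, treated$transcript_id), ],
       ids = ids)
}

#' Differential sedimentation score (deltaSed)
#'
#' \eqn{\Delta Sed = (lopSup_{control} - lopSup_{treated}) / \sigma_{control}},
#' where \eqn{\sigma_{control}} is the SD over all transcripts of the
#' control's residual from its length-windowed mean. Positive values indicate
#' stress-induced sedimentation (condensation).
#'
#' @param control,treated Score tables from \code{\link{scoreTable}} for the
#'   control and treated conditions. Transcripts missing from either are
#'   dropped.
#' @return Data.frame with \code{transcript_id}, \code{delta_sed},
#'   \code{length_nt}.
#' @export
deltaSed <- function(control, treated) {
  m <- .match_conditions(control, treated)
  s0 <- .sigma_control(control)
  data.frame(transcript_id = m$ids,
             delta_sed = (m$control$lopSup - m$treated$lopSup) / s0,
             length_nt = m$control$length_nt,
             stringsAsFactors = FALSE)
}

#' Escape-from-sedimentation score (eSed)
#'
#' \eqn{eSed = [(lopSup_T - \mu_{L,T}) - (lopSup_{control} -
#' \mu_{L,control})] / \sigma_{control}}: how much less (positive) or more
#' (negative) a transcript sediments under treatment than same-length
#' transcripts, relative to its own control behaviour. The denominator is the
#' control's global residual SD, not the windowed SD.
#'
#' @inheritParams deltaSed
#' @return Data.frame with \code{transcript_id}, \code{e_sed},
#'   \code{length_nt}.
#' @export
escapeSed <- function(control, treated) {
  m <- .match_conditions(control, treated)
  s0 <- .sigma_control(control)
  e <- ((m$treated$lopSup - m$treated$mu_L) -
        (m$control$lopSup - m$control$mu_L)) / s0
  data.frame(transcript_id = m$ids, e_sed = e,
             length_nt = m$control$length_nt, stringsAsFactors = FALSE)
}

## Binned z-scores for one replicate: sort by length, consecutive bins of
## bin_size (final partial bin merged into its predecessor), z within bin.
.binned_z <- function(psup_df, bin_size, eps) {
  n <- nrow(psup_df)
  lop <- logOdds(psup_df$psup, eps = eps)
  ord <- order(psup_df$length_nt)
  n_bins <- max(n %/% bin_size, 1L)
  bin <- pmin((seq_len(n) - 1L) %/% bin_size + 1L, n_bins)
  z <- numeric(n)
  for (b in seq_len(n_bins)) {
    idx <- ord[bin == b]
    v <- lop[idx]
    s <- stats::sd(v)
    z[idx] <- if (!is.finite(s) || s == 0) 0 else (v - mean(v)) / s
  }
  stats::setNames(z, psup_df$transcript_id)
}

#' Length-relative sedimentation z-score (sedScore / rSed)
#'
#' Per replicate, transcripts are sorted by length (including UTRs) and
#' partitioned into consecutive bins of \code{bin_size}; within each bin the
#' log-odds pSup is z-scored. The final partial bin is merged into its
#' predecessor. Scores are averaged across replicates. High rSed = sediments
#' more than similar-length transcripts.
#'
#' @param psup_replicates A data.frame (one replicate) or list of data.frames,
#'   each with \code{transcript_id}, \code{psup}, \code{length_nt}.
#' @param bin_size Transcripts per length bin (default 100). With fewer
#'   transcripts than \code{bin_size} a single bin is used (with a message).
#' @param eps pSup clamping bound before the log-odds transform.
#' @return Data.frame with \code{transcript_id}, \code{r_sed}.
#' @examples
#' cat <- makeCatalog(250, seed = 6)
#' ps <- simulateTruePSup(cat, conditionSpec("mock"), seed = 6)
#' rs <- sedScore(data.frame(transcript_id = cat$transcript_id, psup = ps,
#'                           length_nt = cat$length_nt))
#' head(rs)
#' @export
sedScore <- function(psup_replicates, bin_size = 100, eps = 1e-4) {
  if (is.data.frame(psup_replicates))
    psup_replicates <- list(psup_replicates)
  if (any(vapply(psup_replicates, nrow, 1L) < bin_size))
    message("fewer transcripts than bin_size in some replicate; ",
            "using a single bin")
  zs <- lapply(psup_replicates, .binned_z, bin_size = bin_size, eps = eps)
  ids <- Reduce(intersect, lapply(zs, names))
  zmat <- vapply(zs, function(z) z[ids], numeric(length(ids)))
  zmat <- matrix(zmat, nrow = length(ids))
  data.frame(transcript_id = ids, r_sed = rowMeans(zmat),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full score table for a control/treated pair
#'
#' Convenience wrapper assembling, per transcript, the log-odds pSup, windowed
#' mean/SD, deltaSed, eSed and the within-condition rSed of the treated
#' condition.
#'
#' @param control_psup,treated_psup pSup data.frames (\code{transcript_id},
#'   \code{psup}, \code{length_nt}).
#' @param condition Label for the treated condition.
#' @param window_fraction,bin_size,eps See \code{\link{scoreTable}} and
#'   \code{\link{sedScore}}.
#' @return A per-transcript score table (one row per transcript present in
#'   both conditions).
#' @export
condensationScores <- function(control_psup, treated_psup,
                               condition = "treated",
                               window_fraction = 0.02, bin_size = 100,
                               eps = 1e-4) {
  ctrl <- scoreTable(control_psup, "control", window_fraction, eps)
  trt <- scoreTable(treated_psup, condition, window_fraction, eps)
  ds <- deltaSed(ctrl, trt)
  es <- escapeSed(ctrl, trt)
  rs <- sedScore(treated_psup, bin_size = bin_size, eps = eps)
  m <- .match_conditions(ctrl, trt)
  out <- data.frame(
    transcript_id = m$ids,
    condition = condition,
    lopSup = m$treated$lopSup,
    mu_L = m$treated$mu_L,
    sigma_L = m$treated$sigma_L,
    delta_sed = ds$delta_sed[match(m$ids, ds$transcript_id)],
    e_sed = es$e_sed[match(m$ids, es$transcript_id)],
    r_sed = rs$r_sed[match(m$ids, rs$transcript_id)],
    length_nt = m$treated$length_nt,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
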