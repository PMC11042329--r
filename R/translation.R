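## Spike-in anchored translation metrics: absolute ribosome occupancy from
## free/bound fractions, ribosome association, the EDTA-corrected sucrose
## cushion occupancy, and the length-normalized 5' UTR structure score.

#' Spike-in normalize fraction abundances
#'
#' Divides every transcript's abundance within each fraction by the median
#' abundance of the spike-in transcripts in that fraction (spikes must exceed
#' a count filter to qualify), putting all fractions on a common absolute
#' scale anchored by the fixed spike mass added per fraction.
#'
#' @param abundances Data.frame with columns \code{transcript_id},
#'   \code{fraction}, \code{tpm}, \code{is_spike} and optionally
#'   \code{est_counts} (e.g. from \code{\link{simulatePolysome}} or a
#'   quantifier's TPM table joined to a spike-id list).
#' @param min_spike_counts Spikes must have more than this many estimated
#'   counts to be used (default 100; ignored when \code{est_counts} absent).
#' @param min_spikes Minimum number of qualifying spikes per fraction
#'   (default 3).
#' @return The input with a \code{norm_abundance} column; the per-fraction
#'   spike medians are attached as \code{attr(, "spike_median")}.
#' @export
spikeinNormalize <- function(abundances, min_spike_counts = 100,
                             min_spikes = 3) {
  need <- c("transcript_id", "fraction", "tpm", "is_spike")
  if (!all(need %in% names(abundances)))
    stop("abundance table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sp <- abundances[abundances$is_spike, ]
  if ("est_counts" %in% names(sp))
    sp <- sp[sp$est_counts > min_spike_counts, ]
  med <- tapply(sp$tpm, sp$fraction, stats::median)
  fr <- unique(abundances$fraction)
  n_ok <- table(factor(sp$fraction, levels = fr))
  if (any(n_ok < min_spikes) || any(!fr %in% names(med)))
    stop("fewer than ", min_spikes, " qualifying spike transcripts in some ",
         "fraction", call. = FALSE)
  abundances$norm_abundance <-
    abundances$tpm / as.numeric(med[abundances$fraction])
  attr(abundances, "spike_median") <- med
  abundances
}

#' Absolute ribosome occupancy from normalized free/bound abundances
#'
#' \eqn{occ = bound / (bound + free)}: the fraction of a transcript's
#' molecules bound by at least one ribosome. Inputs must already be on a
#' common scale (see \code{\link{spikeinNormalize}}). Transcripts with zero
#' abundance in both fractions are dropped.
#'
#' @param normalized Data.frame with a \code{norm_abundance} column and
#'   fractions \code{"free"} and \code{"bound"}; spikes are excluded.
#' @return Data.frame with \code{transcript_id}, \code{occupancy}.
#' @export
ribosomeOccupancy <- function(normalized) {
  d <- normalized[!normalized$is_spike &
                    normalized$fraction %in% c("free", "bound"), ]
  free <- d[d$fraction == "free", ]
  bound <- d[d$fraction == "bound", ]
  ids <- intersect(free$transcript_id, bound$transcript_id)
  f <- free$norm_abundance[match(ids, free$transcript_id)]
  b <- bound$norm_abundance[match(ids, bound$transcript_id)]
  keep <- (f + b) > 0
  if (any(!keep))
    message(sum(!keep), " transcript(s) with zero free + bound dropped")
  data.frame(transcript_id = ids[keep], occupancy = b[keep] / (f + b)[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ribosome association score
#'
#' \eqn{bound / total} on the TPM scale, the translation metric used when
#' condensed RNA may pellet out of a gradient and absolute occupancy cannot be
#' computed. Changes between conditions are reported as log2 ratios with a
#' pseudocount.
#'
#' @param total_tpm,bound_tpm Named numeric vectors (names = transcript ids).
#' @param pseudocount Added to both terms of a change ratio (default 0.5 TPM);
#'   not used for the score itself.
#' @return Data.frame with \code{transcript_id}, \code{association}.
#'   Transcripts with zero total TPM are dropped.
#' @export
ribosomeAssociation <- function(total_tpm, bound_tpm, pseudocount = 0.5) {
  ids <- intersect(names(total_tpm), names(bound_tpm))
  tt <- total_tpm[ids]; bb <- bound_tpm[ids]
  keep <- tt > 0
  if (any(!keep))
    message(sum(!keep), " transcript(s) with zero total TPM dropped")
  data.frame(transcript_id = ids[keep],
             association = as.numeric(bb[keep] / tt[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Change in ribosome association between conditions
#'
#' @param assoc_control,assoc_treated Association tables from
#'   \code{\link{ribosomeAssociation}}.
#' @param pseudocount Stabilizing constant added to both ratios (default 0.5).
#' @return Data.frame with \code{transcript_id}, \code{log2_change}.
#' @export
associationChange <- function(assoc_control, assoc_treated,
                              pseudocount = 0.5) {
  ids <- intersect(assoc_control$transcript_id, assoc_treated$transcript_id)
  a0 <- assoc_control$association[match(ids, assoc_control$transcript_id)]
  a1 <- assoc_treated$association[match(ids, assoc_treated$transcript_id)]
  data.frame(transcript_id = ids,
             log2_change = log2((a1 + pseudocount) / (a0 + pseudocount)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' EDTA-corrected sucrose-cushion ribosome occupancy
#'
#' EDTA dissolves ribosomes, so pelleting that persists in EDTA is condensate,
#' not polysome. The EDTA-sensitive share of pelleting, conditional on the
#' material not being condensate, is the occupancy:
#' \eqn{occ = (p_{+} - p_{EDTA}) / (1 - p_{EDTA})}, clamped to [0, 1]. A
#' simple-subtraction mode (\eqn{p_{+} - p_{EDTA}}) is available.
#'
#' @param pellet_frac_plus Pelleted fraction without EDTA, in [0, 1].
#' @param pellet_frac_edta Pelleted fraction with EDTA, in [0, 1].
#' @param mode \code{"conditional"} (default) or \code{"subtract"}.
#' @return Occupancy in [0, 1]; \code{NA} (with a warning) where
#'   \code{pellet_frac_edta = 1}.
#' @examples
#' cushionOccupancy(0.8, 0.5)   # 0.6
#' @export
cushionOccupancy <- function(pellet_frac_plus, pellet_frac_edta,
                             mode = c("conditional", "subtract")) {
  mode <- match.arg(mode)
  if (any(pellet_frac_plus < 0 | pellet_frac_plus > 1) ||
      any(pellet_frac_edta < 0 | pellet_frac_edta > 1))
    stop("pelleted fractions must lie in [0, 1]", call. = FALSE)
  if (mode == "subtract")
    return(clamp(pellet_frac_plus - pellet_frac_edta, 0, 1))
  out <- (pellet_frac_plus - pellet_frac_edta) / (1 - pellet_frac_edta)
  bad <- pellet_frac_edta == 1
  if (any(bad)) {
    warning("pellet_frac_edta = 1: occupancy undefined, returning NA")
    out[bad] <- NA_real_
  }
  clamp(out, 0, 1)
}

#' Length-normalized 5' UTR structure score
#'
#' Folding free energy divided by UTR length, removing the direct correlation
#' of free energy with length. More negative scores mean more structure per
#' nucleotide. Free energies are consumed from an external folding engine.
#'
#' @param delta_g Folding free energy (kcal/mol, typically <= 0).
#' @param utr5_length_nt 5' UTR length (nt). Zero-length UTRs fall back to
#'   \code{default_utr_length} (with a message).
#' @param default_utr_length Fallback UTR length (nt; default 50, a typical
#'   yeast median).
#' @return Score in kcal/mol/nt.
#' @examples
#' structureScore(-30, 100)   # -0.3
#' @export
structureScore <- function(delta_g, utr5_length_nt, default_utr_length = 50) {
  if (any(utr5_length_nt < 0))
    stop("'utr5_length_nt' must be non-negative", call. = FALSE)
  zero <- utr5_length_nt == 0
  if (any(zero)) {
    message(sum(zero), " zero-length UTR(s): using the default UTR length (",
            default_utr_length, " nt)")
    utr5_length_nt[zero] <- default_utr_length
  }
  delta_g / utr5_length_nt
}
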