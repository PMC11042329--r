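---
title: "Quantifying mRNA condensation from sedimentation fractionation data"
author: "sedseq package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mRNA condensation from sedimentation fractionation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedseq)
```

## The measurement and the model

Sedimentation fractionation coupled to RNA sequencing (Sed-seq) measures
mRNP condensation in budding yeast. A lysate is split into a Total sample
and, after centrifugation, Supernatant and Pellet samples; all three are
sequenced. For transcript $i$, the proportion of molecules remaining in the
supernatant,

$$ pSup_i = \frac{\alpha_S S_i}{\alpha_S S_i + \alpha_P P_i}, $$

is the core readout: condensed mRNPs pellet, so a drop in pSup under stress
indicates condensation. The per-experiment mixing ratios $(\alpha_S,
\alpha_P)$ restore conservation of mass $T_i = \alpha_S S_i + \alpha_P P_i$,
which holds in the lysate but not in the sequenced libraries (each fraction
is processed, amplified and sequenced at its own effective depth).

### Estimating the mixing ratios

`estimateMixingRatios()` places the model on all transcripts exceeding 20
counts in all three fractions, with Gamma(1,1) priors on the ratios and a
half-Cauchy(0,3) prior on the noise scale. Two likelihood readings are
implemented:

* **`model = "eiv"` (default).** Conservation of mass constrains the *true*
  amounts, but every measured count — including $S_i$ and $P_i$ — is noisy
  (negative-binomially distributed around its expectation, shared dispersion
  $\phi$). Treating this honestly is an errors-in-variables problem: for each
  transcript the latent true supernatant and pellet amounts are profiled out
  by an inner Newton maximization (vectorized across transcripts), and
  $(\alpha_S, \alpha_P, \phi)$ maximize the resulting profile posterior. The
  reported dispersion divides the raw profile estimate by 3: profiling two
  latent amounts out of three observations leaves one residual dimension per
  transcript, which inflates the apparent NB size by that factor.
* **`model = "regression"`.** The display-style reading
  $T_i \sim \mathrm{NB}(\alpha_S S_i + \alpha_P P_i, \phi)$ with $S_i, P_i$
  as fixed covariates. This is simpler but attenuated: because most
  transcripts have similar pSup, the two covariates are nearly collinear, and
  even 10% multiplicative noise in $S$ and $P$ biases the fitted ratio
  substantially; the test suite verifies the attenuation by direct
  comparison with the errors-in-variables fit on the same simulated
  experiment. The regression reading is retained for comparison and for
  data where the fractions can be regarded as noise-free.

Only the ratio $\alpha_S/\alpha_P$ is identifiable up to the relative depths
of the libraries, and only the ratio matters for pSup. The MAP backend is
deterministic; `method = "MCMC"` runs adaptive random-walk Metropolis chains
whose proposal is shaped by the curvature at the mode (the posterior is a
narrow ridge in the two log-ratios), reporting split-R-hat and acceptance
rates. On well-conditioned data the two backends agree to well under 2% on
the ratio.

### Length-controlled condensation scores

All scores operate on the natural-log odds of pSup (`logOdds()`), which
undoes compression near 0 and 1. pSup estimates of exactly 0 or 1 (a
transcript absent from one fraction) are clamped at $\epsilon = 10^{-4}$
before the transform so scores stay finite; the handling of these boundary
values is a package decision, documented here because upstream descriptions
leave it open.

Long transcripts sediment more in every condition, so condensation must be
scored against length-matched expectation:

* `windowedStats()` computes, for each transcript, the mean $\mu_L$ and SD
  $\sigma_L$ of log-odds pSup over all transcripts within a sliding window
  in log length; the window width is 0.02 of the full log-length range, and
  windows are centred on each transcript (not tiled). Windows holding fewer
  than three transcripts widen to the three nearest neighbours.
* `deltaSed()` scores the stress-induced drop,
  $(lopSup_{ctrl} - lopSup_{trt}) / \sigma_{ctrl}$, where $\sigma_{ctrl}$
  is the SD of the control's residuals from its windowed mean.
* `escapeSed()` scores escape relative to same-length transcripts:
  $[(lopSup_{trt} - \mu_{L,trt}) - (lopSup_{ctrl} - \mu_{L,ctrl})] /
  \sigma_{ctrl}$. The denominator is deliberately the *global* control
  residual SD, not the windowed $\sigma_L$ (which is computed and reported
  but not used as the scale).
* `sedScore()` is the within-condition, length-relative z-score (rSed):
  transcripts sorted by length, partitioned into consecutive bins of 100,
  z-scored within bins, averaged across replicates. The final partial bin is
  merged into its predecessor — remainder handling is unspecified upstream,
  and merging backward avoids a small-noisy tail bin. When replicates are
  supplied, the z-transform is applied per replicate and then averaged;
  applying it to replicate-averaged pSup instead changes scores negligibly
  on our simulations but the per-replicate order is the one implemented.

The sliding-window z and the binned rSed rank transcripts almost identically
(Spearman $\rho > 0.95$ at 5000 transcripts); the binned form is the one
reported, with the windowed variant available for sensitivity analysis.

### The biophysical sedimentation model

In unstressed cells the probability of pelleting is modelled as a power law
in transcript mass (equivalently length): $pSup(L) = 1 - \beta L^\chi$. A
condensation-inducing treatment multiplies the pelleted fraction by
$e^{\mu + \nu L}$, with a per-molecule term $\mu$ (e.g. interactions at the
5′ or 3′ end) and a per-nucleotide term $\nu$. Fits minimize squared error
on the log-odds pSup scale (`fitBaseline()`, `fitStress()`), with
multi-start over a log-spaced $\beta$ grid plus a linearized start obtained
by regressing the log pelleted fraction on log-length (and, for stress
fits, the treatment indicator and $L$). Convergence tolerances are $10^{-13}$
relative on the RSS; predicted pelleted fractions are clamped just below 1
and flagged when the clamp engages. The exponential factor's sign convention
is chosen so that $\mu, \nu \ge 0$ increase pelleting under stress.

`fitStress()` fits $(\beta, \chi)$ jointly with the condensation terms on the
stacked control + treated data by default; whether the original analyses
shared the baseline across treatments or re-fit it per treatment is not
stated in the available material, so both modes exist
(`share_baseline = FALSE` fixes the baseline from a control-only fit).

`nestedFTest()` compares nested fits by the extra-sum-of-squares F statistic.
The headline comparison drops the per-molecule (length-independent) term,
i.e. full $(\beta, \chi, \mu, \nu)$ against $\nu$-only. On simulated null
data the test holds its nominal 5% level (the acceptance script measures
the rejection rate over 1000 replicates), and it detects a true per-molecule effect with power > 0.95 at
100 length points and noise SD 0.2.

`effectiveSizeRatio()` converts a pSup change into the implied mass multiple
$k = [(1-pSup_{trt})/(1-pSup_{ctrl})]^{1/\chi}$ under the mass-only model,
and `mrnpMass()` / `proteinSpacing()` implement the polysome-scale mass
arithmetic (ribosome 3.3 MDa; 0.30 kDa per nucleotide, which reproduces the
1.8 kb $\to$ 0.54 MDa conversion exactly; RNA-binding protein 65 kDa).

### Translation metrics

Polysome fractionation with a fixed mass of foreign-species spike-in RNA per
pooled fraction anchors absolute comparisons across fractions:
`spikeinNormalize()` divides every transcript's abundance by the median
spike abundance of its fraction (spikes must exceed 100 estimated counts).
Ribosome occupancy is then $bound/(bound+free)$; ribosome association, used
when condensed RNA may pellet out of the gradient, is $bound/total$ on the
TPM scale, with condition changes reported as log2 ratios with a 0.5 TPM
pseudocount (a package choice; upstream shrinkage-based differential
pipelines are out of scope). The sucrose-cushion occupancy corrects for
condensate pelleting that persists in EDTA:
$occ = (p_{+} - p_{EDTA})/(1 - p_{EDTA})$, which maps EDTA-resistant
pelleting to zero occupancy and stays in $[0,1]$; the exact correction
formula is not written out in the upstream description, and a
simple-subtraction mode is provided for comparison. The 5′ UTR structure
score divides a precomputed folding free energy by UTR length (folding
itself is out of scope); zero-length UTRs fall back to a 50 nt default, a
typical yeast median.

### smFISH colocalization

`cellZscore()` compares granule-marker intensity at RNA spot centroids
(mean of a 3×3 pixel box) against 100 random positions drawn uniformly with
replacement over the cell mask, as
$z = (\bar I_{spots} - \bar I_{rand}) / SD(I_{rand})$, independently per
cell so that cell-to-cell background differences cancel. Boxes crossing the
cell boundary use the full image neighbourhood (sampling is of locations,
not masked pixels), boxes crossing the image edge are clipped, and random
sampling covers the whole mask (no nuclear exclusion — whether the original
measurement excluded nuclei is not stated). A flat marker yields $z = 0$
with a warning. The population score is the arithmetic mean of per-cell
z-scores; conditions are compared by pairwise Welch t-tests with Holm
correction.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed (each
function salts the seed internally, so passing the same integer to different
generators does not alias their random streams).

* **Catalogs** (`makeCatalog()`): lengths log-normal with median 1.3 kb and
  log-SD 0.6, clipped to 200–15000 nt — spanning short yeast transcripts up
  to beyond the heaviest detected unstressed mRNP (the 12.4 kb dynein
  transcript); abundances log-normal (log-SD 1.2) summing to $10^6$;
  regulon labels drawn at configurable proportions.
* **True pSup** (`simulateTruePSup()`): the biophysical model above with
  defaults $\beta = 2\times10^{-4}$, $\chi = 0.8$ (median-length pSup
  $\approx 0.94$ unstressed, long-transcript pSup $\approx 0.6$ — the
  qualitative pattern of unstressed cells). Transcript-level scatter is
  added on the log-odds scale (`gene_noise_sd`, default 0.35): the scores
  and fits operate on log-odds, so gene-level biological scatter is most
  natural there. No target value for this scatter is published; 0.35 gives
  control-condition residual SDs of realistic magnitude (clearly nonzero,
  small relative to stress effects) and is fixed once here, not tuned.
  Regulon escape effects add on log-odds; induction multiplies abundance.
* **Counts** (`simulateFractionCounts()`): expectations split the latent
  totals by true pSup and divide by the true mixing ratios; all three
  fractions draw NB counts with one shared dispersion (a single $\phi$ is
  assumed throughout; per-fraction dispersions are not modelled).
* **Polysome tables** (`simulatePolysome()`): Free:Bound splits follow a
  supplied occupancy; spikes receive identical expected abundance per
  fraction (emulating 50 ng of foreign total RNA per pooled fraction);
  per-fraction lognormal scale distortions (SD 0.3 — arbitrary but
  documented; what is tested is their recoverability) multiply spikes and
  cellular transcripts alike, plus per-entry lognormal measurement noise (SD 0.01, the repeatability
  scale of quantifier TPM estimates for well-covered transcripts; the
  spike-median normalizer inherits the middle spike's noise rather than
  averaging over spikes, so recoverability of the distortions is governed
  by this value).
* **qPCR plates** (`simulateCqTable()`): Cq values consistent with given
  pSup, spike amounts (1 ng pellet / 0.1 ng supernatant by default) and a
  10× pellet concentration, at amplification efficiency 2.
* **Image fields** (`simulateFishField()`): single-plane two-channel fields
  of circular cells with per-cell backgrounds, 1–3 bright granule blobs, and
  Gaussian spots placed uniformly (enrichment 0) or weighted
  $1 + e$ inside granule footprints. The colocalization statistic uses only
  centroid neighbourhoods, which a 2-D field exercises fully; no 3-D optics
  are modelled.

What passing tests on these data do show: the estimators are unbiased and
calibrated under the statistical structure the analysis assumes (NB counts,
log-odds-scale scatter, power-law length dependence, fraction-scale
distortions). What they do not show: robustness to features of real data
the generators omit — UMI/alignment artifacts, transcript-specific
dispersions, spatially structured image noise, segmentation errors, or
departures of real sedimentation from the power-law form. Real-data
headline statistics (the published F values, the occupancy–rSed
correlation, named-transcript rSed values) require the deposited dataset
and are deliberately not asserted by the test suite.

## Problem sizes and numerical choices

The test suite and acceptance script use: 1000 null replicates and 100
power replicates for F-test calibration (100 length points each); 20 seeds
of 5000-transcript, depth-$10^7$ experiments for mixing-ratio/pSup recovery
(dispersion 100, $\alpha_S/\alpha_P = 4$); 250-transcript tables for exact
brute-force oracle comparisons; 3000-transcript experiments for directional
checks; and 50-cell fields for colocalization. These sizes were chosen so
each property is measured with comfortable statistical margin while the
whole suite runs in minutes on one CPU.

Degenerate inputs are handled explicitly rather than silently: zero
supernatant + pellet rows are dropped with a message; windows with fewer
than three transcripts widen; bins with zero SD return z = 0; a flat marker
returns z = 0 with a warning; a full-model RSS above a reduced-model RSS
(an optimizer failure signal) yields F = 0 with a warning rather than a
negative statistic.

## A compact end-to-end run

```{r, eval = FALSE}
cfg <- demoConfig(seed = 1, outdir = tempfile("sedseq_"))
man <- runPipeline(cfg)
# counts -> pSup -> scores -> model fits -> occupancy -> colocalization,
# with a JSON manifest of every product and its hash
```

## Known limitations

* The mixing-ratio model profiles latent amounts rather than integrating
  them; the dispersion therefore carries a degrees-of-freedom correction
  and is the least precisely estimated of the three parameters.
* The mass model is phenomenological: no hydrodynamics (rotor geometry,
  viscosity, particle shape) is modelled, and deviations for the longest
  transcripts are expected and not corrected.
* Association changes use plain pseudocounted log2 ratios; no shrinkage.
* The colocalization statistic assumes spot coordinates are given; spot
  detection on real micrographs is out of scope.
* The per-cell colocalization z carries a small positive small-sample bias
  (of order skewness / n_random, measured around +0.07 on granule-bearing
  textures) because the denominator is the SD of only 100 random samples
  correlated with their mean; this is intrinsic to the statistic as defined
  and is negligible against the per-cell noise and the enrichment signal.
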