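## Per-cell smFISH colocalization: compare granule-marker intensity at RNA
## spot centroids against random in-cell positions, as a z-score computed
## independently per cell so cell-to-cell background differences cancel.

#' Mean marker intensity in a square neighbourhood
#'
#' Mean of the \code{box} x \code{box} pixel neighbourhood around a centroid.
#' Boxes crossing the image edge are clipped to the image (the remaining
#' pixels are averaged); boxes crossing a cell boundary still use the full
#' image neighbourhood.
#'
#' @param image Numeric matrix (rows = y, cols = x).
#' @param y,x Centroid pixel coordinates (1-based).
#' @param box Odd box side (default 3). \code{box = 1} returns the pixel.
#' @return Mean intensity (scalar, or vector when \code{y}, \code{x} are
#'   vectors).
#' @examples
#' img <- matrix(1:25, 5, 5)
#' markerIntensityAt(img, 3, 3)   # mean of the central 3x3 block
#' @export
markerIntensityAt <- function(image, y, x, box = 3) {
  if (box %% 2 != 1) stop("'box' must be odd", call. = FALSE)
  if (any(y < 1 | y > nrow(image) | x < 1 | x > ncol(image)))
    stop("centroid outside image", call. = FALSE)
  r <- (box - 1) / 2
  vapply(seq_along(y), function(i) {
    ys <- max(1, y[i] - r):min(nrow(image), y[i] + r)
    xs <- max(1, x[i] - r):min(ncol(image), x[i] + r)
    mean(image[ys, xs])
  }, numeric(1))
}

#' Per-cell colocalization z-score
#'
#' Samples \code{n_random} positions uniformly (with replacement) over the
#' cell's mask pixels, measures the 3x3 mean marker intensity at each, and
#' scores the spots as
#' \eqn{z = (\overline{I}_{spots} - \overline{I}_{random}) / SD(I_{random})}.
#' A zero random-sample SD (e.g. a flat marker) returns 0 with a warning.
#'
#' @param marker_image Numeric matrix, marker channel.
#' @param cell_mask Logical or 0/1 matrix selecting this cell's pixels.
#' @param spots Data.frame with \code{y_px}, \code{x_px} for this cell's
#'   spots (>= 1 row).
#' @param n_random Number of random positions (default 100).
#' @param box Neighbourhood side (default 3).
#' @param seed Integer seed for the random positions.
#' @return The z-score (scalar).
#' @export
cellZscore <- function(marker_image, cell_mask, spots, n_random = 100,
                       box = 3, seed = 1L) {
  pix <- which(cell_mask != 0)
  .cell_z(marker_image, pix, spots, n_random, box, seed)
}

.cell_z <- function(marker_image, pix, spots, n_random, box, seed) {
  if (nrow(spots) < 1) stop("cell has no spots", call. = FALSE)
  if (length(pix) < 1) stop("empty cell mask", call. = FALSE)
  H <- nrow(marker_image)
  rand_pix <- with_seed(seed, sample(pix, n_random, replace = TRUE))
  ry <- ((rand_pix - 1) %% H) + 1
  rx <- ((rand_pix - 1) %/% H) + 1
  rand_int <- markerIntensityAt(marker_image, ry, rx, box)
  spot_int <- markerIntensityAt(marker_image, spots$y_px, spots$x_px, box)
  s <- stats::sd(rand_int)
  if (!is.finite(s) || s == 0) {
    warning("random-sample SD is zero; returning z = 0")
    return(0)
  }
  (mean(spot_int) - mean(rand_int)) / s
}

#' Colocalization scores for all cells in a field
#'
#' Applies \code{\link{cellZscore}} to every cell with at least one spot.
#'
#' @param marker_image Numeric matrix, marker channel.
#' @param mask Integer labeled mask (0 = background, k = cell k).
#' @param spots Data.frame with \code{cell_id}, \code{y_px}, \code{x_px}.
#' @param n_random Random positions per cell (default 100).
#' @param seed Base seed; each cell gets a derived seed.
#' @return Data.frame with \code{cell_id}, \code{z_score}, \code{n_spots},
#'   \code{n_random}.
#' @examples
#' f <- simulateFishField(n_cells = 4, granule_enrichment = 10, seed = 2)
#' colocalizationScores(f$marker, f$mask, f$spots, seed = 2)
#' @export
colocalizationScores <- function(marker_image, mask, spots, n_random = 100,
                                 seed = 1L) {
  cells <- sort(unique(spots$cell_id))
  in_cell <- mask != 0
  pix_by_cell <- split(which(in_cell), mask[in_cell])
  spots_by_cell <- split(spots, spots$cell_id)
  rows <- lapply(cells, function(cell) {
    sp <- spots_by_cell[[as.character(cell)]]
    z <- .cell_z(marker_image, pix_by_cell[[as.character(cell)]], sp,
                 n_random = n_random, box = 3,
                 seed = derive_seed(seed, cell))
    data.frame(cell_id = cell, z_score = z, n_spots = nrow(sp),
               n_random = n_random)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population colocalization score and condition comparisons
#'
#' The population score is the arithmetic mean of per-cell z-scores. When
#' per-cell results from several conditions are supplied, pairwise Welch
#' t-tests with Holm correction compare conditions.
#'
#' @param per_cell Data.frame with \code{z_score} and optionally
#'   \code{condition}.
#' @return List with \code{score} (single condition) or \code{scores} (named
#'   per-condition means) plus a \code{comparisons} data.frame of pairwise
#'   Welch tests (\code{p_holm}).
#' @export
populationScore <- function(per_cell) {
  if (nrow(per_cell) < 1) stop("need at least one cell", call. = FALSE)
  if (!"condition" %in% names(per_cell) ||
      length(unique(per_cell$condition)) == 1L)
    return(list(score = mean(per_cell$z_score), n_cells = nrow(per_cell)))
  conds <- unique(per_cell$condition)
  scores <- vapply(conds, function(cc)
    mean(per_cell$z_score[per_cell$condition == cc]), numeric(1))
  names(scores) <- conds
  pairs <- utils::combn(conds, 2)
  comp <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    p_value = apply(pairs, 2, function(pr)
      stats::t.test(per_cell$z_score[per_cell$condition == pr[1]],
                    per_cell$z_score[per_cell$condition == pr[2]])$p.value))
  comp$p_holm <- stats::p.adjust(comp$p_value, method = "holm")
  list(scores = scores, comparisons = comp,
       n_cells = as.list(table(per_cell$condition)))
}
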