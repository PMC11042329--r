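## Synthetic two-channel smFISH fields: a granule-marker channel (per-cell
## background plus bright Gaussian blobs) and an RNA spot channel, with
## ground-truth spot coordinates and granule membership.

## Add a 2-D Gaussian blob to an image matrix (rows = y, cols = x).
.add_blob <- function(img, y0, x0, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  ys <- max(1, round(y0) - r):min(nrow(img), round(y0) + r)
  xs <- max(1, round(x0) - r):min(ncol(img), round(x0) + r)
  g <- outer(ys, xs, function(y, x)
    amplitude * exp(-((y - y0)^2 + (x - x0)^2) / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + g
  img
}

#' Simulate a two-channel smFISH field with cell masks and spot truth
#'
#' Lays cells out on a grid of circular masks. The marker channel gets a
#' per-cell background level, Gaussian read noise, and 1--3 bright granule
#' blobs per cell. RNA spots are placed at integer pixel positions inside the
#' cell: uniformly when \code{granule_enrichment = 0}, or with sampling weight
#' \code{1 + granule_enrichment} inside granule footprints. Spots are rendered
#' into a second channel with a Gaussian point-spread function.
#'
#' @param n_cells Number of cells (>= 1).
#' @param spots_per_cell RNA spots per cell.
#' @param granule_enrichment Relative sampling weight of granule pixels for
#'   spot placement; 0 gives uniform placement.
#' @param psf_sigma_px Gaussian PSF sigma for rendered spots (pixels).
#' @param cell_radius_px Cell mask radius (pixels).
#' @param granules_per_cell Granule blobs per cell.
#' @param granule_sigma_px Granule blob sigma (pixels).
#' @param granule_amplitude Peak granule intensity above the cell background.
#' @param background_mean,background_sd Per-cell marker background level
#'   distribution.
#' @param read_noise_sd Gaussian pixel noise on both channels.
#' @param seed Integer seed.
#' @return A list with elements \code{marker} and \code{spots_img} (numeric
#'   matrices), \code{mask} (integer labeled matrix, 0 = outside cells),
#'   \code{granule_mask} (logical matrix of granule footprints), and
#'   \code{spots}: a data.frame with \code{cell_id}, \code{spot_id},
#'   \code{y_px}, \code{x_px}, \code{spot_intensity},
#'   \code{normalized_intensity}, \code{in_granule}.
#' @examples
#' f <- simulateFishField(n_cells = 4, spots_per_cell = 5,
#'                        granule_enrichment = 0, seed = 1)
#' dim(f$marker); nrow(f$spots)
#' @export
simulateFishField <- function(n_cells, spots_per_cell = 10,
                              granule_enrichment = 0, psf_sigma_px = 1.2,
                              cell_radius_px = 12, granules_per_cell = 2,
                              granule_sigma_px = 2, granule_amplitude = 400,
                              background_mean = 100, background_sd = 20,
                              read_noise_sd = 5, seed = 1L) {
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (granule_enrichment < 0)
    stop("'granule_enrichment' must be >= 0", call. = FALSE)
  tile <- 2 * (cell_radius_px + 4)
  ncol_cells <- ceiling(sqrt(n_cells))
  nrow_cells <- ceiling(n_cells / ncol_cells)
  H <- nrow_cells * tile; W <- ncol_cells * tile
  with_seed(derive_seed(seed, 83), {
    marker <- matrix(0, H, W)
    spots_img <- matrix(0, H, W)
    mask <- matrix(0L, H, W)
    granule_mask <- matrix(FALSE, H, W)
    spot_rows <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      ## work on the cell's tile only
      ty0 <- ((cell - 1) %/% ncol_cells) * tile
      tx0 <- ((cell - 1) %% ncol_cells) * tile
      ys <- (ty0 + 1):(ty0 + tile); xs <- (tx0 + 1):(tx0 + tile)
      cy <- ty0 + tile / 2; cx <- tx0 + tile / 2
      yy <- matrix(ys, tile, tile); xx <- matrix(xs, tile, tile, byrow = TRUE)
      inside <- (yy - cy)^2 + (xx - cx)^2 <= cell_radius_px^2
      m_tile <- mask[ys, xs]; m_tile[inside] <- cell; mask[ys, xs] <- m_tile
      bg <- max(rnorm(1, background_mean, background_sd), 10)
      mk <- marker[ys, xs]; mk[inside] <- mk[inside] + bg
      marker[ys, xs] <- mk
      ## granules: bright marker blobs well inside the cell
      n_gran <- sample(seq_len(max(granules_per_cell, 1)), 1)
      gran_cell <- matrix(FALSE, tile, tile)
      for (g in seq_len(n_gran)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, cell_radius_px * 0.5)
        gy <- cy + rad * sin(ang); gx <- cx + rad * cos(ang)
        marker <- .add_blob(marker, gy, gx, granule_sigma_px,
                            granule_amplitude)
        gran_cell <- gran_cell |
          ((yy - gy)^2 + (xx - gx)^2 <= (2 * granule_sigma_px)^2)
      }
      gran_cell <- gran_cell & inside
      gm <- granule_mask[ys, xs]; granule_mask[ys, xs] <- gm | gran_cell
      ## spot placement over in-cell pixels, weighted toward granules
      pix <- which(inside)
      w <- rep(1, length(pix))
      w[gran_cell[pix]] <- 1 + granule_enrichment
      chosen <- sample(pix, spots_per_cell, replace = TRUE, prob = w)
      sy <- ty0 + ((chosen - 1) %% tile) + 1
      sx <- tx0 + ((chosen - 1) %/% tile) + 1
      amp <- rlnorm(spots_per_cell, log(300), 0.3)
      for (s in seq_len(spots_per_cell))
        spots_img <- .add_blob(spots_img, sy[s], sx[s], psf_sigma_px, amp[s])
      spot_rows[[cell]] <- data.frame(
        cell_id = cell, spot_id = seq_len(spots_per_cell),
        y_px = sy, x_px = sx, spot_intensity = amp,
        in_granule = gran_cell[chosen])
    }
    marker <- marker + matrix(rnorm(H * W, 0, read_noise_sd), H, W)
    spots_img <- spots_img + matrix(rnorm(H * W, 0, read_noise_sd), H, W)
    spots <- do.call(rbind, spot_rows)
    mean_by_cell <- tapply(spots$spot_intensity, spots$cell_id, mean)
    spots$normalized_intensity <-
      spots$spot_intensity / mean_by_cell[as.character(spots$cell_id)]
    list(marker = marker, spots_img = spots_img, mask = mask,
         granule_mask = granule_mask, spots = spots)
  })
}
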