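## Plain-text and TIFF I/O for the documented inter-stage file formats.

#' Write / read three-fraction count tables as TSV
#'
#' Columns: \code{transcript_id}, \code{total}, \code{sup}, \code{pellet},
#' plus \code{length_nt} when present.
#'
#' @param fc A \linkS4class{FractionCounts}.
#' @param path Output file.
#' @return \code{writeCountsTSV}: the path, invisibly. \code{readCountsTSV}:
#'   a \linkS4class{FractionCounts}.
#' @export
writeCountsTSV <- function(fc, path) {
  d <- data.frame(transcript_id = rownames(fc),
                  total = totalCounts(fc), sup = supCounts(fc),
                  pellet = pelletCounts(fc))
  len <- transcriptLengths(fc)
  if (!is.null(len)) d$length_nt <- len
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTSV
#' @param experiment_id Label for the read experiment.
#' @export
readCountsTSV <- function(path, experiment_id = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  FractionCounts(total = d$total, sup = d$sup, pellet = d$pellet,
                 transcript_id = d$transcript_id,
                 length_nt = if ("length_nt" %in% names(d)) d$length_nt,
                 experiment_id = experiment_id)
}

#' Write / read a grayscale image as TIFF
#'
#' TIFF payloads are written on a [0, 1] scale (32-bit float); the affine
#' range of the original intensities is stored in a small plain-text sidecar
#' (\code{<path>.scale}) so arbitrary intensities round-trip. Labeled masks
#' are stored as 16-bit integers.
#'
#' @param image Numeric matrix.
#' @param path Output file.
#' @return The path (write) or a numeric matrix (read), masks as integer
#'   matrices.
#' @export
writeImageTIFF <- function(image, path) {
  lo <- min(image); hi <- max(image)
  rng <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image - lo) / rng, path, bits.per.sample = 32L,
                  reduce = FALSE)
  writeLines(sprintf("%.17g %.17g", lo, rng), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sidecar <- paste0(path, ".scale")
  if (file.exists(sidecar)) {
    sc <- scan(sidecar, quiet = TRUE)
    img <- img * sc[2] + sc[1]
  }
  img
}

#' @rdname writeImageTIFF
#' @param mask Integer labeled matrix (values < 65536).
#' @export
writeMaskTIFF <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readMaskTIFF <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

## Generic TSV helpers used by the pipeline stages.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
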