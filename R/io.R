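# TIFF / YAML / JSON plumbing.
#
# Image data are written as 32-bit multi-page TIFF.  The TIFF writer stores
# float samples in [0, 1], so each file is scaled by its maximum and the
# scale factor travels in a JSON sidecar (<file>.json) together with the
# voxel sizes and any provenance (seed, configuration).  Reading applies
# the inverse scale, so a round trip is lossless at 32-bit float precision.

.writePages <- function(pages, path) {
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
}

#' Write / read a sample volume as multi-page TIFF
#'
#' One page per z plane; voxel sizes, intensity scale and the label mask
#' summary go to a JSON sidecar.  The label mask, when present, is written
#' as a second TIFF (`<path>.labels.tif`) with 8-bit pages.
#'
#' @param vol a [SampleVolume-class]
#' @param path output TIFF path
#' @param sidecar optional named list merged into the JSON sidecar
#' @return `path`, invisibly
#' @export
writeVolumeTiff <- function(vol, path, sidecar = list()) {
  V <- vol@values
  sc <- max(V)
  if (sc == 0) sc <- 1
  pages <- lapply(seq_len(dim(V)[3]), function(k) t(V[, , k]) / sc)
  .writePages(pages, path)
  meta <- c(list(type = "SampleVolume", dims = dim(V), voxel = vol@voxel,
                 scale = sc, has_labels = length(vol@labels) > 0), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (length(vol@labels)) {
    lp <- lapply(seq_len(dim(V)[3]), function(k) t(vol@labels[, , k]) * 1)
    suppressWarnings(tiff::writeTIFF(lp, paste0(path, ".labels.tif"),
                                     bits.per.sample = 8L))
  }
  invisible(path)
}

#' @rdname writeVolumeTiff
#' @export
readVolumeTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    warning("no sidecar found; assuming unit scale and 0.325/0.5 um voxels")
    meta <- list(scale = 1, voxel = c(0.325, 0.325, 0.5),
                 has_labels = FALSE)
  }
  V <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) V[, , k] <- t(pages[[k]]) * meta$scale
  lab <- array(logical(0), c(0, 0, 0))
  lp <- paste0(path, ".labels.tif")
  if (isTRUE(meta$has_labels) && file.exists(lp)) {
    lpages <- tiff::readTIFF(lp, all = TRUE)
    lab <- array(FALSE, dim(V))
    for (k in seq_along(lpages)) lab[, , k] <- t(lpages[[k]]) > 0.5
  }
  new("SampleVolume", values = V, voxel = as.numeric(meta$voxel),
      labels = lab)
}

#' Write / read a raw off-axis stack as multi-page TIFF
#'
#' One page per off-axis line; the scan configuration, focal plane and
#' intensity scale go to the JSON sidecar.
#'
#' @param stack a [RawOffAxisStack-class]
#' @param path output TIFF path
#' @param sidecar optional named list merged into the sidecar
#' @return `path`, invisibly
#' @export
writeStackTiff <- function(stack, path, sidecar = list()) {
  A <- stack@images
  sc <- max(A)
  if (sc == 0) sc <- 1
  pages <- lapply(seq_len(dim(A)[3]), function(nl) t(A[, , nl]) / sc)
  .writePages(pages, path)
  s <- stack@scan
  meta <- c(list(type = "RawOffAxisStack", dims = dim(A), scale = sc,
                 plane_z = stack@plane_z,
                 scan = list(n_lines = s@n_lines, pitch = s@pitch,
                             scan_step = s@scan_step, noise = s@noise,
                             photons = s@photons, read_sd = s@read_sd,
                             seed = s@seed)), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  A <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (nl in seq_along(pages)) A[, , nl] <- t(pages[[nl]]) * meta$scale
  sc <- do.call(scanConfig, meta$scan)
  new("RawOffAxisStack", images = A, plane_z = meta$plane_z, scan = sc)
}
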