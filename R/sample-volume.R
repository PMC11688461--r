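# Synthetic 3D phantoms: random-trajectory filament volumes and analytic
# probes (thin fluorescent sheet, point source).

#' 3D fluorophore-density phantom
#'
#' @slot values non-negative 3D density array (x, y, z)
#' @slot voxel voxel sizes (dx, dy, dz) in um
#' @slot labels logical array marking structure voxels (for SBR scoring);
#'   may be empty for analytic probes
#' @aliases SampleVolume-class
#' @exportClass SampleVolume
setClass("SampleVolume",
  representation(values = "array", voxel = "numeric", labels = "array"))

setValidity("SampleVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@values)) != 3)
    msg <- c(msg, "values must be a 3D array")
  if (min(object@values) < 0)
    msg <- c(msg, "densities must be non-negative")
  if (length(object@voxel) != 3 || any(object@voxel <= 0))
    msg <- c(msg, "voxel must be three positive sizes (um)")
  if (length(object@labels) > 0 &&
      !identical(dim(object@labels), dim(object@values)))
    msg <- c(msg, "labels must match the volume dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SampleVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("SampleVolume: %d x %d x %d voxels at (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], object@voxel[1], object@voxel[2],
              object@voxel[3]))
  if (length(object@labels))
    cat(sprintf("  labelled fraction: %.3g\n", mean(object@labels)))
})

#' Accessors for SampleVolume
#' @param vol a [SampleVolume-class]
#' @return the density array, voxel sizes, or label mask
#' @name samplevolume-accessors
#' @export
volumeValues <- function(vol) vol@values
#' @rdname samplevolume-accessors
#' @export
voxelSize <- function(vol) vol@voxel
#' @rdname samplevolume-accessors
#' @export
volumeLabels <- function(vol) vol@labels

#' Random-trajectory filament phantom
#'
#' Rasterizes smoothed 3D random-walk trajectories as tubes of the given
#' radius into a volume block, emulating neurite-like filaments.  Each path
#' starts at a uniform random position with a uniform random direction; at
#' every step the direction receives Gaussian jitter (curvature-bounded
#' smoothing) and the path advances by `step_length`.  The per-point
#' intensity follows a lognormal random walk (the fluorophore density
#' varies along the axial position), clamped to a factor-five band around
#' the path's base amplitude.  A logical label mask marks all tube voxels.
#'
#' The default desk-scale block is 256 x 256 x 128 voxels at 0.325 um
#' lateral and 0.5 um axial sampling; the full-scale 1024^3 block at the
#' same voxel sizes is a configuration, not a default.
#'
#' @param shape volume dimensions in voxels (nx, ny, nz)
#' @param voxel voxel sizes (dx, dy, dz) in um
#' @param n_paths number of trajectories
#' @param radius tube radius in um (paths thinner than one voxel are
#'   rasterized as single-voxel chains with a warning)
#' @param steps steps per trajectory
#' @param step_length step length in um
#' @param direction_sd s.d. of the per-step direction jitter
#' @param intensity_sdlog lognormal s.d. of the per-path base amplitude
#' @param intensity_drift lognormal s.d. of the per-step intensity drift
#' @param background uniform background density added everywhere
#'   (default 0)
#' @param seed integer seed; identical seeds give bitwise-identical volumes
#' @return a [SampleVolume-class]
#' @examples
#' vol <- trajectoryVolume(shape = c(64, 64, 32), n_paths = 4,
#'                         steps = 200, seed = 1)
#' @export
trajectoryVolume <- function(shape = c(256, 256, 128),
                             voxel = c(0.325, 0.325, 0.5),
                             n_paths = 48, radius = 0.5, steps = 1200,
                             step_length = 0.3, direction_sd = 0.25,
                             intensity_sdlog = 0.5, intensity_drift = 0.08,
                             background = 0, seed = 1) {
  if (any(shape <= 0)) stop("shape must be positive", call. = FALSE)
  set.seed(seed)
  V <- array(0, shape)
  lab <- array(FALSE, shape)
  if (radius < min(voxel)) {
    warning("tube radius below one voxel; rasterizing as single-voxel chains")
  }
  rr <- pmax(ceiling(radius / voxel), 0)
  off <- as.matrix(expand.grid(i = -rr[1]:rr[1], j = -rr[2]:rr[2],
                               k = -rr[3]:rr[3]))
  d2 <- (off[, 1] * voxel[1])^2 + (off[, 2] * voxel[2])^2 +
    (off[, 3] * voxel[3])^2
  off <- off[d2 <= max(radius, min(voxel) / 2)^2, , drop = FALSE]
  if (nrow(off) == 0) off <- matrix(0, 1, 3)
  ext <- shape * voxel
  for (pth in seq_len(n_paths)) {
    pos <- runif(3) * ext
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    amp <- exp(rnorm(1, 0, intensity_sdlog))
    intens <- amp
    for (s in seq_len(steps)) {
      dir <- dir + rnorm(3, 0, direction_sd)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pmin(pmax(pos + dir * step_length, 0), ext - 1e-9)
      intens <- min(max(intens * exp(rnorm(1, 0, intensity_drift)),
                        0.2 * amp), 5 * amp)
      ci <- pmin(pmax(floor(pos / voxel) + 1, 1), shape)
      idx <- cbind(pmin(pmax(off[, 1] + ci[1], 1), shape[1]),
                   pmin(pmax(off[, 2] + ci[2], 1), shape[2]),
                   pmin(pmax(off[, 3] + ci[3], 1), shape[3]))
      V[idx] <- pmax(V[idx], intens)
      lab[idx] <- TRUE
    }
  }
  if (background > 0) V <- V + background
  new("SampleVolume", values = V, voxel = voxel, labels = lab)
}

#' Thin fluorescent sheet phantom
#'
#' A single z-plane of uniform unit intensity — the probe whose simulated
#' image sweep traces out a method's axial response.
#'
#' @param z0 plane position in um (measured from the first plane at
#'   z = voxel[3]/2)
#' @param shape volume dimensions in voxels
#' @param voxel voxel sizes in um
#' @return a [SampleVolume-class]
#' @export
fluorescentSheet <- function(z0, shape = c(64, 64, 64),
                             voxel = c(0.325, 0.325, 0.5)) {
  zc <- (seq_len(shape[3]) - 0.5) * voxel[3]
  if (z0 < 0 || z0 > shape[3] * voxel[3])
    stop("z0 outside the volume", call. = FALSE)
  k <- which.min(abs(zc - z0))
  V <- array(0, shape)
  V[, , k] <- 1
  new("SampleVolume", values = V, voxel = voxel,
      labels = array(V > 0, shape))
}

#' Point-source phantom
#'
#' A single voxel of unit intensity; the simulated image of a centred
#' point reproduces the system PSF section.
#'
#' @param position voxel indices (i, j, k)
#' @param shape volume dimensions in voxels
#' @param voxel voxel sizes in um
#' @return a [SampleVolume-class]
#' @export
pointSource <- function(position = NULL, shape = c(64, 64, 64),
                        voxel = c(0.325, 0.325, 0.5)) {
  if (is.null(position)) position <- ceiling(shape / 2)
  if (any(position < 1) || any(position > shape))
    stop("position outside the volume", call. = FALSE)
  V <- array(0, shape)
  V[position[1], position[2], position[3]] <- 1
  new("SampleVolume", values = V, voxel = voxel,
      labels = array(V > 0, shape))
}
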