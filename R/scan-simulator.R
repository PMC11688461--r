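# Forward model of off-axis spatiotemporal-multiplexed line-scan imaging.
#
# The sample is translated through a line focus; a multi-line detector
# subarray records, at every scan position, one sample per off-axis line.
# Rearranging the columns by off-axis index yields one co-registered image
# I_n per line.  Because stage scanning makes the acquisition
# shift-invariant along x, each I_n is a sum over depth of the sample
# slice convolved with the product kernel
#     K_n(x, z - z_f) = PSF_ill(x, z - z_f) . PSF_det,n(x, z - z_f),
# plus a separable defocused detection blur along the line direction y.
# The convolutions are evaluated by zero-padded FFTs; shot and read noise
# are applied last.

#' Scan configuration
#'
#' @slot n_lines number of off-axis detector lines (>= 2; default 6, the
#'   subarray assumed by the LC/DSIM/DHiLo/LiMo reconstructions; 8 is
#'   supported)
#' @slot pitch detector line pitch in sample space (um)
#' @slot scan_step x step per exposure (um); must equal the lateral voxel
#'   size of the volume being imaged
#' @slot noise `"none"`, `"poisson"`, or `"poisson+gaussian"`
#' @slot photons expected photoelectrons at the brightest pixel of the
#'   most in-focus line (exposure normalization)
#' @slot read_sd Gaussian read-noise s.d. in photoelectrons
#' @slot seed integer noise seed
#' @aliases ScanConfig-class
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(n_lines = "integer", pitch = "numeric",
                 scan_step = "numeric", noise = "character",
                 photons = "numeric", read_sd = "numeric", seed = "integer"))

setValidity("ScanConfig", function(object) {
  msg <- character(0)
  if (object@n_lines < 2) msg <- c(msg, "n_lines must be >= 2")
  if (object@pitch <= 0) msg <- c(msg, "pitch must be > 0")
  if (object@scan_step <= 0) msg <- c(msg, "scan_step must be > 0")
  if (!object@noise %in% c("none", "poisson", "poisson+gaussian"))
    msg <- c(msg, "noise must be none, poisson or poisson+gaussian")
  if (length(msg)) msg else TRUE
})

#' Create a scan configuration
#' @param n_lines number of off-axis detector lines
#' @param pitch line pitch in sample space (um)
#' @param scan_step scan step (um)
#' @param noise noise model
#' @param photons photon budget at the in-focus peak
#' @param read_sd read-noise s.d. (photoelectrons)
#' @param seed noise seed
#' @return a [ScanConfig-class]
#' @export
scanConfig <- function(n_lines = 6, pitch = 0.325, scan_step = 0.325,
                       noise = "poisson+gaussian", photons = 2000,
                       read_sd = 2, seed = 1) {
  new("ScanConfig", n_lines = as.integer(n_lines), pitch = pitch,
      scan_step = scan_step, noise = noise, photons = photons,
      read_sd = read_sd, seed = as.integer(seed))
}

setMethod("show", "ScanConfig", function(object) {
  cat(sprintf("ScanConfig: %d lines, pitch %.4g um, step %.4g um, noise '%s'\n",
              object@n_lines, object@pitch, object@scan_step, object@noise))
})

#' Raw off-axis image stack
#'
#' One co-registered 2D image per off-axis detector line, acquired at a
#' single focal-plane position.
#'
#' @slot images array nx x ny x n_lines, all non-negative
#' @slot plane_z focal-plane position (um)
#' @slot scan the [ScanConfig-class] used
#' @aliases RawOffAxisStack-class
#' @exportClass RawOffAxisStack
setClass("RawOffAxisStack",
  representation(images = "array", plane_z = "numeric", scan = "ScanConfig"))

setValidity("RawOffAxisStack", function(object) {
  if (length(dim(object@images)) != 3)
    "images must be a 3D array (x, y, line)"
  else if (dim(object@images)[3] != object@scan@n_lines)
    "third dimension must equal n_lines"
  else TRUE
})

setMethod("show", "RawOffAxisStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("RawOffAxisStack: %d x %d pixels, %d lines, focal plane %.4g um\n",
              d[1], d[2], d[3], object@plane_z))
})

#' Accessors for RawOffAxisStack
#' @param stack a [RawOffAxisStack-class]
#' @param n line index
#' @return the image array or a single line image
#' @name stack-accessors
#' @export
stackImages <- function(stack) stack@images
#' @rdname stack-accessors
#' @export
lineImage <- function(stack, n) {
  if (n < 1 || n > dim(stack@images)[3])
    stop("no detector line ", n, " in this stack", call. = FALSE)
  stack@images[, , n]
}

#' Precompute the scan kernels
#'
#' Builds the coarse (voxel-sampled) product kernels K_n(x, dz) =
#' PSF_ill . PSF_det,n for every off-axis line and defocus offset, along
#' with the normalized defocused y-blur profiles.  Kernels are evaluated on
#' a fine sub-voxel grid (factor `oversample`) and box-averaged into voxel
#' bins, matching what a detector pixel integrates.  Cached per geometry.
#'
#' @param cfg an [OpticalConfig-class]
#' @param scan a [ScanConfig-class]
#' @param voxel voxel sizes (dx, dy, dz) of the volumes to be imaged (um)
#' @param nz number of z planes the kernels must span
#' @param oversample fine sub-voxel sampling factor
#' @param nfft,nchord PSF builder geometry, see [projectedPsf()]
#' @return an opaque kernel list consumed by [simulatePlane()]
#' @export
scanKernels <- function(cfg, scan, voxel, nz, oversample = 11,
                        nfft = 4096, nchord = 256) {
  if (oversample %% 2 == 0)
    stop("oversample must be odd (keeps a voxel centred on the line)",
         call. = FALSE)
  key <- cacheKey("scankern", cfg@na_det, cfg@na_ill, cfg@wavelength_ex,
                  cfg@wavelength_em, cfg@refractive_index,
                  scan@n_lines, scan@pitch, voxel, nz, oversample,
                  nfft, nchord)
  cacheGet(key, function() {
    dx <- voxel[1]; dz <- voxel[3]
    x_step <- dx / oversample
    zoff <- seq(-(nz - 1), nz - 1) * dz
    ill <- projectedPsf(cfg, zoff, "illumination", x_step = x_step,
                        nfft = nfft, nchord = nchord)
    det <- projectedPsf(cfg, zoff, "detection", x_step = x_step,
                        nfft = nfft, nchord = nchord)
    L <- ill$values
    offsets <- (seq_len(scan@n_lines) - (scan@n_lines + 1) / 2) * scan@pitch
    # bins aligned so that one voxel is centred on the fine sample at x = 0
    c0 <- nfft / 2 + 1
    half <- (oversample - 1) / 2
    st <- ((c0 - half - 1) %% oversample) + 1
    ncoarse <- floor((nfft - st + 1) / oversample)
    binx <- function(M) {
      rowsum(M[st:(st + ncoarse * oversample - 1), , drop = FALSE],
             rep(seq_len(ncoarse), each = oversample)) / oversample
    }
    Kn <- array(0, c(ncoarse, length(zoff), scan@n_lines))
    for (nl in seq_len(scan@n_lines)) {
      Dn <- .stripIntegrate(det$values, x_step,
                            offsets[nl] - scan@pitch / 2,
                            offsets[nl] + scan@pitch / 2)
      Kn[, , nl] <- binx(L * Dn * scan@pitch)
    }
    # normalized y-blur of the defocused detection PSF
    Gy <- sweep(det$values, 2, colSums(det$values) * x_step, "/")
    Gyc <- binx(Gy * x_step)
    Gyc <- sweep(Gyc, 2, colSums(Gyc), "/")
    xc <- rowsum(ill$x[st:(st + ncoarse * oversample - 1)],
                 rep(seq_len(ncoarse), each = oversample)) / oversample
    list(Kn = Kn, Gy = Gyc, zoff = zoff, xc = as.numeric(xc),
         ctr = which.min(abs(xc)), dz = dz, n_lines = scan@n_lines)
  })
}

#' Simulate one focal plane
#'
#' Forward-models the off-axis line-scan acquisition of a single focal
#' plane: every z slice of the volume is excited by the defocused line
#' profile, blurred along the line direction, integrated by each off-axis
#' detector strip, and the resulting per-line columns are reassembled into
#' the images I_n.  Noise (per the scan configuration) is applied last.
#'
#' @param volume a [SampleVolume-class]
#' @param cfg an [OpticalConfig-class]
#' @param scan a [ScanConfig-class]
#' @param plane_z focal-plane position in um (snapped to the volume's z
#'   lattice; default = volume centre)
#' @param kernels optional precomputed [scanKernels()] result
#' @return a [RawOffAxisStack-class]
#' @examples
#' \donttest{
#' vol <- trajectoryVolume(shape = c(64, 64, 32), n_paths = 4, steps = 150)
#' stk <- simulatePlane(vol, opticalConfig(), scanConfig(noise = "none"))
#' }
#' @export
simulatePlane <- function(volume, cfg, scan, plane_z = NULL,
                          kernels = NULL) {
  dims <- dim(volume@values)
  dx <- volume@voxel[1]; dz <- volume@voxel[3]
  if (abs(scan@scan_step - dx) > 1e-9)
    stop(sprintf("scan_step must equal the lateral voxel size (expected %.4g um)",
                 dx), call. = FALSE)
  zc <- (seq_len(dims[3]) - 0.5) * dz
  if (is.null(plane_z)) plane_z <- zc[max(1, dims[3] %/% 2)]
  if (plane_z < 0 || plane_z > dims[3] * dz)
    stop("plane_z outside the volume", call. = FALSE)
  kf <- which.min(abs(zc - plane_z))
  if (is.null(kernels))
    kernels <- scanKernels(cfg, scan, volume@voxel, dims[3])
  nkx <- dim(kernels$Kn)[1]
  if (abs(kernels$dz - dz) > 1e-9)
    stop(sprintf("kernel z spacing %.4g um does not match the volume (%.4g um)",
                 kernels$dz, dz), call. = FALSE)
  padx <- nextPow2(dims[1] + nkx / 2 + 1)
  pady <- nextPow2(dims[2] + nkx / 2 + 1)
  nz0 <- (length(kernels$zoff) + 1) / 2  # index of zero offset
  acc <- vector("list", scan@n_lines)
  for (i in seq_len(scan@n_lines)) acc[[i]] <- matrix(0 + 0i, padx, pady)
  idx_x <- ((seq_len(nkx) - kernels$ctr) %% padx) + 1
  idx_y <- ((seq_len(nkx) - kernels$ctr) %% pady) + 1
  for (k in seq_len(dims[3])) {
    jz <- nz0 + (k - kf)
    if (jz < 1 || jz > length(kernels$zoff)) next
    sl <- volume@values[, , k]
    if (all(sl == 0)) next
    slice <- matrix(0, padx, pady)
    slice[seq_len(dims[1]), seq_len(dims[2])] <- sl
    FV <- fft(slice)
    gpad <- numeric(pady); gpad[idx_y] <- kernels$Gy[, jz]
    FVG <- sweep(FV, 2, fft(gpad), "*")
    for (nl in seq_len(scan@n_lines)) {
      kpad <- numeric(padx); kpad[idx_x] <- kernels$Kn[, jz, nl]
      acc[[nl]] <- acc[[nl]] + sweep(FVG, 1, fft(kpad), "*")
    }
  }
  imgs <- array(0, c(dims[1], dims[2], scan@n_lines))
  for (nl in seq_len(scan@n_lines))
    imgs[, , nl] <- pmax(Re(fft(acc[[nl]], inverse = TRUE))[
      seq_len(dims[1]), seq_len(dims[2])] / (padx * pady), 0)
  if (scan@noise != "none" && max(imgs) > 0) {
    set.seed(scan@seed + kf)
    sc <- scan@photons / max(imgs)
    counts <- array(rpois(length(imgs), imgs * sc), dim(imgs))
    if (scan@noise == "poisson+gaussian")
      counts <- counts + array(rnorm(length(imgs), 0, scan@read_sd),
                               dim(imgs))
    imgs <- pmax(counts, 0) / sc
  }
  new("RawOffAxisStack", images = imgs, plane_z = zc[kf], scan = scan)
}

#' Simulate an axial series of focal planes
#'
#' @inheritParams simulatePlane
#' @param z_step axial step between focal planes (um), > 0
#' @return list of [RawOffAxisStack-class] objects
#' @export
simulateVolume <- function(volume, cfg, scan, z_step = NULL,
                           kernels = NULL) {
  if (is.null(z_step)) z_step <- volume@voxel[3]
  if (z_step <= 0) stop("z_step must be > 0", call. = FALSE)
  dims <- dim(volume@values)
  dz <- volume@voxel[3]
  if (is.null(kernels))
    kernels <- scanKernels(cfg, scan, volume@voxel, dims[3])
  planes <- seq(dz / 2, dims[3] * dz - dz / 2, by = z_step)
  lapply(planes, function(pz)
    simulatePlane(volume, cfg, scan, plane_z = pz, kernels = kernels))
}

#' Coaxial wide-field equivalent image
#'
#' The sum over all off-axis lines: because the sub-detector strips tile
#' the full aperture, this equals imaging with a single detector of width
#' n_lines * pitch — the traditional coaxial line-scan image.
#'
#' @param stack a [RawOffAxisStack-class]
#' @return nx x ny matrix
#' @export
widefieldEquivalent <- function(stack) {
  apply(stack@images, c(1, 2), sum)
}
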