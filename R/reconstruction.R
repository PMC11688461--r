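# Reconstructions on raw off-axis stacks: LC, DSIM, DHiLo, LiMo, and the
# signal-to-background ratio metric.
#
# With six lines indexed 1..6 across the subarray (lines 3 and 4 straddling
# the illumination line), the reconstructions are
#   LC    = I3                                  (virtual-slit line confocal)
#   DSIM  = sqrt(5) |I3 - I1|                   (simplified three-phase form)
#   DHiLo = I3 - gamma LP(I3)                   (simplified HiLo fusion)
#   LiMo  = 2 (I3 + I4) - (I1 + I2 + I5 + I6)   (linear background cancel)
# Negative values are clipped to zero for display and metrics; the
# pre-clip image is retained for linearity checks.

#' Reconstruction parameters
#'
#' @slot method `"LC"`, `"DSIM"`, `"DHiLo"` or `"LiMo"`
#' @slot eta scaling coefficient of the general DHiLo low-pass term (and
#'   the cross-form LiMo/DSIM comparisons)
#' @slot gamma DHiLo low-pass weight in [0, 2]
#' @slot filter_cutoff DHiLo Gaussian low-pass cutoff in cycles/um
#' @slot phase_masks 3 x n_lines matrix assigning lines to the three DSIM
#'   phases
#' @slot k DSIM normalization coefficient
#' @slot dsim_form `"simplified"` or `"general"`
#' @slot dhilo_form `"simplified"` or `"general"`
#' @aliases ReconParams-class
#' @exportClass ReconParams
setClass("ReconParams",
  representation(method = "character", eta = "numeric", gamma = "numeric",
                 filter_cutoff = "numeric", phase_masks = "matrix",
                 k = "numeric", dsim_form = "character",
                 dhilo_form = "character"))

setValidity("ReconParams", function(object) {
  msg <- character(0)
  if (!object@method %in% c("LC", "DSIM", "DHiLo", "LiMo"))
    msg <- c(msg, "method must be LC, DSIM, DHiLo or LiMo")
  if (object@gamma < 0 || object@gamma > 2)
    msg <- c(msg, "gamma must lie in [0, 2]")
  if (object@filter_cutoff <= 0)
    msg <- c(msg, "filter_cutoff must be > 0")
  if (nrow(object@phase_masks) != 3)
    msg <- c(msg, "phase_masks must have 3 rows (one per phase)")
  if (length(msg)) msg else TRUE
})

#' Create reconstruction parameters
#'
#' The default phase masks assign six lines to three phases as pairs
#' (1,4), (2,5), (3,6).  The default DHiLo Gaussian low-pass cutoff of
#' 0.2 cycles/um (about a 5 um wavelength) sits below the spatial
#' frequencies of the filament structures and models the defocused haze.
#'
#' @param method reconstruction method
#' @param eta,gamma,filter_cutoff,k see [ReconParams-class]
#' @param phase_masks 3 x n_lines phase-assignment matrix
#' @param dsim_form,dhilo_form `"simplified"` (printed closed forms,
#'   default) or `"general"` (mask / filter formulations)
#' @return a [ReconParams-class]
#' @export
reconParams <- function(method = "LiMo", eta = 1, gamma = 0.9,
                        filter_cutoff = 0.2, k = 1, phase_masks = NULL,
                        dsim_form = "simplified",
                        dhilo_form = "simplified") {
  if (is.null(phase_masks)) {
    phase_masks <- matrix(0, 3, 6)
    phase_masks[1, c(1, 4)] <- 1
    phase_masks[2, c(2, 5)] <- 1
    phase_masks[3, c(3, 6)] <- 1
  }
  new("ReconParams", method = method, eta = eta, gamma = gamma,
      filter_cutoff = filter_cutoff, phase_masks = phase_masks, k = k,
      dsim_form = dsim_form, dhilo_form = dhilo_form)
}

#' Reconstruction result
#'
#' @slot image reconstructed image, clipped at zero
#' @slot unclipped the pre-clip image (for linearity checks)
#' @slot method method label
#' @slot params the [ReconParams-class] used
#' @slot sbr signal-to-background ratio (NA until scored with [sbr()])
#' @aliases ReconResult-class
#' @exportClass ReconResult
setClass("ReconResult",
  representation(image = "matrix", unclipped = "matrix", method = "character",
                 params = "ReconParams", sbr = "numeric"))

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult '%s': %d x %d image%s\n", object@method,
              nrow(object@image), ncol(object@image),
              if (is.na(object@sbr)) "" else sprintf(", SBR %.3g", object@sbr)))
})

#' Accessors for ReconResult
#' @param x a [ReconResult-class]
#' @return the clipped image, the pre-clip image, or the stored SBR
#' @name recon-accessors
#' @export
reconImage <- function(x) x@image
#' @rdname recon-accessors
#' @export
reconUnclipped <- function(x) x@unclipped
#' @rdname recon-accessors
#' @export
reconSbr <- function(x) x@sbr

.newRecon <- function(raw, method, params) {
  new("ReconResult", image = pmax(raw, 0), unclipped = raw,
      method = method, params = params, sbr = NA_real_)
}

.needLines <- function(stack, n) {
  if (dim(stack@images)[3] < n)
    stop(sprintf("reconstruction needs at least %d detector lines", n),
         call. = FALSE)
}

#' Line-confocal (virtual slit) reconstruction
#'
#' Returns line 3 — the most in-focus detector line — unchanged.
#'
#' @param stack a [RawOffAxisStack-class]
#' @param params a [ReconParams-class]
#' @return a [ReconResult-class]
#' @export
reconLC <- function(stack, params = reconParams("LC")) {
  .needLines(stack, 3)
  .newRecon(stack@images[, , 3], "LC", params)
}

#' Digital structured-illumination (DSIM) reconstruction
#'
#' The simplified printed form is sqrt(5) |I3 - I1|.  The general form
#' assembles three phase images from the lines via the phase masks and
#' combines them as k |sum_i P_i exp(2 pi i j / 3)|; on symmetric in-focus
#' stacks the two forms agree up to an overall scale.
#'
#' @inheritParams reconLC
#' @return a [ReconResult-class]
#' @export
reconDSIM <- function(stack, params = reconParams("DSIM")) {
  if (params@dsim_form == "general") {
    .needLines(stack, ncol(params@phase_masks))
    P <- lapply(1:3, function(i) {
      idx <- which(params@phase_masks[i, ] != 0)
      Reduce(`+`, lapply(idx, function(nn)
        params@phase_masks[i, nn] * stack@images[, , nn]))
    })
    Z <- P[[1]] * exp(2i * pi / 3) + P[[2]] * exp(4i * pi / 3) + P[[3]]
    raw <- params@k * Mod(Z)
  } else {
    .needLines(stack, 3)
    raw <- sqrt(5 * (stack@images[, , 3] - stack@images[, , 1])^2)
  }
  .newRecon(raw, "DSIM", params)
}

#' Digital HiLo (DHiLo) reconstruction
#'
#' Simplified printed form: I3 - gamma LP(I3) with a Gaussian low-pass.
#' The general form fuses the high-pass of I3 with a contrast-weighted
#' low-pass, HP(I3) + eta LP(C_s I3), where the local contrast C_s is the
#' smoothed normalized difference between the most- and least-modulated
#' lines, (I3 - I1)/(I3 + I1).
#'
#' @inheritParams reconLC
#' @return a [ReconResult-class]
#' @export
reconDHiLo <- function(stack, params = reconParams("DHiLo")) {
  .needLines(stack, 3)
  I3 <- stack@images[, , 3]
  dx <- stack@scan@scan_step
  nyq <- 1 / (2 * dx)
  if (params@filter_cutoff > nyq)
    stop(sprintf("filter_cutoff beyond Nyquist (%.3g cycles/um)", nyq),
         call. = FALSE)
  LP <- function(img) .gaussLowPass(img, dx, params@filter_cutoff)
  if (params@dhilo_form == "general") {
    I1 <- stack@images[, , 1]
    Cs <- LP((I3 - I1) / pmax(I3 + I1, 1e-12 * max(I3)))
    raw <- (I3 - LP(I3)) + params@eta * LP(Cs * I3)
  } else {
    raw <- I3 - params@gamma * LP(I3)
  }
  .newRecon(raw, "DHiLo", params)
}

#' LiMo (line-illumination modulation) reconstruction
#'
#' Linear six-line combination 2 (I3 + I4) - (I1 + I2 + I5 + I6): the
#' out-of-focus background, nearly uniform across the off-axis lines,
#' cancels, while the strongly modulated in-focus signal survives.
#'
#' @inheritParams reconLC
#' @return a [ReconResult-class]
#' @export
reconLiMo <- function(stack, params = reconParams("LiMo")) {
  .needLines(stack, 6)
  I <- stack@images
  raw <- 2 * (I[, , 3] + I[, , 4]) -
    (I[, , 1] + I[, , 2] + I[, , 5] + I[, , 6])
  .newRecon(raw, "LiMo", params)
}

#' Reconstruct a raw stack with a named method
#'
#' @inheritParams reconLC
#' @param method one of `"LC"`, `"DSIM"`, `"DHiLo"`, `"LiMo"`
#' @return a [ReconResult-class]
#' @export
reconstruct <- function(stack, method = c("LiMo", "DHiLo", "DSIM", "LC"),
                        params = NULL) {
  method <- match.arg(method)
  if (is.null(params)) params <- reconParams(method)
  switch(method,
         LC = reconLC(stack, params),
         DSIM = reconDSIM(stack, params),
         DHiLo = reconDHiLo(stack, params),
         LiMo = reconLiMo(stack, params))
}

# Gaussian low-pass in the frequency domain, H(f) = exp(-f^2 / (2 fc^2))
.gaussLowPass <- function(img, dx, fc) {
  nx <- nrow(img); ny <- ncol(img)
  fxs <- c(seq(0, floor(nx / 2)), seq(-(ceiling(nx / 2) - 1), -1)) / (nx * dx)
  fys <- c(seq(0, floor(ny / 2)), seq(-(ceiling(ny / 2) - 1), -1)) / (ny * dx)
  H <- exp(-(outer(fxs^2, rep(1, ny)) + outer(rep(1, nx), fys^2)) /
             (2 * fc^2))
  Re(fft(fft(img) * H, inverse = TRUE)) / (nx * ny)
}

#' Signal-to-background ratio
#'
#' Mean intensity over the signal mask divided by the mean over the
#' background mask.  The background mean is floored at a small epsilon
#' (with a message) to keep the ratio finite on empty backgrounds.
#'
#' @param image numeric matrix (or a [ReconResult-class])
#' @param signal_mask,background_mask disjoint, non-empty logical masks
#' @return the ratio (numeric)
#' @export
sbr <- function(image, signal_mask, background_mask) {
  if (is(image, "ReconResult")) image <- image@image
  if (!any(signal_mask) || !any(background_mask))
    stop("masks must be non-empty", call. = FALSE)
  if (any(signal_mask & background_mask))
    stop("masks must be disjoint", call. = FALSE)
  sig <- mean(image[signal_mask])
  bg <- mean(image[background_mask])
  eps <- 1e-12 * max(max(image), 1)
  if (bg < eps) {
    message("background mean below epsilon; flooring")
    bg <- eps
  }
  sig / bg
}

#' Signal / background masks from a phantom's labels
#'
#' Signal: structure voxels within `slab` um of the focal plane, projected
#' to 2D and dilated by `dilate_signal` pixels.  Background: pixels at
#' least `clear_margin` pixels away from any in-focus structure.
#'
#' @param volume a labelled [SampleVolume-class]
#' @param plane_z focal-plane position (um)
#' @param slab half-thickness of the in-focus slab (um)
#' @param dilate_signal dilation radius of the signal mask (pixels)
#' @param clear_margin clearance radius of the background mask (pixels)
#' @return list with logical matrices `signal` and `background`
#' @export
sbrMasks <- function(volume, plane_z, slab = 1, dilate_signal = 1,
                     clear_margin = 6) {
  dims <- dim(volume@values)
  zc <- (seq_len(dims[3]) - 0.5) * volume@voxel[3]
  ksel <- abs(zc - plane_z) <= slab
  if (!any(ksel)) stop("no z planes within the focal slab", call. = FALSE)
  lab <- volume@labels[, , ksel, drop = FALSE]
  sig2d <- apply(lab, c(1, 2), any)
  list(signal = .dilate(sig2d, dilate_signal),
       background = !.dilate(sig2d, clear_margin))
}

# binary dilation with a disk structuring element via shifted ORs
.dilate <- function(M, r) {
  if (r <= 0) return(M)
  out <- M
  nx <- nrow(M); ny <- ncol(M)
  for (a in -r:r) for (b in -r:r) {
    if (a == 0 && b == 0) next
    if (a^2 + b^2 > r^2) next
    xs <- pmin(pmax(seq_len(nx) + a, 1), nx)
    ys <- pmin(pmax(seq_len(ny) + b, 1), ny)
    out <- out | M[xs, ys]
  }
  out
}
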