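# Internal numerical helpers shared across modules.

# package-level cache for expensive, deterministic tables (Bessel integrals,
# OTF grids, PSF kernels).  Keyed by a string built from the arguments; all
# cached objects are pure functions of their key.
.optisectCache <- new.env(parent = emptyenv())

cacheGet <- function(key, builder) {
  if (!is.null(.optisectCache[[key]])) return(.optisectCache[[key]])
  val <- builder()
  assign(key, val, envir = .optisectCache)
  val
}

cacheKey <- function(...) paste(vapply(list(...), function(x)
  paste(format(x, digits = 12), collapse = ","), character(1)), collapse = "|")

#' @noRd
jinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- 2 * besselJ(abs(x[nz]), 1) / abs(x[nz])
  out
}

# sin(x)/x with the removable singularity filled in
#' @noRd
snc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# composite quadrature weights on a uniform grid (Simpson when the point
# count is odd, trapezoid otherwise)
quadWeights <- function(n, h) {
  if (n < 2) stop("quadrature needs at least 2 points")
  if (n %% 2 == 1) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- w[n] <- 1
    w * h / 3
  } else {
    w <- rep(1, n)
    w[1] <- w[n] <- 0.5
    w * h
  }
}

# full width at half maximum of a sampled curve by linear interpolation
# between the bracketing samples on each side of the peak
fwhm1d <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  cross <- function(side) {
    idx <- if (side > 0) seq(pk, length(y)) else seq(pk, 1)
    below <- which(y[idx] < half)
    if (length(below) == 0) return(NA_real_)
    j <- idx[below[1]]
    j0 <- j - side
    x[j0] + (x[j] - x[j0]) * (half - y[j0]) / (y[j] - y[j0])
  }
  xr <- cross(1L)
  xl <- cross(-1L)
  if (is.na(xr) || is.na(xl)) return(NA_real_)
  xr - xl
}

# next power of two >= n
nextPow2 <- function(n) 2^ceiling(log2(n))

# circularly embed a kernel (centered at index `center`) into a length-`len`
# padded axis so that linear convolution via FFT is exact
padKernel <- function(k, center, len) {
  out <- numeric(len)
  idx <- ((seq_along(k) - center) %% len) + 1
  out[idx] <- out[idx] + k
  out
}

stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
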