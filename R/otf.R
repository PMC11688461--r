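# Defocused optical transfer function of an aberration-free circular pupil.
#
# The OTF is the normalized autocorrelation of the defocused pupil
# P(rho) = circ(rho) exp(i u rho^2 / 2).  With the lateral frequency s
# normalized so that the incoherent cutoff is 2 (physical frequency times
# lambda/NA), the autocorrelation reduces to a 1D cosine integral over the
# lens-shaped overlap of two unit disks with centres s apart:
#
#   T(s, u) = (4/pi) Int_0^{1-s/2} cos(u s x) sqrt(1 - (x + s/2)^2) dx
#
# which at u = 0 gives the classical closed form
#   T(s, 0) = (2/pi) [acos(s/2) - (s/2) sqrt(1 - s^2/4)].
# T is real, even in u, and T(0, u) = 1 for every u.

#' In-focus OTF of a circular pupil
#'
#' Closed-form diffraction-limited OTF at normalized frequency s in [0, 2]
#' (cutoff 2): \eqn{T(s,0) = (2/\pi)[\arccos(s/2) - (s/2)\sqrt{1 - s^2/4}]}.
#'
#' @param s normalized lateral frequency, 0 <= s <= 2 (vectorised)
#' @return OTF values in [0, 1]
#' @examples
#' otfInFocus(c(0, 1, 2))
#' @export
otfInFocus <- function(s) {
  if (any(!is.finite(s)) || any(s < 0 | s > 2))
    stop("s must lie in [0, 2]", call. = FALSE)
  (2 / pi) * (acos(s / 2) - (s / 2) * sqrt(1 - s^2 / 4))
}

#' Defocused OTF of a circular pupil
#'
#' Numerical autocorrelation of the defocused pupil with quadratic defocus
#' phase u rho^2 / 2.  Normalized so that T(0, u) = 1 for every u; at u = 0
#' it agrees with [otfInFocus()] to better than 1e-6.
#'
#' @param s normalized lateral frequency in [0, 2] (vectorised)
#' @param u normalized defocus (scalar or same length as s)
#' @param nquad quadrature points across the overlap region
#' @return OTF values, |T| <= 1
#' @export
otfDefocused <- function(s, u, nquad = 401) {
  if (any(!is.finite(s)) || any(s < 0 | s > 2))
    stop("s must lie in [0, 2]", call. = FALSE)
  stopifnotFinite(u, "defocus u")
  n <- max(length(s), length(u))
  s <- rep_len(s, n); u <- rep_len(u, n)
  vapply(seq_len(n), function(i) .otfOne(s[i], u[i], nquad), numeric(1))
}

.otfOne <- function(s, u, nquad) {
  if (s == 0) return(1)
  if (s >= 2) return(0)
  # substitute x + s/2 = cos(theta): removes the square-root endpoint
  # singularity, so the composite Simpson rule converges spectrally
  th_max <- acos(s / 2)
  th <- seq(0, th_max, length.out = nquad)
  w <- quadWeights(nquad, th_max / (nquad - 1))
  sum(sin(th)^2 * cos(u * s * (cos(th) - s / 2)) * w) * 4 / pi
}

#' Sampled defocused OTF grid
#'
#' A matrix of \eqn{T(s, u)} sampled on a normalized frequency grid
#' s in [0, 2] and a symmetric defocus grid u in [-u_max, u_max].  The grid
#' is the common input of every axial-response integral; bilinear
#' interpolation between nodes is provided by [otfAt()].
#'
#' @slot s normalized lateral frequency samples on [0, 2]
#' @slot u normalized defocus samples
#' @slot values matrix of T(s, u), rows indexed by s, columns by u
#' @aliases OTFGrid-class
#' @exportClass OTFGrid
setClass("OTFGrid",
  representation(s = "numeric", u = "numeric", values = "matrix"))

setValidity("OTFGrid", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@s) ||
      ncol(object@values) != length(object@u))
    msg <- c(msg, "values must be length(s) x length(u)")
  else {
    if (max(abs(object@values[1, ] - 1)) > 1e-9)
      msg <- c(msg, "T(0, u) must equal 1 for every u")
    if (max(abs(object@values)) > 1 + 1e-6)
      msg <- c(msg, "|T(s, u)| must not exceed 1")
  }
  if (length(msg)) msg else TRUE
})

#' Build a defocused OTF grid
#'
#' Evaluates the pupil autocorrelation on a regular (s, u) lattice.  Only
#' u >= 0 is computed; negative defocus is filled by the symmetry
#' T(s, -u) = T(s, u) of an aberration-free circular pupil.  Results are
#' cached per grid geometry within the session.
#'
#' @param s_points number of frequency samples on [0, 2] (default 513)
#' @param u_max largest |u| on the defocus axis (default 40)
#' @param u_points number of defocus samples (default 401, odd so that
#'   u = 0 is a node)
#' @param nquad quadrature points per autocorrelation integral
#' @return an [OTFGrid-class]
#' @examples
#' g <- makeOTFGrid(s_points = 65, u_max = 10, u_points = 51)
#' otfAt(g, 1, 0)
#' @export
makeOTFGrid <- function(s_points = 513, u_max = 40, u_points = 401,
                        nquad = 301) {
  key <- cacheKey("otfgrid", s_points, u_max, u_points, nquad)
  cacheGet(key, function() {
    s <- seq(0, 2, length.out = s_points)
    u <- seq(-u_max, u_max, length.out = u_points)
    upos <- u[u >= 0]
    vals_pos <- matrix(0, s_points, length(upos))
    vals_pos[1, ] <- 1
    for (i in 2:s_points) {
      si <- s[i]
      if (si >= 2) { vals_pos[i, ] <- 0; next }
      th_max <- acos(si / 2)
      th <- seq(0, th_max, length.out = nquad)
      w <- quadWeights(nquad, th_max / (nquad - 1))
      g <- sin(th)^2 * w
      vals_pos[i, ] <- (4 / pi) *
        colSums(cos(outer(cos(th) - si / 2, upos * si)) * g)
    }
    # mirror positive-u columns onto negative u (T is even in u)
    vals <- matrix(0, s_points, u_points)
    pos_idx <- which(u >= 0)
    vals[, pos_idx] <- vals_pos
    for (j in which(u < 0))
      vals[, j] <- vals_pos[, (u_points + 1 - j) - (pos_idx[1] - 1)]
    new("OTFGrid", s = s, u = u, values = vals)
  })
}

setMethod("show", "OTFGrid", function(object) {
  cat(sprintf("OTFGrid: %d s-samples on [0, 2], %d u-samples on [%.3g, %.3g]\n",
              length(object@s), length(object@u), min(object@u), max(object@u)))
})

#' Accessors for OTFGrid
#' @param grid an [OTFGrid-class]
#' @return the frequency grid, defocus grid or value matrix
#' @name otfgrid-accessors
#' @export
sGrid <- function(grid) grid@s
#' @rdname otfgrid-accessors
#' @export
uGrid <- function(grid) grid@u
#' @rdname otfgrid-accessors
#' @export
otfValues <- function(grid) grid@values

#' Interpolate an OTF grid
#'
#' Bilinear interpolation of T(s, u) between grid nodes.
#'
#' @param grid an [OTFGrid-class]
#' @param s normalized frequency (vectorised)
#' @param u normalized defocus (scalar or same length as s)
#' @return interpolated T(s, u)
#' @export
otfAt <- function(grid, s, u) {
  n <- max(length(s), length(u))
  s <- rep_len(s, n); u <- rep_len(u, n)
  if (any(s < min(grid@s) - 1e-9) || any(s > max(grid@s) + 1e-9))
    stop("s outside grid range", call. = FALSE)
  si <- findInterval(s, grid@s, rightmost.closed = TRUE)
  ui <- findInterval(u, grid@u, rightmost.closed = TRUE)
  si <- pmin(pmax(si, 1), length(grid@s) - 1)
  ui <- pmin(pmax(ui, 1), length(grid@u) - 1)
  fs <- (s - grid@s[si]) / (grid@s[si + 1] - grid@s[si])
  fu <- (u - grid@u[ui]) / (grid@u[ui + 1] - grid@u[ui])
  fu <- pmin(pmax(fu, 0), 1)
  v00 <- grid@values[cbind(si, ui)]
  v10 <- grid@values[cbind(si + 1, ui)]
  v01 <- grid@values[cbind(si, ui + 1)]
  v11 <- grid@values[cbind(si + 1, ui + 1)]
  (1 - fs) * (1 - fu) * v00 + fs * (1 - fu) * v10 +
    (1 - fs) * fu * v01 + fs * fu * v11
}

# rows of the value matrix resampled at u/scale (used for the halved defocus
# argument of the two-photon integrand); returns a matrix aligned with the
# grid's own (s, u) lattice
otfScaledU <- function(grid, scale) {
  out <- grid@values
  for (i in seq_along(grid@s))
    out[i, ] <- approx(grid@u, grid@values[i, ], grid@u * scale, rule = 2)$y
  out
}

# value matrix resampled at s/scale for every u
otfScaledS <- function(grid, scale) {
  out <- grid@values
  for (j in seq_along(grid@u))
    out[, j] <- approx(grid@s, grid@values[, j], grid@s * scale, rule = 2)$y
  out
}

#' @describeIn makeOTFGrid long-format data frame (s, u, T) for CSV export
#' @param x an [OTFGrid-class]
#' @param row.names,optional,... passed on (unused)
#' @export
as.data.frame.OTFGrid <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(s = rep(x@s, times = length(x@u)),
             u = rep(x@u, each = length(x@s)),
             T = as.vector(x@values))
}
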