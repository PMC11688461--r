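# Axial responses I(u) of the optical-sectioning methods.
#
# Each method's response to a thin fluorescent sheet is an integral of the
# defocused OTF against method-specific apodization factors:
#
#   confocal (pinhole): Int jinc(b s) T^2(s,u) jinc(beta s) s ds
#   confocal (slit)/LC: Int snc(b s)  T^2(s,u) snc(beta s)  ds
#   two-photon        : Int jinc(2b s) T^2(s, u/2) [jinc(beta s)] s ds
#   structured        : |T(s0, u)| / T(s0, 0)
#   hybrid            : sqrt( Int_{smin}^{smax} T^2(s,u) T(s,0) ds )
#   light sheet       : exp(-u^2 / 2 c^2)
#   LiMo              : Int snc(b s) T^2(s,u) snc(beta s) [1 - cos(2 beta s)] ds
#
# where jinc(x) = 2 J1(x)/x and snc(x) = sin(x)/x (both 1 at the origin),
# b is the illumination spot radius and beta the pinhole/slit radius, all in
# normalized frequency units.  Curves are normalized to I(0) = 1 and the
# sectioning strength is reported as the FWHM in normalized defocus units.

.methods_enum <- c("confocal_pinhole", "confocal_slit", "two_photon",
                   "structured", "hybrid", "light_sheet", "limo",
                   "line_confocal", "widefield")

#' Method parameters for axial-response calculations
#'
#' @slot method one of `confocal_pinhole`, `confocal_slit`, `two_photon`,
#'   `structured`, `hybrid`, `light_sheet`, `limo`, `line_confocal`,
#'   `widefield`
#' @slot b illumination spot radius, normalized units (0 = ideal focus)
#' @slot beta pinhole / slit radius, normalized units
#' @slot c light-sheet thickness parameter in normalized defocus units
#' @slot s0 structured-illumination modulation frequency (0 < s0 <= 2)
#' @slot s_min,s_max hybrid-illumination filter band edges in [0, 2]
#' @aliases MethodParams-class
#' @exportClass MethodParams
setClass("MethodParams",
  representation(method = "character", b = "numeric", beta = "numeric",
                 c = "numeric", s0 = "numeric",
                 s_min = "numeric", s_max = "numeric"))

setValidity("MethodParams", function(object) {
  msg <- character(0)
  if (!object@method %in% .methods_enum)
    msg <- c(msg, paste("unknown method:", object@method))
  if (object@b < 0) msg <- c(msg, "b must be >= 0")
  if (object@method %in% c("confocal_pinhole", "confocal_slit",
                           "line_confocal", "limo") &&
      !(is.finite(object@beta) && object@beta > 0))
    msg <- c(msg, "beta must be > 0 for confocal/slit/LiMo methods")
  if (object@method == "light_sheet" &&
      !(is.finite(object@c) && object@c > 0))
    msg <- c(msg, "c must be > 0 for light sheet")
  if (object@method == "structured" &&
      !(is.finite(object@s0) && object@s0 > 0 && object@s0 <= 2))
    msg <- c(msg, "s0 must lie in (0, 2]")
  if (object@method == "hybrid") {
    if (!(is.finite(object@s_min) && is.finite(object@s_max) &&
          object@s_min >= 0 && object@s_max <= 2 &&
          object@s_min <= object@s_max))
      msg <- c(msg, "need 0 <= s_min <= s_max <= 2 for hybrid")
    else if (object@s_min == object@s_max)
      msg <- c(msg, "s_min = s_max collapses hybrid to structured; use method = 'structured'")
  }
  if (length(msg)) msg else TRUE
})

#' Create method parameters
#'
#' @param method method label, see [MethodParams-class]
#' @param b illumination spot radius (normalized); 0 is an ideal focus
#' @param beta pinhole or slit radius (normalized)
#' @param c light-sheet thickness parameter (normalized defocus units)
#' @param s0 structured-illumination frequency
#' @param s_min,s_max hybrid filter band edges
#' @return a [MethodParams-class] object
#' @examples
#' methodParams("confocal_pinhole", beta = 0.5)
#' methodParams("hybrid", s_min = 1, s_max = 2)
#' @export
methodParams <- function(method, b = 0, beta = 0.5, c = NA_real_, s0 = 1,
                         s_min = NA_real_, s_max = NA_real_) {
  new("MethodParams", method = method, b = b, beta = beta, c = c,
      s0 = s0, s_min = s_min, s_max = s_max)
}

#' Axial-response curve of one sectioning method
#'
#' @slot method method label
#' @slot u normalized defocus samples
#' @slot intensity response normalized to I(0) = 1
#' @slot fwhm full width at half maximum in normalized defocus units
#' @aliases AxialResponseCurve-class
#' @exportClass AxialResponseCurve
setClass("AxialResponseCurve",
  representation(method = "character", u = "numeric", intensity = "numeric",
                 fwhm = "numeric"))

setMethod("show", "AxialResponseCurve", function(object) {
  cat(sprintf("AxialResponseCurve '%s': %d u-samples, FWHM = %.4g\n",
              object@method, length(object@u), object@fwhm))
})

#' FWHM sectioning strength
#' @param object an [AxialResponseCurve-class]
#' @return the full width at half maximum in normalized defocus units
#' @export
setGeneric("fwhm", function(object) standardGeneric("fwhm"))

#' @rdname fwhm
#' @export
setMethod("fwhm", "AxialResponseCurve", function(object) object@fwhm)

#' @describeIn axialResponse curve as a data frame (method, u, I)
#' @param x an [AxialResponseCurve-class]
#' @param row.names,optional,... unused
#' @export
as.data.frame.AxialResponseCurve <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(method = x@method, u = x@u, I = x@intensity)
}

.newCurve <- function(method, u, intensity) {
  intensity <- intensity / max(intensity)
  new("AxialResponseCurve", method = method, u = u, intensity = intensity,
      fwhm = fwhm1d(u, intensity))
}

# common quadrature of an s-integrand matrix (rows = otf s grid) over s
.sIntegrate <- function(otf, integrand) {
  ds <- otf@s[2] - otf@s[1]
  w <- quadWeights(length(otf@s), ds)
  colSums(integrand * w)
}

#' Axial response of a sectioning method
#'
#' Evaluates the method's axial-response integral on the defocus grid of
#' `otf`, normalizes to I(0) = 1 and extracts the FWHM.  Dispatches on
#' `params@method`; the per-method functions ([responseConfocal()],
#' [responseTwoPhoton()], [responseModulated()], [responseLightSheet()],
#' [responseLimo()]) can be called directly.
#'
#' @param params a [MethodParams-class]
#' @param otf an [OTFGrid-class] from [makeOTFGrid()]
#' @param ... passed to the per-method function
#' @return an [AxialResponseCurve-class]
#' @examples
#' g <- makeOTFGrid(s_points = 129, u_max = 20, u_points = 101)
#' fwhm(axialResponse(methodParams("confocal_pinhole", beta = 0.5), g))
#' @export
axialResponse <- function(params, otf, ...) {
  switch(params@method,
    confocal_pinhole = ,
    confocal_slit = responseConfocal(params, otf),
    line_confocal = responseConfocal(params, otf),
    two_photon = responseTwoPhoton(params, otf, ...),
    structured = ,
    hybrid = responseModulated(params, otf),
    light_sheet = responseLightSheet(params, otf),
    limo = responseLimo(params, otf),
    widefield = .newCurve("widefield", otf@u, rep(1, length(otf@u))),
    stop("unknown method: ", params@method))
}

#' Confocal (pinhole or slit) axial response
#'
#' Pinhole: radial integral with measure s ds and jinc apodizations for the
#' illumination spot (radius b) and pinhole (radius beta).  Slit (also used
#' for line confocal): one-dimensional integral with sinc apodizations.
#'
#' @inheritParams axialResponse
#' @return an [AxialResponseCurve-class]
#' @export
responseConfocal <- function(params, otf) {
  if (length(otf@u) == 0) stop("empty defocus grid", call. = FALSE)
  s <- otf@s
  T2 <- otf@values^2
  if (params@method == "confocal_pinhole") {
    integ <- jinc(params@b * s) * jinc(params@beta * s) * s * T2
  } else {
    integ <- snc(params@b * s) * snc(params@beta * s) * T2
  }
  .newCurve(params@method, otf@u, .sIntegrate(otf, integ))
}

#' Two-photon axial response
#'
#' Intra-focal excitation: the nonlinear excitation squares the illumination
#' PSF, which in the frequency domain doubles the spot argument (2 b s) and
#' halves the defocus argument (u/2):
#' \deqn{I(u) = \int jinc(2 b s)\, T^2(s, u/2)\, s\, ds.}
#' An optional detection pinhole constrains the detection arm, which
#' multiplies the integrand by its defocused transfer jinc(beta s) T(s, u);
#' smaller pinholes then strengthen the sectioning.
#' `form = "comparison"` instead evaluates the cross-method comparison
#' integrand T(s/2, u/2) T(s, u) s ds, the form used by
#' [sectioningRanking()] where illumination (at the doubled wavelength) and
#' unconstrained detection are kept as separate transfer factors.
#'
#' @inheritParams axialResponse
#' @param pinhole_beta optional detection pinhole radius (normalized); NULL
#'   for unconstrained detection
#' @param form `"squared"` (default) or `"comparison"`
#' @return an [AxialResponseCurve-class]
#' @export
responseTwoPhoton <- function(params, otf, pinhole_beta = NULL,
                              form = c("squared", "comparison")) {
  form <- match.arg(form)
  s <- otf@s
  if (form == "squared") {
    Th <- otfScaledU(otf, 0.5)   # T(s, u/2)
    integ <- jinc(2 * params@b * s) * s * Th^2
    if (!is.null(pinhole_beta))
      integ <- integ * jinc(pinhole_beta * s) * otf@values
  } else {
    Th <- otfScaledU(otfGridScaledS(otf), 0.5)  # T(s/2, u/2)
    integ <- jinc(2 * params@b * s) * s * Th * otf@values
  }
  .newCurve("two_photon", otf@u, .sIntegrate(otf, integ))
}

# helper: OTFGrid whose values are T(s/2, u) on the original lattice
otfGridScaledS <- function(otf) {
  new("OTFGrid", s = otf@s, u = otf@u, values = .clamp01(otfScaledS(otf, 0.5)))
}

.clamp01 <- function(m) { m[m > 1] <- 1; m[m < -1] <- -1; m }

#' Structured / hybrid illumination axial response
#'
#' Structured illumination at a single modulation frequency s0 responds as
#' the OTF magnitude |T(s0, u)| (normalized).  Hybrid illumination with a
#' demodulation filter passing the band [s_min, s_max] responds as the
#' square root of the band integral of T^2(s, u) T(s, 0).
#'
#' @inheritParams axialResponse
#' @return an [AxialResponseCurve-class]
#' @export
responseModulated <- function(params, otf) {
  if (params@method == "structured") {
    I <- abs(otfAt(otf, params@s0, otf@u))
    return(.newCurve("structured", otf@u, I))
  }
  sel <- otf@s >= params@s_min & otf@s <= params@s_max
  if (sum(sel) < 2)
    stop("hybrid band [s_min, s_max] too narrow for the grid", call. = FALSE)
  sub <- otf@s[sel]
  w <- quadWeights(length(sub), sub[2] - sub[1])
  T0 <- otf@values[sel, which.min(abs(otf@u))]
  I <- sqrt(colSums(otf@values[sel, ]^2 * T0 * w))
  .newCurve("hybrid", otf@u, I)
}

#' Light-sheet axial response
#'
#' The selective illumination confines excitation to a Gaussian sheet of
#' normalized thickness parameter c, and on the detection axis
#' T(0, 0, u) = 1, so \eqn{I(u) = \exp(-u^2 / 2c^2)} with
#' FWHM \eqn{= 2 c \sqrt{2 \ln 2}}.
#'
#' @inheritParams axialResponse
#' @return an [AxialResponseCurve-class]
#' @export
responseLightSheet <- function(params, otf) {
  .newCurve("light_sheet", otf@u, exp(-otf@u^2 / (2 * params@c^2)))
}

#' LiMo (line-illumination modulation) axial response
#'
#' Linear decoding of off-axis line-scan detection:
#' \deqn{I(u) = \int snc(b s)\, T^2(s, u)\, snc(\beta s)\,
#'       [1 - \cos(2 \beta s)]\, ds.}
#'
#' @inheritParams axialResponse
#' @return an [AxialResponseCurve-class]
#' @export
responseLimo <- function(params, otf) {
  s <- otf@s
  integ <- snc(params@b * s) * snc(params@beta * s) *
    (1 - cos(2 * params@beta * s)) * otf@values^2
  .newCurve("limo", otf@u, .sIntegrate(otf, integ))
}

#' Light-sheet thickness parameter from the illumination NA
#'
#' Default light-sheet Gaussian parameter: the normalized defocus of the
#' Rayleigh range \eqn{z_R = n \lambda_{ex} / (\pi \mathrm{NA}_{ill}^2)}
#' converted through the illumination arm.
#'
#' @param cfg an [OpticalConfig-class]
#' @return c in normalized defocus units
#' @export
lightSheetC <- function(cfg) {
  zR <- cfg@refractive_index * cfg@wavelength_ex / (pi * cfg@na_ill^2)
  opticalCoordinate(zR, cfg, arm = "illumination")
}

#' Rank sectioning methods by FWHM
#'
#' Evaluates every supplied method on the common defocus grid and returns
#' them sorted by increasing FWHM (strongest sectioning first).  With the
#' default reference parameter set (ideal illumination b = 0, pinhole/slit
#' radius beta = 0.5, structured frequency s0 = 1, hybrid band [1, 2],
#' light-sheet c from the illumination NA via [lightSheetC()], two-photon
#' by the comparison form), the ordering is
#' light sheet < LiMo < confocal < SIM < HiLo < two-photon < line confocal.
#'
#' @param otf an [OTFGrid-class]
#' @param cfg an [OpticalConfig-class] (used for the light-sheet default)
#' @param params_set named list of [MethodParams-class]; NULL for the
#'   reference set
#' @return data frame with columns `method` and `fwhm`, sorted ascending
#' @examples
#' \donttest{
#' g <- makeOTFGrid()
#' sectioningRanking(g, opticalConfig())
#' }
#' @export
sectioningRanking <- function(otf, cfg = opticalConfig(), params_set = NULL) {
  if (is.null(params_set)) {
    params_set <- list(
      light_sheet = methodParams("light_sheet", c = lightSheetC(cfg)),
      limo = methodParams("limo", beta = 0.5),
      confocal = methodParams("confocal_pinhole", beta = 0.5),
      structured = methodParams("structured", s0 = 1),
      hybrid = methodParams("hybrid", s_min = 1, s_max = 2),
      two_photon = methodParams("two_photon"),
      line_confocal = methodParams("line_confocal", beta = 0.5))
  }
  if (length(params_set) == 0) stop("no methods supplied", call. = FALSE)
  if (is.null(names(params_set)))
    names(params_set) <- vapply(params_set, function(p) p@method, character(1))
  fw <- vapply(names(params_set), function(nm) {
    p <- params_set[[nm]]
    cur <- if (p@method == "two_photon")
      responseTwoPhoton(p, otf, form = "comparison")
    else axialResponse(p, otf)
    cur@fwhm
  }, numeric(1))
  out <- data.frame(method = names(params_set), fwhm = fw,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$fwhm), , drop = FALSE]
}
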