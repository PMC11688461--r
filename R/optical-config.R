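#' Optical system configuration
#'
#' Container for the optical parameters shared by every calculation in the
#' package: numerical apertures of the detection and illumination arms,
#' excitation and emission wavelengths, immersion refractive index and
#' lateral magnification.  The default configuration describes a
#' water-immersion 20x / NA 1.0 objective imaging a green fluorophore
#' (excitation 0.488 um, emission 0.520 um), the reference system used for
#' all method comparisons.
#'
#' @slot na_det detection numerical aperture (dimensionless)
#' @slot na_ill illumination numerical aperture (dimensionless)
#' @slot wavelength_ex excitation wavelength (um)
#' @slot wavelength_em emission wavelength (um)
#' @slot refractive_index immersion medium refractive index
#' @slot magnification lateral magnification
#'
#' @aliases OpticalConfig-class
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  representation(
    na_det = "numeric",
    na_ill = "numeric",
    wavelength_ex = "numeric",
    wavelength_em = "numeric",
    refractive_index = "numeric",
    magnification = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character(0)
  n <- object@refractive_index
  if (!(length(n) == 1 && is.finite(n) && n > 0))
    msg <- c(msg, "refractive_index must be a positive number")
  for (slot in c("na_det", "na_ill")) {
    v <- slot(object, slot)
    if (!(length(v) == 1 && is.finite(v) && v > 0 && v <= n))
      msg <- c(msg, sprintf("%s must satisfy 0 < NA <= refractive_index", slot))
  }
  for (slot in c("wavelength_ex", "wavelength_em")) {
    v <- slot(object, slot)
    if (!(length(v) == 1 && is.finite(v) && v > 0))
      msg <- c(msg, sprintf("%s must be strictly positive", slot))
  }
  if (!(length(object@magnification) == 1 && is.finite(object@magnification) &&
        object@magnification > 0))
    msg <- c(msg, "magnification must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Create an optical system configuration
#'
#' @param na_det detection numerical aperture
#' @param na_ill illumination numerical aperture
#' @param wavelength_ex excitation wavelength in um
#' @param wavelength_em emission wavelength in um
#' @param refractive_index immersion refractive index
#' @param magnification lateral magnification
#' @return an [OpticalConfig-class] object
#' @examples
#' cfg <- opticalConfig()
#' opticalCoordinate(1, cfg, arm = "detection")
#' @export
opticalConfig <- function(na_det = 1.0, na_ill = 1.0,
                          wavelength_ex = 0.488, wavelength_em = 0.520,
                          refractive_index = 1.33, magnification = 20) {
  new("OpticalConfig",
      na_det = na_det, na_ill = na_ill,
      wavelength_ex = wavelength_ex, wavelength_em = wavelength_em,
      refractive_index = refractive_index, magnification = magnification)
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  detection   : NA %.3g, emission %.4g um\n",
              object@na_det, object@wavelength_em))
  cat(sprintf("  illumination: NA %.3g, excitation %.4g um\n",
              object@na_ill, object@wavelength_ex))
  cat(sprintf("  medium n = %.3g, magnification %gx\n",
              object@refractive_index, object@magnification))
})

#' Accessors for OpticalConfig
#'
#' @param cfg an [OpticalConfig-class] object
#' @return the requested numeric parameter
#' @name opticalConfig-accessors
#' @export
detectionNA <- function(cfg) cfg@na_det
#' @rdname opticalConfig-accessors
#' @export
illuminationNA <- function(cfg) cfg@na_ill
#' @rdname opticalConfig-accessors
#' @export
wavelengthEx <- function(cfg) cfg@wavelength_ex
#' @rdname opticalConfig-accessors
#' @export
wavelengthEm <- function(cfg) cfg@wavelength_em
#' @rdname opticalConfig-accessors
#' @export
refractiveIndex <- function(cfg) cfg@refractive_index

#' Normalized axial (defocus) optical coordinate
#'
#' Converts a physical defocus distance z (um) into the dimensionless
#' high-aperture defocus coordinate
#' \deqn{u = \frac{8 \pi n z}{\lambda} \sin^2(\alpha/2), \qquad
#'       \sin\alpha = \mathrm{NA}/n,}
#' using the excitation wavelength and illumination NA for the illumination
#' arm and the emission wavelength and detection NA for the detection arm.
#' The coordinate is odd in z: u(-z) = -u(z).
#'
#' @param z physical defocus in um (finite, vectorised)
#' @param cfg an [OpticalConfig-class]
#' @param arm which arm's wavelength/NA to use
#' @return normalized defocus u (same length as z)
#' @export
opticalCoordinate <- function(z, cfg, arm = c("detection", "illumination")) {
  arm <- match.arg(arm)
  stopifnotFinite(z, "defocus z")
  na <- if (arm == "detection") cfg@na_det else cfg@na_ill
  lam <- if (arm == "detection") cfg@wavelength_em else cfg@wavelength_ex
  n <- cfg@refractive_index
  alpha <- asin(na / n)
  (8 * pi * n * z / lam) * sin(alpha / 2)^2
}

#' Inverse of [opticalCoordinate()]: normalized defocus to um
#' @param u normalized defocus
#' @inheritParams opticalCoordinate
#' @return physical defocus z in um
#' @export
physicalDefocus <- function(u, cfg, arm = c("detection", "illumination")) {
  arm <- match.arg(arm)
  u / opticalCoordinate(1, cfg, arm)
}

#' Read / write an optical configuration as YAML
#' @param path file path
#' @param cfg an [OpticalConfig-class]
#' @return `readOpticalConfig` returns an [OpticalConfig-class];
#'   `writeOpticalConfig` returns `path` invisibly
#' @export
readOpticalConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(opticalConfig, vals[intersect(names(vals), names(formals(opticalConfig)))])
}

#' @rdname readOpticalConfig
#' @export
writeOpticalConfig <- function(cfg, path) {
  yaml::write_yaml(list(
    na_det = cfg@na_det, na_ill = cfg@na_ill,
    wavelength_ex = cfg@wavelength_ex, wavelength_em = cfg@wavelength_em,
    refractive_index = cfg@refractive_index,
    magnification = cfg@magnification), path)
  invisible(path)
}
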