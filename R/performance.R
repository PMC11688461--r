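# Performance calculators: imaging-time models for mosaic and strip
# scanning, signal-to-noise ratios, penetration depth and phototoxicity.

#' Mosaic-scan total imaging time
#'
#' Stop-and-stare tiling of an L x L sample with M x M fields:
#' \deqn{T_m = (t_m + \sqrt{4M/a})\, L^2/M^2 - \sqrt{4M/a}.}
#' The square-root term is the stage transit time between fields for a
#' triangular velocity profile at acceleration a.
#'
#' @param t_m per-field exposure time (s)
#' @param M field-of-view side length (mm)
#' @param a stage acceleration (mm/s^2)
#' @param L sample side length (mm), >= M
#' @return total time in seconds
#' @examples
#' mosaicTime(t_m = 0.533, M = 0.67, a = 200, L = 10)
#' @export
mosaicTime <- function(t_m, M, a, L) {
  .checkTiming(t_m, M, a, L)
  if (any(L < M)) stop("L < M: use smallAreaTime()", call. = FALSE)
  tr <- sqrt(4 * M / a)
  (t_m + tr) * L^2 / M^2 - tr
}

#' Strip-scan total imaging time
#'
#' Continuous line-scan strips at per-line exposure t_s and sampling size
#' p: \deqn{T_s = L^2 t_s / (p M) + (L/M - 1)\sqrt{4M/a}.}
#'
#' @param t_s per-line exposure time (s)
#' @param p sampling size (mm)
#' @inheritParams mosaicTime
#' @return total time in seconds
#' @export
stripTime <- function(t_s, p, M, a, L) {
  .checkTiming(t_s, M, a, L, p = p)
  if (any(L < M)) stop("L < M: use smallAreaTime()", call. = FALSE)
  L^2 * t_s / (p * M) + (L / M - 1) * sqrt(4 * M / a)
}

#' Small-area imaging time
#'
#' Below a single field of view the beam is scanned without moving the
#' stage, so the time is camera/scanner limited: T = (t_m / M^2) L^2.
#'
#' @inheritParams mosaicTime
#' @param L sample side length (mm), <= M
#' @return total time in seconds
#' @export
smallAreaTime <- function(t_m, M, L) {
  if (any(L < 0) || M <= 0 || t_m < 0) stop("invalid timing parameters")
  if (any(L > M)) stop("L > M: use mosaicTime()", call. = FALSE)
  t_m / M^2 * L^2
}

.checkTiming <- function(texp, M, a, L, p = 1) {
  if (texp < 0 || M <= 0 || a <= 0 || any(L <= 0) || p <= 0)
    stop("timing parameters must be strictly positive", call. = FALSE)
}

#' Mosaic-time quadratic and constant coefficients
#'
#' The mosaic-scan time is quadratic in the sample side length L:
#' T_m = q L^2 + c with q = (t_m + sqrt(4M/a)) / M^2 and c = -sqrt(4M/a).
#' With the reference stage (M = 0.67 mm, a = 200 mm/s^2) the quadratic
#' coefficients are 1.45 s/mm^2 for point scanning (t_m = 533 ms),
#' 0.28 for spinning disk (10 ms) and 0.28 for wide-field (8.3 ms), with
#' constant -0.12 s.  For small areas the coefficient reduces to t_m/M^2
#' (1.2 s/mm^2 for point scanning).
#'
#' @inheritParams mosaicTime
#' @return list with `quadratic` (s/mm^2) and `constant` (s)
#' @examples
#' mosaicCoefficients(t_m = 2048^2 / (512^2 * 30), M = 0.67, a = 200)
#' @export
mosaicCoefficients <- function(t_m, M, a) {
  tr <- sqrt(4 * M / a)
  list(quadratic = (t_m + tr) / M^2, constant = -tr)
}

#' Per-method SNR
#'
#' Single-image signal-to-noise ratios under a common image statistic f
#' (mean signal) and var(f):
#' \itemize{
#'   \item confocal / line confocal: sqrt(S/S0) f / sd(f) — the aperture
#'     passes only the fraction S/S0 of the illumination spot;
#'   \item two-photon / light sheet: f / sd(f) (unconstrained detection);
#'   \item LiMo: sqrt(C_LiMo) f / sd(f) with
#'     C_LiMo = 2 (m3 + m4) - (m1 + m2 + m5 + m6);
#'   \item SIM: C_SIM sqrt(3)/2 f / sd(f) with
#'     C_SIM = (m3 + m4 - m1 - m6)/k;
#'   \item HiLo: f / (sqrt(C_HiLo) sd(f)) with
#'     C_HiLo = (sd(m)/sqrt(2)) / mean(m) (the sqrt(2) is the 3 dB
#'     band-pass attenuation).
#' }
#' m(i) is the modulation of the i-th off-axis line.
#'
#' @param method one of `confocal`, `line_confocal`, `two_photon`,
#'   `light_sheet`, `limo`, `sim`, `hilo`
#' @param f mean signal level
#' @param var_f signal variance (> 0)
#' @param S aperture (pinhole/slit) area, normalized
#' @param S0 illumination spot area, normalized (S <= S0)
#' @param m per-line modulation values m(1..6)
#' @param k SIM normalization coefficient
#' @return the SNR value
#' @examples
#' snrValue("two_photon", f = 4, var_f = 4)  # 2
#' @export
snrValue <- function(method = c("confocal", "line_confocal", "two_photon",
                                "light_sheet", "limo", "sim", "hilo"),
                     f, var_f, S = 0.25, S0 = 1,
                     m = c(0.5, 0.7, 1, 1, 0.7, 0.5), k = 1) {
  method <- match.arg(method)
  if (var_f <= 0) stop("var_f must be > 0 (undefined ratio)", call. = FALSE)
  if (S > S0) stop("S must not exceed S0", call. = FALSE)
  sdf <- sqrt(var_f)
  switch(method,
    confocal = ,
    line_confocal = sqrt(S) * f / (sqrt(S0) * sdf),
    two_photon = ,
    light_sheet = f / sdf,
    limo = {
      C <- 2 * sum(m[3:4]) - (sum(m[1:2]) + sum(m[5:6]))
      if (C < 0) stop("modulation profile gives negative C_LiMo")
      sqrt(C) * f / sdf
    },
    sim = {
      C <- (m[3] + m[4] - m[1] - m[6]) / k
      C * sqrt(3) / 2 * f / sdf
    },
    hilo = {
      C <- (sd(m) / sqrt(2)) / mean(m)
      f / (sqrt(C) * sdf)
    })
}

#' SNR ranking under a shared modulation profile
#'
#' Evaluates every method's SNR at equal f and var(f) with a common
#' modulation profile and per-method aperture ratios, and returns the
#' methods sorted by decreasing SNR.  With the defaults (gentle modulation
#' across the six lines, pinhole S/S0 = 0.25, slit S/S0 = 0.5) the order
#' is HiLo > LiMo > two-photon = light sheet > SIM > LC > confocal.
#'
#' @param f,var_f common image statistics
#' @param m shared per-line modulation profile
#' @param S_pinhole,S_slit,S0 aperture areas
#' @param k SIM normalization
#' @return data frame with columns `method` and `snr`, sorted descending
#' @export
snrRanking <- function(f = 1, var_f = 1, m = c(0.5, 0.7, 1, 1, 0.7, 0.5),
                       S_pinhole = 0.25, S_slit = 0.5, S0 = 1, k = 1) {
  vals <- c(
    confocal = snrValue("confocal", f, var_f, S = S_pinhole, S0 = S0),
    line_confocal = snrValue("line_confocal", f, var_f, S = S_slit, S0 = S0),
    two_photon = snrValue("two_photon", f, var_f),
    light_sheet = snrValue("light_sheet", f, var_f),
    limo = snrValue("limo", f, var_f, m = m),
    sim = snrValue("sim", f, var_f, m = m, k = k),
    hilo = snrValue("hilo", f, var_f, m = m))
  out <- data.frame(method = names(vals), snr = unname(vals),
                    stringsAsFactors = FALSE)
  out[order(-out$snr), , drop = FALSE]
}

#' Illumination power vs depth
#'
#' Scattering attenuates the illumination exponentially with depth.  The
#' linear (one-photon) power is P0 exp(-z/ls); the effective nonlinear
#' (two-photon) excitation follows the squared attenuation exp(-2 z/ls)
#' (returned relative to the surface).
#'
#' @param z depth in um (vectorised)
#' @param ls scattering length (um)
#' @param P0 surface power (linear branch)
#' @param order `"linear"` or `"nonlinear"`
#' @return power (linear: absolute, scaled by P0; nonlinear: relative)
#' @export
penetrationPower <- function(z, ls, P0 = 1,
                             order = c("linear", "nonlinear")) {
  order <- match.arg(order)
  if (ls <= 0 || P0 <= 0 || any(z < 0))
    stop("parameters must be positive", call. = FALSE)
  if (order == "linear") P0 * exp(-z / ls) else exp(-2 * z / ls)
}

#' Phototoxic dose
#'
#' G = P t / S_area: illumination power times exposure time per unit
#' illuminated area.  In scanning microscopy both the illuminated area and
#' the effective exposure of a defocused plane scale with the same defocus
#' factor, leaving G unchanged — see [scanningInvariance()].
#'
#' @param P illumination power (mW)
#' @param t exposure time (s)
#' @param S_area illuminated area (um^2), > 0
#' @return dose G (mW s / um^2)
#' @export
phototoxicity <- function(P, t, S_area) {
  if (any(S_area <= 0)) stop("S_area must be > 0", call. = FALSE)
  P * t / S_area
}

#' Defocus invariance of the scanning dose
#'
#' Checks that scaling the illuminated area and the exposure time by the
#' same defocus factor leaves the dose unchanged.
#'
#' @inheritParams phototoxicity
#' @param factor defocus scaling factor applied to both t and S_area
#' @return TRUE when the doses agree to machine precision
#' @export
scanningInvariance <- function(P, t, S_area, factor = 2) {
  isTRUE(all.equal(phototoxicity(P, t, S_area),
                   phototoxicity(P, factor * t, factor * S_area)))
}
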