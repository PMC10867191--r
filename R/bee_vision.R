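## Hymenopteran colour hexagon model: receptor quantum catches under von
## Kries adaptation to green foliage, nonlinear transduction, hexagon
## coordinates, and the two signal statistics used throughout the package:
## chromatic colour contrast (cc) and achromatic green contrast (gc).

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Background-relative receptor quantum catches
#'
#' For each receptor i, integrates stimulus x illuminant x sensitivity
#' over the common grid (trapezoid rule) and divides by the same integral
#' for the adaptation background:
#' \deqn{P_i = \int R(\lambda) I(\lambda) S_i(\lambda) d\lambda \Big/
#'            \int B(\lambda) I(\lambda) S_i(\lambda) d\lambda.}
#' This is von Kries adaptation: the green-foliage background yields
#' P = 1 in every receptor, so all catches are expressed relative to the
#' visual system's adapted state and any positive rescaling of the
#' illuminant cancels.
#'
#' @param x a [spectra] object (resampled to `curves$wl` if needed).
#' @param curves a [standard_curves] bundle.
#' @return matrix (one row per curve in `x`) with columns `P_uv`, `P_b`,
#'   `P_g`.
#' @export
quantum_catch <- function(x, curves = standard_curves()) {
  stopifnot(inherits(x, "spectra"), inherits(curves, "standard_curves"))
  if (!isTRUE(all.equal(x$wl, curves$wl))) x <- resample(x, curves$wl)
  wl <- curves$wl
  denom <- vapply(1:3, function(i)
    trapz(wl, curves$background * curves$illuminant * curves$S[, i]),
    numeric(1))
  if (any(denom <= 0))
    stop("degenerate curves: background catch is zero in a receptor")
  P <- t(apply(x$refl, 2, function(r)
    vapply(1:3, function(i)
      trapz(wl, r * curves$illuminant * curves$S[, i]), numeric(1)) / denom))
  P <- matrix(P, ncol = 3,
              dimnames = list(colnames(x$refl), c("P_uv", "P_b", "P_g")))
  P
}

#' Receptor excitation from quantum catch
#'
#' Phototransduction nonlinearity E = P / (P + 1): the adaptation
#' background (P = 1) maps to half-maximal excitation 0.5, and E
#' saturates towards 1 for bright stimuli.
#'
#' @param P matrix or vector of non-negative background-relative catches.
#' @return matrix with columns `E_uv`, `E_b`, `E_g`.
#' @export
excitation <- function(P) {
  P <- if (is.matrix(P)) P else matrix(P, nrow = 1)
  if (ncol(P) != 3) stop("expected a catch triplet (3 columns)")
  if (any(P < 0)) stop("negative quantum catch")
  E <- P / (P + 1)
  colnames(E) <- c("E_uv", "E_b", "E_g")
  E
}

hexagon_sectors <- c("blue-green", "blue", "UV-blue",
                     "UV", "UV-green", "green")

#' Colour hexagon locus, colour contrast and green contrast
#'
#' Maps receptor excitations into the 2-D colour hexagon:
#' x = (sqrt(3)/2)(E_g - E_uv), y = E_b - (E_uv + E_g)/2.
#' Colour contrast `cc` is the Euclidean distance from the locus to the
#' achromatic centre (the background's position); green contrast `gc` is
#' |0.5 - E_g|, the achromatic signal carried by the green receptor
#' channel alone.  Loci closer to the centre than `achromatic_radius` are
#' flagged achromatic: within that disc bees do not reliably perceive a
#' chromatic difference from the foliage background.  Each locus is also
#' assigned to one of six 60-degree hexagon sectors (UV, UV-blue, blue,
#' blue-green, green, UV-green), with the pure-UV direction at the E_uv
#' vertex.
#'
#' @param E matrix of excitations (columns uv, blue, green) in [0, 1].
#' @param achromatic_radius disc radius in hexagon units; default 0.11, a
#'   common behavioural discrimination threshold.
#' @return data.frame with columns `x`, `y`, `cc`, `gc`, `sector`,
#'   `achromatic`.
#' @export
hexagon_locus <- function(E, achromatic_radius = 0.11) {
  E <- if (is.matrix(E)) E else matrix(E, nrow = 1)
  if (any(E < 0 | E > 1)) stop("excitations must lie in [0, 1]")
  x <- sqrt(3) / 2 * (E[, 3] - E[, 1])
  y <- E[, 2] - (E[, 1] + E[, 3]) / 2
  cc <- sqrt(x^2 + y^2)
  gc <- abs(0.5 - E[, 3])
  ang <- atan2(y, x) %% (2 * pi)              # 0 at +x axis
  sector <- hexagon_sectors[findInterval(ang, seq(0, 2 * pi, by = pi / 3),
                                         rightmost.closed = TRUE)]
  sector[cc == 0] <- NA_character_
  data.frame(x = x, y = y, cc = cc, gc = gc, sector = sector,
             achromatic = cc < achromatic_radius,
             row.names = rownames(E), stringsAsFactors = FALSE)
}

#' Full visual pipeline: spectra to hexagon signal table
#'
#' Deterministic composition of [quantum_catch], [excitation] and
#' [hexagon_locus].
#'
#' @inheritParams quantum_catch
#' @inheritParams hexagon_locus
#' @return data.frame with one row per curve: `species`, excitations,
#'   hexagon coordinates, `cc`, `gc`, `sector`, `achromatic`.
#' @export
spectrum_to_signals <- function(x, curves = standard_curves(),
                                achromatic_radius = 0.11) {
  P <- quantum_catch(x, curves)
  E <- excitation(P)
  loc <- hexagon_locus(E, achromatic_radius)
  cbind(data.frame(species = x$meta$species, stringsAsFactors = FALSE),
        as.data.frame(E), loc)
}

## --- cosmetic human-colour rendering ------------------------------------

## Single-lobe Gaussian approximations to the CIE 1931 standard observer
## (adequate for rendering swatches; not used in any statistic).
cie_approx <- function(wl) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2); exp(-0.5 * ((x - mu) / s)^2)
  }
  xbar <- 1.056 * g(wl, 599.8, 37.9, 31.0) +
    0.362 * g(wl, 442.0, 16.0, 26.7) - 0.065 * g(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(wl, 568.8, 46.9, 40.5) + 0.286 * g(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(wl, 437.0, 11.8, 36.0) + 0.681 * g(wl, 459.0, 26.0, 13.8)
  cbind(pmax(xbar, 0), pmax(ybar, 0), pmax(zbar, 0))
}

#' Approximate human-vision colour of reflectance spectra
#'
#' Renders each curve as an sRGB hex string under the D65 illuminant using
#' Gaussian approximations of the CIE 1931 matching functions.  Purely
#' cosmetic (figure tip colours); plays no role in the bee-vision
#' statistics.
#'
#' @param x a [spectra] object.
#' @return character vector of `#RRGGBB` strings, one per curve.
#' @export
spec_to_rgb <- function(x) {
  stopifnot(inherits(x, "spectra"))
  wl <- x$wl
  keep <- wl >= 380 & wl <= 700
  wl <- wl[keep]
  cmf <- cie_approx(wl)
  ill <- stats::approx(d65_wl, d65_spd, xout = wl, rule = 2)$y
  k <- 1 / trapz(wl, ill * cmf[, 2])
  m <- rbind(c(3.2406, -1.5372, -0.4986),
             c(-0.9689, 1.8758, 0.0415),
             c(0.0557, -0.2040, 1.0570))
  apply(x$refl[keep, , drop = FALSE], 2, function(r) {
    XYZ <- k * vapply(1:3, function(i) trapz(wl, r * ill * cmf[, i]),
                      numeric(1))
    rgb_lin <- pmin(pmax(as.vector(m %*% XYZ), 0), 1)
    srgb <- ifelse(rgb_lin <= 0.0031308, 12.92 * rgb_lin,
                   1.055 * rgb_lin^(1 / 2.4) - 0.055)
    grDevices::rgb(srgb[1], srgb[2], srgb[3])
  })
}
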