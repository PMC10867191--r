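## Built-in standard curves for the bee visual model: daylight illuminant,
## green-foliage adaptation background, and honeybee receptor sensitivities.

## CIE standard illuminant D65, relative spectral power at 10 nm steps,
## 300-700 nm (energy units; normalised to 100 at 560 nm).
d65_wl <- seq(300, 700, by = 10)
d65_spd <- c(
  0.03, 3.29, 20.24, 37.05, 39.95, 44.91, 46.64, 52.09, 49.98, 54.65,
  82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86, 115.92,
  108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05, 100.00, 96.33,
  95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70, 80.03, 80.21, 82.28,
  78.28, 69.72, 71.61)

#' Standard daylight illuminant in relative quantum units
#'
#' CIE D65 spectral power interpolated to `grid` and converted from energy
#' to relative photon flux (multiplication by wavelength), then scaled to
#' a maximum of 1.  Photoreceptor models count photons, not energy, hence
#' the quantum conversion.
#'
#' @param grid wavelengths in nm.
#' @return numeric vector of relative quanta on `grid`.
#' @export
illuminant_d65 <- function(grid = 300:700) {
  e <- stats::approx(d65_wl, d65_spd, xout = grid, rule = 2)$y
  q <- e * grid
  q / max(q)
}

#' Green-foliage adaptation background reflectance
#'
#' A smooth canonical green-leaf curve (synthetic, parametric): low
#' UV/blue reflectance, the chlorophyll "green bump" near 550 nm, and the
#' onset of the red edge towards 700 nm.  It reproduces the qualitative
#' shape of published leaf spectra used as the adaptation background in
#' hymenopteran colour-space work; it is not a measurement.
#'
#' @param grid wavelengths in nm.
#' @return numeric vector of reflectance fractions on `grid`.
#' @export
leaf_background <- function(grid = 300:700) {
  0.04 +
    0.10 * exp(-((grid - 550) / 45)^2) +
    0.35 * stats::plogis((grid - 705) / 18)
}

#' Visual pigment absorbance template (rhodopsin nomogram)
#'
#' Govardovskii et al. (2000) A1 template: alpha band plus beta band,
#' parameterised only by the peak wavelength `lmax`.
#'
#' @param grid wavelengths in nm.
#' @param lmax peak absorbance wavelength in nm.
#' @return normalized absorbance (max 1) on `grid`.
#' @export
pigment_template <- function(grid, lmax) {
  x <- lmax / grid
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  b <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((grid - lmb) / b)^2)
  s <- alpha + beta
  s / max(s)
}

#' Honeybee photoreceptor spectral sensitivities
#'
#' UV, blue and green receptor curves for *Apis mellifera*, generated from
#' the rhodopsin nomogram with literature peak wavelengths 344, 436 and
#' 544 nm and normalised to a maximum of 1.
#'
#' @param grid wavelengths in nm.
#' @return matrix with columns `uv`, `blue`, `green`.
#' @export
bee_sensitivities <- function(grid = 300:700) {
  lmax <- c(uv = 344, blue = 436, green = 544)
  vapply(lmax, function(l) pigment_template(grid, l), numeric(length(grid)))
}

#' Bundle of standard curves for the bee visual model
#'
#' Collects, on one common wavelength grid, the daylight illuminant
#' (relative quanta), the green-foliage adaptation background and the
#' three honeybee receptor sensitivities.  All colour computations in the
#' package take such a bundle, so alternative curves (another illuminant,
#' a measured local leaf) can be substituted by building the object by
#' hand with the same fields.
#'
#' @param grid wavelengths in nm; default 300-700 at 1 nm, the measured
#'   range of flower spectra in this pipeline.
#' @return object of class `standard_curves`: list with elements `wl`,
#'   `illuminant`, `background`, `S` (sensitivity matrix), `lmax`.
#' @export
standard_curves <- function(grid = 300:700) {
  structure(list(wl = as.numeric(grid),
                 illuminant = illuminant_d65(grid),
                 background = leaf_background(grid),
                 S = bee_sensitivities(grid),
                 lmax = c(uv = 344, blue = 436, green = 544)),
            class = "standard_curves")
}

#' @export
print.standard_curves <- function(x, ...) {
  cat(sprintf("standard_curves: %g-%g nm, receptor peaks %s nm\n",
              min(x$wl), max(x$wl), paste(x$lmax, collapse = "/")))
  invisible(x)
}
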