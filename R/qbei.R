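#' Backscatter coefficient of a pure element
#'
#' Reuter's polynomial in atomic number Z,
#' `eta(Z) = -0.0254 + 0.016 Z - 1.86e-4 Z^2 + 8.3e-7 Z^3`,
#' the conventional approximation for ~20 kV backscattered-electron yields.
#'
#' @param z atomic number(s).
#' @return Backscatter coefficient(s).
#' @export
backscatter_coefficient <- function(z) {
  -0.0254 + 0.016 * z - 1.86e-4 * z^2 + 8.3e-7 * z^3
}

#' Two-reference qBEI calibration curve
#'
#' Gray levels of an 8-bit backscattered-electron image are tied to
#' backscatter coefficients by the linear map fixed by the pure-carbon
#' (Z = 6) and pure-aluminium (Z = 13) reference measurements; calcium
#' content is then the affine function of gray level passing through two
#' anchor points `(gray level equivalent, wt% Ca)`. The default anchors
#' place 0 wt% Ca at the carbon gray level and 39.86 wt% Ca (pure
#' hydroxyapatite) at the aluminium gray level - a documented convention of
#' this implementation, configurable to any laboratory's standard.
#'
#' @param gl_carbon,gl_aluminum reference gray levels,
#'   `0 <= gl_carbon < gl_aluminum <= 255`.
#' @param anchors list of two `c(gray, wt_pct_ca)` anchor points.
#' @return list of class `qbei_calibration`: `c0`, `c1` (wt%Ca = c0 + c1 GL),
#'   `gl_carbon`, `gl_aluminum`, `eta_carbon`, `eta_aluminum`.
#' @export
build_calibration <- function(gl_carbon = 25, gl_aluminum = 225,
                              anchors = list(c(25, 0), c(225, 39.86))) {
  if (!(gl_carbon >= 0 && gl_carbon < gl_aluminum && gl_aluminum <= 255))
    stop("need 0 <= gl_carbon < gl_aluminum <= 255")
  a1 <- anchors[[1]]; a2 <- anchors[[2]]
  if (abs(a2[1] - a1[1]) < 1e-12)
    stop("degenerate anchors: identical gray-level equivalents")
  c1 <- (a2[2] - a1[2]) / (a2[1] - a1[1])
  if (c1 <= 0) stop("calibration must be increasing (c1 > 0)")
  structure(list(c0 = a1[2] - c1 * a1[1], c1 = c1,
                 gl_carbon = gl_carbon, gl_aluminum = gl_aluminum,
                 eta_carbon = backscatter_coefficient(6),
                 eta_aluminum = backscatter_coefficient(13)),
            class = "qbei_calibration")
}

#' Gray level to backscatter coefficient under a calibration
#'
#' @param curve a [build_calibration()] curve.
#' @param gl gray level(s).
#' @return eta value(s), linear through the two reference points.
#' @export
gray_to_eta <- function(curve, gl) {
  curve$eta_carbon + (curve$eta_aluminum - curve$eta_carbon) *
    (gl - curve$gl_carbon) / (curve$gl_aluminum - curve$gl_carbon)
}

# inverse calibration: gray level encoding a given calcium content
gray_for_ca <- function(curve, ca) (ca - curve$c0) / curve$c1

#' Apply a qBEI calibration to an 8-bit gray-level image
#'
#' @param image integer matrix with values 0..255.
#' @param curve a [build_calibration()] curve.
#' @return list of class `ca_map`: `gl`, `wt_pct_ca` (matrix), `curve`, and
#'   `summary` (mean, sd, histogram over 0..255 gray levels).
#' @export
apply_calibration <- function(image, curve) {
  stopifnot(inherits(curve, "qbei_calibration"))
  gl <- as.matrix(image)
  if (any(gl < 0 | gl > 255) || any(gl != round(gl)))
    stop("image must contain integer gray values in 0..255")
  ca <- curve$c0 + curve$c1 * gl
  structure(list(gl = gl, wt_pct_ca = ca, curve = curve,
                 summary = list(mean = mean(ca), sd = stats::sd(as.numeric(ca)),
                                gl_histogram = tabulate(as.integer(gl) + 1L,
                                                        nbins = 256))),
            class = "ca_map")
}
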