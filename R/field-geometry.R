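#' Rectangular MLC field specification
#'
#' Describes a symmetric rectangular field shaped by the multileaf collimator
#' (MLC) with the jaws parked at a fixed, larger opening so that the MLC is the
#' collimating device.  Fields are named in Y-then-X order ("YxX"): X is the
#' leaf-motion (leaf-end) direction, Y the leaf-side direction.
#'
#' @param y_cm Field side along the leaf-side (Y) direction, cm.
#' @param x_cm Field side along the leaf-motion (X) direction, cm.
#' @param beam_quality One of `"6X"`, `"6FFF"`, `"10X"`, `"10FFF"`.
#' @param jaw_x_cm,jaw_y_cm Jaw openings, cm.  Must strictly exceed the MLC
#'   sides (default 4.4 cm against a maximum 4 cm MLC field).
#' @param depth_cm Measurement depth, cm (default 10).
#' @return An object of class `field_spec` with a `label` rendered "Y x X".
#' @examples
#' field_spec(0.5, 4)   # elongated: Y = 0.5 cm, X = 4 cm
#' @export
field_spec <- function(y_cm, x_cm, beam_quality = "6X",
                       jaw_x_cm = 4.4, jaw_y_cm = 4.4, depth_cm = 10) {
  beam_quality <- match.arg(beam_quality, c("6X", "6FFF", "10X", "10FFF"))
  check_positive_side(y_cm, "y_cm")
  check_positive_side(x_cm, "x_cm")
  if (jaw_x_cm <= x_cm || jaw_y_cm <= y_cm)
    stop("jaw openings must strictly exceed the MLC-defined field sides",
         call. = FALSE)
  structure(
    list(y_cm = y_cm, x_cm = x_cm, beam_quality = beam_quality,
         jaw_x_cm = jaw_x_cm, jaw_y_cm = jaw_y_cm, depth_cm = depth_cm,
         label = paste(format(y_cm), "x", format(x_cm))),
    class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("MLC field %s cm (Y x X), %s, jaws %.1f x %.1f cm, depth %g cm\n",
              x$label, x$beam_quality, x$jaw_y_cm, x$jaw_x_cm, x$depth_cm))
  invisible(x)
}

#' Dosimetric field size measured on profiles
#'
#' A pair of field sides measured as FWHM at depth, used as the `A`, `B`
#' inputs of the equivalent-square-field formulas when available.
#'
#' @param a_cm,b_cm Measured FWHM along the two axes, cm.
#' @param source Where the sides came from: `"nominal"`, `"measured"`, or
#'   `"simulated"`.
#' @return An object of class `dosimetric_size`.
#' @export
dosimetric_size <- function(a_cm, b_cm,
                            source = c("nominal", "measured", "simulated")) {
  source <- match.arg(source)
  check_positive_side(a_cm, "a_cm")
  check_positive_side(b_cm, "b_cm")
  structure(list(a_cm = a_cm, b_cm = b_cm, source = source),
            class = "dosimetric_size")
}

# Reject non-positive and degenerate (< 0.01 cm) sides: below any OCF table
# domain, so extrapolation would be meaningless.
check_positive_side <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  if (v < 0.01)
    stop(sprintf("'%s' = %g cm is degenerate (< 0.01 cm)", name, v),
         call. = FALSE)
  invisible(v)
}

new_equivalent_square <- function(esf_cm, method, exponent_a = NULL) {
  structure(list(esf_cm = esf_cm, method = method, exponent_a = exponent_a),
            class = "equivalent_square")
}

#' @export
print.equivalent_square <- function(x, ...) {
  cat(sprintf("equivalent square field: %.4f cm (method %s%s)\n", x$esf_cm,
              x$method,
              if (!is.null(x$exponent_a)) sprintf(", a = %g", x$exponent_a)
              else ""))
  invisible(x)
}

#' Equivalent square field side of an elongated rectangular field
#'
#' Computes the side of the square field dosimetrically equivalent to an
#' `A x B` rectangle using the empirical generalization of the Sterling
#' formula,
#' \deqn{ESF = 2 \, \min(A,B)^a \, \max(A,B)^{2-a} / (A + B),}
#' with exponent `a = 1.12` determined empirically for small elongated MLC
#' fields.  At `a = 1` the expression reduces exactly to the Sterling
#' four-area-over-perimeter form; the weighting of the short side grows with
#' `a`, reflecting that the short side dominates the output of an elongated
#' small field.
#'
#' @param a_side,b_side The two field sides, cm (dosimetric FWHM sides when
#'   available, nominal otherwise).  Order is immaterial.
#' @param exponent Dimensionless exponent, in `[1, 2]`; default 1.12.
#' @return An `equivalent_square` object of method `"modified_sterling"`.
#' @seealso [sterling_square()], [area_equivalent_square()]
#' @examples
#' equivalent_square_field(0.5, 4)$esf_cm      # ~0.693 cm
#' equivalent_square_field(0.5, 4, 1)$esf_cm   # Sterling value 0.8889 cm
#' @export
equivalent_square_field <- function(a_side, b_side, exponent = 1.12) {
  check_positive_side(a_side, "a_side")
  check_positive_side(b_side, "b_side")
  if (!is.numeric(exponent) || length(exponent) != 1L ||
      !is.finite(exponent) || exponent < 1 || exponent > 2)
    stop("'exponent' must lie in [1, 2]", call. = FALSE)
  lo <- min(a_side, b_side)
  hi <- max(a_side, b_side)
  esf <- 2 * lo^exponent * hi^(2 - exponent) / (lo + hi)
  new_equivalent_square(esf, "modified_sterling", exponent_a = exponent)
}

#' Sterling equivalent square
#'
#' Classic equivalent square: four times the field area divided by its
#' perimeter, `2AB/(A+B)`.
#'
#' @inheritParams equivalent_square_field
#' @return An `equivalent_square` of method `"sterling"`.
#' @export
sterling_square <- function(a_side, b_side) {
  check_positive_side(a_side, "a_side")
  check_positive_side(b_side, "b_side")
  new_equivalent_square(2 * a_side * b_side / (a_side + b_side), "sterling")
}

#' Equivalent-area square with aspect-ratio validity window
#'
#' TRS-483 equivalent-area rule `sqrt(A*B)`, valid only for near-square
#' fields with aspect ratio in the open interval (0.7, 1.4).  With
#' `enforce_range = TRUE` (the default) an out-of-window ratio raises an
#' error naming the ratio instead of silently returning a value the
#' formalism does not cover.
#'
#' @inheritParams equivalent_square_field
#' @param enforce_range Check the aspect-ratio validity window.
#' @return An `equivalent_square` of method `"area"`.
#' @export
area_equivalent_square <- function(a_side, b_side, enforce_range = TRUE) {
  check_positive_side(a_side, "a_side")
  check_positive_side(b_side, "b_side")
  ratio <- a_side / b_side
  if (enforce_range && (ratio <= 0.7 || ratio >= 1.4))
    stop(sprintf(
      "aspect ratio A/B = %.3g outside the equivalent-area validity window (0.7, 1.4)",
      ratio), call. = FALSE)
  new_equivalent_square(sqrt(a_side * b_side), "area")
}
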