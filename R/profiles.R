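#' Sampled 1-D dose profile
#'
#' A dose (or detector signal) profile sampled along one axis through the
#' beam center.  Positions are millimeters at the measurement plane;
#' `axis = "X"` is the leaf-motion (leaf-end) direction, `"Y"` the leaf-side
#' direction.
#'
#' @param positions_mm Strictly increasing sample coordinates, mm; at least 8
#'   samples.
#' @param values Dose or signal values, all `>= 0`, not all zero.
#' @param axis `"X"` or `"Y"`.
#' @param meta Optional named list (beam quality, field label, depth, ...).
#' @return An object of class `beam_profile`.
#' @export
beam_profile <- function(positions_mm, values, axis = c("X", "Y"),
                         meta = list()) {
  axis <- match.arg(axis)
  if (length(positions_mm) < 8L)
    stop("a profile needs at least 8 samples", call. = FALSE)
  if (length(values) != length(positions_mm))
    stop("positions and values differ in length", call. = FALSE)
  if (any(diff(positions_mm) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (any(values < 0))
    stop("profile values must be non-negative", call. = FALSE)
  if (max(values) <= 0)
    stop("all-zero profile", call. = FALSE)
  structure(list(positions_mm = as.numeric(positions_mm),
                 values = as.numeric(values), axis = axis, meta = meta),
            class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf("beam profile, axis %s, %d samples over [%g, %g] mm, max %g\n",
              x$axis, length(x$values), min(x$positions_mm),
              max(x$positions_mm), max(x$values)))
  invisible(x)
}

#' Normalize a profile to 100% at its maximum
#'
#' @param profile A [beam_profile()].
#' @return The profile rescaled so `max(values) == 100`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "beam_profile"))
  profile$values <- profile$values / max(profile$values) * 100
  profile
}

# All positions where the piecewise-linear profile crosses `level`, by linear
# interpolation between bracketing samples.  Exact sample hits count once.
level_crossings <- function(positions, values, level) {
  v <- values - level
  out <- positions[v == 0]
  s <- v[-length(v)] * v[-1L]
  idx <- which(s < 0)
  if (length(idx)) {
    p0 <- positions[idx]; p1 <- positions[idx + 1L]
    v0 <- v[idx]; v1 <- v[idx + 1L]
    out <- c(out, p0 + (0 - v0) / (v1 - v0) * (p1 - p0))
  }
  sort(out)
}

#' Beam center from the half-maximum crossings
#'
#' Midpoint of the two 50%-of-maximum crossings of the normalized profile.
#' Profiles with other than exactly two crossings (ramps, multi-peaked
#' shapes) raise a shape error.
#'
#' @param profile A [beam_profile()].
#' @return Beam center position, mm.
#' @export
beam_center <- function(profile) {
  p <- normalize_profile(profile)
  cr <- level_crossings(p$positions_mm, p$values, 50)
  if (length(cr) != 2L)
    stop(sprintf("expected exactly two 50%% crossings, found %d", length(cr)),
         call. = FALSE)
  mean(cr)
}

#' Dosimetric field size (FWHM) of a profile
#'
#' Distance between the two 50%-of-maximum crossings, located by linear
#' interpolation between samples -- the dosimetric field size at the
#' measurement depth.
#'
#' @param profile A [beam_profile()].
#' @return FWHM, mm.
#' @export
fwhm <- function(profile) {
  p <- normalize_profile(profile)
  cr <- level_crossings(p$positions_mm, p$values, 50)
  if (length(cr) != 2L)
    stop(sprintf("expected exactly two 50%% crossings, found %d", length(cr)),
         call. = FALSE)
  diff(cr)
}

# One shoulder's 20-80 distance.  `side` = +1 (right) or -1 (left); crossings
# are searched outward from the beam center, and on a non-monotone shoulder
# the crossing nearest the field edge (the 50% position) is used, with a
# warning.
shoulder_span <- function(positions, values, center, side) {
  sel <- if (side > 0) positions >= center else positions <= center
  pos <- positions[sel]; val <- values[sel]
  edge <- level_crossings(pos, val, 50)
  if (!length(edge))
    stop("no field edge (50% level) on this shoulder", call. = FALSE)
  edge <- edge[which.min(abs(edge - center))]
  pick <- function(level) {
    cr <- level_crossings(pos, val, level)
    if (!length(cr))
      stop(sprintf("profile never crosses the %g%% level on one shoulder",
                   level), call. = FALSE)
    if (length(cr) > 1L)
      warning(sprintf(
        "non-monotone shoulder: %d crossings of the %g%% level; using the one nearest the field edge",
        length(cr), level), call. = FALSE)
    cr[which.min(abs(cr - edge))]
  }
  abs(pick(80) - pick(20))
}

#' 20-80% penumbra widths of a profile
#'
#' Lateral distance between the 20% and 80% dose levels on each shoulder of
#' the normalized profile, found moving outward from the beam center with
#' linear interpolation between samples.
#'
#' @param profile A [beam_profile()].
#' @return Named vector `c(left = ..., right = ...)`, mm.
#' @seealso [profile_metrics()] for the combined report.
#' @export
penumbra_20_80 <- function(profile) {
  p <- normalize_profile(profile)
  ctr <- beam_center(p)
  c(left = shoulder_span(p$positions_mm, p$values, ctr, -1),
    right = shoulder_span(p$positions_mm, p$values, ctr, +1))
}

#' All profile metrics at once
#'
#' @param profile A [beam_profile()].
#' @return Object of class `profile_metrics` with `center_mm`, `fwhm_mm`,
#'   `penumbra_left_mm`, `penumbra_right_mm`, `penumbra_mean_mm`, and the
#'   `normalization_value` (the raw maximum mapped to 100%).
#' @export
profile_metrics <- function(profile) {
  stopifnot(inherits(profile, "beam_profile"))
  pen <- penumbra_20_80(profile)
  structure(list(center_mm = beam_center(profile),
                 fwhm_mm = fwhm(profile),
                 penumbra_left_mm = unname(pen["left"]),
                 penumbra_right_mm = unname(pen["right"]),
                 penumbra_mean_mm = mean(pen),
                 normalization_value = max(profile$values)),
            class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf(
    "center %.3f mm, FWHM %.3f mm, penumbra L/R %.3f/%.3f mm (mean %.3f mm)\n",
    x$center_mm, x$fwhm_mm, x$penumbra_left_mm, x$penumbra_right_mm,
    x$penumbra_mean_mm))
  invisible(x)
}

#' Median-filter a noisy measured profile
#'
#' Optional window-3 running median, applied before metric extraction when a
#' measured profile is too noisy for stable crossings.  The package never
#' smooths implicitly.
#'
#' @param profile A [beam_profile()].
#' @return The filtered profile.
#' @export
median_filter_profile <- function(profile) {
  stopifnot(inherits(profile, "beam_profile"))
  message("applying window-3 running median before metric extraction")
  profile$values <- stats::runmed(profile$values, 3L, endrule = "keep")
  profile
}
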