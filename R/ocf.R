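#' Detector specification for small-field output measurements
#'
#' Holds the detector identity and, per beam quality, the smallest equivalent
#' square field side for which a published output correction factor exists.
#' Queries below that side are a hard domain error, never a silent clamp: a
#' detector without a published OCF at a field size cannot produce a valid
#' output factor there.
#'
#' @param name Detector identifier, e.g. `"microDiamond"`.
#' @param min_field_cm_by_quality Named numeric vector, smallest tabulated
#'   equivalent square side (cm) per beam quality.
#' @param notes Optional free text.
#' @return An object of class `detector_spec`.
#' @examples
#' detector_spec("microDiamond", c("6X" = 0.4, "10X" = 0.4))
#' @export
detector_spec <- function(name, min_field_cm_by_quality = numeric(), notes = "") {
  if (length(min_field_cm_by_quality) &&
      (is.null(names(min_field_cm_by_quality)) ||
       any(min_field_cm_by_quality <= 0)))
    stop("'min_field_cm_by_quality' must be a named vector of positive sides",
         call. = FALSE)
  structure(list(name = name,
                 min_field_cm_by_quality = min_field_cm_by_quality,
                 notes = notes),
            class = "detector_spec")
}

#' Reference detectors
#'
#' The three detectors commonly used for small-field output factor work, with
#' the smallest field sides for which published output correction factors are
#' available: microDiamond down to 0.4 cm (6 and 10 MV), PinPoint3D down to
#' 0.8 cm (6 MV) / 1 cm (10 MV), unshielded DiodeE down to 0.5 cm (6 MV) /
#' 0.6 cm (10 MV).
#'
#' @param name One of `"microDiamond"`, `"PinPoint3D"`, `"DiodeE"`.
#' @return A [detector_spec()].
#' @export
reference_detector <- function(name = c("microDiamond", "PinPoint3D", "DiodeE")) {
  name <- match.arg(name)
  limits <- switch(name,
    microDiamond = c("6X" = 0.4, "6FFF" = 0.4, "10X" = 0.4, "10FFF" = 0.4),
    PinPoint3D   = c("6X" = 0.8, "6FFF" = 0.8, "10X" = 1.0, "10FFF" = 1.0),
    DiodeE       = c("6X" = 0.5, "6FFF" = 0.5, "10X" = 0.6, "10FFF" = 0.6))
  detector_spec(name, limits)
}

new_ocf_table <- function(entries, detector, beam_quality) {
  structure(list(entries = entries, detector = detector,
                 beam_quality = beam_quality),
            class = "ocf_table")
}

#' @export
print.ocf_table <- function(x, ...) {
  cat(sprintf("OCF table: %s, %s, %d entries over [%g, %g] cm\n",
              if (inherits(x$detector, "detector_spec")) x$detector$name
              else as.character(x$detector),
              x$beam_quality, nrow(x$entries),
              min(x$entries$field_side_cm), max(x$entries$field_side_cm)))
  invisible(x)
}

#' Load an output-correction-factor table
#'
#' Reads a per-detector OCF table mapping equivalent square field side to the
#' output correction factor `k` of the TRS-483 formalism.  Accepts either a
#' data frame or a path to a CSV file with header `field_side_cm,ocf`
#' (comment lines starting with `#` carry `key=value` metadata).
#'
#' @param source Data frame or CSV path.
#' @param detector A [detector_spec()] or a bare name.
#' @param beam_quality Beam quality label.
#' @return An object of class `ocf_table`, entries sorted ascending in field
#'   side.
#' @export
load_ocf_table <- function(source, detector = "unknown", beam_quality = "6X") {
  if (is.character(source) && length(source) == 1L) {
    df <- utils::read.csv(source, comment.char = "#",
                          colClasses = c("character", "character"))
  } else if (is.data.frame(source)) {
    df <- source
  } else stop("'source' must be a data frame or a CSV path", call. = FALSE)
  need <- c("field_side_cm", "ocf")
  if (!all(need %in% names(df)))
    stop("OCF source must have columns 'field_side_cm' and 'ocf'",
         call. = FALSE)
  side <- suppressWarnings(as.numeric(df$field_side_cm))
  ocf <- suppressWarnings(as.numeric(df$ocf))
  if (anyNA(side) || anyNA(ocf))
    stop("non-numeric cell in OCF table", call. = FALSE)
  if (length(side) < 2L)
    stop("OCF table needs at least 2 rows", call. = FALSE)
  if (anyDuplicated(side))
    stop("duplicate field side in OCF table: ",
         paste(unique(side[duplicated(side)]), collapse = ", "),
         call. = FALSE)
  ord <- order(side)
  entries <- data.frame(field_side_cm = side[ord], ocf = ocf[ord])
  new_ocf_table(entries, detector, beam_quality)
}

#' Drop correction factors more than a threshold from unity
#'
#' TRS-483 practice: output correction factors more than 5% from unity are
#' neither reported nor used.  Entries with `|ocf - 1| > threshold` are
#' removed (each removal is messaged); an empty result is returned with a
#' warning rather than an error.  The operation is idempotent.
#'
#' @param table An `ocf_table`.
#' @param threshold Validity band half-width around 1; default 0.05.
#' @return The filtered `ocf_table`.
#' @export
filter_ocf_validity <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "ocf_table"))
  keep <- abs(table$entries$ocf - 1) <= threshold
  dropped <- table$entries[!keep, , drop = FALSE]
  for (i in seq_len(nrow(dropped)))
    message(sprintf(
      "dropping OCF %.4f at %g cm: more than %.0f%% from unity",
      dropped$ocf[i], dropped$field_side_cm[i], 100 * threshold))
  if (!any(keep))
    warning("no OCF entry within the validity band; empty table returned",
            call. = FALSE)
  out <- table
  out$entries <- table$entries[keep, , drop = FALSE]
  rownames(out$entries) <- NULL
  out
}

#' Interpolate an output correction factor
#'
#' Piecewise-linear interpolation of the OCF at an equivalent square field
#' side.  Queries below the smallest tabulated side are an out-of-domain
#' error (the detector has no published correction there).  Queries above the
#' largest side return 1.0 only when the table itself terminates at unity
#' (large fields need no correction); otherwise they are an error too.
#'
#' @param table A (validity-filtered) `ocf_table`.
#' @param esf Equivalent square field side, cm.
#' @return The interpolated correction factor (dimensionless).
#' @export
ocf_lookup <- function(table, esf) {
  stopifnot(inherits(table, "ocf_table"))
  e <- table$entries
  if (nrow(e) < 2L)
    stop("OCF table has fewer than 2 entries", call. = FALSE)
  lo <- e$field_side_cm[1L]
  hi <- e$field_side_cm[nrow(e)]
  det <- if (inherits(table$detector, "detector_spec")) table$detector$name
         else as.character(table$detector)
  if (esf < lo)
    stop(sprintf(
      "field side %.3f cm below the smallest tabulated OCF side (%g cm) for %s",
      esf, lo, det), call. = FALSE)
  if (esf > hi) {
    if (isTRUE(all.equal(e$ocf[nrow(e)], 1.0))) return(1.0)
    stop(sprintf(
      "field side %.3f cm above the largest tabulated OCF side (%g cm) for %s",
      esf, hi, det), call. = FALSE)
  }
  stats::approx(e$field_side_cm, e$ocf, xout = esf, method = "linear",
                ties = "ordered")$y
}
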