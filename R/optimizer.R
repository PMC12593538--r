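#' Candidate grid for ESS optimization
#'
#' The discrete ESS values evaluated by the grid-search procedures, by
#' default 0 to 1.5 mm with 0.1 mm increments between 0.5 and 1.0 mm
#' (finer where the optimum is expected), plus the objective-space tie
#' tolerance below which two candidates are declared equivalent and
#' reported as an interval.
#'
#' @param values_mm Strictly increasing candidate values, mm, within
#'   `[0, 5]`.
#' @param tie_tolerance_pct Percent-difference tolerance for ties (default
#'   0.02 percentage points).
#' @return An object of class `ess_grid_spec`.
#' @export
ess_grid_spec <- function(values_mm = c(0, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9,
                                        1, 1.5),
                          tie_tolerance_pct = 0.02) {
  if (any(diff(values_mm) <= 0) || any(values_mm < 0) || any(values_mm > 5))
    stop("candidate values must be strictly increasing within [0, 5] mm",
         call. = FALSE)
  if (tie_tolerance_pct < 0)
    stop("'tie_tolerance_pct' must be >= 0", call. = FALSE)
  structure(list(values_mm = values_mm,
                 tie_tolerance_pct = tie_tolerance_pct),
            class = "ess_grid_spec")
}

#' Synthetic forward-model engine for ESS optimization
#'
#' Wraps the closed-form dose engine as a calculation interface for the
#' optimizer: given an ESS pair it returns the calculated FOF grid.
#'
#' @param kernel A [scatter_kernel()].
#' @param geometry A [beam_geometry()].
#' @param y_sides_cm,x_sides_cm Grid axes, cm.
#' @param msr_side_cm Reference field side, cm.
#' @param beam_quality Beam quality label.
#' @return An object of classes `synthetic_fof_engine`, `fof_engine`.
#' @export
synthetic_fof_engine <- function(kernel = default_scatter_kernel(),
                                 geometry = beam_geometry(),
                                 y_sides_cm = default_field_sides(),
                                 x_sides_cm = default_field_sides(),
                                 msr_side_cm = 4, beam_quality = "6X") {
  structure(list(kernel = kernel, geometry = geometry,
                 y_sides_cm = y_sides_cm, x_sides_cm = x_sides_cm,
                 msr_side_cm = msr_side_cm, beam_quality = beam_quality),
            class = c("synthetic_fof_engine", "fof_engine"))
}

#' Precomputed-grid engine
#'
#' Drives the optimizer from a directory of per-ESS calculated FOF grid
#' CSVs named `ess_<x>_<y>.csv` (values in mm, decimal point), as exported
#' from a real treatment planning system.  Grids are read lazily.
#'
#' @param dir Directory of grid CSVs.
#' @return An object of classes `precomputed_grid_engine`, `fof_engine`.
#' @export
precomputed_grid_engine <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  structure(list(dir = dir),
            class = c("precomputed_grid_engine", "fof_engine"))
}

#' Precomputed-difference engine from ESS sweep tables
#'
#' Drives the optimizer directly from tables of percent calculated-minus-
#' measured differences over (ESSy, ESSx) combinations for the two extreme
#' elongated fields (such as the packaged [reference_ess_sweeps()]).  No
#' measured grid is needed; unevaluated combinations are engine failures
#' the sweep records and skips.
#'
#' @param sweep_y4_x05 Sparse difference matrix for the (Y = 4, X = 0.5)
#'   field, rows = ESSy, columns = ESSx (mm in dimnames).
#' @param sweep_y05_x4 Same for the (Y = 0.5, X = 4) field.
#' @return An object of classes `table_diff_engine`, `fof_engine`.
#' @export
table_diff_engine <- function(sweep_y4_x05, sweep_y05_x4) {
  structure(list(sweep_y4_x05 = sweep_y4_x05, sweep_y05_x4 = sweep_y05_x4),
            class = c("table_diff_engine", "fof_engine"))
}

sweep_lookup <- function(sweep, essy_mm, essx_mm) {
  near <- function(v, axis) {
    i <- which(abs(as.numeric(axis) - v) < 1e-9)
    if (length(i) == 1L) i else NA_integer_
  }
  r <- near(essy_mm, rownames(sweep))
  c0 <- near(essx_mm, colnames(sweep))
  if (is.na(r) || is.na(c0))
    stop(sprintf("ESS combination (y=%g, x=%g) mm not tabulated",
                 essy_mm, essx_mm), call. = FALSE)
  v <- sweep[r, c0]
  if (is.na(v))
    stop(sprintf("ESS combination (y=%g, x=%g) mm not evaluated",
                 essy_mm, essx_mm), call. = FALSE)
  v
}

# Percent differences (calc - meas) at the two extreme elongated fields for
# one candidate ESS pair, via whichever engine drives the search.
engine_extreme_diffs <- function(engine, ess, meas = NULL,
                                 convention = "relative") {
  UseMethod("engine_extreme_diffs")
}

#' @export
engine_extreme_diffs.synthetic_fof_engine <- function(engine, ess,
                                                      meas = NULL,
                                                      convention = "relative") {
  if (is.null(meas))
    stop("a measured grid is required with a grid engine", call. = FALSE)
  calc <- simulate_fof_grid(ess, engine$kernel, engine$geometry,
                            engine$y_sides_cm, engine$x_sides_cm,
                            engine$msr_side_cm, engine$beam_quality)
  extreme_field_differences(difference_grid(calc, meas, convention))
}

#' @export
engine_extreme_diffs.precomputed_grid_engine <- function(engine, ess,
                                                         meas = NULL,
                                                         convention = "relative") {
  if (is.null(meas))
    stop("a measured grid is required with a grid engine", call. = FALSE)
  path <- file.path(engine$dir,
                    sprintf("ess_%s_%s.csv", format(ess$essx_mm),
                            format(ess$essy_mm)))
  if (!file.exists(path))
    stop("no precomputed grid for ESS (x=", ess$essx_mm, ", y=",
         ess$essy_mm, ") mm: ", path, call. = FALSE)
  extreme_field_differences(
    difference_grid(read_fof_grid(path), meas, convention))
}

#' @export
engine_extreme_diffs.table_diff_engine <- function(engine, ess, meas = NULL,
                                                   convention = "relative") {
  c(y4_x05 = sweep_lookup(engine$sweep_y4_x05, ess$essy_mm, ess$essx_mm),
    y05_x4 = sweep_lookup(engine$sweep_y05_x4, ess$essy_mm, ess$essx_mm))
}

#' Sweep one ESS axis and record the extreme-field differences
#'
#' Evaluates the engine at every candidate value of the free axis, the
#' other axis held fixed, and records the percent calculated-minus-measured
#' differences at the two extreme elongated fields.  Engine failures
#' (e.g. combinations a precomputed table never evaluated) are recorded as
#' failed rows and the sweep continues.
#'
#' @param engine A `fof_engine`.
#' @param meas Measured [fof_grid()] (ignored by difference engines).
#' @param candidates An [ess_grid_spec()].
#' @param free_axis `"x"` or `"y"`: the swept component.
#' @param fixed_mm Value of the other component, mm.
#' @param convention Percent-difference convention for grid engines.
#' @return Data frame with columns `essx_mm`, `essy_mm`, `diff_y4_x05`,
#'   `diff_y05_x4`, `ok`, `message`; attribute `free_axis`.
#' @export
sweep_extreme_fields <- function(engine, meas = NULL,
                                 candidates = ess_grid_spec(),
                                 free_axis = c("x", "y"), fixed_mm,
                                 convention = "relative") {
  free_axis <- match.arg(free_axis)
  stopifnot(inherits(engine, "fof_engine"),
            inherits(candidates, "ess_grid_spec"))
  rows <- lapply(candidates$values_mm, function(v) {
    essx <- if (free_axis == "x") v else fixed_mm
    essy <- if (free_axis == "y") v else fixed_mm
    d <- tryCatch(
      engine_extreme_diffs(engine, ess_pair(essx, essy), meas, convention),
      error = function(e) e)
    if (inherits(d, "error"))
      data.frame(essx_mm = essx, essy_mm = essy, diff_y4_x05 = NA_real_,
                 diff_y05_x4 = NA_real_, ok = FALSE,
                 message = conditionMessage(d))
    else
      data.frame(essx_mm = essx, essy_mm = essy,
                 diff_y4_x05 = unname(d["y4_x05"]),
                 diff_y05_x4 = unname(d["y05_x4"]), ok = TRUE,
                 message = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "free_axis") <- free_axis
  out
}

# Point (first minimizer in candidate order) and tie interval of |objective|
# over the successful rows of a sweep.
select_candidate <- function(values_mm, objective, tie_tol) {
  ok <- is.finite(objective)
  if (!any(ok)) stop("all candidates failed", call. = FALSE)
  obj <- abs(objective[ok])
  vals <- values_mm[ok]
  m <- min(obj)
  tied <- vals[obj - m <= tie_tol]
  list(point = vals[which.min(obj)], interval = range(tied), tied = tied,
       objective_min = m)
}

#' Sequential ESS optimization from extreme elongated fields
#'
#' The two-step grid-search procedure: starting from a vendor-style initial
#' pair, (1) sweep ESSx with ESSy fixed and pick the value minimizing the
#' absolute calculated-minus-measured FOF difference for the (Y = 4,
#' X = 0.5 cm) field, whose short side lies along X; (2) sweep ESSy with
#' ESSx fixed at that value and minimize the difference for the (Y = 0.5,
#' X = 4 cm) field.  Candidates whose objective lies within the tie
#' tolerance of the minimum are reported as an interval, reflecting that a
#' beam model may produce indistinguishable output at adjacent spot sizes.
#'
#' @inheritParams sweep_extreme_fields
#' @param start Numeric `c(essx, essy)` start, mm; default `c(0.5, 0.7)`.
#' @return An object of class `optimization_result`: per-axis intervals and
#'   point estimates, residual differences at the optimum, the full
#'   evaluation trace, and `objective = "sequential"`.
#' @export
optimize_sequential <- function(engine, meas = NULL,
                                candidates = ess_grid_spec(),
                                start = c(0.5, 0.7),
                                convention = "relative") {
  tie_tol <- candidates$tie_tolerance_pct
  sweep_x <- sweep_extreme_fields(engine, meas, candidates, "x",
                                  fixed_mm = start[2L], convention)
  sel_x <- select_candidate(sweep_x$essx_mm, sweep_x$diff_y4_x05, tie_tol)
  sweep_y <- sweep_extreme_fields(engine, meas, candidates, "y",
                                  fixed_mm = sel_x$point, convention)
  sel_y <- select_candidate(sweep_y$essy_mm, sweep_y$diff_y05_x4, tie_tol)
  at_opt <- tryCatch(
    engine_extreme_diffs(engine, ess_pair(sel_x$point, sel_y$point), meas,
                         convention),
    error = function(e) c(y4_x05 = NA_real_, y05_x4 = NA_real_))
  trace <- rbind(cbind(sweep_x, step = "sweep_x"),
                 cbind(sweep_y, step = "sweep_y"))
  structure(list(essx_mm = sel_x$interval, essy_mm = sel_y$interval,
                 essx_point = sel_x$point, essy_point = sel_y$point,
                 essx_tied = sel_x$tied, essy_tied = sel_y$tied,
                 residual_x_pct = unname(at_opt["y4_x05"]),
                 residual_y_pct = unname(at_opt["y05_x4"]),
                 trace = trace, objective = "sequential",
                 tie_tolerance_pct = tie_tol),
            class = "optimization_result")
}

#' Joint ESS grid search
#'
#' Exhaustive search over the candidate product grid minimizing a
#' scalarization of the two extreme-field absolute differences, used as a
#' cross-check of the sequential procedure.  When every evaluated pair ties
#' within tolerance the intervals span the full candidate range and a
#' degeneracy warning is issued.
#'
#' @inheritParams sweep_extreme_fields
#' @param objective `"max_abs"` (worst of the two differences) or
#'   `"sum_abs"`.
#' @return An `optimization_result` with `objective` set accordingly.
#' @export
optimize_joint <- function(engine, meas = NULL, candidates = ess_grid_spec(),
                           objective = c("max_abs", "sum_abs"),
                           convention = "relative") {
  objective <- match.arg(objective)
  tie_tol <- candidates$tie_tolerance_pct
  grid <- expand.grid(essx_mm = candidates$values_mm,
                      essy_mm = candidates$values_mm)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- tryCatch(
      engine_extreme_diffs(engine,
                           ess_pair(grid$essx_mm[i], grid$essy_mm[i]),
                           meas, convention),
      error = function(e) e)
    if (inherits(d, "error"))
      data.frame(essx_mm = grid$essx_mm[i], essy_mm = grid$essy_mm[i],
                 diff_y4_x05 = NA_real_, diff_y05_x4 = NA_real_,
                 ok = FALSE, message = conditionMessage(d))
    else
      data.frame(essx_mm = grid$essx_mm[i], essy_mm = grid$essy_mm[i],
                 diff_y4_x05 = unname(d["y4_x05"]),
                 diff_y05_x4 = unname(d["y05_x4"]), ok = TRUE,
                 message = "")
  })
  trace <- do.call(rbind, rows)
  scal <- switch(objective,
                 max_abs = pmax(abs(trace$diff_y4_x05),
                                abs(trace$diff_y05_x4)),
                 sum_abs = abs(trace$diff_y4_x05) + abs(trace$diff_y05_x4))
  ok <- trace$ok & is.finite(scal)
  if (!any(ok)) stop("all candidate pairs failed", call. = FALSE)
  m <- min(scal[ok])
  tied <- ok & (scal - m <= tie_tol)
  if (sum(tied) == sum(ok))
    warning("objective degenerate: every evaluated pair ties within tolerance",
            call. = FALSE)
  best <- which(ok)[which.min(scal[ok])]
  structure(list(essx_mm = range(trace$essx_mm[tied]),
                 essy_mm = range(trace$essy_mm[tied]),
                 essx_point = trace$essx_mm[best],
                 essy_point = trace$essy_mm[best],
                 essx_tied = sort(unique(trace$essx_mm[tied])),
                 essy_tied = sort(unique(trace$essy_mm[tied])),
                 residual_x_pct = trace$diff_y4_x05[best],
                 residual_y_pct = trace$diff_y05_x4[best],
                 trace = trace, objective = objective,
                 tie_tolerance_pct = tie_tol),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  fmt_int <- function(iv) if (diff(iv) == 0) sprintf("%g", iv[1L])
                          else sprintf("%g-%g", iv[1L], iv[2L])
  cat(sprintf("ESS optimization (%s objective)\n", x$objective))
  cat(sprintf("  ESSx: %s mm (point %g), residual %+.3f%% at (Y=4, X=0.5)\n",
              fmt_int(x$essx_mm), x$essx_point, x$residual_x_pct))
  cat(sprintf("  ESSy: %s mm (point %g), residual %+.3f%% at (Y=0.5, X=4)\n",
              fmt_int(x$essy_mm), x$essy_point, x$residual_y_pct))
  cat(sprintf("  trace: %d evaluations (%d failed), tie tolerance %g%%\n",
              nrow(x$trace), sum(!x$trace$ok), x$tie_tolerance_pct))
  invisible(x)
}

#' Over/under-estimation diagnosis along a sweep
#'
#' A spot size set too small leaves the calculated small-field dose too
#' high (positive calc-minus-meas difference); one set too large
#' underestimates it.  The difference should therefore fall monotonically
#' along an ESS sweep and cross zero at the optimum.  This report checks
#' that monotonicity over the successful rows of a sweep and labels every
#' candidate as below, above, or at the optimum by the sign of its
#' difference.
#'
#' @param sweep A trace from [sweep_extreme_fields()].
#' @param field Which extreme-field difference to diagnose:
#'   `"y4_x05"` or `"y05_x4"`.  Defaults to the field paired with the swept
#'   axis (X sweep drives the X = 0.5 cm field).
#' @param tolerance_pct Allowed upward wiggle before an increase counts as
#'   a violation (use the measurement noise scale for noisy data).
#' @return A list with `labels` (data frame: ess_mm, diff_pct, side),
#'   `violations` (data frame of increasing steps), and `monotone`.
#' @export
sign_diagnosis <- function(sweep, field = NULL, tolerance_pct = 0) {
  free_axis <- attr(sweep, "free_axis")
  if (is.null(field))
    field <- if (identical(free_axis, "y")) "y05_x4" else "y4_x05"
  field <- match.arg(field, c("y4_x05", "y05_x4"))
  col <- paste0("diff_", field)
  ess_col <- if (identical(free_axis, "y")) "essy_mm" else "essx_mm"
  ok <- sweep$ok & is.finite(sweep[[col]])
  ess <- sweep[[ess_col]][ok]
  d <- sweep[[col]][ok]
  ord <- order(ess)
  ess <- ess[ord]; d <- d[ord]
  side <- ifelse(d > tolerance_pct, "below_optimum",
                 ifelse(d < -tolerance_pct, "above_optimum", "at_optimum"))
  inc <- which(diff(d) > tolerance_pct)
  violations <- data.frame(from_mm = ess[inc], to_mm = ess[inc + 1L],
                           rise_pct = diff(d)[inc])
  list(labels = data.frame(ess_mm = ess, diff_pct = d, side = side),
       violations = violations, monotone = nrow(violations) == 0L)
}
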