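#' Effective spot size pair
#'
#' Per-axis width of the Gaussian smoothing applied to the primary-photon
#' energy fluence in the beam model: ESSx along the leaf-motion axis, ESSy
#' along the leaf-side axis.  The width may be interpreted as the Gaussian
#' sigma (default) or as a FWHM (converted internally by 1/2.3548).
#'
#' @param essx_mm,essy_mm Spot widths, mm, each in `[0, 5]`.
#' @param interpretation `"sigma"` or `"fwhm"`.
#' @return An object of class `ess_pair`.
#' @export
ess_pair <- function(essx_mm, essy_mm, interpretation = c("sigma", "fwhm")) {
  interpretation <- match.arg(interpretation)
  for (v in c(essx_mm, essy_mm))
    if (!is.numeric(v) || !is.finite(v) || v < 0 || v > 5)
      stop("ESS components must lie in [0, 5] mm", call. = FALSE)
  structure(list(essx_mm = essx_mm, essy_mm = essy_mm,
                 interpretation = interpretation),
            class = "ess_pair")
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))   # 1/2.3548

ess_sigmas_mm <- function(ess) {
  s <- c(x = ess$essx_mm, y = ess$essy_mm)
  if (ess$interpretation == "fwhm") s <- s * FWHM_TO_SIGMA
  s
}

#' @export
print.ess_pair <- function(x, ...) {
  cat(sprintf("ESS (%s): x = %g mm, y = %g mm\n", x$interpretation,
              x$essx_mm, x$essy_mm))
  invisible(x)
}

#' Multi-Gaussian lateral scatter kernel
#'
#' Mixture of centered 2-D Gaussians describing the lateral spread of dose
#' around a primary ray: a narrow component for the in-field dose and broad
#' components for phantom scatter.  Weights must be positive and sum to 1.
#'
#' @param weights Component weights (sum 1 within 1e-9).
#' @param sigma_x_mm,sigma_y_mm Per-component standard deviations, mm, > 0.
#' @return An object of class `scatter_kernel`.
#' @export
scatter_kernel <- function(weights, sigma_x_mm, sigma_y_mm = sigma_x_mm) {
  if (length(sigma_y_mm) != length(weights) ||
      length(sigma_x_mm) != length(weights))
    stop("weights and sigmas must have equal length", call. = FALSE)
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be positive and sum to 1", call. = FALSE)
  if (any(sigma_x_mm <= 0) || any(sigma_y_mm <= 0))
    stop("kernel sigmas must be positive", call. = FALSE)
  structure(list(weights = weights, sigma_x_mm = sigma_x_mm,
                 sigma_y_mm = sigma_y_mm),
            class = "scatter_kernel")
}

#' Default two-component scatter kernel
#'
#' Weights (0.88, 0.12) with isotropic sigmas 1.5 mm and 18 mm: a narrow
#' primary component and a broad phantom-scatter component, chosen so that
#' the synthetic 6X output-factor grid is qualitatively comparable to
#' measured HD-MLC data (output factors of roughly 0.6-0.8 for 0.5 cm
#' sides).  No quantitative fidelity to any commercial dose engine is
#' claimed; the engine's contract is parameter recovery, not value matching.
#'
#' @return A [scatter_kernel()].
#' @export
default_scatter_kernel <- function() {
  scatter_kernel(weights = c(0.88, 0.12),
                 sigma_x_mm = c(1.5, 18), sigma_y_mm = c(1.5, 18))
}

#' Divergent-beam geometry for source-blur projection
#'
#' The focal spot sits at the source; its blur is projected through the
#' collimator to the isocenter plane with magnification
#' `(SAD - d_c) / d_c`, where `d_c` is the source-to-collimator distance.
#' Defaults (SAD 1000 mm, `d_c` 500 mm) give a projection factor of exactly
#' 1, so ESS values act directly at isocenter scale.
#'
#' @param sad_mm Source-axis distance, mm.
#' @param collimator_distance_mm Source-to-collimator distance, mm, in
#'   `(0, sad_mm)`.
#' @param projection_factor Override for the blur magnification; computed
#'   from the distances when `NULL`.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(sad_mm = 1000, collimator_distance_mm = 500,
                          projection_factor = NULL) {
  if (collimator_distance_mm <= 0 || collimator_distance_mm >= sad_mm)
    stop("need 0 < collimator_distance_mm < sad_mm", call. = FALSE)
  if (is.null(projection_factor))
    projection_factor <- (sad_mm - collimator_distance_mm) /
      collimator_distance_mm
  if (projection_factor <= 0)
    stop("projection factor must be positive", call. = FALSE)
  structure(list(sad_mm = sad_mm,
                 collimator_distance_mm = collimator_distance_mm,
                 projection_factor = projection_factor),
            class = "beam_geometry")
}

#' Measurement noise model for synthetic output factors
#'
#' Multiplicative Gaussian noise emulating the combined (type A and B)
#' uncertainty of small-field output measurements: 1SD of 1.8% for fields
#' whose smallest side is below 1 cm (the 0.5 cm fields) and 0.9% for fields
#' of 1 cm and larger, matching microDiamond-class uncertainties.
#'
#' @param sd_small_pct Relative 1SD (percent) for min side < 1 cm.
#' @param sd_large_pct Relative 1SD (percent) for min side >= 1 cm.
#' @param seed Integer seed; draws are scoped to this seed and do not touch
#'   the global random state.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_small_pct = 1.8, sd_large_pct = 0.9, seed = 1L) {
  if (sd_small_pct < 0 || sd_large_pct < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(sd_small_pct = sd_small_pct, sd_large_pct = sd_large_pct,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Per-component effective sigmas (mm) along each axis: projected source blur
# added in quadrature with the kernel component width.
effective_sigmas <- function(ess, kernel, geometry) {
  s <- ess_sigmas_mm(ess) * geometry$projection_factor
  list(x = sqrt(s[["x"]]^2 + kernel$sigma_x_mm^2),
       y = sqrt(s[["y"]]^2 + kernel$sigma_y_mm^2))
}

#' Central-axis dose of a rectangular field (closed form)
#'
#' Forward model of source occlusion: the rectangular MLC aperture is
#' convolved with the projected Gaussian focal spot and the multi-Gaussian
#' scatter kernel, and evaluated at the field center.  Separability of
#' Gaussians over a rectangle gives the closed form
#' \deqn{D = \sum_k w_k \,\mathrm{erf}\!\big(X/(2\sqrt2\,s_{x,k})\big)\,
#'            \mathrm{erf}\!\big(Y/(2\sqrt2\,s_{y,k})\big),}
#' with per-axis effective sigma
#' \eqn{s_k = \sqrt{(\mathrm{ESS}\cdot m)^2 + \sigma_k^2}} (projection
#' magnification `m`).  The result is the relative dose in (0, 1]; it falls
#' when a field side becomes comparable to the effective blur -- the
#' mechanism that makes small-field output sensitive to the spot size.
#'
#' @param field A [field_spec()] (sides in cm; converted to mm internally).
#' @param ess An [ess_pair()].
#' @param kernel A [scatter_kernel()].
#' @param geometry A [beam_geometry()].
#' @return Relative central dose, dimensionless.
#' @export
central_dose <- function(field, ess, kernel = default_scatter_kernel(),
                         geometry = beam_geometry()) {
  stopifnot(inherits(field, "field_spec"), inherits(ess, "ess_pair"),
            inherits(kernel, "scatter_kernel"),
            inherits(geometry, "beam_geometry"))
  s <- effective_sigmas(ess, kernel, geometry)
  x_mm <- field$x_cm * 10
  y_mm <- field$y_cm * 10
  fx <- erf(x_mm / (2 * sqrt(2) * s$x))
  fy <- erf(y_mm / (2 * sqrt(2) * s$y))
  sum(kernel$weights * fx * fy)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Simulate a calculated FOF grid
#'
#' Deterministic forward run of [central_dose()] over a grid of field sides,
#' normalized to the msr field so that the msr cell is exactly 1.
#'
#' @param ess An [ess_pair()].
#' @param kernel A [scatter_kernel()].
#' @param geometry A [beam_geometry()].
#' @param y_sides_cm,x_sides_cm Grid axes, cm; must contain `msr_side_cm`.
#' @param msr_side_cm Machine-specific reference field side, cm.
#' @param beam_quality Label carried on the grid.
#' @return A [fof_grid()] of kind `"calculated"`.
#' @export
simulate_fof_grid <- function(ess, kernel = default_scatter_kernel(),
                              geometry = beam_geometry(),
                              y_sides_cm = default_field_sides(),
                              x_sides_cm = default_field_sides(),
                              msr_side_cm = 4, beam_quality = "6X") {
  if (!any(abs(y_sides_cm - msr_side_cm) < 1e-9) ||
      !any(abs(x_sides_cm - msr_side_cm) < 1e-9))
    stop("msr side must be on both axes", call. = FALSE)
  dose <- function(y, x)
    central_dose(field_spec(y, x, beam_quality), ess, kernel, geometry)
  d_msr <- dose(msr_side_cm, msr_side_cm)
  vals <- outer(y_sides_cm, x_sides_cm, Vectorize(function(y, x)
    dose(y, x) / d_msr))
  iy <- which(abs(y_sides_cm - msr_side_cm) < 1e-9)
  ix <- which(abs(x_sides_cm - msr_side_cm) < 1e-9)
  vals[iy, ix] <- 1.0
  fof_grid(vals, y_sides_cm, x_sides_cm, "calculated", beam_quality,
           msr_side_cm)
}

#' Simulate a 1-D dose profile
#'
#' Separable closed-form profile along one axis through the field center:
#' per kernel component, the blurred-aperture factor along the scanned axis
#' is a difference of Gaussian CDFs, while the orthogonal-axis factor is
#' frozen at its field-center value.  An optional top-hat convolution of
#' width `detector_diameter_mm` emulates detector volume averaging.
#'
#' @param field A [field_spec()].
#' @param axis `"X"` or `"Y"`: the scanned direction.
#' @param ess An [ess_pair()].
#' @param kernel A [scatter_kernel()].
#' @param geometry A [beam_geometry()].
#' @param sampling_mm Sample spacing, mm (default 0.1, deliberately finer
#'   than a typical 1 mm TPS dose grid).
#' @param detector_diameter_mm Top-hat averaging width, mm; 0 disables.
#' @param half_range_mm Scan half-length, mm; default covers the field and
#'   shoulders.
#' @return A [beam_profile()], symmetric about 0.
#' @export
simulate_profile <- function(field, axis = c("X", "Y"), ess,
                             kernel = default_scatter_kernel(),
                             geometry = beam_geometry(),
                             sampling_mm = 0.1, detector_diameter_mm = 0,
                             half_range_mm = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(field, "field_spec"), inherits(ess, "ess_pair"))
  if (!is.numeric(sampling_mm) || sampling_mm <= 0)
    stop("'sampling_mm' must be positive", call. = FALSE)
  s <- effective_sigmas(ess, kernel, geometry)
  along <- if (axis == "X") s$x else s$y
  ortho <- if (axis == "X") s$y else s$x
  w_along_mm <- 10 * (if (axis == "X") field$x_cm else field$y_cm)
  w_ortho_mm <- 10 * (if (axis == "X") field$y_cm else field$x_cm)
  if (is.null(half_range_mm))
    half_range_mm <- w_along_mm / 2 + max(15, 6 * max(along))
  # symmetric sampling grid about 0
  p <- seq(0, half_range_mm, by = sampling_mm)
  p <- c(-rev(p[-1L]), p)
  ortho_factor <- erf(w_ortho_mm / (2 * sqrt(2) * ortho))
  vals <- rep(0, length(p))
  for (k in seq_along(kernel$weights)) {
    aperture <- 0.5 * (erf((w_along_mm / 2 - p) / (sqrt(2) * along[k])) +
                       erf((w_along_mm / 2 + p) / (sqrt(2) * along[k])))
    vals <- vals + kernel$weights[k] * ortho_factor[k] * aperture
  }
  if (detector_diameter_mm > 0) {
    taps <- max(1L, round(detector_diameter_mm / sampling_mm))
    if (taps %% 2L == 0L) taps <- taps + 1L
    kern <- rep(1 / taps, taps)
    padded <- c(rep(vals[1L], (taps - 1L) / 2L), vals,
                rep(vals[length(vals)], (taps - 1L) / 2L))
    vals <- stats::filter(padded, kern, sides = 2)
    vals <- as.numeric(vals[!is.na(vals)])
  }
  beam_profile(p, vals, axis = axis,
               meta = list(field = field$label,
                           beam_quality = field$beam_quality,
                           essx_mm = ess$essx_mm, essy_mm = ess$essy_mm,
                           interpretation = ess$interpretation))
}

#' Add multiplicative measurement noise to a grid
#'
#' Turns a calculated grid into a synthetic "measured" grid: every non-msr
#' cell is multiplied by `1 + e`, `e ~ N(0, sd)` with the small-field or
#' large-field SD of the [noise_model()] depending on the cell's smallest
#' side.  The msr cell stays exactly 1.  Draws are scoped to the model's
#' seed, so the same model yields the same grid.
#'
#' @param grid A complete [fof_grid()] of kind `"calculated"`.
#' @param noise A [noise_model()].
#' @return A [fof_grid()] of kind `"measured"`.
#' @export
add_measurement_noise <- function(grid, noise) {
  stopifnot(inherits(grid, "fof_grid"), inherits(noise, "noise_model"))
  vals <- grid$values
  sds <- outer(grid$y_sides_cm, grid$x_sides_cm, function(y, x)
    ifelse(pmin(y, x) < 1, noise$sd_small_pct, noise$sd_large_pct) / 100)
  eps <- withr::with_seed(noise$seed,
    matrix(stats::rnorm(length(vals)), nrow(vals), ncol(vals)))
  vals <- vals * (1 + eps * sds)
  iy <- which(abs(grid$y_sides_cm - grid$msr_side_cm) < 1e-9)
  ix <- which(abs(grid$x_sides_cm - grid$msr_side_cm) < 1e-9)
  if (length(iy) == 1L && length(ix) == 1L) vals[iy, ix] <- 1.0
  fof_grid(vals, grid$y_sides_cm, grid$x_sides_cm, "measured",
           grid$beam_quality, grid$msr_side_cm)
}

#' Fit a scatter kernel to a target FOF grid
#'
#' Least-squares fit (Levenberg-Marquardt via \pkg{minpack.lm}) of the
#' component weights and isotropic sigmas of a [scatter_kernel()] so that
#' the forward model reproduces a target grid at a fixed, known ESS pair.
#' Used to make synthetic fixtures resemble measured data; parameter
#' recovery on self-generated grids is its correctness contract.
#'
#' @param target_grid A complete measured or calculated [fof_grid()].
#' @param ess_fixed The [ess_pair()] held fixed during the fit.
#' @param n_components Number of kernel components.
#' @param geometry A [beam_geometry()].
#' @param start Optional [scatter_kernel()] start point.
#' @param maxiter Iteration budget.
#' @return A list with `kernel`, `residual_rms` (FOF units), and
#'   `converged`.  A fit that exhausts the budget raises a condition of
#'   class `smallfof_convergence_error` carrying the best-so-far result.
#' @export
fit_kernel <- function(target_grid, ess_fixed, n_components = 2,
                       geometry = beam_geometry(), start = NULL,
                       maxiter = 200) {
  stopifnot(inherits(target_grid, "fof_grid"))
  if (anyNA(target_grid$values))
    stop("target grid must be complete", call. = FALSE)
  n <- as.integer(n_components)
  if (is.null(start)) {
    sig0 <- exp(seq(log(1.5), log(20), length.out = n))
    w0 <- rep(1 / n, n)
  } else {
    sig0 <- start$sigma_x_mm
    w0 <- start$weights
  }
  # free params: n-1 weight logits + n log-sigmas (weights close via softmax)
  par0 <- c(log(w0[-n] / w0[n]), log(sig0))
  unpack <- function(par) {
    logit <- c(par[seq_len(n - 1)], 0)
    w <- exp(logit) / sum(exp(logit))
    sig <- exp(par[n:(2 * n - 1)])
    scatter_kernel(w, sig, sig)
  }
  resid_fun <- function(par) {
    k <- unpack(par)
    g <- simulate_fof_grid(ess_fixed, k, geometry,
                           target_grid$y_sides_cm, target_grid$x_sides_cm,
                           target_grid$msr_side_cm,
                           target_grid$beam_quality)
    as.numeric(g$values - target_grid$values)
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter))
  kernel <- unpack(fit$par)
  rms <- sqrt(mean(fit$fvec^2))
  converged <- fit$info %in% 1:4
  result <- list(kernel = kernel, residual_rms = rms, converged = converged)
  if (!converged) {
    cond <- structure(
      class = c("smallfof_convergence_error", "error", "condition"),
      list(message = sprintf(
             "kernel fit did not converge within %d iterations (residual RMS %.3g)",
             maxiter, rms),
           call = sys.call(-1), best = result))
    stop(cond)
  }
  result
}
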