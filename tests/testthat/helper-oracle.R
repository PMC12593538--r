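# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form paths: doses come from brute-force 2-D quadrature,
# profiles from the normal CDF directly.

# Central dose by 2-D midpoint quadrature of the blurred aperture: per
# kernel component, the projected source blur and the component width are
# combined in quadrature and the resulting 2-D Gaussian is integrated
# numerically over the rectangular aperture.
oracle_central_dose <- function(field, ess, kernel,
                                geometry = beam_geometry(), h = 0.05) {
  s_src <- c(ess$essx_mm, ess$essy_mm)
  if (ess$interpretation == "fwhm") s_src <- s_src / (2 * sqrt(2 * log(2)))
  s_src <- s_src * geometry$projection_factor
  xs <- seq(-field$x_cm * 5 + h / 2, field$x_cm * 5 - h / 2, by = h)
  ys <- seq(-field$y_cm * 5 + h / 2, field$y_cm * 5 - h / 2, by = h)
  tot <- 0
  for (k in seq_along(kernel$weights)) {
    sx <- sqrt(s_src[1L]^2 + kernel$sigma_x_mm[k]^2)
    sy <- sqrt(s_src[2L]^2 + kernel$sigma_y_mm[k]^2)
    gx <- stats::dnorm(xs, 0, sx)
    gy <- stats::dnorm(ys, 0, sy)
    tot <- tot + kernel$weights[k] * sum(outer(gx, gy)) * h * h
  }
  tot
}

# Gaussian-blurred rectangular edge profile straight from the normal CDF.
blurred_edge_profile <- function(width_mm = 40, sigma_mm = 1,
                                 sampling_mm = 0.05, shift_mm = 0) {
  x <- seq(-width_mm, width_mm, by = sampling_mm)
  v <- stats::pnorm((width_mm / 2 - (x - shift_mm)) / sigma_mm) -
       stats::pnorm((-width_mm / 2 - (x - shift_mm)) / sigma_mm)
  beam_profile(x, v)
}

# Closed-form 20-80 penumbra coefficient of a Gaussian-blurred step:
# z(0.8) - z(0.2) of the standard normal.
PENUMBRA_COEFF <- qnorm(0.8) - qnorm(0.2)   # 1.68324

# Is `recovered` within one candidate-grid step of `truth`?
within_one_step <- function(recovered, truth, values_mm) {
  i <- which(abs(values_mm - truth) < 1e-9)
  lo <- values_mm[max(1L, i - 1L)]
  hi <- values_mm[min(length(values_mm), i + 1L)]
  recovered >= lo - 1e-9 && recovered <= hi + 1e-9
}
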