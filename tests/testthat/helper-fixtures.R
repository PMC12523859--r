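# Shared fixtures, built in code. Small grids keep the optics tests fast;
# the physics being checked (closed forms, conservation laws) is
# grid-size-independent.

plain_lens <- function(sa = 0) {
  diffractive_lens(harmonics = data.frame(amplitude = numeric(),
                                          index = integer(),
                                          phase = numeric()),
                   sa_coefficient = sa)
}

single_harmonic_lens <- function(m, sa = 0, ...) {
  diffractive_lens(harmonics = data.frame(amplitude = m, index = 1L,
                                          phase = 0),
                   sa_coefficient = sa, ...)
}

small_eye <- function(pupils = 3, grid = 256, wavelengths = 550,
                      weights = rep(1, length(wavelengths)),
                      defocus = seq(1, -4, by = -0.5), ...) {
  model_eye(wavelengths = wavelengths, luminosity_weights = weights,
            pupil_diameters = pupils, defocus = defocus,
            grid_size = grid, ...)
}

# piecewise-linear synthetic VA defocus curve through given (defocus, va)
# knots, sampled on a uniform spectacle-plane grid
synthetic_vadc <- function(knots_d, knots_va, grid = seq(1, -4, by = -0.1)) {
  va <- stats::approx(knots_d, knots_va, xout = grid, rule = 2)$y
  structure(data.frame(defocus = grid, va = va),
            class = c("vadc", "data.frame"), pupil = NA, model_name = "synthetic")
}
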