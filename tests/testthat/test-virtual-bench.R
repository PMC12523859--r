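# Fourier-optics engine: pupil synthesis, PSF energy bookkeeping, and the
# radially averaged MTF against closed-form oracles.

test_that("unaberrated pupil has uniform phase and correct area", {
  lens <- plain_lens()
  eye <- small_eye(pupils = 4.5)
  fld <- pupil_function(lens, eye, 3, 550, 0, base_offset = 0)
  ph <- Arg(fld$field[Mod(fld$field) > 0.999])
  expect_lt(max(abs(ph)), 1e-12)
  # doubling the aperture area doubles the transmitted energy
  e3 <- sum(Mod(fld$field)^2)
  fld2 <- pupil_function(lens, eye, 3 * sqrt(2), 550, 0, base_offset = 0)
  expect_equal(sum(Mod(fld2$field)^2) / e3, 2, tolerance = 1e-2)
})

test_that("spherical aberration rescales as (pupil/6)^4", {
  lens <- plain_lens(sa = -0.1)
  eye <- small_eye(grid = 256)
  g6 <- iolbench:::pupil_geometry(lens, model_eye(pupil_diameters = 6,
                                                  grid_size = 256), 6)
  g3 <- iolbench:::pupil_geometry(lens, eye, 3)
  # Z(4,0) edge value is c40*sqrt(5) (rho = 1): ratio of edge wavefronts
  # between apertures must be (3/6)^4
  edge6 <- max(abs(g6$W_sa))
  edge3 <- max(abs(g3$W_sa))
  expect_equal(edge3 / edge6, (3 / 6)^4, tolerance = 0.05)
  expect_equal(edge6, 0.1 * sqrt(5), tolerance = 0.05)
})

test_that("PSF conserves energy and reproduces the Airy first zero", {
  lens <- plain_lens()
  eye <- small_eye(grid = 512)
  fld <- pupil_function(lens, eye, 3, 550, 0, base_offset = 0)
  p <- psf(fld)
  expect_equal(sum(p$intensity), sum(Mod(fld$field)^2),
               tolerance = 1e-6)                      # Parseval
  # radial profile: first minimum at 1.22 lambda f / D
  inten <- p$intensity
  N <- p$N
  prof <- inten[1, 1:(N / 2)]                          # along one axis
  k <- which(diff(prof) > 0)[1]                        # first upturn
  r_zero <- (k - 0.5) * p$dx                           # between samples
  airy <- 1.22 * 550e-6 * 16.67 / 3
  expect_lt(abs(r_zero - airy), p$dx)                  # within one cell
})

test_that("diffraction-limited MTF matches the circular-aperture closed form", {
  lens <- plain_lens()
  for (pupil in c(1.5, 3.0, 4.5)) {
    eye <- small_eye(pupils = pupil, grid = 512)
    cv <- mtf(psf(pupil_function(lens, eye, pupil, 550, 0, base_offset = 0)),
              eye)
    ref <- iolbench:::diffraction_limited_mtf(cv$frequency, pupil, 550, 16.67)
    sel <- cv$frequency <= 50
    expect_lt(max(abs(cv$modulation - ref)[sel]), 0.01)
    expect_equal(cv$modulation[1], 1)                  # MTF(0) = 1
    expect_true(all(cv$modulation >= 0 & cv$modulation <= 1 + 1e-9))
  }
})

test_that("aberrated MTF never exceeds the diffraction-limited bound", {
  lens <- plain_lens()
  eye <- small_eye(grid = 512)
  dl <- mtf(psf(pupil_function(lens, eye, 3, 550, 0, base_offset = 0)), eye)
  ab <- mtf(psf(pupil_function(lens, eye, 3, 550, 0.5, base_offset = 0)), eye)
  expect_true(all(ab$modulation <= dl$modulation + 5e-3))
  expect_lt(mtfa(ab), mtfa(dl))
})

test_that("defocus sign shifts the through-focus peak to the conjugate vergence", {
  lens <- plain_lens()
  eye <- small_eye(defocus = seq(2, -2, by = -0.25), grid = 256)
  peak_at <- function(offset) {
    v <- vapply(eye$defocus, function(d) {
      mtfa(mtf(psf(pupil_function(lens, eye, 3, 550, d,
                                  base_offset = offset)), eye))
    }, numeric(1))
    eye$defocus[which.max(v)]
  }
  expect_equal(peak_at(0), 0)
  expect_equal(peak_at(1), -1)      # +1 D base power focuses a -1 D vergence
  expect_equal(peak_at(-1), 1)      # opposite conjugate shift
})

test_that("wavelength sets the diffraction-limited cutoff ordering", {
  # cutoff = D/(lambda f): bluer light transmits higher frequencies
  c450 <- iolbench:::cutoff_frequency(3, 450, 16.67)
  c650 <- iolbench:::cutoff_frequency(3, 650, 16.67)
  expect_equal(c450 / c650, 650 / 450, tolerance = 1e-12)
  lens <- plain_lens()
  eye <- small_eye(grid = 256, wavelengths = c(450, 650), weights = c(1, 1))
  m450 <- mtf(psf(pupil_function(lens, eye, 3, 450, 0, base_offset = 0)), eye)
  m650 <- mtf(psf(pupil_function(lens, eye, 3, 650, 0, base_offset = 0)), eye)
  expect_gt(mtfa(m450), mtfa(m650))
})

test_that("sweep is exhaustive and iteration-order invariant", {
  lens <- single_harmonic_lens(1.0)
  eye <- small_eye(pupils = c(2, 3), grid = 128,
                   wavelengths = c(500, 550), weights = c(0.5, 1),
                   defocus = seq(1, -4, by = -1))
  sw <- through_focus_sweep(lens, eye)
  expect_equal(nrow(sw$mtfa), 2 * 2 * 6)
  # permutation invariance: sweeping pupils in reverse order gives the
  # same per-cell values
  sw2 <- through_focus_sweep(lens, eye, pupils = c(3, 2))
  key <- function(s) s$mtfa[order(s$mtfa$pupil, s$mtfa$wavelength,
                                  s$mtfa$defocus), "mtfa"]
  expect_equal(key(sw), key(sw2), tolerance = 1e-12)
  # default full-grid arithmetic: 9 pupils x 5 wavelengths x 51 defocus
  full <- model_eye()
  expect_equal(length(full$pupil_diameters) * length(full$wavelengths) *
                 length(full$defocus), 2295)
})

test_that("configuration guards fire", {
  lens <- plain_lens()
  eye <- small_eye()
  expect_error(pupil_function(lens, eye, 13, 550, 0), "extent")
  expect_error(model_eye(grid_size = 300), "power of two")
  expect_error(model_eye(defocus = c(1, 0.5, 0.1)), "uniform")
  expect_error(model_eye(pupil_diameters = 3, pupil_plane_extent = 10),
               "Nyquist")
  bad <- psf(pupil_function(lens, eye, 3, 550, 0))
  bad$intensity[] <- 0
  expect_error(mtf(bad, eye), "normalization")
})
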