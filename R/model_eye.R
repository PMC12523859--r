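#' Model-eye and simulation configuration
#'
#' Configuration of the Fourier-optics model eye: wavelengths and their
#' photopic luminosity weights, pupil diameters, the through-focus defocus
#' grid (object vergence at the IOL plane), the effective focal length that
#' sets the image-plane spatial-frequency scale, and the numerical grid.
#'
#' The pupil-plane sampling must satisfy the incoherent Nyquist condition:
#' the incoherent cutoff frequency \eqn{D/(\lambda f)} may not exceed half
#' the PSF-plane Nyquist frequency. With a pupil-plane extent \eqn{L} the
#' condition reduces to \eqn{L \ge 4D} for every simulated aperture,
#' independent of wavelength; the default extent is exactly 4x the largest
#' pupil.
#'
#' @param wavelengths Wavelengths in nm.
#' @param luminosity_weights Photopic V(lambda) weights, one per wavelength.
#' @param pupil_diameters Pupil diameters in mm.
#' @param defocus Object vergence grid in diopters at the IOL plane;
#'   must be uniformly spaced and strictly monotone.
#' @param focal_length Effective focal length in mm mapping pupil-plane
#'   frequency to image-plane lp/mm (default 16.67).
#' @param grid_size Samples per grid side; must be a power of two.
#' @param pupil_plane_extent Physical side length of the pupil-plane grid in
#'   mm; default `4 * max(pupil_diameters)`.
#' @return An object of class `model_eye`.
#' @export
#' @examples
#' eye <- model_eye(pupil_diameters = 3, grid_size = 256)
#' eye
model_eye <- function(wavelengths = c(450, 500, 550, 600, 650),
                      luminosity_weights = c(0.038, 0.323, 0.995, 0.631, 0.107),
                      pupil_diameters = seq(1.5, 5.5, by = 0.5),
                      defocus = seq(1.0, -4.0, by = -0.1),
                      focal_length = 16.67,
                      grid_size = 1024,
                      pupil_plane_extent = NULL) {
  if (length(wavelengths) != length(luminosity_weights))
    stop("wavelengths and luminosity_weights must have the same length")
  if (any(wavelengths <= 0) || any(luminosity_weights < 0))
    stop("wavelengths must be positive, weights nonnegative")
  if (length(defocus) < 2) stop("defocus grid needs at least two points")
  dd <- diff(defocus)
  if (any(abs(dd - dd[1]) > 1e-9) || dd[1] == 0)
    stop("defocus grid must be uniform and strictly monotone")
  if (grid_size < 2 || bitwAnd(grid_size, grid_size - 1L) != 0)
    stop("grid_size must be a power of two")
  if (is.null(pupil_plane_extent))
    pupil_plane_extent <- 4 * max(pupil_diameters)
  if (pupil_plane_extent < 4 * max(pupil_diameters) - 1e-9)
    stop(sprintf(paste0("pupil_plane_extent %.3g mm violates the Nyquist ",
                        "condition extent >= 4 x largest aperture (%.3g mm)"),
                 pupil_plane_extent, 4 * max(pupil_diameters)))
  # defocus grid rounded to a stable representation (0.1 D steps suffer
  # from floating accumulation in seq())
  defocus <- round(defocus, 10)
  structure(list(
    wavelengths = wavelengths,
    luminosity_weights = luminosity_weights,
    pupil_diameters = pupil_diameters,
    defocus = defocus,
    focal_length = focal_length,
    grid_size = as.integer(grid_size),
    pupil_plane_extent = pupil_plane_extent
  ), class = "model_eye")
}

#' @export
print.model_eye <- function(x, ...) {
  cat("Fourier-optics model eye\n")
  cat(sprintf("  wavelengths : %s nm (weights %s)\n",
              paste(x$wavelengths, collapse = ", "),
              paste(x$luminosity_weights, collapse = ", ")))
  cat(sprintf("  pupils : %s mm\n", paste(x$pupil_diameters, collapse = ", ")))
  cat(sprintf("  defocus : %+.1f to %+.1f D in %d steps of %.2g D (IOL plane)\n",
              x$defocus[1], x$defocus[length(x$defocus)], length(x$defocus) - 1,
              diff(x$defocus)[1]))
  cat(sprintf("  focal length %.4g mm | grid %d^2 over %.3g mm\n",
              x$focal_length, x$grid_size, x$pupil_plane_extent))
  invisible(x)
}

# Incoherent cutoff frequency of a circular aperture, lp/mm at image plane.
cutoff_frequency <- function(pupil_mm, wavelength_nm, focal_length_mm) {
  pupil_mm / (wavelength_nm * 1e-6 * focal_length_mm)
}

# Closed-form diffraction-limited MTF of a circular aperture.
# nu in lp/mm at image plane.
diffraction_limited_mtf <- function(nu, pupil_mm, wavelength_nm,
                                    focal_length_mm) {
  nc <- cutoff_frequency(pupil_mm, wavelength_nm, focal_length_mm)
  s <- pmin(abs(nu) / nc, 1)
  (2 / pi) * (acos(s) - s * sqrt(1 - s^2))
}
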