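# Virtual optical bench: pupil-plane synthesis -> PSF -> radially averaged
# MTF, through focus. The physical bench geometry (Badal lens, 4f relay,
# pinhole, camera) is replaced by direct pupil-plane synthesis: object
# vergence is injected as a quadratic wavefront over the aperture, which is
# exactly what a Badal arrangement produces at the pupil.

# Per-pupil geometric precomputation shared by all wavelengths/defocus.
pupil_geometry <- function(lens, eye, pupil) {
  N <- eye$grid_size
  L <- eye$pupil_plane_extent
  if (pupil > L + 1e-9)
    stop(sprintf("aperture %.3g mm exceeds simulated extent %.3g mm",
                 pupil, L))
  # incoherent cutoff <= half the PSF-plane Nyquist frequency reduces to
  # extent >= 4 x aperture (wavelength-independent)
  if (pupil > L / 4 + 1e-9)
    stop("pupil-plane extent too small for Nyquist-adequate PSF sampling")
  dxi <- L / N
  x <- (seq_len(N) - 1 - N / 2) * dxi
  r2 <- outer(x^2, x^2, "+")          # mm^2
  r <- sqrt(r2)
  R <- pupil / 2
  # grey-pixel aperture edge: linear ramp one pixel wide, reduces edge
  # pixelation error in the MTF
  mask <- pmin(pmax((R - r) / dxi + 0.5, 0), 1)
  inside <- r <= R
  in_zone <- inside & (2 * r >= lens$zone_inner_diameter) &
    (2 * r <= lens$zone_outer_diameter)
  # diffractive phase at the design wavelength (zone-gated)
  phi_design <- matrix(0, N, N)
  if (nrow(lens$harmonics)) {
    T2 <- lens_period_r2(lens)
    u <- 2 * pi * r2 / T2
    for (i in seq_len(nrow(lens$harmonics)))
      phi_design <- phi_design + lens$harmonics$amplitude[i] *
        sin(lens$harmonics$index[i] * u + lens$harmonics$phase[i])
    phi_design[!in_zone] <- 0
  }
  # spherical aberration wavefront in micrometers over this aperture:
  # Z(4,0) with the 6 mm coefficient rescaled by (pupil/6)^4
  W_sa <- matrix(0, N, N)
  if (lens$sa_coefficient != 0) {
    c40 <- lens$sa_coefficient * (pupil / 6)^4
    rho2 <- pmin(r2 / R^2, 1)
    W_sa <- c40 * sqrt(5) * (6 * rho2^2 - 6 * rho2 + 1)
    W_sa[!inside] <- 0
  }
  # base-power offset map (diopters): which focus the carrier (order 0)
  # sits at. In the diffractive annulus order 0 is the intermediate focus,
  # i.e. offset = +order_spacing; the refractive central zone carries the
  # far focus (offset 0) by default.
  offset <- matrix(0, N, N)
  offset[in_zone] <- lens$order_spacing
  if (lens$central_zone_role == "intermediate")
    offset[inside & !in_zone] <- lens$order_spacing
  list(N = N, dxi = dxi, r2 = r2, mask = mask, inside = inside,
       phi_design = phi_design, W_sa = W_sa, offset = offset, pupil = pupil)
}

#' Complex pupil function of the model eye
#'
#' Assembles the complex field at the exit pupil: a (grey-edged) circular
#' aperture carrying the diffractive surface phase, the spherical-aberration
#' wavefront (Z(4,0), rescaled from its 6 mm definition by `(pupil/6)^4`),
#' and the defocus wavefront corresponding to the requested object vergence
#' at the IOL plane.
#'
#' @param lens A [diffractive_lens()].
#' @param eye A [model_eye()].
#' @param pupil Pupil diameter in mm.
#' @param wavelength Wavelength in nm.
#' @param defocus Object vergence in diopters at the IOL plane.
#' @param base_offset Optional scalar override (diopters) of the lens-derived
#'   base-power map; `0` gives a plain aperture focused at 0 D defocus.
#' @param geometry Precomputed [pupil_geometry] (internal; avoids repeating
#'   the per-pupil setup inside sweeps).
#' @return A list of class `pupil_field` with the complex `field` matrix and
#'   the sampling metadata.
#' @export
pupil_function <- function(lens, eye, pupil, wavelength, defocus,
                           base_offset = NULL, geometry = NULL) {
  validate_lens(lens)
  if (is.null(geometry)) geometry <- pupil_geometry(lens, eye, pupil)
  g <- geometry
  lam_mm <- wavelength * 1e-6
  k <- 2 * pi / lam_mm
  phi <- g$phi_design * (lens$design_wavelength / wavelength) +
    k * (g$W_sa * 1e-3)                     # um -> mm
  P <- if (is.null(base_offset)) defocus + g$offset else defocus + base_offset
  # vergence error P (D) -> wavefront P/2 * r^2 (r in m, W in m); with r in
  # mm and W in mm this is P/2 * r2 * 1e-3
  phi <- phi + k * (P / 2) * g$r2 * 1e-3
  field <- g$mask * exp(1i * phi)
  structure(list(field = field, dxi = g$dxi, pupil = pupil,
                 wavelength = wavelength, defocus = defocus,
                 focal_length = eye$focal_length),
            class = "pupil_field")
}

#' Point-spread function of a pupil field
#'
#' Squared modulus of the far-field (Fraunhofer) transform of the pupil
#' field, normalized so that total PSF energy equals the energy transmitted
#' by the pupil (Parseval).
#'
#' @param field A `pupil_field` from [pupil_function()].
#' @return A list of class `psf_grid` with the intensity matrix (`intensity`,
#'   unshifted FFT layout) and the image-plane sample spacing `dx` in mm.
#' @export
psf <- function(field) {
  stopifnot(inherits(field, "pupil_field"))
  if (!all(is.finite(Re(field$field)) & is.finite(Im(field$field))))
    stop("pupil field contains non-finite values")
  N <- nrow(field$field)
  F <- stats::fft(field$field)
  intensity <- Re(F * Conj(F)) / N^2
  dx <- (field$wavelength * 1e-6) * field$focal_length /
    (N * field$dxi)                         # mm at image plane
  structure(list(intensity = intensity, dx = dx, N = N,
                 pupil = field$pupil, wavelength = field$wavelength,
                 defocus = field$defocus),
            class = "psf_grid")
}

# radial bin indices for the OTF grid: bin k collects |nu| in
# [(k-0.5) dnu, (k+0.5) dnu); returned as integer vector over the matrix.
otf_radial_bins <- function(N, dnu, nu_max) {
  f1 <- c(0:(N / 2), -(N / 2 - 1):-1)       # cycles per full grid
  nu2 <- outer(f1^2, f1^2, "+")
  bins <- as.integer(round(sqrt(nu2)))      # in units of dnu
  kmax <- as.integer(ceiling(nu_max / dnu))
  bins[bins > kmax] <- -1L
  list(bins = bins, kmax = kmax)
}

#' Radially averaged MTF of a PSF
#'
#' Fourier transforms the PSF to the optical transfer function, normalizes
#' to unity at zero frequency, and reduces the 2-D modulation surface to a
#' 1-D curve by averaging over orientation in radial frequency bins. The
#' frequency axis is expressed in line pairs per mm at the image plane via
#' the configured effective focal length.
#'
#' @param p A `psf_grid` from [psf()].
#' @param eye A [model_eye()] (provides the focal length; must match the one
#'   used to build the field).
#' @param nu_max Largest frequency (lp/mm) retained in the curve.
#' @return A data.frame of class `mtf_curve` with columns `frequency`
#'   (uniform grid from 0) and `modulation`, plus pupil/wavelength/defocus
#'   attributes.
#' @export
mtf <- function(p, eye, nu_max = 60) {
  stopifnot(inherits(p, "psf_grid"))
  tot <- sum(p$intensity)
  if (tot <= 0) stop("undefined normalization: PSF has no energy")
  otf <- stats::fft(p$intensity)
  m2d <- Mod(otf) / Re(otf[1, 1])
  N <- p$N
  dnu <- 1 / (N * p$dx)                     # lp/mm
  rb <- otf_radial_bins(N, dnu, nu_max)
  keep <- rb$bins >= 0L
  sums <- rowsum(as.vector(m2d)[keep], as.vector(rb$bins)[keep])
  cnts <- rowsum(rep(1, sum(keep)), as.vector(rb$bins)[keep])
  k <- as.integer(rownames(sums))
  modulation <- as.vector(sums / cnts)
  ord <- order(k)
  out <- data.frame(frequency = k[ord] * dnu, modulation = modulation[ord])
  structure(out, class = c("mtf_curve", "data.frame"),
            pupil = p$pupil, wavelength = p$wavelength, defocus = p$defocus)
}

#' Through-focus sweep of the virtual bench
#'
#' Runs the full deterministic sweep over pupil x wavelength x defocus and
#' collapses every MTF curve to its MTF-area (see [mtfa()]). Optionally the
#' individual curves are retained.
#'
#' @param lens A [diffractive_lens()].
#' @param eye A [model_eye()].
#' @param pupils Pupil diameters to sweep (default: all in `eye`).
#' @param keep_curves Keep the per-cell `mtf_curve` objects (memory-heavy
#'   for full grids; default `FALSE` stores only MTFa values).
#' @param f_max Upper integration limit for MTFa in lp/mm.
#' @param verbose Print per-pupil progress.
#' @return A list of class `tf_sweep` with a long data.frame `$mtfa`
#'   (columns `pupil`, `wavelength`, `defocus`, `mtfa`) and, if requested,
#'   `$curves` keyed `"pupil|wavelength|defocus"`.
#' @export
through_focus_sweep <- function(lens, eye, pupils = eye$pupil_diameters,
                                keep_curves = FALSE, f_max = 50,
                                verbose = FALSE) {
  validate_lens(lens)
  rows <- expand.grid(defocus = eye$defocus, wavelength = eye$wavelengths,
                      pupil = pupils, KEEP.OUT.ATTRS = FALSE)
  rows <- rows[, c("pupil", "wavelength", "defocus")]
  rows$mtfa <- NA_real_
  curves <- if (keep_curves) vector("list", nrow(rows)) else NULL
  i <- 0L
  for (p in pupils) {
    if (verbose) message(sprintf("pupil %.1f mm ...", p))
    g <- pupil_geometry(lens, eye, p)
    for (w in eye$wavelengths) {
      for (d in eye$defocus) {
        i <- i + 1L
        fld <- pupil_function(lens, eye, p, w, d, geometry = g)
        cv <- mtf(psf(fld), eye, nu_max = max(60, f_max * 1.2))
        rows$mtfa[i] <- mtfa(cv, f_max = f_max)
        if (keep_curves) curves[[i]] <- cv
      }
    }
  }
  if (keep_curves)
    names(curves) <- sprintf("%g|%g|%g", rows$pupil, rows$wavelength,
                             rows$defocus)
  structure(list(mtfa = rows, curves = curves, eye = eye, f_max = f_max),
            class = "tf_sweep")
}

#' @export
print.tf_sweep <- function(x, ...) {
  cat(sprintf("Through-focus sweep: %d cells (%d pupils x %d wavelengths x %d defocus)\n",
              nrow(x$mtfa), length(unique(x$mtfa$pupil)),
              length(unique(x$mtfa$wavelength)),
              length(unique(x$mtfa$defocus))))
  invisible(x)
}
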