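# MTF-area metric, photopic weighting, and through-focus assembly.

#' MTF area (MTFa)
#'
#' Composite-trapezoid integral of the modulation transfer function over
#' spatial frequency from 0 to `f_max` lp/mm (default 50), the scalar
#' image-quality metric that empirical visual-acuity prediction models take
#' as input. No smoothing is applied; if `f_max` falls between grid nodes
#' the final partial interval is integrated against a linearly interpolated
#' endpoint.
#'
#' @param curve An `mtf_curve` (or any data.frame with `frequency` and
#'   `modulation` columns, frequencies ascending).
#' @param f_max Upper integration limit, lp/mm.
#' @return The area (units lp/mm, modulation being unitless).
#' @export
mtfa <- function(curve, f_max = 50) {
  f <- curve$frequency
  m <- curve$modulation
  if (is.null(f) || is.null(m)) stop("curve must have frequency and modulation")
  if (is.unsorted(f, strictly = TRUE)) stop("frequencies must be ascending")
  if (min(f) > 0 || max(f) < f_max)
    stop(sprintf("curve covers [%.3g, %.3g] lp/mm, not [0, %g]",
                 min(f), max(f), f_max))
  keep <- f <= f_max
  fk <- f[keep]; mk <- m[keep]
  if (max(fk) < f_max) {
    mend <- stats::approx(f, m, xout = f_max)$y
    fk <- c(fk, f_max); mk <- c(mk, mend)
  }
  sum(diff(fk) * (utils::head(mk, -1) + utils::tail(mk, -1)) / 2)
}

#' Polychromatic MTFa by photopic weighting
#'
#' Combines per-wavelength MTFa values with photopic luminosity V(lambda)
#' weights. By default the weighted sum is normalized by the sum of the
#' weights, i.e. a weighted mean, so the polychromatic value stays on the
#' same scale as the monochromatic inputs (the scale on which the
#' prediction models were built); `normalize = FALSE` gives the raw
#' weighted sum.
#'
#' @param values Named numeric vector of MTFa values, names = wavelengths nm.
#' @param weights Named numeric vector of weights over the same wavelengths.
#' @param normalize Divide by the sum of weights (default `TRUE`).
#' @return Scalar polychromatic MTFa.
#' @export
#' @examples
#' w <- c(`450` = 0.038, `500` = 0.323, `550` = 0.995, `600` = 0.631,
#'        `650` = 0.107)
#' polychromatic_mtfa(c(`450` = 0, `500` = 0, `550` = 1, `600` = 0,
#'                      `650` = 0), w)  # 0.995 / 2.094
polychromatic_mtfa <- function(values, weights, normalize = TRUE) {
  if (is.null(names(values)) || is.null(names(weights)))
    stop("values and weights must be named by wavelength")
  if (!setequal(names(values), names(weights)))
    stop("mismatched wavelength sets between values and weights")
  w <- weights[names(values)]
  s <- sum(as.numeric(w) * as.numeric(values))
  if (normalize) s / sum(w) else s
}

#' Assemble a through-focus MTFa table for one pupil
#'
#' Reshapes sweep results into the exchange table: one row per defocus value
#' with one MTFa column per wavelength plus the photopically weighted
#' polychromatic column.
#'
#' @param sweep A `tf_sweep` from [through_focus_sweep()].
#' @param pupil Pupil diameter (mm) to extract.
#' @param normalize Passed to [polychromatic_mtfa()].
#' @return A data.frame of class `through_focus_mtfa` with columns
#'   `defocus`, `mtfa_<wavelength>` ... and `mtfa_poly`; attributes `pupil`,
#'   `wavelengths`, `weights`.
#' @export
assemble_through_focus <- function(sweep, pupil, normalize = TRUE) {
  stopifnot(inherits(sweep, "tf_sweep"))
  eye <- sweep$eye
  df <- sweep$mtfa[abs(sweep$mtfa$pupil - pupil) < 1e-9, ]
  if (!nrow(df)) stop(sprintf("sweep holds no results for pupil %g mm", pupil))
  out <- data.frame(defocus = eye$defocus)
  for (w in eye$wavelengths) {
    v <- df$mtfa[abs(df$wavelength - w) < 1e-9][
      match(eye$defocus, df$defocus[abs(df$wavelength - w) < 1e-9])]
    if (any(is.na(v)))
      stop(sprintf("incomplete sweep: missing (%g nm, defocus) cells for pupil %g",
                   w, pupil))
    out[[paste0("mtfa_", w)]] <- v
  }
  wts <- stats::setNames(eye$luminosity_weights, eye$wavelengths)
  out$mtfa_poly <- apply(out[, paste0("mtfa_", eye$wavelengths), drop = FALSE],
                         1, function(row) {
                           polychromatic_mtfa(
                             stats::setNames(row, eye$wavelengths), wts,
                             normalize = normalize)
                         })
  structure(out, class = c("through_focus_mtfa", "data.frame"),
            pupil = pupil, wavelengths = eye$wavelengths,
            weights = eye$luminosity_weights)
}

#' Locate through-focus MTFa peaks
#'
#' Finds the local maxima of a through-focus MTFa column and labels the
#' far peak (local maximum closest to 0 D), the near peak (most myopic
#' local maximum) and, when present, the intermediate peak (tallest local
#' maximum strictly between them). Maxima below `min_height_frac` times the
#' curve maximum are treated as ripple and ignored.
#'
#' @param tf A `through_focus_mtfa`.
#' @param column Which column to analyse (e.g. `"mtfa_poly"`, `"mtfa_550"`).
#' @param min_height_frac Ripple-rejection threshold as a fraction of the
#'   column maximum.
#' @return A list with `far`, `intermediate`, `near` defocus values (D, IOL
#'   plane; `intermediate` may be `NA`) and the full `peaks` data.frame.
#' @export
tf_peaks <- function(tf, column = "mtfa_poly", min_height_frac = 0.1) {
  stopifnot(inherits(tf, "through_focus_mtfa"))
  v <- tf[[column]]
  if (is.null(v)) stop(sprintf("no column `%s` in through-focus table", column))
  d <- tf$defocus
  ord <- order(d)
  d <- d[ord]; v <- v[ord]
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              FALSE)
  is_max <- is_max & v >= min_height_frac * max(v)
  peaks <- data.frame(defocus = d[is_max], value = v[is_max])
  if (!nrow(peaks)) stop("no through-focus peaks found")
  far <- peaks$defocus[which.min(abs(peaks$defocus))]
  near <- min(peaks$defocus)
  mid <- peaks[peaks$defocus > near & peaks$defocus < far, , drop = FALSE]
  intermediate <- if (nrow(mid)) mid$defocus[which.max(mid$value)] else NA_real_
  list(far = far, intermediate = intermediate, near = near, peaks = peaks)
}

#' Write / read the through-focus MTFa exchange CSV
#'
#' Plain UTF-8, dot-decimal CSV with columns `pupil_mm`, `defocus_D`, one
#' `mtfa_<wavelength>` column per wavelength and `mtfa_poly`. This is the
#' interchange dialect for externally measured bench data; reading validates
#' grid uniformity and completeness.
#'
#' @param tfs A single `through_focus_mtfa` or a list of them (one per
#'   pupil).
#' @param path File path.
#' @return `read_mtfa_csv` returns a named list of `through_focus_mtfa`
#'   (names = pupil diameters); `write_mtfa_csv` returns `path` invisibly.
#' @export
write_mtfa_csv <- function(tfs, path) {
  if (inherits(tfs, "through_focus_mtfa")) tfs <- list(tfs)
  rows <- lapply(tfs, function(tf) {
    df <- as.data.frame(tf)
    cbind(pupil_mm = attr(tf, "pupil"),
          stats::setNames(df, c("defocus_D", names(df)[-1])))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_mtfa_csv
#' @export
read_mtfa_csv <- function(path) {
  if (any(grepl(";", readLines(path, n = 2L))))
    stop("semicolon/comma-decimal (locale) CSV detected; expected dot-decimal, comma-separated")
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("pupil_mm", "defocus_D", "mtfa_poly")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed header: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  wcols <- grep("^mtfa_[0-9]+$", names(df), value = TRUE)
  if (!length(wcols)) stop("malformed header: no mtfa_<wavelength> columns")
  if (any(!vapply(df, is.numeric, logical(1))))
    stop("non-numeric cells found; check decimal separator and header")
  wavelengths <- as.numeric(sub("mtfa_", "", wcols))
  out <- list()
  for (p in unique(df$pupil_mm)) {
    sub <- df[df$pupil_mm == p, ]
    sub <- sub[order(-sub$defocus_D), ]
    dd <- diff(sub$defocus_D)
    if (length(dd) < 1 || any(abs(dd - dd[1]) > 1e-6))
      stop(sprintf("non-uniform or incomplete defocus grid for pupil %g mm", p))
    tf <- data.frame(defocus = sub$defocus_D)
    for (w in wcols) tf[[w]] <- sub[[w]]
    tf$mtfa_poly <- sub$mtfa_poly
    out[[as.character(p)]] <- structure(
      tf, class = c("through_focus_mtfa", "data.frame"),
      pupil = p, wavelengths = wavelengths, weights = NULL)
  }
  out
}
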