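# Spectacle-plane conversion, depth-of-field, intermediate-to-near delta VA
# and the functional classification rules.

#' Paraxial plane-conversion parameters
#'
#' Parameters for converting defocus between the spectacle plane (where
#' clinical defocus-curve trial lenses sit) and the IOL plane (where the
#' bench vergence grid is defined), by paraxial vergence propagation through
#' the vertex distance and the cornea. Two presets are provided: the bench
#' model eye (27.8 D achromatic cornea) and a physiological eye (43 D
#' cornea).
#'
#' @param preset `"bench"` (default) or `"physiological"`; explicit
#'   arguments override preset values.
#' @param spectacle_vertex_distance Vertex distance, mm.
#' @param cornea_power Corneal power, D.
#' @param cornea_to_iol_distance Cornea-to-IOL distance, mm.
#' @param aqueous_index Refractive index of the medium between cornea and
#'   IOL.
#' @return An object of class `plane_conversion`.
#' @export
plane_conversion <- function(preset = c("bench", "physiological"),
                             spectacle_vertex_distance = 12,
                             cornea_power = NULL,
                             cornea_to_iol_distance = 4.0,
                             aqueous_index = 1.336) {
  preset <- match.arg(preset)
  if (is.null(cornea_power))
    cornea_power <- switch(preset, bench = 27.8, physiological = 43)
  p <- list(spectacle_vertex_distance = spectacle_vertex_distance,
            cornea_power = cornea_power,
            cornea_to_iol_distance = cornea_to_iol_distance,
            aqueous_index = aqueous_index, preset = preset)
  if (any(unlist(p[1:4]) <= 0))
    stop("plane-conversion distances, power and index must be positive")
  structure(p, class = "plane_conversion")
}

# Forward vergence chase: power of a thin trial lens at the spectacle plane
# -> defocus it produces at the IOL plane (D), for a distant object.
spectacle_to_iol_defocus <- function(d_spec, params) {
  stopifnot(inherits(params, "plane_conversion"))
  t1 <- params$spectacle_vertex_distance * 1e-3           # m, in air
  t2 <- params$cornea_to_iol_distance * 1e-3 / params$aqueous_index
  chase <- function(P) {
    v <- P / (1 - t1 * P)
    v <- v + params$cornea_power
    v / (1 - t2 * v)
  }
  chase(d_spec) - chase(0)
}

#' Convert IOL-plane defocus to the spectacle plane
#'
#' Finds the spectacle-plane trial-lens power that, propagated through the
#' vertex distance and the cornea by paraxial vergence chase, reproduces the
#' given vergence error at the IOL plane. The mapping is strictly monotone,
#' so grid ordering is preserved.
#'
#' @param d_iol Defocus value(s) in diopters at the IOL plane (|d| < 20).
#' @param params A [plane_conversion()].
#' @return Defocus in diopters at the spectacle plane.
#' @export
#' @examples
#' iol_to_spectacle_defocus(c(0, -1.8, -3.6), plane_conversion("bench"))
iol_to_spectacle_defocus <- function(d_iol, params = plane_conversion("bench")) {
  stopifnot(inherits(params, "plane_conversion"))
  if (any(abs(d_iol) >= 20))
    stop("vergence outside paraxial validity (|D| < 20)")
  vapply(d_iol, function(d) {
    if (d == 0) return(0)
    stats::uniroot(function(P) spectacle_to_iol_defocus(P, params) - d,
                   interval = c(-19, 19), tol = 1e-12)$root
  }, numeric(1))
}

#' Depth-of-field of a visual-acuity defocus curve
#'
#' Dioptric range from 0 D to the defocus cut-off: walking from 0 D toward
#' negative (near) defocus, the first upward crossing of the acuity
#' threshold, located by linear interpolation between grid points. If the
#' curve never exceeds the threshold within the grid, the grid extent is
#' returned with the `grid_bounded` attribute set.
#'
#' @param curve A `vadc` (or data.frame with `defocus` and `va`), with 0 D
#'   inside its grid and VA(0) at or below the threshold.
#' @param threshold Acuity cut-off in logMAR (0.2 default, 0.3 the common
#'   alternative).
#' @param crossing `"first"` (default) or `"last"`: multifocal curves can
#'   re-enter the threshold; the range definition does not address re-entry,
#'   so the first crossing is the default.
#' @return Depth-of-field in diopters (positive), with attribute
#'   `grid_bounded` (logical).
#' @export
dofi <- function(curve, threshold = 0.2, crossing = c("first", "last")) {
  crossing <- match.arg(crossing)
  d <- curve$defocus; va <- curve$va
  ord <- order(d, decreasing = TRUE)        # from positive toward near
  d <- d[ord]; va <- va[ord]
  if (min(d) > 0 || max(d) < 0) stop("curve must contain 0 D within its grid")
  va0 <- stats::approx(d, va, xout = 0)$y
  if (va0 > threshold)
    stop(sprintf("far vision fails threshold: VA(0) = %.3f > %.3f logMAR",
                 va0, threshold))
  dn <- c(0, d[d < 0]); vn <- c(va0, va[d < 0])
  crossings <- c()
  for (i in seq_len(length(dn) - 1)) {
    if (vn[i] <= threshold && vn[i + 1] > threshold) {
      dc <- dn[i] + (threshold - vn[i]) / (vn[i + 1] - vn[i]) *
        (dn[i + 1] - dn[i])
      crossings <- c(crossings, abs(dc))
    }
  }
  if (!length(crossings))
    return(structure(abs(min(dn)), grid_bounded = TRUE))
  val <- if (crossing == "first") crossings[1] else crossings[length(crossings)]
  structure(val, grid_bounded = FALSE)
}

#' Intermediate-to-near visual-acuity difference
#'
#' The difference between the worst acuity in the intermediate window
#' (defocus -0.50 to -2.00 D) and the best acuity in the near window
#' (-2.00 to -4.00 D), clamped at zero when near vision never improves on
#' the intermediate dip (a monotonically worsening curve).
#'
#' @param curve A `vadc` (spectacle-plane axis). The grid must cover the
#'   intermediate window; the near window is intersected with the grid and
#'   flagged `near_window_clipped` if the grid ends before -4 D.
#' @param intermediate_window,near_window Defocus windows in D.
#' @return Delta VA in logMAR (>= 0), with attributes `intermediate` and
#'   `near` (the located defocus positions) and `near_window_clipped`.
#' @export
delta_va <- function(curve, intermediate_window = c(-2.0, -0.5),
                     near_window = c(-4.0, -2.0)) {
  d <- curve$defocus; va <- curve$va
  if (min(d) > intermediate_window[1] || max(d) < intermediate_window[2])
    stop(sprintf("insufficient grid coverage: need [%g, %g] D, have [%g, %g]",
                 intermediate_window[1], intermediate_window[2], min(d), max(d)))
  if (max(d) < near_window[2] - 1e-9 || min(d) > near_window[2])
    stop("insufficient grid coverage: grid does not reach the near window")
  ii <- d >= intermediate_window[1] - 1e-9 & d <= intermediate_window[2] + 1e-9
  clipped <- min(d) > near_window[1] + 1e-9
  ni <- d >= near_window[1] - 1e-9 & d <= near_window[2] + 1e-9
  worst_int <- max(va[ii])
  best_near <- min(va[ni])
  structure(max(worst_int - best_near, 0),
            intermediate = d[ii][which.max(va[ii])],
            near = d[ni][which.min(va[ni])],
            near_window_clipped = clipped)
}

#' Functional classification from DOFi and delta VA
#'
#' Assigns the functional category: Partial when the depth-of-field is below
#' 2.3 D; otherwise Full, subtyped by the intermediate-to-near improvement:
#' Continuous (< 0.05 logMAR), Smooth (0.05 to < 0.14), Steep (>= 0.14).
#' Boundary values follow these inequality directions exactly.
#'
#' @param dofi_value Depth-of-field in D (>= 0).
#' @param delta Intermediate-to-near delta VA in logMAR (>= 0).
#' @param full_cut Full/Partial DOFi cut-off in D (2.3).
#' @return A list of class `functional_classification` with `category`
#'   (factor: Partial, Full_Continuous, Full_Smooth, Full_Steep), the
#'   single-letter `code` (p/a/b/c) and the inputs.
#' @export
#' @examples
#' classify(3.0, 0.12)   # Full_Smooth
#' classify(3.0, 0.14)   # Full_Steep (boundary inclusive)
#' classify(2.0, 0.30)   # Partial
classify <- function(dofi_value, delta, full_cut = 2.3) {
  if (dofi_value < 0 || delta < 0) stop("dofi_value and delta must be >= 0")
  lev <- c("Partial", "Full_Continuous", "Full_Smooth", "Full_Steep")
  category <- if (dofi_value < full_cut) "Partial"
  else if (delta < 0.05) "Full_Continuous"
  else if (delta < 0.14) "Full_Smooth"
  else "Full_Steep"
  code <- c(Partial = "p", Full_Continuous = "a", Full_Smooth = "b",
            Full_Steep = "c")[[category]]
  structure(list(category = factor(category, levels = lev), code = code,
                 dofi = dofi_value, delta_va = delta, full_cut = full_cut),
            class = "functional_classification")
}

#' @export
print.functional_classification <- function(x, ...) {
  cat(sprintf("%s (code %s): DOFi %.2f D, delta VA %.3f logMAR\n",
              as.character(x$category), x$code, x$dofi, x$delta_va))
  invisible(x)
}

#' Classify an IOL across pupils and prediction models
#'
#' Runs the full classification matrix: for every through-focus table (one
#' per pupil) and every prediction model, predicts the spectacle-plane
#' visual-acuity defocus curve, computes the depth-of-field and the
#' intermediate-to-near delta VA, and assigns the functional category.
#'
#' @param tfs A list of `through_focus_mtfa` objects (one per pupil), e.g.
#'   from [assemble_through_focus()] or [read_mtfa_csv()].
#' @param models A list of `va_model`s (default: the full registry).
#' @param plane A [plane_conversion()].
#' @param dofi_threshold Acuity threshold for the depth-of-field (0.2 or
#'   0.3 logMAR).
#' @param input Column selection passed to [predict_vadc()].
#' @return An object of class `iol_classification`: a long data.frame
#'   `$table` (pupil, model, dofi, grid_bounded, delta_va, category, code)
#'   plus the `$vadc` curves and the call parameters.
#' @export
classify_iol <- function(tfs, models = va_models(),
                         plane = plane_conversion("bench"),
                         dofi_threshold = 0.2, input = "auto") {
  if (inherits(tfs, "through_focus_mtfa")) tfs <- list(tfs)
  rows <- list(); curves <- list()
  for (tf in tfs) {
    pupil <- attr(tf, "pupil")
    for (m in models) {
      vc <- predict_vadc(m, tf, plane = plane, input = input)
      dv <- delta_va(vc)
      df <- dofi(vc, threshold = dofi_threshold)
      cl <- classify(as.numeric(df), as.numeric(dv))
      rows[[length(rows) + 1]] <- data.frame(
        pupil = pupil, model = m$name, dofi = as.numeric(df),
        grid_bounded = attr(df, "grid_bounded"), delta_va = as.numeric(dv),
        category = as.character(cl$category), code = cl$code)
      curves[[sprintf("%g|%s", pupil, m$name)]] <- vc
    }
  }
  structure(list(table = do.call(rbind, rows), vadc = curves,
                 models = names(models), dofi_threshold = dofi_threshold,
                 plane = plane),
            class = "iol_classification")
}

#' @export
print.iol_classification <- function(x, ...) {
  cat(sprintf("Functional classification (DOFi threshold %.1f logMAR)\n",
              x$dofi_threshold))
  print(classification_matrix(x))
  cat("codes: a = Full Continuous, b = Full Smooth, c = Full Steep, p = Partial\n")
  invisible(x)
}

#' @export
summary.iol_classification <- function(object, ...) {
  t <- object$table
  cat(sprintf("Pupils %g-%g mm, %d models; DOFi range %.2f-%.2f D\n",
              min(t$pupil), max(t$pupil), length(unique(t$model)),
              min(t$dofi), max(t$dofi)))
  shifts <- tapply(t$category, t$model, function(v) length(unique(v)))
  dep <- names(shifts)[shifts > 1]
  if (length(dep))
    cat(sprintf("pupil-dependent response (category changes with pupil): %s\n",
                paste(dep, collapse = ", ")))
  invisible(object)
}

# Wide delta-VA matrix with category code superscripts, mirroring the
# published presentation (rows = pupils, columns = models).
classification_matrix <- function(x) {
  t <- x$table
  pupils <- sort(unique(t$pupil))
  models <- unique(t$model)
  m <- matrix("", length(pupils), length(models),
              dimnames = list(sprintf("%.1f mm", pupils), models))
  for (i in seq_len(nrow(t))) {
    m[match(t$pupil[i], pupils), match(t$model[i], models)] <-
      sprintf("%.2f %s", t$delta_va[i], t$code[i])
  }
  as.data.frame(m)
}

#' Write the classification matrix CSV
#'
#' One row per pupil; for every model a `<model>_delta_va` column and a
#' `<model>_code` column (a = Continuous, b = Smooth, c = Steep,
#' p = Partial).
#'
#' @param x An `iol_classification`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(x, path) {
  t <- x$table
  pupils <- sort(unique(t$pupil))
  out <- data.frame(pupil_mm = pupils)
  for (m in unique(t$model)) {
    sub <- t[t$model == m, ]
    sub <- sub[match(pupils, sub$pupil), ]
    out[[paste0(m, "_delta_va")]] <- sub$delta_va
    out[[paste0(m, "_code")]] <- sub$code
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference intermediate-to-near delta VA table
#'
#' The published bench-measured intermediate-to-near delta VA values
#' (logMAR) for the modelled sinusoidal trifocal lens, per pupil diameter
#' (rows, 1.5-5.5 mm) and prediction model (columns). Shipped as plain-text
#' data for exercising the classification rules on real printed values.
#'
#' @return data.frame with column `pupil_mm` and one column per model.
#' @export
reference_delta_va <- function() {
  path <- system.file("extdata", "reference_delta_va.csv",
                      package = "iolbench", mustWork = TRUE)
  utils::read.csv(path)
}
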