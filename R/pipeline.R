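# End-to-end orchestration: calibrate -> sweep -> metrics -> predict ->
# classify, with config serialization and the exchange CSV/plot outputs.

#' Build a pipeline run configuration
#'
#' A complete, serializable description of a run: the lens (or the
#' calibration target it is fitted to), the model-eye configuration, the
#' plane-conversion parameters, the model selection and the classification
#' threshold. Identical configurations yield identical outputs; the only
#' optimizer involved (profile calibration) starts from a fixed point, so
#' the `seed` is recorded for provenance but nothing in the pipeline draws
#' random numbers.
#'
#' @param lens A [diffractive_lens()], or `NULL` to calibrate one from
#'   `target_split`.
#' @param target_split Far/intermediate/near split for [calibrate_lens()]
#'   when `lens` is `NULL`.
#' @param eye A [model_eye()].
#' @param plane A [plane_conversion()].
#' @param models Character vector of model names (default: all).
#' @param dofi_threshold 0.2 (default) or 0.3 logMAR.
#' @param seed Integer recorded in the provenance block.
#' @return An object of class `run_config`.
#' @export
run_config <- function(lens = NULL,
                       target_split = c(0.43, 0.21, 0.36),
                       eye = model_eye(),
                       plane = plane_conversion("bench"),
                       models = names(va_models()),
                       dofi_threshold = 0.2,
                       seed = 1L) {
  if (!dofi_threshold %in% c(0.2, 0.3))
    stop("dofi_threshold must be 0.2 or 0.3 logMAR")
  structure(list(lens = lens, target_split = target_split, eye = eye,
                 plane = plane, models = models,
                 dofi_threshold = dofi_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror [run_config()]; nested blocks `lens`, `eye` and `plane`
#' are passed to the respective constructors. Missing fields fall back to
#' the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  lens <- if (!is.null(x$lens))
    do.call(diffractive_lens, c(x$lens[setdiff(names(x$lens), "harmonics")],
      list(harmonics = as.data.frame(x$lens$harmonics))))
  eye <- if (is.null(x$eye)) model_eye() else do.call(model_eye, x$eye)
  plane <- if (is.null(x$plane)) plane_conversion("bench")
  else do.call(plane_conversion, x$plane)
  run_config(lens = lens,
             target_split = x$target_split %||% c(0.43, 0.21, 0.36),
             eye = eye, plane = plane,
             models = x$models %||% names(va_models()),
             dofi_threshold = x$dofi_threshold %||% 0.2,
             seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable fingerprint of a config for the provenance block
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(rapply(unclass(config), function(x) signif(x, 12),
                 classes = c("numeric", "integer"), how = "replace"),
          tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full virtual-bench pipeline
#'
#' Calibrates (or takes) the lens, sweeps through-focus MTFa for every
#' configured pupil and wavelength, predicts visual-acuity defocus curves
#' for the selected models, classifies each (pupil, model) cell, and, if an
#' output directory is given, writes the through-focus MTFa CSV, the VADC
#' CSV, the classification matrix CSV and a per-pupil defocus-curve plot.
#'
#' Instead of simulating, externally measured bench data can be supplied
#' via `input_mtfa_csv`; downstream behaviour is identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param input_mtfa_csv Optional path to a through-focus MTFa CSV in the
#'   [write_mtfa_csv()] dialect, skipping the simulation stage.
#' @param verbose Progress messages.
#' @return A list of class `run_report`: the lens, the through-focus tables,
#'   the `iol_classification`, output paths and a provenance block.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         input_mtfa_csv = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(s, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", s, conditionMessage(e)), call. = FALSE))
  }
  lens <- stage("lens", {
    if (is.null(config$lens)) calibrate_lens(config$target_split)
    else { validate_lens(config$lens); config$lens }
  })
  if (is.null(input_mtfa_csv)) {
    sweep <- stage("bench", through_focus_sweep(lens, config$eye,
                                                verbose = verbose))
    tfs <- stage("metrics", lapply(config$eye$pupil_diameters, function(p)
      assemble_through_focus(sweep, p)))
  } else {
    tfs <- stage("io", read_mtfa_csv(input_mtfa_csv))
  }
  models <- stage("models", va_models(config$models))
  cls <- stage("classify", classify_iol(tfs, models, plane = config$plane,
                                        dofi_threshold = config$dofi_threshold))
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$mtfa <- file.path(out_dir, "through_focus_mtfa.csv")
    stage("io", write_mtfa_csv(tfs, paths$mtfa))
    paths$vadc <- file.path(out_dir, "vadc.csv")
    stage("io", write_vadc_csv(cls, paths$vadc))
    paths$classification <- file.path(out_dir, "classification.csv")
    stage("io", write_classification_csv(cls, paths$classification))
    paths$plot <- file.path(out_dir, "vadc.png")
    stage("plot", {
      grDevices::png(paths$plot, width = 1600, height = 1200, res = 150)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_vadc_panel(cls)
    })
  }
  structure(list(lens = lens, through_focus = tfs, classification = cls,
                 paths = paths,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   package_version =
                                     as.character(utils::packageVersion("iolbench")),
                                   r_version = R.version.string)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Virtual-bench run report\n")
  print(x$lens)
  print(x$classification)
  cat(sprintf("provenance: config %s | seed %d | iolbench %s\n",
              x$provenance$config_hash, x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}

# long-format VADC CSV: pupil_mm, model, defocus_spectacle_D, va_logmar
write_vadc_csv <- function(cls, path) {
  rows <- lapply(names(cls$vadc), function(k) {
    vc <- cls$vadc[[k]]
    data.frame(pupil_mm = attr(vc, "pupil"), model = attr(vc, "model_name"),
               defocus_spectacle_D = vc$defocus, va_logmar = vc$va)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Panel plot of predicted defocus curves
#'
#' One panel per pupil diameter, all prediction models overlaid, acuity axis
#' inverted (better vision up) with the 0.2 logMAR threshold marked.
#'
#' @param cls An `iol_classification`.
#' @param pupils Subset of pupils to draw (default: all).
#' @export
plot_vadc_panel <- function(cls, pupils = NULL) {
  t <- cls$table
  all_p <- sort(unique(t$pupil))
  if (is.null(pupils)) pupils <- all_p
  models <- unique(t$model)
  nc <- ceiling(sqrt(length(pupils)))
  nr <- ceiling(length(pupils) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(models), "Dark 3")
  ylim <- rev(range(vapply(cls$vadc, function(v) range(v$va),
                           numeric(2))))
  for (p in pupils) {
    first <- TRUE
    for (i in seq_along(models)) {
      vc <- cls$vadc[[sprintf("%g|%s", p, models[i])]]
      if (is.null(vc)) next
      if (first) {
        graphics::plot(vc$defocus, vc$va, type = "l", col = cols[i],
                       ylim = ylim, xlab = "Defocus (D, spectacle)",
                       ylab = "VA (logMAR)",
                       main = sprintf("pupil %.1f mm", p))
        first <- FALSE
      } else graphics::lines(vc$defocus, vc$va, col = cols[i])
    }
    graphics::abline(h = cls$dofi_threshold, lty = 3)
  }
  graphics::legend("bottomleft", legend = models, col = cols, lty = 1,
                   cex = 0.6, bty = "n")
  invisible(cls)
}
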