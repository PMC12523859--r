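# Registry of empirical MTFa -> visual acuity (logMAR) prediction models.
#
# Each model is a named closed-form function of the MTF area with a handful
# of coefficients. Four functional forms occur in the literature:
#   exponential_decay     VA = a * exp(-MTFa / b) + c
#   linear                VA = intercept + slope * MTFa
#   inverse_power         VA = a / MTFa + b      (MTFa raised to the -1)
#   inverse_proportional  VA = a / MTFa + b
# Models built under monochromatic green light take the 550 nm MTFa column;
# models built under polychromatic light take the photopically weighted
# column. An optional floor clamps the prediction (a ceiling effect on
# acuity: studies that never recorded acuities better than 0.0 logMAR
# produce models that cannot predict below it).

#' Load the visual-acuity prediction model registry
#'
#' Reads the model registry shipped with the package (or a user-supplied
#' file in the same JSON dialect) and returns the models as validated
#' `va_model` objects. The shipped coefficients are synthetic
#' representative values (see the file's own comment and the methods
#' vignette); the forms, light types and prediction scopes follow the
#' published models.
#'
#' @param names Optional character vector selecting a subset (in registry
#'   order) by name.
#' @param path Optional path to an alternative registry JSON.
#' @return Named list of `va_model` objects.
#' @export
#' @examples
#' names(va_models())
#' predict_va(va_model("alarcon2016"), 20)
va_models <- function(names = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "va_models_synthetic.json",
                        package = "iolbench", mustWork = TRUE)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)$models
  reg_names <- base::names(reg)
  out <- lapply(seq_along(reg), function(i) {
    m <- reg[[i]]
    new_va_model(name = reg_names[i], label = m$label, form = m$form,
                 coefficients = m$coefficients,
                 light_type = m$light_type,
                 prediction_scope = m$prediction_scope,
                 va_floor = if (is.null(m$va_floor)) NULL else m$va_floor)
  })
  names(out) <- reg_names
  if (!is.null(names)) {
    miss <- setdiff(names, base::names(out))
    if (length(miss))
      stop(sprintf("unknown model(s): %s", paste(miss, collapse = ", ")))
    out <- out[names]
  }
  out
}

#' @rdname va_models
#' @param name Single model name, e.g. `"vega2018"`.
#' @export
va_model <- function(name, path = NULL) va_models(name, path)[[1]]

new_va_model <- function(name, label, form, coefficients, light_type,
                         prediction_scope, va_floor = NULL) {
  form <- match.arg(form, c("exponential_decay", "linear", "inverse_power",
                            "inverse_proportional"))
  co <- as.list(coefficients)
  if (!all(vapply(co, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("model coefficients must be finite numbers")
  m <- structure(list(name = name, label = label, form = form,
                      coefficients = co,
                      light_type = match.arg(light_type,
                                             c("monochromatic", "polychromatic")),
                      prediction_scope = match.arg(prediction_scope,
                                                   c("monocular", "binocular")),
                      va_floor = va_floor),
                 class = "va_model")
  # predicted VA must be nonincreasing in MTFa on (0, 50]
  g <- seq(0.5, 50, by = 0.5)
  v <- predict_va(m, g)
  if (any(diff(v) > 1e-12))
    stop(sprintf("model %s is not nonincreasing in MTFa", name))
  m
}

#' @export
print.va_model <- function(x, ...) {
  eq <- switch(x$form,
    exponential_decay = sprintf("%g * exp(-MTFa / %g) + %g",
                                x$coefficients$a, x$coefficients$b,
                                x$coefficients$c),
    linear = sprintf("%g + %g * MTFa", x$coefficients$intercept,
                     x$coefficients$slope),
    inverse_power = ,
    inverse_proportional = sprintf("%g / MTFa + %g", x$coefficients$a,
                                   x$coefficients$b))
  cat(sprintf("%s: VA(logMAR) = %s  [%s, %s%s]\n", x$label, eq,
              x$light_type, x$prediction_scope,
              if (!is.null(x$va_floor))
                sprintf(", floor %.2f logMAR", x$va_floor) else ""))
  invisible(x)
}

#' Predict visual acuity from MTFa
#'
#' Evaluates a prediction model's closed form at the given MTF-area values
#' and applies the model's floor clamp if it has one.
#'
#' @param model A `va_model`.
#' @param mtfa MTF-area value(s), >= 0 (strictly positive for the inverse
#'   forms).
#' @return Predicted visual acuity in logMAR (vectorized over `mtfa`).
#' @export
predict_va <- function(model, mtfa) {
  stopifnot(inherits(model, "va_model"))
  if (any(mtfa < 0)) stop("mtfa must be >= 0")
  co <- model$coefficients
  va <- switch(model$form,
    exponential_decay = co$a * exp(-mtfa / co$b) + co$c,
    linear = co$intercept + co$slope * mtfa,
    inverse_power = ,
    inverse_proportional = {
      if (any(mtfa == 0))
        stop(sprintf("MTFa = 0 is singular for the %s form", model$form))
      co$a / mtfa + co$b
    })
  if (!is.null(model$va_floor)) va <- pmax(va, model$va_floor)
  va
}

#' @export
predict.va_model <- function(object, newdata, ...) predict_va(object, newdata)

#' Predict a visual-acuity defocus curve
#'
#' Applies a prediction model element-wise to a through-focus MTFa table and
#' attaches the spectacle-plane defocus axis obtained by paraxial vergence
#' conversion of the IOL-plane grid (clinical defocus curves are measured
#' with trial lenses at the spectacle plane, so predicted curves must be
#' expressed on that axis before functional classification).
#'
#' @param model A `va_model`.
#' @param tf A `through_focus_mtfa`.
#' @param plane A [plane_conversion()] parameter set (default: the bench
#'   cornea preset).
#' @param input Which MTFa column to feed the model: `"auto"` (550 nm for
#'   monochromatic models, the weighted column for polychromatic models; the
#'   default), `"mono550"`, or `"poly"`.
#' @return A data.frame of class `vadc` with columns `defocus` (D, spectacle
#'   plane), `va` (logMAR); attributes `pupil`, `model_name`,
#'   `defocus_iol`.
#' @export
predict_vadc <- function(model, tf, plane = plane_conversion("bench"),
                         input = c("auto", "mono550", "poly")) {
  stopifnot(inherits(model, "va_model"), inherits(tf, "through_focus_mtfa"))
  input <- match.arg(input)
  use_mono <- switch(input, auto = model$light_type == "monochromatic",
                     mono550 = TRUE, poly = FALSE)
  col <- if (use_mono) "mtfa_550" else "mtfa_poly"
  if (is.null(tf[[col]]))
    stop(sprintf("through-focus table lacks required column `%s`", col))
  d_spec <- iol_to_spectacle_defocus(tf$defocus, plane)
  structure(data.frame(defocus = d_spec, va = predict_va(model, tf[[col]])),
            class = c("vadc", "data.frame"),
            pupil = attr(tf, "pupil"), model_name = model$name,
            defocus_iol = tf$defocus)
}

#' @export
plot.vadc <- function(x, ..., main = NULL) {
  if (is.null(main))
    main <- sprintf("%s, pupil %.1f mm", attr(x, "model_name"),
                    attr(x, "pupil"))
  graphics::plot(x$defocus, x$va, type = "l", xlab = "Defocus (D, spectacle plane)",
                 ylab = "Predicted VA (logMAR)", ylim = rev(range(x$va)),
                 main = main, ...)
  graphics::abline(h = 0.2, lty = 3)
  invisible(x)
}
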