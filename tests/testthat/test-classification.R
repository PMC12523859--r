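# Spectacle-plane conversion, depth-of-field, intermediate-to-near delta VA
# and the category rules.

test_that("plane conversion matches an independent vergence-chase oracle", {
  plane <- plane_conversion("bench")
  expect_equal(iol_to_spectacle_defocus(0, plane), 0)
  # oracle built separately from the implementation: explicit two-surface
  # paraxial chain (12 mm vertex in air, 27.8 D cornea, 4 mm aqueous of
  # index 1.336), inverted by bisection at transcription time
  expect_equal(iol_to_spectacle_defocus(3.6, plane), 2.89207599,
               tolerance = 1e-6)
  expect_equal(iol_to_spectacle_defocus(-4.0, plane), -3.54371108,
               tolerance = 1e-6)
  expect_equal(iol_to_spectacle_defocus(-1.8, plane), -1.54859352,
               tolerance = 1e-6)
  # monotonicity: grid ordering is preserved
  g <- seq(1, -4, by = -0.1)
  cg <- iol_to_spectacle_defocus(g, plane)
  expect_true(all(diff(cg) < 0))
  # physiological preset compresses more (higher-power cornea)
  phys <- plane_conversion("physiological")
  expect_lt(abs(iol_to_spectacle_defocus(-3.6, phys)),
            abs(iol_to_spectacle_defocus(-3.6, plane)))
  expect_error(iol_to_spectacle_defocus(25, plane), "paraxial")
  expect_error(plane_conversion(spectacle_vertex_distance = -1), "positive")
})

test_that("dofi walks from 0 D to the interpolated threshold crossing", {
  # hand interpolation: VA 0.10 at -2.0 and 0.30 at -2.5 crosses 0.2 at -2.25
  vc <- synthetic_vadc(c(1, -2.0, -2.5, -4), c(0.0, 0.10, 0.30, 0.40))
  d <- dofi(vc)
  expect_equal(as.numeric(d), 2.25, tolerance = 1e-12)
  expect_false(attr(d, "grid_bounded"))
  # flat curve never crosses: grid extent with the bounded flag
  flat <- synthetic_vadc(c(1, -4), c(0, 0))
  df <- dofi(flat)
  expect_equal(as.numeric(df), 4)
  expect_true(attr(df, "grid_bounded"))
  # threshold strictness: dofi at 0.2 <= dofi at 0.3
  expect_lte(as.numeric(dofi(vc, 0.2)), as.numeric(dofi(vc, 0.3)))
  # far vision failing the threshold is a precondition error
  bad <- synthetic_vadc(c(1, -4), c(0.5, 0.5))
  expect_error(dofi(bad), "far vision fails")
})

test_that("dofi first/last crossing options differ on re-entrant curves", {
  # multifocal curve leaves and re-enters the threshold band
  vc <- synthetic_vadc(c(1, 0, -1, -1.5, -2.5, -3, -4),
                       c(0.05, 0.02, 0.25, 0.25, 0.05, 0.25, 0.5))
  first <- dofi(vc, crossing = "first")
  last <- dofi(vc, crossing = "last")
  expect_lt(as.numeric(first), 1)
  expect_gt(as.numeric(last), 2.5)
})

test_that("delta_va recovers planted dip/peak differences exactly", {
  # planted: intermediate dip 0.15 at -1.5, near best 0.03 at -2.8
  vc <- synthetic_vadc(c(1, 0, -1.5, -2.2, -2.8, -4),
                       c(0.0, 0.0, 0.15, 0.08, 0.03, 0.4))
  dv <- delta_va(vc)
  expect_equal(as.numeric(dv), 0.12, tolerance = 1e-12)
  expect_equal(attr(dv, "intermediate"), -1.5)
  expect_equal(attr(dv, "near"), -2.8)
  # invariance to adding a constant to the whole curve
  vc2 <- vc; vc2$va <- vc2$va + 0.07
  expect_equal(as.numeric(delta_va(vc2)), 0.12, tolerance = 1e-12)
  # random planted cases under a fixed seed
  set.seed(42)
  for (i in 1:25) {
    dip <- runif(1, 0.05, 0.4); gain <- runif(1, 0, 0.3)
    peak <- dip - gain
    vc3 <- synthetic_vadc(c(1, 0, -1.2, -3.0, -4),
                          c(0, 0, dip, peak, peak + 0.5))
    expect_equal(as.numeric(delta_va(vc3)), gain, tolerance = 1e-12)
  }
})

test_that("delta_va clamps at zero and enforces coverage", {
  # monotonically worsening curve: near never improves on the dip
  mono <- synthetic_vadc(c(1, 0, -4), c(-0.1, 0, 0.6))
  expect_equal(as.numeric(delta_va(mono)), 0)
  # equal dip and peak
  eq <- synthetic_vadc(c(1, 0, -1.5, -2.8, -4), c(0, 0, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(delta_va(eq)), 0)
  short <- synthetic_vadc(c(1, -1), c(0, 0.1), grid = seq(1, -1, by = -0.1))
  expect_error(delta_va(short), "coverage")
  # spectacle-converted grids end short of -4 D: clipped, not an error
  clipped <- synthetic_vadc(c(1, 0, -1.5, -2.8, -3.5),
                            c(0, 0, 0.15, 0.03, 0.2),
                            grid = seq(1, -3.5, by = -0.1))
  dv <- delta_va(clipped)
  expect_true(attr(dv, "near_window_clipped"))
  expect_equal(as.numeric(dv), 0.12, tolerance = 1e-12)
})

test_that("classification honors the published band boundaries exactly", {
  expect_equal(as.character(classify(3.0, 0.12)$category), "Full_Smooth")
  expect_equal(as.character(classify(3.0, 0.17)$category), "Full_Steep")
  expect_equal(as.character(classify(2.0, 0.30)$category), "Partial")
  # boundaries: 0.05 -> Smooth (inclusive), 0.14 -> Steep (inclusive)
  expect_equal(as.character(classify(3.0, 0.05)$category), "Full_Smooth")
  expect_equal(as.character(classify(3.0, 0.14)$category), "Full_Steep")
  expect_equal(as.character(classify(3.0, 0.0499999)$category),
               "Full_Continuous")
  expect_equal(as.character(classify(3.0, 0.1399999)$category), "Full_Smooth")
  # DOFi cut at 2.3 D: below is Partial regardless of delta
  expect_equal(as.character(classify(2.2999, 0.2)$category), "Partial")
  expect_equal(as.character(classify(2.3, 0.2)$category), "Full_Steep")
  expect_equal(classify(2.3, 0.2)$code, "c")
  expect_error(classify(-1, 0.1), ">= 0")
})

test_that("classification partitions the (dofi, delta) plane totally", {
  set.seed(7)
  for (i in 1:100) {
    d <- runif(1, 0, 4); dv <- runif(1, 0, 0.3)
    cl <- classify(d, dv)
    expect_true(as.character(cl$category) %in%
                  c("Partial", "Full_Continuous", "Full_Smooth", "Full_Steep"))
    if (d < 2.3) expect_equal(as.character(cl$category), "Partial")
    else if (dv >= 0.14) expect_equal(as.character(cl$category), "Full_Steep")
  }
})

test_that("classify_iol builds the full pupil-by-model matrix", {
  grid <- seq(1, -4, by = -0.1)
  mk_tf <- function(pupil, base) {
    # synthetic trifocal-like through-focus MTFa with far/int/near humps
    m <- base + 14 * exp(-((grid - 0)^2) / 0.18) +
      7 * exp(-((grid + 1.8)^2) / 0.18) + 10 * exp(-((grid + 3.6)^2) / 0.18)
    structure(data.frame(defocus = grid, mtfa_550 = m, mtfa_poly = m * 0.95),
              class = c("through_focus_mtfa", "data.frame"), pupil = pupil)
  }
  tfs <- list(mk_tf(2, 6), mk_tf(3, 5))
  cls <- classify_iol(tfs, va_models(c("vega2018", "alarcon2016")))
  expect_s3_class(cls, "iol_classification")
  expect_equal(nrow(cls$table), 4)
  expect_setequal(unique(cls$table$model), c("vega2018", "alarcon2016"))
  expect_true(all(cls$table$delta_va >= 0))
  expect_true(all(cls$table$dofi > 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_classification_csv(cls, path)
  out <- utils::read.csv(path)
  expect_equal(out$pupil_mm, c(2, 3))
  expect_true("vega2018_code" %in% names(out))
})
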