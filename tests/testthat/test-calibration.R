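test_that("calibration fit recovers exact and noisy lines (OLS oracle)", {
  # exact line through the origin
  cc <- fitCalibration(exactStandards(), "d3-NAD+")
  expect_s4_class(cc, "CalibrationCurve")
  expect_equal(slope(cc), 100)
  expect_equal(intercept(cc), 0)
  expect_equal(rSquared(cc), 1)
  expect_equal(validRange(cc), c(0, 5))

  # scattered standards: expected values frozen from the normal equations
  # worked by hand (n = 4, Sx = 15, Sy = 1510, Sxy = 8585, Sxx = 85):
  # slope = (4*8585 - 15*1510) / (4*85 - 225) = 11690 / 115
  std <- data.frame(analyte = "d3-Nam", amount_pmol = c(1, 2, 4, 8),
    peak_area = c(95, 205, 400, 810))
  cc2 <- fitCalibration(std, "d3-Nam", minRSquared = 0.99)
  expect_equal(slope(cc2), 11690 / 115, tolerance = 1e-12)
  expect_equal(intercept(cc2), (1510 - (11690 / 115) * 15) / 4,
    tolerance = 1e-12)
  expect_gt(rSquared(cc2), 0.999)
})

test_that("degenerate or failed calibrations error out", {
  flat <- data.frame(analyte = "d0-Nam", amount_pmol = c(1, 1, 1),
    peak_area = c(100, 100, 100))
  expect_error(fitCalibration(flat, "d0-Nam"), "degenerate")
  expect_error(fitCalibration(exactStandards()[1:2, ], "d3-NAD+"),
    ">= 3 standards")
  down <- data.frame(analyte = "d0-Nam", amount_pmol = c(0, 1, 2),
    peak_area = c(200, 100, 0))
  expect_error(fitCalibration(down, "d0-Nam"), "non-positive")
  # poor linearity is refused unless forced
  bent <- data.frame(analyte = "d4-Nam", amount_pmol = c(0, 1, 2, 4),
    peak_area = c(0, 100, 120, 130))
  expect_error(fitCalibration(bent, "d4-Nam"), "R\\^2")
  expect_s4_class(fitCalibration(bent, "d4-Nam", force = TRUE),
    "CalibrationCurve")
})

test_that("per-analyte LOQ configuration falls back to the conservative 0.4 pmol", {
  cc <- fitCalibration(exactStandards(), "d3-NAD+")
  expect_equal(loq(cc), 0.4)
  cc2 <- fitCalibration(exactStandards(), "d3-NAD+",
    loqDefaults = list(`d3-NAD+` = 0.1))
  expect_equal(loq(cc2), 0.1)
  cc3 <- fitCalibration(exactStandards(), "d3-NAD+", loq = 0.25)
  expect_equal(loq(cc3), 0.25)
})

test_that("peak quantification inverts the line and sets flags, never clips silently", {
  cc <- fitCalibration(exactStandards(), "d3-NAD+")
  q <- quantifyPeak(cc, 250)
  expect_equal(q$amount_pmol, 2.5)
  expect_false(q$below_loq)
  expect_false(q$out_of_range)

  # below the limit of quantification: value kept, flag set
  q2 <- quantifyPeak(cc, 20)
  expect_equal(q2$amount_pmol, 0.2)
  expect_true(q2$below_loq)

  # area equal to the intercept -> zero amount, flagged
  q3 <- quantifyPeak(cc, 0)
  expect_equal(q3$amount_pmol, 0)
  expect_true(q3$below_loq)

  q4 <- quantifyPeak(cc, 1e4)
  expect_true(q4$out_of_range)
  expect_error(quantifyPeak(cc, -1), "non-negative")
})

test_that("round-trip and monotonicity hold across generated curves", {
  set.seed(11)
  for (i in 1:20) {
    sl <- runif(1, 10, 500)
    ic <- runif(1, 0, 50)
    amounts <- sort(runif(5, 0, 10))
    std <- data.frame(analyte = "d0-NAD+", amount_pmol = amounts,
      peak_area = ic + sl * amounts)
    cc <- fitCalibration(std, "d0-NAD+")
    x <- seq(min(amounts), max(amounts), length.out = 7)
    back <- quantifyPeak(cc, ic + sl * x)$amount_pmol
    expect_equal(back, x, tolerance = 1e-9)
    areas <- sort(runif(6, 0, ic + sl * 10))
    expect_false(is.unsorted(quantifyPeak(cc, areas)$amount_pmol))
  }
})

test_that("labeling table normalizes per 10^6 cells and routes compartments", {
  curves <- syntheticCurves()
  # cellular d3-NAD+ of 111.5 pmol at 4.04e5 cells -> 276 pmol/10^6 cells
  pk <- data.frame(
    sample_id = "s1", time_h = 3,
    compartment = c("cells", "cells", "medium"),
    analyte = c("d3-NAD+", "d0-NAD+", "d4-Nam"),
    peak_area = c(slope(curves[["d3-NAD+"]]) * 111.5,
      slope(curves[["d0-NAD+"]]) * 476.3,
      slope(curves[["d4-Nam"]]) * 1813))
  lab <- buildLabelingTable(pk, curves, refContext())
  expect_equal(lab$cell_d3_nad, 111.5 / 0.404, tolerance = 1e-9)
  expect_equal(lab$cell_d0_nad, 476.3 / 0.404, tolerance = 1e-9)
  expect_equal(lab$medium_d4_nam, 1813 / 0.404, tolerance = 1e-9)
  # unmeasured analytes stay absent, not zero
  expect_true(is.na(lab$medium_d3_nam))

  # identity normalization at 10^6 cells
  ctx1 <- cellContext(1e6, 2.5)
  pk1 <- pk[1, ]
  pk1$peak_area <- slope(curves[["d3-NAD+"]]) * 276
  expect_equal(buildLabelingTable(pk1, curves, ctx1)$cell_d3_nad, 276)
})

test_that("labeling table rejects unknown analytes, duplicates, wrong compartments", {
  curves <- syntheticCurves()
  bad <- data.frame(sample_id = "s1", time_h = 3, compartment = "cells",
    analyte = "d2-NAD+", peak_area = 100)
  expect_error(buildLabelingTable(bad, curves, refContext()),
    "unknown analyte")
  dup <- data.frame(sample_id = "s1", time_h = 3, compartment = "cells",
    analyte = rep("d3-NAD+", 2), peak_area = c(100, 120))
  expect_error(buildLabelingTable(dup, curves, refContext()), "duplicate")
  wrongc <- data.frame(sample_id = "s1", time_h = 3, compartment = "medium",
    analyte = "d3-NAD+", peak_area = 100)
  expect_error(buildLabelingTable(wrongc, curves, refContext()),
    "compartment")
})

test_that("quantified-amounts CSV round-trips through the documented header", {
  ds <- generateDataset(refParams(seed = 5L), times = c(0, 3))
  lab <- buildLabelingTable(ds$peak_table, ds$curves, refContext())
  path <- withr::local_tempfile(fileext = ".csv")
  long <- writeQuantifiedTable(lab, path)
  back <- utils::read.csv(path)
  expect_named(back, c("sample_id", "time_h", "compartment", "analyte",
    "amount_pmol_per_1e6cells", "below_loq", "out_of_range"))
  expect_equal(nrow(back), nrow(long))
  d3 <- back[back$analyte == "d3-NAD+" & back$time_h == 3, ]
  expect_equal(d3$amount_pmol_per_1e6cells,
    lab$cell_d3_nad[lab$time_h == 3], tolerance = 1e-6)
})
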