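test_that("rate definitions reproduce the worked HepG2 example", {
  expect_equal(computeRs(276, 3), 92)
  expect_equal(computeRb(258, 3), 86)
  expect_equal(totalNad(276, 1179), 1455)
  expect_equal(computeRs(0, 3), 0)
  expect_equal(computeRs(45, 1.5), 30)
  expect_equal(computeRb(129, 1.5), 86)
  expect_error(computeRs(10, 0), "time")
  expect_error(computeRs(-1, 3), "vanish")
})

test_that("volume normalization is the exact pmol/10^6 cells -> uM identity", {
  expect_equal(amountToConcentration(500, 1), 500)
  expect_equal(amountToConcentration(1455, 2.5), 582)
  expect_equal(amountToConcentration(0, 3), 0)
  expect_error(amountToConcentration(100, 0), "volume")
  # normalization and rate-taking commute
  a <- 276; t <- 3; v <- 2.5
  expect_equal(amountToConcentration(computeRs(a, t), v),
    computeRs(amountToConcentration(a, v), t))
})

test_that("first-order half-life matches the printed turnover range and scales right", {
  expect_equal(halfLife(500, 30), log(2) * 500 / 30)
  expect_equal(halfLife(500, 30), 11.55, tolerance = 1e-3)
  expect_equal(halfLife(800, 60), 9.24, tolerance = 1e-3)
  expect_equal(halfLife(100, log(2) * 100), 1)
  # scale invariance: common rescaling of pool and rate leaves t1/2 alone
  for (k in c(0.1, 2.5, 40)) {
    expect_equal(halfLife(k * 500, k * 30), halfLife(500, 30))
  }
  expect_warning(hl0 <- halfLife(500, 0), "undefined")
  expect_true(is.na(hl0))
})

test_that("fold changes reproduce the induction arithmetic", {
  expect_equal(foldChange(800, 500), 1.6)
  expect_equal(foldChange(600, 100), 6)
  expect_equal(foldChange(7, 7), 1)
  expect_error(foldChange(1, 0), "baseline")
})

test_that("two-point estimation reproduces the worked example end to end", {
  fr <- estimateFluxes(wt0(), wt3(), refContext())
  expect_s4_class(fr, "FluxResult")
  expect_equal(rS(fr), 92)
  expect_equal(rB(fr), 86)
  expect_equal(fr@totalNad, 1455)
  expect_equal(nadConc(fr), 582)
  expect_equal(fr@rSConc, 36.8)
  expect_equal(fr@rBConc, 34.4)
  expect_equal(nadHalfLife(fr), log(2) * 582 / 34.4)
  # the printed 3-h medium composition passes the recycling gate
  expect_true(isValid(fr))
})

test_that("degenerate two-point inputs behave as documented", {
  # no change -> zero rates, conservation of the bookkeeping
  same <- labelingTimepoint(3, cellD3Nad = 0, cellD0Nad = 1437)
  fr <- estimateFluxes(wt0(), same, refContext())
  expect_equal(rS(fr), 0)
  expect_equal(rB(fr), 0)
  expect_equal(fr@totalNad, totalNad(0, 1437))
  expect_true(is.na(nadHalfLife(fr)))

  # steady state: a = b keeps total NAD+ unchanged
  tN <- labelingTimepoint(3, cellD3Nad = 100, cellD0Nad = 1337)
  frSS <- estimateFluxes(wt0(), tN, refContext())
  expect_equal(frSS@totalNad, totalNad(0, 1437))

  # noisy d0 increase: clamped with a flag, never an error
  up <- labelingTimepoint(3, cellD3Nad = 10, cellD0Nad = 1450)
  frUp <- estimateFluxes(wt0(), up, refContext())
  expect_equal(rB(frUp), 0)
  expect_false(isValid(frUp))
  expect_match(paste(frUp@flags, collapse = " "), "clamped")

  # labels cannot vanish
  down <- labelingTimepoint(3, cellD3Nad = 0, cellD0Nad = 1437)
  t0d3 <- labelingTimepoint(0, cellD3Nad = 5, cellD0Nad = 1437)
  expect_error(estimateFluxes(t0d3, down, refContext()), "vanish")
  expect_error(estimateFluxes(wt3(), wt0(), refContext()), "later")
})

test_that("negative observed breakdown is clamped with a warning", {
  expect_warning(rb <- computeRb(-5, 3), "clamped")
  expect_equal(rb, 0)
})

test_that("the multi-timepoint slope estimator matches the two-point one on a line", {
  times <- c(0, 3, 6, 9)
  d3 <- 92 * times
  d0 <- 1437 - 86 * times
  fit <- fluxSlope(times, d3, d0)
  expect_equal(fit$r_s, 92)
  expect_equal(fit$r_b, 86)
  expect_equal(fit$r_squared, 1)
})

test_that("fluxTable drives the estimator over a multi-sample labeling table", {
  curves <- syntheticCurves()
  p1 <- refParams(seed = 3L)
  d1 <- generateDataset(p1, times = c(0, 3), curves, sampleId = "a")
  d2 <- generateDataset(refParams(seed = 4L), c(0, 3), curves,
    sampleId = "b")
  peaks <- rbind(d1$peak_table, d2$peak_table)
  meta <- rbind(d1$metadata, d2$metadata)
  lab <- buildLabelingTable(peaks, curves, meta)
  flux <- fluxTable(lab, meta)
  expect_equal(flux$sample_id, c("a", "b"))
  expect_equal(flux$r_s_pmol_per_1e6cells_h, rep(92, 2), tolerance = 1e-6)
  expect_equal(flux$r_b_pmol_per_1e6cells_h, rep(86, 2), tolerance = 1e-6)
  expect_equal(flux$nad_conc_uM, rep(582, 2), tolerance = 1e-6)
  expect_true(all(flux$valid))

  path <- withr::local_tempfile(fileext = ".csv")
  writeFluxTable(flux, path)
  expect_named(utils::read.csv(path), names(flux))
})
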