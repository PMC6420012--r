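test_that("feedback Km anchors and limits hold", {
  expect_equal(kmEffective(0), 1)
  expect_equal(kmEffective(500), 25)
  # no feedback in the weak-inhibition limit
  expect_equal(kmEffective(500, km0 = 1, kiFeedback = 1e12), 1,
    tolerance = 1e-9)
  expect_error(kmEffective(-1), ">= 0")
})

test_that("synthesis flux saturates in substrate and respects the closed form", {
  p <- kineticParams(vmax = 100)
  expect_equal(synthesisFlux(2, 500, p), 100 * 2 / 27, tolerance = 1e-12)
  # half-max at S = Km_eff
  expect_equal(synthesisFlux(25, 500, p), 50)
  # saturation
  expect_equal(synthesisFlux(1e9, 500, p), 100, tolerance = 1e-6)
  expect_equal(synthesisFlux(0, 500, p), 0)
})

test_that("nicotinamide-moiety mass is conserved on every run", {
  grid <- list(
    refParams(),
    refParams(recycling = FALSE),
    refParams(vmax = 100, kB = 0.2, namMedium0 = 10),
    refParams(kiFeedback = 1e12, namMedium0 = 0.5, namD0Residual = 0.3),
    refParams(isotopeEffect = 0.8)
  )
  for (p in grid) {
    traj <- simulateLabeling(p, times = seq(0, 12, by = 1))
    total <- traj$med_d4_nam + traj$med_d3_nam + traj$med_d0_nam +
      traj$cell_d0_nad + traj$cell_d3_nad
    expect_equal(total, rep(total[1], length(total)), tolerance = 1e-6)
    # non-negativity of every pool at every output
    expect_true(all(traj[, 2:6] >= 0))
  }
})

test_that("decoupled limits behave analytically", {
  # kB = 0 (and no d0-Nam carryover to feed unlabeled synthesis):
  # d0-NAD+ constant, d3-NAD+ grows at j_s
  p0 <- refParams(kB = 0, namD0Residual = 0)
  tr0 <- simulateLabeling(p0, times = c(0, 1, 2, 3))
  expect_equal(tr0$cell_d0_nad, rep(1437, 4), tolerance = 1e-8)
  expect_true(all(diff(tr0$cell_d3_nad) > 0))
  expect_equal(tr0$med_d3_nam, rep(0, 4), tolerance = 1e-8)

  # recycling off: d0-NAD+ decays exponentially regardless of synthesis
  p <- refParams(recycling = FALSE)
  tr <- simulateLabeling(p, times = seq(0, 9, by = 1))
  expect_equal(tr$cell_d0_nad, 1437 * exp(-p@kB * tr$time_h),
    tolerance = 1e-6)
})

test_that("a steady-state run holds total NAD+ constant", {
  # clamp the medium by making the reservoir enormous (no carryover, so
  # the substrate is exactly namMedium0), and start the pool at the
  # algebraic fixed point
  p <- refParams(mediumVolume = 1e4, namD0Residual = 0)
  ss <- steadyStateNad(p)
  pSS <- refParams(mediumVolume = 1e4, namD0Residual = 0,
    nad0 = ss$nad_conc)
  traj <- simulateLabeling(pSS, times = seq(0, 9, by = 1))
  total <- traj$cell_d0_nad + traj$cell_d3_nad
  expect_equal(total / total[1], rep(1, length(total)), tolerance = 1e-4)
  # and the label composition still turns over underneath
  expect_true(all(diff(traj$cell_d3_nad) > 0))
})

test_that("half-life is consistent between the simulator and the closed form", {
  p <- refParams(vmax = 0)
  thalf <- log(2) / p@kB
  traj <- simulateLabeling(p, times = c(0, thalf, 2 * thalf))
  total <- traj$cell_d0_nad + traj$cell_d3_nad
  expect_equal(total[2] / total[1], 0.5, tolerance = 1e-6)
  expect_equal(total[3] / total[1], 0.25, tolerance = 1e-6)
  c0 <- amountToConcentration(total[1], p@cellVolume)
  expect_equal(halfLife(c0, p@kB * c0), thalf, tolerance = 1e-12)
})

test_that("dataset generation is deterministic under a fixed seed", {
  p <- kineticParams(seed = 99L)
  d1 <- generateDataset(p, times = c(0, 3))
  d2 <- generateDataset(p, times = c(0, 3))
  expect_identical(d1$peak_table, d2$peak_table)
  expect_identical(d1$metadata, d2$metadata)
  d3 <- generateDataset(kineticParams(seed = 100L), times = c(0, 3))
  expect_false(identical(d1$peak_table, d3$peak_table))
})

test_that("noiseless generation reproduces the trajectory exactly", {
  p <- refParams()
  ds <- generateDataset(p, times = c(0, 3))
  lab <- buildLabelingTable(ds$peak_table, ds$curves, refContext())
  lab <- lab[order(lab$time_h), ]
  expect_equal(lab$cell_d3_nad, ds$truth$cell_d3_nad, tolerance = 1e-9)
  expect_equal(lab$cell_d0_nad, ds$truth$cell_d0_nad, tolerance = 1e-9)
  expect_equal(lab$medium_d4_nam, ds$truth$med_d4_nam, tolerance = 1e-9)
})

test_that("the noise model delivers the configured coefficient of variation", {
  p <- kineticParams(noiseCv = 0.05, seed = 7L)
  vals <- vapply(1:50, function(i) {
    pi <- p
    pi@seed <- as.integer(7L + i)
    ds <- generateDataset(pi, times = c(0, 3))
    pk <- ds$peak_table
    pk$peak_area[pk$analyte == "d3-NAD+" & pk$time_h == 3]
  }, numeric(1))
  cv <- stats::sd(vals) / mean(vals)
  expect_gte(cv, 0.035)
  expect_lte(cv, 0.065)
})

test_that("bias scan shows monotone underestimation of the gross fluxes", {
  bs <- biasScan(refParams(), times = c(1, 2, 3, 6, 9, 12, 18, 24))
  # label re-degradation and recycling both deepen the bias with time
  expect_true(all(diff(bs$bias_rs) < 0))
  expect_true(all(diff(bs$bias_rb) < 0))
  expect_true(all(bs$bias_rs < 0))
  # t -> 0: the finite difference converges on the gross flux
  bs0 <- biasScan(refParams(), times = c(0.01, 0.05))
  expect_equal(bs0$bias_rs[1], 0, tolerance = 2e-3)
  expect_equal(bs0$bias_rb[1], 0, tolerance = 2e-3)
  # recycling makes the synthesis-rate bias strictly worse
  bsOff <- biasScan(refParams(recycling = FALSE), times = c(3, 9, 24))
  bsOn <- biasScan(refParams(), times = c(3, 9, 24))
  expect_true(all(bsOn$bias_rs < bsOff$bias_rs))
})

test_that("induction raises the synthesis rate sublinearly with balanced breakdown", {
  p <- refParams()
  ind <- inductionScenario(p, 6)
  expect_gt(ind$rs_fold, 1)
  expect_lt(ind$rs_fold, 6)
  expect_equal(ind$rs_fold, ind$rb_fold)
  expect_gt(ind$nad_fold, 1)
  # identity at fold 1
  ind1 <- inductionScenario(p, 1)
  expect_equal(ind1$rs_fold, 1)
  expect_equal(ind1$nad_fold, 1)
  # no feedback and saturating Nam: synthesis scales with vmax
  pSat <- refParams(kiFeedback = 1e12, namMedium0 = 1e5)
  indSat <- inductionScenario(pSat, 6)
  expect_equal(indSat$rs_fold, 6, tolerance = 1e-6)
})

test_that("steady state solves the balance equation", {
  p <- refParams()
  ss <- steadyStateNad(p)
  lhs <- synthesisFlux(p@namMedium0, ss$nad_conc, p)
  expect_equal(lhs, p@kB * ss$nad_conc, tolerance = 1e-10)
  expect_equal(ss$r_s, ss$r_b)
})

test_that("parameter recovery through the full pipeline is exact without noise", {
  pr <- parameterRecovery(refParams(seed = 5L), nDatasets = 3)
  expect_equal(pr$summary$rel_err_r_s, 0, tolerance = 1e-9)
  expect_equal(pr$summary$rel_err_r_b, 0, tolerance = 1e-9)
  expect_equal(pr$truth$r_s, 92, tolerance = 1e-6)
  expect_equal(pr$truth$r_b, 86, tolerance = 1e-6)
})

test_that("simulator input validation catches malformed requests", {
  expect_error(simulateLabeling(refParams(), times = c(1, 3)), "start at 0")
  expect_error(simulateLabeling(refParams(), times = c(0, 3, 2)),
    "increasing")
  expect_error(kineticParams(vmax = -1), "vmax")
  expect_error(kineticParams(cellVolume = 0), "cellVolume")
})
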