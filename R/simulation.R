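#' Effective Nam Km under NAD+ feedback inhibition
#'
#' Nampt is feedback-inhibited by its distal product: intracellular NAD+
#' lowers the enzyme's affinity for nicotinamide. The model uses a
#' competitive-style linear inflation of the Michaelis constant,
#' `Km_eff = km0 * (1 + C / kiFeedback)`. With the default anchors
#' `km0 = 1` uM and `kiFeedback = 500/24` uM the effective Km rises from
#' 1 uM at zero NAD+ to 25 uM at the physiological 500 uM NAD+.
#'
#' @param nadConc Intracellular NAD+ concentration C, uM (>= 0).
#' @param km0 Km at zero NAD+, uM.
#' @param kiFeedback Feedback constant, uM.
#' @return Effective Km, uM.
#' @examples
#' kmEffective(0)    # 1
#' kmEffective(500)  # 25
#' @export
kmEffective <- function(nadConc, km0 = 1, kiFeedback = 500 / 24) {
  if (any(nadConc < 0) || any(km0 < 0) || any(kiFeedback <= 0))
    stop("concentrations must be >= 0 and kiFeedback > 0")
  km0 * (1 + nadConc / kiFeedback)
}

#' Instantaneous NAD+ synthesis flux
#'
#' Michaelis-Menten rate on the total accessible medium nicotinamide with
#' the feedback-inflated Km: `j_S = vmax * S / (Km_eff(C) + S)`. The total
#' flux is apportioned among the Nam isotopomers by their molar fractions
#' (the d4-Nam share additionally scaled by `isotopeEffect`); d4-Nam
#' consumption yields d3-NAD+ because one ring deuterium is lost on the
#' way into the dinucleotide.
#'
#' @param namTotal Total accessible Nam concentration S, uM.
#' @param nadConc Intracellular NAD+ concentration C, uM.
#' @param p A [KineticParams-class].
#' @return Total synthesis flux, uM/h (cell-volume basis).
#' @examples
#' p <- kineticParams(vmax = 100)
#' synthesisFlux(2, 500, p)  # 100 * 2 / 27
#' @export
synthesisFlux <- function(namTotal, nadConc, p) {
  stopifnot(methods::is(p, "KineticParams"))
  if (any(namTotal < 0) || any(nadConc < 0))
    stop("concentrations must be >= 0")
  km <- kmEffective(nadConc, p@km0, p@kiFeedback)
  ifelse(namTotal > 0, p@vmax * namTotal / (km + namTotal), 0)
}

# Unit helpers: the simulator integrates absolute pmol; callers see pmol
# per 10^6 cells.
.cellVolUl <- function(p) p@cellCount * p@cellVolume * 1e-6  # total, uL
.medVolUl <- function(p) p@mediumVolume * 1e3
.per1e6 <- function(p) 1e6 / p@cellCount

.derivs <- function(t, state, p) {
  medUl <- .medVolUl(p)
  cellUl <- .cellVolUl(p)
  n4 <- max(state[["n4"]], 0)
  n3 <- max(state[["n3"]], 0)
  n0 <- max(state[["n0"]], 0)
  d0 <- max(state[["d0"]], 0)
  d3 <- max(state[["d3"]], 0)

  cNad <- (d0 + d3) / cellUl
  s4 <- n4 / medUl
  s3 <- if (p@recycling) n3 / medUl else 0
  s0 <- if (p@recycling) n0 / medUl else 0
  sTot <- s4 + s3 + s0

  if (sTot > 0) {
    km <- kmEffective(cNad, p@km0, p@kiFeedback)
    jTotAbs <- p@vmax * cellUl * sTot / (km + sTot)  # pmol/h
    j4 <- jTotAbs * (s4 / sTot) * p@isotopeEffect
    j3 <- jTotAbs * (s3 / sTot)
    j0 <- jTotAbs * (s0 / sTot)
  } else {
    j4 <- j3 <- j0 <- 0
  }
  b3 <- p@kB * d3
  b0 <- p@kB * d0

  list(c(
    n4 = -j4,
    n3 = -j3 + b3,
    n0 = -j0 + b0,
    d0 = j0 - b0,
    d3 = j4 + j3 - b3,
    cumSyn = j4 + j3 + j0,
    cumBrk = b3 + b0
  ))
}

#' Simulate a d4-Nam labeling time course
#'
#' Deterministic ODE model of the salvage-pathway labeling experiment.
#' State: three medium nicotinamide pools (d4 precursor, d3 and d0 released
#' by NAD+ breakdown / carried over) and two cellular NAD+ pools (d0, d3).
#' Synthesis follows [synthesisFlux()]; breakdown is lumped first-order
#' (`kB`) on each NAD+ isotopologue and releases nicotinamide of matching
#' label into the medium. When `recycling` is off, released (and carryover)
#' d3-/d0-Nam accumulate in the medium but are excluded from the synthesis
#' substrate. Integration uses `deSolve::lsoda` with rtol 1e-8 / atol
#' 1e-10.
#'
#' Nicotinamide-moiety mass is conserved: the sum of all five pools (mole
#' basis across compartments) is constant over any run, since breakdown
#' returns the Nam moiety to the medium and the ADP-ribose half leaves the
#' balance.
#'
#' @param p A [KineticParams-class].
#' @param times Sorted output times, h, starting at 0 (the medium switch:
#'   d3 pools empty, d0-NAD+ at `nad0`).
#' @return data.frame ("trajectory") with columns `time_h`; medium
#'   `med_d4_nam`, `med_d3_nam`, `med_d0_nam` and cellular `cell_d0_nad`,
#'   `cell_d3_nad` (all pmol per 10^6 cells); instantaneous fluxes
#'   `j_s_uM_h`, `j_b_uM_h`; cumulative gross fluxes `cum_syn_pmol_1e6`,
#'   `cum_brk_pmol_1e6`; and `nam_depletion_frac` (fraction of the initial
#'   d4-Nam consumed). The parameters travel in `attr(, "params")`.
#' @examples
#' traj <- simulateLabeling(kineticParams(), times = c(0, 3, 6, 9))
#' traj$cell_d3_nad  # rises ~linearly; ~276 pmol/10^6 cells at 3 h
#' @export
simulateLabeling <- function(p, times = seq(0, 9, by = 0.25)) {
  stopifnot(methods::is(p, "KineticParams"))
  methods::validObject(p)
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0")
  medUl <- .medVolUl(p)
  cellUl <- .cellVolUl(p)
  y0 <- c(
    n4 = p@namMedium0 * medUl,
    n3 = 0,
    n0 = p@namD0Residual * medUl,
    d0 = p@nad0 * cellUl,
    d3 = 0,
    cumSyn = 0,
    cumBrk = 0
  )
  sol <- deSolve::lsoda(y0, times, .derivs, p, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; final state: ",
      paste(sprintf("%s=%.6g", colnames(sol), sol[nrow(sol), ]),
        collapse = ", "))
  sol <- as.data.frame(sol)
  if (min(sol$n4, sol$n3, sol$n0, sol$d0, sol$d3) < -1e-6 * sum(y0))
    stop("integrator produced a materially negative pool")

  f <- .per1e6(p)
  # instantaneous fluxes at the output times, uM/h (cell-volume basis)
  js <- jb <- numeric(nrow(sol))
  for (i in seq_len(nrow(sol))) {
    d <- .derivs(sol$time[i], unlist(sol[i, -1]), p)[[1]]
    js[i] <- d[["cumSyn"]] / cellUl
    jb[i] <- d[["cumBrk"]] / cellUl
  }
  out <- data.frame(
    time_h = sol$time,
    med_d4_nam = pmax(sol$n4, 0) * f,
    med_d3_nam = pmax(sol$n3, 0) * f,
    med_d0_nam = pmax(sol$n0, 0) * f,
    cell_d0_nad = pmax(sol$d0, 0) * f,
    cell_d3_nad = pmax(sol$d3, 0) * f,
    j_s_uM_h = js,
    j_b_uM_h = jb,
    cum_syn_pmol_1e6 = sol$cumSyn * f,
    cum_brk_pmol_1e6 = sol$cumBrk * f,
    nam_depletion_frac = if (y0[["n4"]] > 0) {
      (y0[["n4"]] - sol$n4) / y0[["n4"]]
    } else 0
  )
  attr(out, "params") <- p
  out
}

.SYNTH_CURVE_SLOPES <- c("d0-NAD+" = 120, "d3-NAD+" = 115, "d0-Nam" = 300,
  "d3-Nam" = 290, "d4-Nam" = 280)

#' Synthetic calibration standards and curves
#'
#' Convenience generators for exercising the full pipeline on simulated
#' data: per-analyte linear standards (distinct slopes, zero intercept)
#' spanning `maxAmount` pmol, and the curves fitted to them.
#'
#' @param maxAmount Upper end of the standard range, pmol (wide enough to
#'   cover whole-well absolute amounts).
#' @return `syntheticStandards`: data.frame of standards;
#'   `syntheticCurves`: named list of [CalibrationCurve-class] objects.
#' @export
syntheticStandards <- function(maxAmount = 20000) {
  amounts <- c(0, maxAmount * c(0.01, 0.05, 0.1, 0.25, 0.5, 1))
  do.call(rbind, lapply(NADFLUX_ANALYTES, function(a) {
    data.frame(analyte = a, amount_pmol = amounts,
      peak_area = .SYNTH_CURVE_SLOPES[[a]] * amounts,
      stringsAsFactors = FALSE)
  }))
}

#' @rdname syntheticStandards
#' @param standards Standards table (default [syntheticStandards()]).
#' @export
syntheticCurves <- function(standards = syntheticStandards()) {
  curves <- lapply(NADFLUX_ANALYTES, function(a)
    fitCalibration(standards, a))
  names(curves) <- NADFLUX_ANALYTES
  curves
}

#' Generate a synthetic labeling dataset
#'
#' Samples the deterministic trajectory at the design times, applies
#' multiplicative log-normal measurement noise with coefficient of
#' variation `p@noiseCv` independently to every observation (the log-normal
#' is mean-preserving: `E[noisy] = true`), and emits the vendor-style
#' peak-area table by pushing the absolute amounts back through the
#' calibration curves (`area = slope * pmol + intercept`). The result feeds
#' the full pipeline: [buildLabelingTable()] then [estimateFluxes()] /
#' [fluxTable()]. A fixed `p@seed` makes the output reproducible.
#'
#' @param p A [KineticParams-class] (its `noiseCv` and `seed` are used).
#' @param times Design sampling times, h (first must be 0).
#' @param curves Named list of calibration curves (default
#'   [syntheticCurves()]).
#' @param sampleId Sample identifier used in the tables.
#' @return List with `peak_table` (sample_id, time_h, compartment, analyte,
#'   peak_area), `metadata` (one row, flux-pipeline layout), `curves`, and
#'   `truth` (the noiseless trajectory at `times`).
#' @export
generateDataset <- function(p, times = c(0, 3), curves = syntheticCurves(),
                            sampleId = "sim01") {
  stopifnot(methods::is(p, "KineticParams"))
  traj <- simulateLabeling(p, times)
  set.seed(p@seed)
  cv <- p@noiseCv
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- function(x) {
    if (cv == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  absAmt <- function(per1e6) per1e6 * p@cellCount / 1e6
  cols <- c(`d3-NAD+` = "cell_d3_nad", `d0-NAD+` = "cell_d0_nad",
    `d3-Nam` = "med_d3_nam", `d0-Nam` = "med_d0_nam",
    `d4-Nam` = "med_d4_nam")
  rows <- list()
  for (i in seq_along(times)) {
    for (an in names(cols)) {
      amt <- noisy(absAmt(traj[[cols[[an]]]][i]))
      curve <- curves[[an]]
      if (is.null(curve)) stop("no curve for analyte '", an, "'")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleId, time_h = times[i],
        compartment = .ANALYTE_MAP$compartment[.ANALYTE_MAP$analyte == an],
        analyte = an,
        peak_area = curve@intercept + curve@slope * amt,
        stringsAsFactors = FALSE)
    }
  }
  list(
    peak_table = do.call(rbind, rows),
    metadata = data.frame(sample_id = sampleId, cell_count = p@cellCount,
      cell_volume_pL = p@cellVolume, medium_volume_mL = p@mediumVolume,
      d4_nam_conc_uM = p@namMedium0, time_h = max(times),
      stringsAsFactors = FALSE),
    curves = curves,
    truth = traj
  )
}

#' Estimator bias across labeling times
#'
#' For each labeling time t, applies the two-point estimator to the
#' noiseless (0, t) simulated pair and compares it with the true
#' time-averaged gross fluxes from the integrator (`cum_syn / t`,
#' `cum_brk / t`). The estimator reads net isotopologue exchange, so it
#' under-reads the gross fluxes as t grows — freshly made d3-NAD+ is
#' itself degraded, and with recycling on, released d3-/d0-Nam re-enters
#' synthesis, both biases deepening monotonically with t.
#'
#' @param p A [KineticParams-class].
#' @param times Grid of labeling times, h (> 0).
#' @return data.frame with columns `time_h`, `true_rs`, `true_rb` (gross,
#'   pmol per 10^6 cells per h), `est_rs`, `est_rb`, `bias_rs`, `bias_rb`
#'   (relative), and `nam_depletion_frac`.
#' @export
biasScan <- function(p, times = c(1, 2, 3, 6, 9, 12, 18, 24)) {
  stopifnot(all(times > 0))
  traj <- simulateLabeling(p, c(0, sort(times)))
  t0 <- traj[1, ]
  out <- lapply(seq_len(nrow(traj))[-1], function(i) {
    r <- traj[i, ]
    t <- r$time_h
    est_rs <- (r$cell_d3_nad - t0$cell_d3_nad) / t
    est_rb <- (t0$cell_d0_nad - r$cell_d0_nad) / t
    true_rs <- r$cum_syn_pmol_1e6 / t
    true_rb <- r$cum_brk_pmol_1e6 / t
    data.frame(time_h = t, true_rs = true_rs, true_rb = true_rb,
      est_rs = est_rs, est_rb = est_rb,
      bias_rs = est_rs / true_rs - 1, bias_rb = est_rb / true_rb - 1,
      nam_depletion_frac = r$nam_depletion_frac)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Steady-state NAD+ concentration under clamped medium Nam
#'
#' With medium nicotinamide held at `S = namMedium0` (routinely refreshed
#' medium), the steady state of the feedback model solves
#' `vmax * S / (km0 * (1 + C/ki) + S) = kB * C`, a quadratic in C:
#' `(kB * km0 / ki) C^2 + kB (km0 + S) C - vmax S = 0`; the positive root
#' is returned. At steady state synthesis and breakdown balance, so
#' `R_S = R_B = kB * C*`.
#'
#' @param p A [KineticParams-class].
#' @return List: `nad_conc` (uM), `r_s` = `r_b` (uM/h), `half_life_h`.
#' @export
steadyStateNad <- function(p) {
  stopifnot(methods::is(p, "KineticParams"))
  s <- p@namMedium0
  if (s <= 0 || p@vmax == 0 || p@kB == 0)
    stop("steady state requires positive vmax, kB and medium Nam")
  a <- p@kB * p@km0 / p@kiFeedback
  b <- p@kB * (p@km0 + s)
  # positive root in the cancellation-safe form (a can be ~0 for weak
  # feedback): C = 2 vmax S / (b + sqrt(b^2 + 4 a vmax S))
  cStar <- 2 * p@vmax * s / (b + sqrt(b^2 + 4 * a * p@vmax * s))
  r <- p@kB * cStar
  list(nad_conc = cStar, r_s = r, r_b = r, half_life_h = log(2) / p@kB)
}

#' Nampt-induction scenario
#'
#' Scales `vmax` (the total-Nampt-activity proxy) by `vmaxFold` and
#' compares the new steady state with the baseline one (clamped medium
#' Nam; see [steadyStateNad()]). Because Nam is far below the
#' feedback-inflated Km and extra NAD+ inflates the Km further while the
#' first-order breakdown grows with the pool, the synthesis-rate fold is
#' strictly between 1 and `vmaxFold`, and the R_S and R_B folds are equal
#' at steady state.
#'
#' @param p Baseline [KineticParams-class].
#' @param vmaxFold Fold increase of vmax (>= 1).
#' @return List: `vmax_fold`, `rs_fold`, `rb_fold`, `nad_fold`, plus the
#'   two steady states (`baseline`, `induced`).
#' @examples
#' inductionScenario(kineticParams(), 6)
#' @export
inductionScenario <- function(p, vmaxFold) {
  if (vmaxFold < 1) stop("vmaxFold must be >= 1")
  base <- steadyStateNad(p)
  pInd <- p
  pInd@vmax <- p@vmax * vmaxFold
  ind <- steadyStateNad(pInd)
  list(vmax_fold = vmaxFold,
    rs_fold = foldChange(ind$r_s, base$r_s),
    rb_fold = foldChange(ind$r_b, base$r_b),
    nad_fold = foldChange(ind$nad_conc, base$nad_conc),
    baseline = base, induced = ind)
}

#' Parameter-recovery study on noisy synthetic datasets
#'
#' Generates `nDatasets` independently seeded noisy datasets under the
#' design (default: the assay's 2 uM / 3 h two-point design), runs each
#' through the full pipeline (calibration inversion, per-cell
#' normalization, two-point estimation), and summarizes recovery of the
#' true net rates (the noiseless trajectory's d3 appearance and d0
#' disappearance per time).
#'
#' @param p A [KineticParams-class]; dataset i uses seed `p@seed + i`.
#' @param nDatasets Number of datasets (default 50).
#' @param times Design times (default `c(0, 3)`).
#' @return List with `estimates` (data.frame of per-dataset `r_s`, `r_b`),
#'   `truth` (`r_s`, `r_b`), and `summary` (means, relative errors of the
#'   means, empirical CVs).
#' @export
parameterRecovery <- function(p, nDatasets = 50, times = c(0, 3)) {
  curves <- syntheticCurves()
  p0 <- p
  p0@noiseCv <- 0
  tr <- simulateLabeling(p0, times)
  tEnd <- max(times)
  truth <- list(
    r_s = (tr$cell_d3_nad[nrow(tr)] - tr$cell_d3_nad[1]) / tEnd,
    r_b = (tr$cell_d0_nad[1] - tr$cell_d0_nad[nrow(tr)]) / tEnd
  )
  est <- lapply(seq_len(nDatasets), function(i) {
    pi <- p
    pi@seed <- as.integer(p@seed + i)
    ds <- generateDataset(pi, times, curves)
    lab <- buildLabelingTable(ds$peak_table, curves,
      cellContext(p@cellCount, p@cellVolume, p@mediumVolume, p@namMedium0))
    lab <- lab[order(lab$time_h), ]
    tp <- function(r) labelingTimepoint(r$time_h, r$cell_d3_nad,
      r$cell_d0_nad, r$medium_d3_nam, r$medium_d0_nam, r$medium_d4_nam)
    fr <- suppressWarnings(estimateFluxes(tp(lab[1, ]), tp(lab[nrow(lab), ]),
      cellContext(p@cellCount, p@cellVolume, p@mediumVolume, p@namMedium0)))
    data.frame(dataset = i, r_s = fr@rS, r_b = fr@rB)
  })
  est <- do.call(rbind, est)
  summ <- list(
    mean_r_s = mean(est$r_s), mean_r_b = mean(est$r_b),
    rel_err_r_s = mean(est$r_s) / truth$r_s - 1,
    rel_err_r_b = mean(est$r_b) / truth$r_b - 1,
    cv_r_s = stats::sd(est$r_s) / mean(est$r_s),
    cv_r_b = stats::sd(est$r_b) / mean(est$r_b)
  )
  list(estimates = est, truth = truth, summary = summ)
}

#' Write a trajectory or bias table as CSV
#'
#' @param x data.frame from [simulateLabeling()] or [biasScan()].
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
writeTrajectory <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
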