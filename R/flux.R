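#' Rate of NAD+ synthesis from label appearance
#'
#' The assay defines the synthesis rate as the amount of d3-NAD+ that has
#' appeared per unit labeling time, `R_S = a / t`.
#'
#' @param d3NadAppeared Amount of d3-NAD+ appeared (a), pmol per 10^6 cells.
#' @param time Labeling time t, h (> 0).
#' @return Rate in pmol per 10^6 cells per h.
#' @examples
#' computeRs(276, 3)  # 92
#' @export
computeRs <- function(d3NadAppeared, time) {
  if (any(time <= 0)) stop("labeling time must be > 0")
  if (any(d3NadAppeared < 0))
    stop("d3-NAD+ appeared must be >= 0 (labels cannot vanish)")
  d3NadAppeared / time
}

#' Rate of NAD+ breakdown from label disappearance
#'
#' `R_B = b / t`, where b is the decrease of d0-NAD+ over the labeling
#' time. A negative observed decrease (d0-NAD+ apparently rising, possible
#' under measurement noise) is clamped to zero with a warning rather than
#' an error so a noisy replicate cannot halt a batch; callers see the clamp
#' through the warning and, in [estimateFluxes()], through a flag.
#'
#' @param d0NadDecreased Decrease of d0-NAD+ (b), pmol per 10^6 cells.
#' @param time Labeling time t, h (> 0).
#' @return Rate in pmol per 10^6 cells per h.
#' @examples
#' computeRb(258, 3)  # 86
#' @export
computeRb <- function(d0NadDecreased, time) {
  if (any(time <= 0)) stop("labeling time must be > 0")
  if (any(d0NadDecreased < 0)) {
    warning("negative observed d0-NAD+ decrease clamped to 0")
    d0NadDecreased <- pmax(d0NadDecreased, 0)
  }
  d0NadDecreased / time
}

#' Total NAD+ content
#'
#' Sum of the labeled and unlabeled pools.
#'
#' @param d3,d0 d3-/d0-NAD+ amounts, pmol per 10^6 cells (>= 0).
#' @return Total NAD+, pmol per 10^6 cells.
#' @examples
#' totalNad(276, 1179)  # 1455
#' @export
totalNad <- function(d3, d0) {
  if (any(d3 < 0) || any(d0 < 0)) stop("amounts must be >= 0")
  d3 + d0
}

#' Convert a per-cell amount to an absolute concentration
#'
#' pmol per 10^6 cells divided by the mean single-cell volume in pL is
#' exactly uM: 10^6 cells x 1 pL = 1 uL, and pmol/uL = uM. The same
#' identity converts per-cell rates (pmol per 10^6 cells per h) to uM/h.
#'
#' @param amount Amount (or rate), pmol per 10^6 cells (per h).
#' @param cellVolume Mean cell volume, pL (> 0).
#' @return Concentration in uM (or uM/h).
#' @examples
#' amountToConcentration(1455, 2.5)  # 582 uM
#' @export
amountToConcentration <- function(amount, cellVolume) {
  if (any(cellVolume <= 0)) stop("cell volume must be > 0")
  amount / cellVolume
}

#' First-order NAD+ half-life
#'
#' Under pool-proportional (first-order) breakdown, the instantaneous
#' turnover constant is `k = R_B / C`, so the half-life is
#' `t_1/2 = ln(2) * C / R_B`. It is invariant under common rescaling of C
#' and R_B, so per-cell and concentration-basis inputs give the same
#' answer as long as both are on the same basis.
#'
#' @param nadConc NAD+ concentration C (uM), or per-cell content.
#' @param rB Breakdown rate on the same basis (uM/h or pmol/10^6 cells/h).
#' @return Half-life in h; NA (with a warning) when `rB` is 0.
#' @examples
#' halfLife(500, 30)  # 11.55 h
#' @export
halfLife <- function(nadConc, rB) {
  if (any(nadConc <= 0)) stop("NAD+ concentration must be > 0")
  if (any(rB < 0)) stop("breakdown rate must be >= 0")
  out <- ifelse(rB > 0, log(2) * nadConc / rB, NA_real_)
  if (any(rB == 0))
    warning("half-life undefined where the breakdown rate is 0")
  out
}

#' Fold change relative to a baseline
#'
#' @param value Quantity of interest.
#' @param baseline Reference value in the same units (> 0).
#' @return `value / baseline`.
#' @examples
#' foldChange(800, 500)  # 1.6
#' @export
foldChange <- function(value, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  value / baseline
}

#' Two-point flux estimation for one labeling run
#'
#' Implements the assay's estimator on a (t0, tN) pair of measurements:
#' `a = d3-NAD+(tN) - d3-NAD+(t0)`, `b = d0-NAD+(t0) - d0-NAD+(tN)`,
#' `R_S = a/t`, `R_B = b/t` with `t = tN - t0`. Total NAD+ and its
#' concentration are taken at tN; the half-life comes from the
#' concentration-basis breakdown rate. When the tN record carries medium
#' nicotinamide isotopomers, [recyclingCheck()] is run and its outcome sets
#' the validity flag.
#'
#' @param t0,tN [LabelingTimepoint-class] records with `tN@time > t0@time`.
#'   Under the labeling protocol t0 is the medium switch, where d3-NAD+ is
#'   zero.
#' @param context A [CellContext-class]; supplies the mean cell volume for
#'   the uM-basis outputs.
#' @param recyclingThreshold Maximal combined non-precursor medium Nam
#'   fraction accepted as negligible recycling (default 0.10).
#' @return A [FluxResult-class].
#' @examples
#' t0 <- labelingTimepoint(0, cellD3Nad = 0, cellD0Nad = 1437)
#' t3 <- labelingTimepoint(3, cellD3Nad = 276, cellD0Nad = 1179)
#' estimateFluxes(t0, t3, cellContext(4.04e5, 2.5))
#' @export
estimateFluxes <- function(t0, tN, context, recyclingThreshold = 0.10) {
  stopifnot(methods::is(t0, "LabelingTimepoint"),
    methods::is(tN, "LabelingTimepoint"),
    methods::is(context, "CellContext"))
  t <- tN@time - t0@time
  if (t <= 0) stop("tN must be later than t0")
  flags <- character()
  a <- tN@cellD3Nad - t0@cellD3Nad
  if (a < 0) stop("d3-NAD+ decreased between t0 and tN: labels cannot vanish")
  b <- t0@cellD0Nad - tN@cellD0Nad
  if (b < 0) {
    flags <- c(flags, "negative d0-NAD+ decrease clamped to 0")
    rb <- withCallingHandlers(computeRb(b, t),
      warning = function(w) invokeRestart("muffleWarning"))
  } else {
    rb <- computeRb(b, t)
  }
  rs <- computeRs(a, t)
  tot <- totalNad(tN@cellD3Nad, tN@cellD0Nad)
  conc <- amountToConcentration(tot, context@cellVolume)
  rsConc <- amountToConcentration(rs, context@cellVolume)
  rbConc <- amountToConcentration(rb, context@cellVolume)
  hl <- if (rbConc > 0 && conc > 0) log(2) * conc / rbConc else NA_real_
  if (is.na(hl)) flags <- c(flags, "half-life undefined (R_B = 0)")

  valid <- NA
  medium <- c(tN@mediumD3Nam, tN@mediumD0Nam, tN@mediumD4Nam)
  if (!any(is.na(medium))) {
    rec <- recyclingCheck(tN@mediumD3Nam, tN@mediumD0Nam, tN@mediumD4Nam,
      threshold = recyclingThreshold)
    valid <- rec$pass
    if (!rec$pass)
      flags <- c(flags, sprintf(
        "recycling check failed: %.1f%% non-precursor medium Nam",
        100 * rec$combined_nonprecursor_frac))
  }
  if (length(flags) && any(grepl("clamped", flags))) valid <- FALSE

  methods::new("FluxResult", rS = rs, rB = rb, rSConc = rsConc,
    rBConc = rbConc, totalNad = tot, nadConc = conc, halfLife = hl,
    valid = valid, flags = flags)
}

#' Multi-timepoint slope estimator of R_S
#'
#' For a multi-timepoint labeling series the synthesis rate can
#' be estimated as the slope of the through-origin OLS of d3-NAD+ amount
#' versus time, `sum(t * y) / sum(t^2)`; the companion R_B estimate
#' regresses the d0-NAD+ decrease the same way.
#'
#' @param times Labeling times, h (>= 3 values including or excluding 0).
#' @param d3Nad d3-NAD+ amounts, pmol per 10^6 cells.
#' @param d0Nad Optional d0-NAD+ amounts; when given, R_B is estimated from
#'   the decreases `d0Nad[1] - d0Nad`.
#' @return List with `r_s`, and `r_b` when `d0Nad` is supplied (pmol per
#'   10^6 cells per h), plus the through-origin `r_squared` of the d3 fit.
#' @export
fluxSlope <- function(times, d3Nad, d0Nad = NULL) {
  stopifnot(length(times) == length(d3Nad), length(times) >= 3)
  rs <- sum(times * d3Nad) / sum(times^2)
  fitted <- rs * times
  ssTot <- sum((d3Nad - mean(d3Nad))^2)
  r2 <- if (ssTot > 0) 1 - sum((d3Nad - fitted)^2) / ssTot else 1
  out <- list(r_s = rs, r_squared = r2)
  if (!is.null(d0Nad)) {
    stopifnot(length(d0Nad) == length(times))
    dec <- d0Nad[which.min(times)] - d0Nad
    out$r_b <- sum(times * dec) / sum(times^2)
  }
  out
}

#' Flux estimates for every sample of a labeling table
#'
#' Applies [estimateFluxes()] to each `sample_id` of a labeling table
#' (earliest timepoint as t0, latest as tN) using per-sample metadata.
#'
#' @param labeling Labeling table from [buildLabelingTable()].
#' @param metadata data.frame with columns `sample_id`, `cell_count`,
#'   `cell_volume_pL`, `medium_volume_mL`, `d4_nam_conc_uM` (see
#'   [readMetadata()]).
#' @param recyclingThreshold Passed to [estimateFluxes()].
#' @return data.frame, one row per sample, in the flux CSV layout
#'   (`sample_id`, rates on both bases, total NAD+, concentration,
#'   half-life, `valid`).
#' @export
fluxTable <- function(labeling, metadata, recyclingThreshold = 0.10) {
  stopifnot(all(c("sample_id", "cell_count", "cell_volume_pL",
    "medium_volume_mL", "d4_nam_conc_uM") %in% names(metadata)))
  out <- lapply(unique(labeling$sample_id), function(sid) {
    rows <- labeling[labeling$sample_id == sid, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    if (nrow(rows) < 2)
      stop("sample '", sid, "' needs at least two timepoints")
    m <- metadata[match(sid, metadata$sample_id), ]
    if (is.na(m$sample_id)) stop("no metadata for sample '", sid, "'")
    ctx <- cellContext(m$cell_count, m$cell_volume_pL, m$medium_volume_mL,
      m$d4_nam_conc_uM)
    tp <- function(r) labelingTimepoint(r$time_h, r$cell_d3_nad,
      r$cell_d0_nad, r$medium_d3_nam, r$medium_d0_nam, r$medium_d4_nam)
    fr <- estimateFluxes(tp(rows[1, ]), tp(rows[nrow(rows), ]), ctx,
      recyclingThreshold = recyclingThreshold)
    cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE),
      as.data.frame(fr))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a sample-metadata CSV
#'
#' Expected header: `sample_id,cell_count,cell_volume_pL,medium_volume_mL,
#' d4_nam_conc_uM,time_h`.
#'
#' @param path File path.
#' @return data.frame of metadata.
#' @export
readMetadata <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_count", "cell_volume_pL", "medium_volume_mL",
    "d4_nam_conc_uM")
  if (!all(need %in% names(m)))
    stop("metadata CSV must have header ", paste(need, collapse = ","),
      "[,time_h]")
  m
}

#' Write a flux CSV
#'
#' @param flux data.frame from [fluxTable()].
#' @param path Output file path.
#' @return Invisibly, `flux`.
#' @export
writeFluxTable <- function(flux, path) {
  utils::write.csv(flux, path, row.names = FALSE, quote = FALSE)
  invisible(flux)
}
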