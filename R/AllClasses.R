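#' Recognized SRM analytes
#'
#' The five isotopologue channels quantified by the assay: unlabeled and
#' triply deuterated NAD+ measured in the cell extract, and unlabeled,
#' triply and quadruply deuterated nicotinamide measured in the culture
#' medium.
#'
#' @format Character vector of length five.
#' @export
NADFLUX_ANALYTES <- c("d0-NAD+", "d3-NAD+", "d0-Nam", "d3-Nam", "d4-Nam")

.checkScalar <- function(x, what, positive = FALSE, nonneg = FALSE,
                         naOk = FALSE) {
  if (length(x) != 1L) return(sprintf("%s must be a single value", what))
  if (is.na(x)) {
    if (naOk) return(NULL)
    return(sprintf("%s must not be NA", what))
  }
  if (positive && x <= 0) return(sprintf("%s must be > 0", what))
  if (nonneg && x < 0) return(sprintf("%s must be >= 0", what))
  NULL
}

#' Per-analyte linear calibration curve
#'
#' Linear detector-response model `peak_area = slope * amount + intercept`
#' fitted to calibration standards, together with its limit of
#' quantification (LOQ, pmol) and the amount range spanned by the standards.
#'
#' @slot analyte Analyte identifier (one of [NADFLUX_ANALYTES]).
#' @slot slope Detector response per pmol (must be positive).
#' @slot intercept Detector response at zero amount.
#' @slot rSquared Coefficient of determination of the fit.
#' @slot loq Limit of quantification in pmol.
#' @slot validRange Numeric length-2: amount range (pmol) covered by the
#'   standards; quantified amounts outside it are flagged.
#' @slot weighting Either `"none"` or `"1/x"`.
#'
#' @seealso [fitCalibration()], [quantifyPeak()]
#' @export
setClass("CalibrationCurve",
  representation(
    analyte = "character",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    loq = "numeric",
    validRange = "numeric",
    weighting = "character"
  ),
  prototype(weighting = "none")
)

setValidity("CalibrationCurve", function(object) {
  msgs <- c(
    .checkScalar(object@slope, "slope", positive = TRUE),
    .checkScalar(object@loq, "loq", positive = TRUE),
    .checkScalar(object@rSquared, "rSquared")
  )
  if (length(object@analyte) != 1L || !nzchar(object@analyte))
    msgs <- c(msgs, "analyte must be a single non-empty string")
  if (is.null(msgs) || length(msgs) == 0) {
    if (object@rSquared > 1 + 1e-12)
      msgs <- c(msgs, "rSquared must be <= 1")
  }
  if (length(object@validRange) != 2L || diff(object@validRange) < 0)
    msgs <- c(msgs, "validRange must be increasing length-2 numeric")
  if (!object@weighting %in% c("none", "1/x"))
    msgs <- c(msgs, "weighting must be 'none' or '1/x'")
  if (length(msgs)) msgs else TRUE
})

#' Normalization context of a labeling experiment
#'
#' Cell count, mean single-cell volume and medium volume for one sample: the
#' basis on which per-10^6-cell amounts and absolute concentrations are
#' computed. Because 10^6 cells x 1 pL = 1 uL, pmol per 10^6 cells divided
#' by the mean cell volume in pL is exactly uM.
#'
#' @slot cellCount Number of cells in the well.
#' @slot cellVolume Mean single-cell volume in pL (Coulter-principle
#'   readout).
#' @slot mediumVolume Culture-medium volume in mL.
#' @slot d4NamConc Tracer (d4-Nam) concentration in the medium, uM.
#'
#' @seealso [cellContext()]
#' @export
setClass("CellContext",
  representation(
    cellCount = "numeric",
    cellVolume = "numeric",
    mediumVolume = "numeric",
    d4NamConc = "numeric"
  )
)

setValidity("CellContext", function(object) {
  msgs <- c(
    .checkScalar(object@cellCount, "cellCount", positive = TRUE),
    .checkScalar(object@cellVolume, "cellVolume", positive = TRUE),
    .checkScalar(object@mediumVolume, "mediumVolume", positive = TRUE),
    .checkScalar(object@d4NamConc, "d4NamConc", positive = TRUE)
  )
  if (length(msgs)) msgs else TRUE
})

#' Construct a CellContext
#'
#' @param cellCount Number of cells.
#' @param cellVolume Mean cell volume, pL.
#' @param mediumVolume Medium volume, mL.
#' @param d4NamConc d4-Nam concentration in the medium, uM.
#' @return A [CellContext-class] object.
#' @examples
#' cellContext(4.04e5, cellVolume = 2.5, mediumVolume = 0.95, d4NamConc = 2)
#' @export
cellContext <- function(cellCount, cellVolume, mediumVolume = 0.95,
                        d4NamConc = 2) {
  methods::new("CellContext", cellCount = as.numeric(cellCount),
    cellVolume = as.numeric(cellVolume),
    mediumVolume = as.numeric(mediumVolume),
    d4NamConc = as.numeric(d4NamConc))
}

#' Measured isotopologue amounts at one labeling time
#'
#' All amounts are pmol per 10^6 cells. Cellular NAD+ isotopologues come
#' from the cell extract; nicotinamide isotopomers from the culture medium.
#' Medium values may be NA when not measured.
#'
#' @slot time Hours since the medium switch to d4-Nam.
#' @slot cellD3Nad,cellD0Nad Cellular d3-/d0-NAD+ (pmol per 10^6 cells).
#' @slot mediumD3Nam,mediumD0Nam,mediumD4Nam Medium nicotinamide isotopomers
#'   (pmol per 10^6 cells), NA when absent.
#'
#' @seealso [labelingTimepoint()], [estimateFluxes()]
#' @export
setClass("LabelingTimepoint",
  representation(
    time = "numeric",
    cellD3Nad = "numeric",
    cellD0Nad = "numeric",
    mediumD3Nam = "numeric",
    mediumD0Nam = "numeric",
    mediumD4Nam = "numeric"
  )
)

setValidity("LabelingTimepoint", function(object) {
  msgs <- c(
    .checkScalar(object@time, "time", nonneg = TRUE),
    .checkScalar(object@cellD3Nad, "cellD3Nad", nonneg = TRUE),
    .checkScalar(object@cellD0Nad, "cellD0Nad", nonneg = TRUE),
    .checkScalar(object@mediumD3Nam, "mediumD3Nam", nonneg = TRUE, naOk = TRUE),
    .checkScalar(object@mediumD0Nam, "mediumD0Nam", nonneg = TRUE, naOk = TRUE),
    .checkScalar(object@mediumD4Nam, "mediumD4Nam", nonneg = TRUE, naOk = TRUE)
  )
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabelingTimepoint
#'
#' @param time Hours since the medium switch.
#' @param cellD3Nad,cellD0Nad Cellular NAD+ isotopologues, pmol per 10^6
#'   cells.
#' @param mediumD3Nam,mediumD0Nam,mediumD4Nam Medium Nam isotopomers, pmol
#'   per 10^6 cells (optional).
#' @return A [LabelingTimepoint-class] object.
#' @examples
#' labelingTimepoint(3, cellD3Nad = 276, cellD0Nad = 1179)
#' @export
labelingTimepoint <- function(time, cellD3Nad, cellD0Nad,
                              mediumD3Nam = NA_real_,
                              mediumD0Nam = NA_real_,
                              mediumD4Nam = NA_real_) {
  methods::new("LabelingTimepoint", time = as.numeric(time),
    cellD3Nad = as.numeric(cellD3Nad), cellD0Nad = as.numeric(cellD0Nad),
    mediumD3Nam = as.numeric(mediumD3Nam),
    mediumD0Nam = as.numeric(mediumD0Nam),
    mediumD4Nam = as.numeric(mediumD4Nam))
}

#' Output record of the flux assay
#'
#' Rates are stored on the per-cell basis (pmol per 10^6 cells per h);
#' concentration-basis values (uM/h) are derived through the mean cell
#' volume and stored alongside so the volume provenance travels with them.
#'
#' @slot rS,rB NAD+ synthesis/breakdown rate, pmol per 10^6 cells per h.
#' @slot rSConc,rBConc The same rates in uM/h (NA when no cell volume was
#'   supplied).
#' @slot totalNad Total NAD+ (d0 + d3) at the end timepoint, pmol per 10^6
#'   cells.
#' @slot nadConc Intracellular NAD+ concentration, uM.
#' @slot halfLife First-order NAD+ half-life, h (NA when rB is 0).
#' @slot valid Logical validity flag (recycling check et al.).
#' @slot flags Character vector of diagnostic notes.
#'
#' @seealso [estimateFluxes()]
#' @export
setClass("FluxResult",
  representation(
    rS = "numeric",
    rB = "numeric",
    rSConc = "numeric",
    rBConc = "numeric",
    totalNad = "numeric",
    nadConc = "numeric",
    halfLife = "numeric",
    valid = "logical",
    flags = "character"
  ),
  prototype(valid = NA, flags = character())
)

setValidity("FluxResult", function(object) {
  msgs <- c(
    .checkScalar(object@rS, "rS", nonneg = TRUE),
    .checkScalar(object@rB, "rB", nonneg = TRUE),
    .checkScalar(object@totalNad, "totalNad", nonneg = TRUE),
    .checkScalar(object@nadConc, "nadConc", nonneg = TRUE, naOk = TRUE),
    .checkScalar(object@halfLife, "halfLife", positive = TRUE, naOk = TRUE)
  )
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the salvage-pathway labeling simulator
#'
#' The kinetic model behind [simulateLabeling()]: Michaelis-Menten NAD+
#' synthesis from medium nicotinamide with competitive-style feedback
#' inflation of the Nam Km by intracellular NAD+
#' (`Km_eff = km0 * (1 + C/kiFeedback)`), and lumped first-order NAD+
#' breakdown (`j_B = kB * C`) that releases nicotinamide of matching label
#' back into the medium.
#'
#' Defaults reproduce the reference HepG2 labeling run (2 uM d4-Nam, 3 h,
#' 4.04e5 cells in 0.95 mL): see [kineticParams()].
#'
#' @slot vmax Maximal synthesis rate, uM/h on the cell-volume basis (a proxy
#'   for total Nampt activity).
#' @slot km0 Nam Km at zero NAD+, uM.
#' @slot kiFeedback Feedback constant, uM; Km doubles at `C = kiFeedback`.
#' @slot kB First-order breakdown constant, 1/h.
#' @slot nad0 Initial d0-NAD+ concentration, uM.
#' @slot namMedium0 d4-Nam concentration in the fresh medium, uM.
#' @slot namD0Residual Unlabeled Nam carried over into the medium at the
#'   switch, uM.
#' @slot cellCount,cellVolume,mediumVolume As in [CellContext-class].
#' @slot recycling Logical: may nicotinamide released by NAD+ breakdown
#'   (and d0 carryover) be re-used as a synthesis substrate?
#' @slot isotopeEffect Multiplicative factor on the d4-Nam consumption flux
#'   (1 = labeled and unlabeled substrate handled identically).
#' @slot noiseCv Coefficient of variation of the multiplicative log-normal
#'   measurement noise in [generateDataset()].
#' @slot seed Integer seed for stochastic routines.
#'
#' @export
setClass("KineticParams",
  representation(
    vmax = "numeric",
    km0 = "numeric",
    kiFeedback = "numeric",
    kB = "numeric",
    nad0 = "numeric",
    namMedium0 = "numeric",
    namD0Residual = "numeric",
    cellCount = "numeric",
    cellVolume = "numeric",
    mediumVolume = "numeric",
    recycling = "logical",
    isotopeEffect = "numeric",
    noiseCv = "numeric",
    seed = "integer"
  )
)

setValidity("KineticParams", function(object) {
  msgs <- c(
    .checkScalar(object@vmax, "vmax", nonneg = TRUE),
    .checkScalar(object@km0, "km0", positive = TRUE),
    .checkScalar(object@kiFeedback, "kiFeedback", positive = TRUE),
    .checkScalar(object@kB, "kB", nonneg = TRUE),
    .checkScalar(object@nad0, "nad0", nonneg = TRUE),
    .checkScalar(object@namMedium0, "namMedium0", nonneg = TRUE),
    .checkScalar(object@namD0Residual, "namD0Residual", nonneg = TRUE),
    .checkScalar(object@cellCount, "cellCount", positive = TRUE),
    .checkScalar(object@cellVolume, "cellVolume", positive = TRUE),
    .checkScalar(object@mediumVolume, "mediumVolume", positive = TRUE),
    .checkScalar(object@isotopeEffect, "isotopeEffect", positive = TRUE),
    .checkScalar(object@noiseCv, "noiseCv", nonneg = TRUE)
  )
  if (length(object@recycling) != 1L || is.na(object@recycling))
    msgs <- c(msgs, "recycling must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct simulator parameters
#'
#' Defaults define the reference labeling experiment the simulator
#' emulates: HepG2-like cells (4.04e5 cells of mean volume 2.5 pL in
#' 0.95 mL medium) switched to 2 uM d4-Nam, starting from 1437 pmol
#' d0-NAD+ per 10^6 cells (574.8 uM). `vmax` and `kB` are back-computed so
#' the noiseless model reproduces the reference 3-h isotopologue exchange
#' (276 pmol/10^6 cells d3-NAD+ appeared, 258 pmol/10^6 cells d0-NAD+
#' lost, i.e. R_S = 92 and R_B = 86 pmol/10^6 cells/h); the feedback
#' anchors `km0 = 1` uM and `kiFeedback = 500/24` uM place the effective Km
#' at 25 uM when NAD+ is 500 uM.
#'
#' @param vmax Maximal synthesis rate, uM/h.
#' @param km0 Nam Km at zero NAD+, uM.
#' @param kiFeedback Feedback constant, uM (`Inf`-like large values disable
#'   feedback; use `kiFeedback = 1e12` rather than `Inf`).
#' @param kB First-order breakdown constant, 1/h.
#' @param nad0 Initial d0-NAD+ concentration, uM.
#' @param namMedium0 d4-Nam in the fresh medium, uM.
#' @param namD0Residual d0-Nam carryover at the switch, uM.
#' @param cellCount,cellVolume,mediumVolume Normalization context.
#' @param recycling Allow re-use of released/carryover Nam as substrate.
#' @param isotopeEffect Factor on labeled-substrate flux.
#' @param noiseCv Measurement-noise CV for [generateDataset()].
#' @param seed Integer seed.
#' @return A [KineticParams-class] object.
#' @examples
#' p <- kineticParams()
#' traj <- simulateLabeling(p, times = c(0, 3))
#' @export
kineticParams <- function(vmax = 647.006992, km0 = 1, kiFeedback = 500 / 24,
                          kB = 0.06845969, nad0 = 574.8, namMedium0 = 2,
                          namD0Residual = 0.0026, cellCount = 4.04e5,
                          cellVolume = 2.5, mediumVolume = 0.95,
                          recycling = TRUE, isotopeEffect = 1,
                          noiseCv = 0.05, seed = 1L) {
  methods::new("KineticParams", vmax = as.numeric(vmax),
    km0 = as.numeric(km0), kiFeedback = as.numeric(kiFeedback),
    kB = as.numeric(kB), nad0 = as.numeric(nad0),
    namMedium0 = as.numeric(namMedium0),
    namD0Residual = as.numeric(namD0Residual),
    cellCount = as.numeric(cellCount), cellVolume = as.numeric(cellVolume),
    mediumVolume = as.numeric(mediumVolume), recycling = recycling,
    isotopeEffect = as.numeric(isotopeEffect), noiseCv = as.numeric(noiseCv),
    seed = as.integer(seed))
}
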