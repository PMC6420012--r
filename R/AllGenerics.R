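#' @name curve-accessors
#' @title Accessors for CalibrationCurve objects
#' @param object A [CalibrationCurve-class].
#' @return The corresponding slot value.
#' @examples
#' std <- data.frame(analyte = "d3-NAD+", amount_pmol = 0:5,
#'                   peak_area = 100 * (0:5))
#' cc <- fitCalibration(std, "d3-NAD+")
#' slope(cc); loq(cc); rSquared(cc)
NULL

#' @rdname curve-accessors
#' @export
setGeneric("analyte", function(object) standardGeneric("analyte"))
#' @rdname curve-accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))
#' @rdname curve-accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))
#' @rdname curve-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname curve-accessors
#' @export
setGeneric("loq", function(object) standardGeneric("loq"))
#' @rdname curve-accessors
#' @export
setGeneric("validRange", function(object) standardGeneric("validRange"))

#' @rdname curve-accessors
setMethod("analyte", "CalibrationCurve", function(object) object@analyte)
#' @rdname curve-accessors
setMethod("slope", "CalibrationCurve", function(object) object@slope)
#' @rdname curve-accessors
setMethod("intercept", "CalibrationCurve", function(object) object@intercept)
#' @rdname curve-accessors
setMethod("rSquared", "CalibrationCurve", function(object) object@rSquared)
#' @rdname curve-accessors
setMethod("loq", "CalibrationCurve", function(object) object@loq)
#' @rdname curve-accessors
setMethod("validRange", "CalibrationCurve", function(object) object@validRange)

#' @name flux-accessors
#' @title Accessors for FluxResult objects
#' @param object A [FluxResult-class].
#' @return The corresponding slot value; `rS`/`rB` in pmol per 10^6 cells
#'   per h, `nadConc` in uM, `nadHalfLife` in h.
NULL

#' @rdname flux-accessors
#' @export
setGeneric("rS", function(object) standardGeneric("rS"))
#' @rdname flux-accessors
#' @export
setGeneric("rB", function(object) standardGeneric("rB"))
#' @rdname flux-accessors
#' @export
setGeneric("nadConc", function(object) standardGeneric("nadConc"))
#' @rdname flux-accessors
#' @export
setGeneric("nadHalfLife", function(object) standardGeneric("nadHalfLife"))
#' @rdname flux-accessors
#' @export
setGeneric("isValid", function(object) standardGeneric("isValid"))

#' @rdname flux-accessors
setMethod("rS", "FluxResult", function(object) object@rS)
#' @rdname flux-accessors
setMethod("rB", "FluxResult", function(object) object@rB)
#' @rdname flux-accessors
setMethod("nadConc", "FluxResult", function(object) object@nadConc)
#' @rdname flux-accessors
setMethod("nadHalfLife", "FluxResult", function(object) object@halfLife)
#' @rdname flux-accessors
setMethod("isValid", "FluxResult", function(object) object@valid)

#' @describeIn CalibrationCurve-class Compact display.
#' @param object A `CalibrationCurve`.
setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s]: area = %.6g * pmol + %.6g (R^2 = %.5f)\n",
    object@analyte, object@slope, object@intercept, object@rSquared))
  cat(sprintf("  LOQ %.3g pmol; valid range [%.3g, %.3g] pmol; weighting %s\n",
    object@loq, object@validRange[1], object@validRange[2], object@weighting))
  invisible(NULL)
})

#' @describeIn FluxResult-class Compact display.
#' @param object A `FluxResult`.
setMethod("show", "FluxResult", function(object) {
  cat("FluxResult (NAD+ turnover)\n")
  cat(sprintf("  R_S: %.4g pmol/10^6 cells/h (%.4g uM/h)\n",
    object@rS, object@rSConc))
  cat(sprintf("  R_B: %.4g pmol/10^6 cells/h (%.4g uM/h)\n",
    object@rB, object@rBConc))
  cat(sprintf("  total NAD+: %.4g pmol/10^6 cells; [NAD+] = %.4g uM\n",
    object@totalNad, object@nadConc))
  cat(sprintf("  half-life: %.4g h; valid: %s\n", object@halfLife,
    ifelse(is.na(object@valid), "not assessed", object@valid)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

#' @describeIn KineticParams-class Compact display.
#' @param object A `KineticParams`.
setMethod("show", "KineticParams", function(object) {
  cat("KineticParams (salvage-pathway simulator)\n")
  cat(sprintf("  vmax %.4g uM/h, km0 %.3g uM, kiFeedback %.4g uM, kB %.4g /h\n",
    object@vmax, object@km0, object@kiFeedback, object@kB))
  cat(sprintf("  nad0 %.4g uM; medium d4-Nam %.3g uM (+%.3g uM d0 carryover)\n",
    object@nad0, object@namMedium0, object@namD0Residual))
  cat(sprintf("  %.3g cells x %.3g pL in %.3g mL; recycling %s\n",
    object@cellCount, object@cellVolume, object@mediumVolume,
    object@recycling))
  cat(sprintf("  isotope effect %.3g; noise CV %.3g; seed %d\n",
    object@isotopeEffect, object@noiseCv, object@seed))
  invisible(NULL)
})

#' Coerce a FluxResult to a one-row data.frame
#'
#' @param x A [FluxResult-class].
#' @param row.names,optional,... Passed on conventions of
#'   [base::as.data.frame()]; ignored.
#' @return One-row data.frame with the flux CSV column layout.
#' @export
as.data.frame.FluxResult <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(
    r_s_pmol_per_1e6cells_h = x@rS,
    r_b_pmol_per_1e6cells_h = x@rB,
    r_s_uM_h = x@rSConc,
    r_b_uM_h = x@rBConc,
    total_nad_pmol_per_1e6cells = x@totalNad,
    nad_conc_uM = x@nadConc,
    half_life_h = x@halfLife,
    valid = x@valid,
    stringsAsFactors = FALSE
  )
}
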