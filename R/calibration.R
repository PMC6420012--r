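#' Fit a per-analyte calibration curve
#'
#' Ordinary least-squares fit of detector response versus standard amount,
#' `area = slope * amount + intercept`. An optional 1/x weighting (weights
#' proportional to 1/amount, zero-amount standards receiving the largest
#' finite weight present) is available for response ranges wide enough that
#' variance grows with amount; the default is unweighted, appropriate for
#' the modest pmol ranges of these SRM channels.
#'
#' Curves whose coefficient of determination falls below `minRSquared` are
#' rejected unless `force = TRUE`: linearity of the response is the only
#' quality criterion the assay relies on, so the gate is explicit and
#' adjustable rather than silent.
#'
#' @param standards data.frame with columns `analyte`, `amount_pmol`,
#'   `peak_area` (extra columns ignored). See [readStandards()].
#' @param analyte Which analyte to fit (one of [NADFLUX_ANALYTES]).
#' @param loq Limit of quantification, pmol. Default `NULL` looks up
#'   `loqDefaults[[analyte]]`, falling back to 0.4 pmol, the most
#'   conservative end of the instrument's 0.1-0.4 pmol LOQ range.
#' @param loqDefaults Named list/vector of per-analyte LOQs (pmol).
#' @param minRSquared Minimal acceptable R^2 (default 0.99).
#' @param weighting `"none"` (default) or `"1/x"`.
#' @param force Skip the R^2 gate.
#' @return A [CalibrationCurve-class].
#' @examples
#' std <- data.frame(analyte = "d3-NAD+", amount_pmol = c(0, 1, 2, 5),
#'                   peak_area = c(0, 100, 200, 500))
#' fitCalibration(std, "d3-NAD+")
#' @export
fitCalibration <- function(standards, analyte, loq = NULL,
                           loqDefaults = list(), minRSquared = 0.99,
                           weighting = c("none", "1/x"), force = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(standards),
    all(c("analyte", "amount_pmol", "peak_area") %in% names(standards)))
  .checkAnalytes(analyte)
  s <- standards[standards$analyte == analyte, , drop = FALSE]
  if (nrow(s) < 3L)
    stop("degenerate design: need >= 3 standards for '", analyte, "', got ",
      nrow(s))
  x <- as.numeric(s$amount_pmol)
  y <- as.numeric(s$peak_area)
  if (any(x < 0) || any(y < 0))
    stop("standards must have non-negative amounts and peak areas")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all standard amounts identical for '",
      analyte, "'")
  w <- NULL
  if (weighting == "1/x") {
    w <- ifelse(x > 0, 1 / x, NA_real_)
    w[is.na(w)] <- max(w, na.rm = TRUE)
  }
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  b <- unname(stats::coef(fit))
  r2 <- if (stats::var(y) == 0) {
    1  # flat responses on a flat line: perfect (if useless) fit
  } else {
    unname(stats::cor(x, y)^2)
  }
  if (b[2] <= 0)
    stop("calibration failure: non-positive fitted slope for '", analyte, "'")
  if (!force && r2 < minRSquared)
    stop(sprintf(
      "calibration failure: R^2 = %.5f < %.5f for '%s' (set force = TRUE to override)",
      r2, minRSquared, analyte))
  if (is.null(loq)) {
    loq <- loqDefaults[[analyte]]
    if (is.null(loq)) loq <- 0.4
  }
  methods::new("CalibrationCurve", analyte = analyte, slope = b[2],
    intercept = b[1], rSquared = r2, loq = as.numeric(loq),
    validRange = range(x), weighting = weighting)
}

#' Convert peak areas to amounts through a calibration curve
#'
#' Inverts the linear response, `amount = (area - intercept) / slope`,
#' floors negative solutions at zero, and flags rather than censors:
#' `below_loq` when the amount is under the curve's limit of quantification
#' and `out_of_range` when it falls outside the amount range spanned by the
#' standards.
#'
#' @param curve A [CalibrationCurve-class].
#' @param peakArea Numeric vector of detector responses (>= 0).
#' @return data.frame with columns `analyte`, `peak_area`, `amount_pmol`,
#'   `below_loq`, `out_of_range`, one row per input area.
#' @examples
#' std <- data.frame(analyte = "d3-Nam", amount_pmol = c(0, 1, 2, 5),
#'                   peak_area = c(0, 100, 200, 500))
#' cc <- fitCalibration(std, "d3-Nam")
#' quantifyPeak(cc, c(250, 20))
#' @export
quantifyPeak <- function(curve, peakArea) {
  stopifnot(methods::is(curve, "CalibrationCurve"))
  peakArea <- as.numeric(peakArea)
  if (any(is.na(peakArea)) || any(peakArea < 0))
    stop("peak areas must be non-negative and non-missing")
  amount <- pmax((peakArea - curve@intercept) / curve@slope, 0)
  data.frame(
    analyte = curve@analyte,
    peak_area = peakArea,
    amount_pmol = amount,
    below_loq = amount < curve@loq,
    out_of_range = amount < curve@validRange[1] | amount > curve@validRange[2],
    stringsAsFactors = FALSE
  )
}

.checkAnalytes <- function(a) {
  bad <- setdiff(unique(a), NADFLUX_ANALYTES)
  if (length(bad))
    stop("unknown analyte label(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(NADFLUX_ANALYTES, collapse = ", "), ")")
  invisible(TRUE)
}

# analyte -> (compartment it is measured in, LabelingTimepoint field)
.ANALYTE_MAP <- data.frame(
  analyte = NADFLUX_ANALYTES,
  compartment = c("cells", "cells", "medium", "medium", "medium"),
  field = c("cell_d0_nad", "cell_d3_nad", "medium_d0_nam", "medium_d3_nam",
    "medium_d4_nam"),
  stringsAsFactors = FALSE
)

#' Build a per-10^6-cells labeling table from peak areas
#'
#' Runs every peak-table row through its analyte's calibration curve and
#' normalizes to pmol per 10^6 cells (`amount_pmol / cell_count * 1e6`).
#' Cell-compartment rows populate the NAD+ isotopologue columns, medium
#' rows the nicotinamide isotopomer columns; analytes that were not
#' measured stay NA (absent, never silently zero). LOQ and range flags are
#' aggregated per (sample, time).
#'
#' @param peakTable data.frame with columns `sample_id`, `time_h`,
#'   `compartment` (`"cells"` or `"medium"`), `analyte`, `peak_area`. See
#'   [readPeakTable()].
#' @param curves Named list of [CalibrationCurve-class] objects covering
#'   every analyte present.
#' @param context A [CellContext-class] (its `cellCount` is the
#'   normalization basis), or a data.frame of per-sample metadata with
#'   columns `sample_id` and `cell_count`.
#' @return data.frame with one row per (sample_id, time_h): columns
#'   `sample_id`, `time_h`, `cell_d3_nad`, `cell_d0_nad`, `medium_d3_nam`,
#'   `medium_d0_nam`, `medium_d4_nam` (pmol per 10^6 cells), `below_loq`,
#'   `out_of_range`.
#' @export
buildLabelingTable <- function(peakTable, curves, context) {
  stopifnot(is.data.frame(peakTable), all(c("sample_id", "time_h",
    "compartment", "analyte", "peak_area") %in% names(peakTable)))
  .checkAnalytes(peakTable$analyte)
  if (!all(peakTable$compartment %in% c("cells", "medium")))
    stop("compartment must be 'cells' or 'medium'")
  wrong <- merge(peakTable, .ANALYTE_MAP, by = "analyte")
  if (any(wrong$compartment.x != wrong$compartment.y))
    stop("analyte measured in the wrong compartment (NAD+ belongs to ",
      "'cells', Nam to 'medium')")
  key <- paste(peakTable$sample_id, peakTable$time_h, peakTable$analyte)
  if (anyDuplicated(key))
    stop("ambiguous peak table: duplicate (sample, time, analyte) rows: ",
      paste(unique(key[duplicated(key)]), collapse = "; "))

  cellCountFor <- function(sid) {
    if (methods::is(context, "CellContext")) return(context@cellCount)
    stopifnot(is.data.frame(context),
      all(c("sample_id", "cell_count") %in% names(context)))
    i <- match(sid, context$sample_id)
    if (is.na(i)) stop("no metadata row for sample '", sid, "'")
    cc <- context$cell_count[i]
    if (!is.finite(cc) || cc <= 0)
      stop("cell_count must be positive for sample '", sid, "'")
    cc
  }

  groups <- unique(peakTable[c("sample_id", "time_h")])
  groups <- groups[order(groups$sample_id, groups$time_h), , drop = FALSE]
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- peakTable[peakTable$sample_id == groups$sample_id[i] &
      peakTable$time_h == groups$time_h[i], , drop = FALSE]
    row <- list(sample_id = groups$sample_id[i], time_h = groups$time_h[i],
      cell_d3_nad = NA_real_, cell_d0_nad = NA_real_,
      medium_d3_nam = NA_real_, medium_d0_nam = NA_real_,
      medium_d4_nam = NA_real_, below_loq = FALSE, out_of_range = FALSE)
    nCells <- cellCountFor(groups$sample_id[i])
    for (j in seq_len(nrow(g))) {
      an <- g$analyte[j]
      curve <- curves[[an]]
      if (is.null(curve))
        stop("no calibration curve supplied for analyte '", an, "'")
      q <- quantifyPeak(curve, g$peak_area[j])
      field <- .ANALYTE_MAP$field[.ANALYTE_MAP$analyte == an]
      row[[field]] <- q$amount_pmol * 1e6 / nCells
      row$below_loq <- row$below_loq || q$below_loq
      row$out_of_range <- row$out_of_range || q$out_of_range
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a calibration-standards CSV
#'
#' Expected header: `analyte,amount_pmol,peak_area` (UTF-8, dot decimal).
#'
#' @param path File path.
#' @return data.frame of standards.
#' @export
readStandards <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "amount_pmol", "peak_area")
  if (!all(need %in% names(s)))
    stop("standards CSV must have header ", paste(need, collapse = ","))
  .checkAnalytes(s$analyte)
  s
}

#' Read an SRM peak-area CSV
#'
#' Expected header: `sample_id,time_h,compartment,analyte,peak_area`
#' (compartment `cells` or `medium`).
#'
#' @param path File path.
#' @return data.frame of peak areas.
#' @export
readPeakTable <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "compartment", "analyte", "peak_area")
  if (!all(need %in% names(p)))
    stop("peak-area CSV must have header ", paste(need, collapse = ","))
  p
}

#' Write a quantified-amounts CSV
#'
#' Long-format export of a labeling table: one row per measured analyte
#' with header `sample_id,time_h,compartment,analyte,
#' amount_pmol_per_1e6cells,below_loq,out_of_range`.
#'
#' @param labeling Labeling table from [buildLabelingTable()].
#' @param path Output file path.
#' @return Invisibly, the long-format data.frame written.
#' @export
writeQuantifiedTable <- function(labeling, path) {
  rows <- lapply(seq_len(nrow(labeling)), function(i) {
    r <- labeling[i, ]
    vals <- c(r$cell_d0_nad, r$cell_d3_nad, r$medium_d0_nam, r$medium_d3_nam,
      r$medium_d4_nam)
    keep <- !is.na(vals)
    data.frame(sample_id = r$sample_id, time_h = r$time_h,
      compartment = .ANALYTE_MAP$compartment[keep],
      analyte = .ANALYTE_MAP$analyte[keep],
      amount_pmol_per_1e6cells = vals[keep],
      below_loq = r$below_loq, out_of_range = r$out_of_range,
      stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(long)
}
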