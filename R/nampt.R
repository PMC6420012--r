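#' Specific Nampt activity from a lysate assay
#'
#' The lysate assay measures NMN formed from saturating nicotinamide
#' (50 uM) and PRPP (300 uM) over a fixed incubation; the specific
#' activity is product per hour per 10^6 cell-equivalents of lysate:
#' `product_pmol / time_h / cells * 1e6`. No substrate-depletion
#' correction is applied — at 50 uM Nam with excess PRPP the 1-h assay
#' stays in the initial-rate regime.
#'
#' @param productPmol NMN formed, pmol (>= 0).
#' @param timeH Incubation time, h (> 0).
#' @param cellsEquivalent Cell-equivalents of lysate input (> 0).
#' @return Activity, pmol per 10^6 cells per h.
#' @examples
#' specificActivity(150, 1, 1e6)    # 150
#' specificActivity(150, 1, 5e5)    # 300
#' @export
specificActivity <- function(productPmol, timeH, cellsEquivalent) {
  if (any(productPmol < 0)) stop("product amount must be >= 0")
  if (any(timeH <= 0)) stop("incubation time must be > 0")
  if (any(cellsEquivalent <= 0)) stop("cells equivalent must be > 0")
  productPmol / timeH / cellsEquivalent * 1e6
}

#' Total Nampt activity on the concentration basis
#'
#' Divides the per-cell specific activity by the mean cell volume (pL),
#' the same unit identity as [amountToConcentration()], yielding uM/h —
#' directly comparable with the in-cell synthesis rate R_S.
#'
#' @param specAct Specific activity, pmol per 10^6 cells per h.
#' @param cellVolume Mean cell volume, pL (> 0).
#' @return Activity in uM/h.
#' @examples
#' activityConcentration(150, 2)  # 75
#' @export
activityConcentration <- function(specAct, cellVolume) {
  amountToConcentration(specAct, cellVolume)
}

#' In-cell suppression of Nampt
#'
#' Ratio of the in-cell synthesis rate to the total lysate activity on the
#' same uM/h basis. Values well below 1 quantify how strongly the enzyme
#' is held back in the cell (feedback inhibition and/or limited Nam).
#'
#' @param rS In-cell synthesis rate, uM/h.
#' @param totalActivity Total Nampt activity, uM/h (> 0).
#' @return Unitless ratio `rS / totalActivity`.
#' @examples
#' suppressionRatio(33, 180)  # 0.183
#' @export
suppressionRatio <- function(rS, totalActivity) {
  if (any(totalActivity <= 0)) stop("total activity must be > 0")
  rS / totalActivity
}

#' Append Nampt activity to a flux table
#'
#' Computes each sample's total Nampt activity (uM/h) and suppression
#' ratio from a lysate-assay CSV/data.frame and joins them onto a flux
#' table.
#'
#' @param flux Flux table from [fluxTable()].
#' @param lysate data.frame (or CSV path) with columns `sample_id`,
#'   `product_pmol`, `time_h`, `cells_equivalent`.
#' @param metadata Metadata table with `sample_id` and `cell_volume_pL`.
#' @return `flux` with columns `total_nampt_activity_uM_h` and
#'   `suppression_ratio` appended.
#' @export
namptActivityTable <- function(flux, lysate, metadata) {
  if (is.character(lysate)) lysate <- utils::read.csv(lysate,
    stringsAsFactors = FALSE)
  need <- c("sample_id", "product_pmol", "time_h", "cells_equivalent")
  if (!all(need %in% names(lysate)))
    stop("lysate table must have columns ", paste(need, collapse = ","))
  i <- match(flux$sample_id, lysate$sample_id)
  j <- match(flux$sample_id, metadata$sample_id)
  if (anyNA(i) || anyNA(j))
    stop("every flux sample needs a lysate and a metadata row")
  spec <- specificActivity(lysate$product_pmol[i], lysate$time_h[i],
    lysate$cells_equivalent[i])
  act <- activityConcentration(spec, metadata$cell_volume_pL[j])
  flux$total_nampt_activity_uM_h <- act
  flux$suppression_ratio <- suppressionRatio(flux$r_s_uM_h, act)
  flux
}
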