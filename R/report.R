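#' Ordinary least-squares summary for cross-sample relationships
#'
#' Fits `y ~ x` with intercept and reports slope, intercept, the squared
#' Pearson correlation as R^2, and n — the form used to relate R_S, R_B,
#' NAD+ concentration and total Nampt activity across samples.
#'
#' @param x,y Equal-length numeric vectors (n >= 2); `x` must not be
#'   constant.
#' @return List of class `regressionSummary`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' regressSummary(c(1, 2, 3), c(2, 4, 7))
#' @export
regressSummary <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (stats::var(x) == 0) stop("degenerate regression: x is constant")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit))
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  structure(list(slope = b[2], intercept = b[1], r_squared = r2,
    n = length(x)), class = "regressionSummary")
}

#' @export
print.regressionSummary <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g x + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Dose-response summary of R_S versus medium Nam
#'
#' Tabulates synthesis rates over the tested medium Nam concentrations and
#' reports the saturating concentration: the smallest concentration whose
#' rate reaches at least `satFraction` (default 95%) of the maximum
#' observed rate. When only the highest tested concentration qualifies and
#' the rates are still strictly increasing there, the response is flagged
#' as not saturated (with a warning).
#'
#' @param conc Medium Nam concentrations, uM (>= 3 values).
#' @param rS Synthesis rates at those concentrations.
#' @param satFraction Fraction of the maximum defining saturation.
#' @return List: `table` (conc, r_s, ordered by conc),
#'   `saturating_conc` (uM), `saturated` (logical).
#' @examples
#' doseResponseSummary(c(0.1, 1, 2, 10), c(10, 96, 100, 101))
#' @export
doseResponseSummary <- function(conc, rS, satFraction = 0.95) {
  if (length(conc) < 3 || length(rS) != length(conc))
    stop("need >= 3 (concentration, rate) pairs")
  o <- order(conc)
  conc <- conc[o]; rS <- rS[o]
  thr <- satFraction * max(rS)
  qualify <- which(rS >= thr)
  satConc <- conc[qualify[1]]
  saturated <- TRUE
  if (satConc == conc[length(conc)] && length(conc) >= 2 &&
      all(diff(rS) > 0)) {
    saturated <- FALSE
    warning("rates still strictly increasing at the highest tested ",
      "concentration: response may not be saturated")
  }
  list(table = data.frame(conc_uM = conc, r_s = rS),
    saturating_conc = satConc, saturated = saturated)
}

#' Induction fold-change table
#'
#' Fold changes of total Nampt activity, R_S, R_B and NAD+ concentration
#' for each condition relative to the single baseline (uninduced) row.
#'
#' @param conditions data.frame with columns `label`, `total_activity`,
#'   `r_s`, `r_b`, `nad_conc`, and logical `baseline` marking exactly one
#'   row.
#' @return data.frame with the original columns plus `fold_activity`,
#'   `fold_r_s`, `fold_r_b`, `fold_nad`.
#' @examples
#' inductionTable(data.frame(
#'   label = c("uninduced", "induced"), baseline = c(TRUE, FALSE),
#'   total_activity = c(100, 600), r_s = c(40, 80), r_b = c(30, 60),
#'   nad_conc = c(500, 800)))
#' @export
inductionTable <- function(conditions) {
  need <- c("label", "total_activity", "r_s", "r_b", "nad_conc", "baseline")
  if (!all(need %in% names(conditions)))
    stop("conditions must have columns ", paste(need, collapse = ","))
  nb <- sum(conditions$baseline)
  if (nb != 1) stop("exactly one row must be marked baseline, found ", nb)
  b <- conditions[conditions$baseline, ]
  conditions$fold_activity <- foldChange(conditions$total_activity,
    b$total_activity)
  conditions$fold_r_s <- foldChange(conditions$r_s, b$r_s)
  conditions$fold_r_b <- foldChange(conditions$r_b, b$r_b)
  conditions$fold_nad <- foldChange(conditions$nad_conc, b$nad_conc)
  conditions
}
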