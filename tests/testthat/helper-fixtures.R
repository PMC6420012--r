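# Shared fixtures: all synthetic data are built in code at test time.

# Standards lying exactly on a line through the origin.
exactStandards <- function(analyte = "d3-NAD+", slope = 100,
                           amounts = c(0, 1, 2, 5)) {
  data.frame(analyte = analyte, amount_pmol = amounts,
    peak_area = slope * amounts, stringsAsFactors = FALSE)
}

# Reference labeling run (noiseless by default): the HepG2-like conditions
# the simulator defaults encode.
refParams <- function(...) {
  args <- list(...)
  if (is.null(args$noiseCv)) args$noiseCv <- 0
  do.call(kineticParams, args)
}

# Two-point worked-example records.
wt0 <- function() labelingTimepoint(0, cellD3Nad = 0, cellD0Nad = 1437)
wt3 <- function() labelingTimepoint(3, cellD3Nad = 276, cellD0Nad = 1179,
  mediumD3Nam = 48, mediumD0Nam = 264, mediumD4Nam = 4488)
refContext <- function() cellContext(4.04e5, cellVolume = 2.5,
  mediumVolume = 0.95, d4NamConc = 2)
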