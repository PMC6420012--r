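# nadflux

Quantitative analysis of NAD+ turnover in cultured mammalian cells from a
stable-isotope (d4-nicotinamide) labeling assay with LC-MS/MS readout.

Cells are switched to medium containing [2,4,5,6-D4]nicotinamide; newly
synthesized NAD+ carries three deuteriums, so selected-reaction-monitoring
peak areas resolve d3-NAD+ appearing (amount *a*) and d0-NAD+ disappearing
(amount *b*) over a labeling time *t*. The package implements the assay's
whole computational path:

* **Calibration & quantification** — per-analyte OLS calibration curves
  with limit-of-quantification and range flags (`fitCalibration`,
  `quantifyPeak`, `buildLabelingTable`).
* **Flux estimation** — R_S = a/t, R_B = b/t (pmol per 10^6 cells per h);
  absolute concentration via mean cell volume (pmol/10^6 cells ÷ pL = µM
  exactly); first-order half-life t½ = ln(2)·C/R_B
  (`estimateFluxes`, `amountToConcentration`, `halfLife`).
* **Validity checks** — negligible nicotinamide recycling (combined
  non-precursor medium Nam ≤ 10%), labeling-time linearity, tracer
  bioavailability equivalence (`recyclingCheck`, `linearityCheck`,
  `equivalenceCheck`).
* **Kinetic simulator** — five-pool ODE model of salvage labeling:
  Michaelis–Menten synthesis with NAD+ feedback inflation of the Nam Km
  (Km_eff = km0·(1 + C/Ki); 1 µM at zero NAD+, 25 µM at 500 µM NAD+),
  lumped first-order breakdown with isotope-resolved Nam release, noisy
  dataset generation, estimator-bias scans and parameter recovery
  (`simulateLabeling`, `generateDataset`, `biasScan`,
  `inductionScenario`, `parameterRecovery`).
* **Lysate Nampt activity & reporting** — specific activity on the same
  µM/h basis as R_S, suppression ratios, cross-sample regressions,
  dose–response and induction fold tables (`specificActivity`,
  `suppressionRatio`, `regressSummary`, `inductionTable`).

A thin command-line wrapper with verbs `calibrate`, `quantify`, `flux`,
`validate`, `simulate`, `generate`, `scan`, `report` lives at
`inst/scripts/nadflux.R`.

## Worked example

The reference labeling run: 4.04×10^5 HepG2-like cells (mean volume
2.5 pL) in 0.95 mL medium, 2 µM d4-Nam, 3 h.

```r
library(nadflux)

t0 <- labelingTimepoint(0, cellD3Nad = 0,   cellD0Nad = 1437)
t3 <- labelingTimepoint(3, cellD3Nad = 276, cellD0Nad = 1179,
                        mediumD3Nam = 48, mediumD0Nam = 264,
                        mediumD4Nam = 4488)
estimateFluxes(t0, t3, cellContext(4.04e5, cellVolume = 2.5))
#> FluxResult (NAD+ turnover)
#>   R_S: 92 pmol/10^6 cells/h (36.8 uM/h)
#>   R_B: 86 pmol/10^6 cells/h (34.4 uM/h)
#>   total NAD+: 1455 pmol/10^6 cells; [NAD+] = 582 uM
#>   half-life: 11.73 h; valid: TRUE
```

276 pmol of d3-NAD+ per 10^6 cells appeared and 258 disappeared from the
d0 pool over 3 h, giving synthesis and breakdown rates of 92 and
86 pmol/10^6 cells/h; the 2.5 pL cell volume turns the 1455 pmol total
into an absolute 582 µM, and the first-order half-life of the pool is
11.7 h. `valid: TRUE` is the recycling gate: medium Nam is still 93.5%
precursor (6.5% combined d3+d0), so released label was not meaningfully
re-incorporated.

The same numbers emerge from the simulator through the full pipeline
(peak areas → calibration → normalization → estimator):

```r
p  <- kineticParams(noiseCv = 0)           # reference study conditions
ds <- generateDataset(p, times = c(0, 3))  # vendor-style peak areas
lab <- buildLabelingTable(ds$peak_table, ds$curves,
                          cellContext(4.04e5, 2.5))
fluxTable(lab, ds$metadata)[, c(1:3, 7:8)]
#>   sample_id r_s_pmol_per_1e6cells_h r_b_pmol_per_1e6cells_h nad_conc_uM half_life_h
#> 1     sim01                      92                      86         582    11.72708
```

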