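---
title: "Measuring NAD+ synthesis and breakdown rates with a d4-nicotinamide flux assay"
author: "nadflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring NAD+ synthesis and breakdown rates with a d4-nicotinamide flux assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadflux)
```

## The assay

Mammalian cells make most of their NAD+ from nicotinamide (Nam) through
the salvage pathway, with Nam phosphoribosyltransferase (Nampt) as the
rate-limiting step, and degrade NAD+ back to Nam through consumers such as
PARPs and sirtuins. The flux assay this package implements swaps the
culture medium to one containing deuterated nicotinamide
([2,4,5,6-D4]Nam, "d4-Nam") at the same concentration the cells were
pre-incubated with. New NAD+ made from the tracer carries three deuteriums
(one ring position is lost on the way in), so LC-MS/MS in
selected-reaction-monitoring (SRM) mode can watch, over a labeling time
$t$:

* d3-NAD+ appearing in the cells (amount $a$),
* d0-NAD+ disappearing from the cells (amount $b$),
* d3-, d0- and d4-Nam in the medium (the breakdown products and the
  remaining precursor).

The rates are defined as

$$R_S = a/t, \qquad R_B = b/t,$$

in pmol per $10^6$ cells per hour. Dividing by the mean single-cell
volume $V$ (pL, from a Coulter-principle counter) converts any per-cell
quantity to an absolute concentration, because
$10^6\ \text{cells} \times 1\ \text{pL} = 1\ \mu\text{L}$ and
pmol/µL = µM. The half-life of the pool under first-order
(pool-proportional) breakdown is

$$t_{1/2} = \ln 2 \cdot C / R_B.$$

We use the first-order form rather than linear depletion $C/(2R_B)$
because proportional degradation is the natural model for a pool consumed
by enzymes far below saturation in NAD+, and because it reproduces the
assay's own worked numbers: $\ln 2 \cdot 500/30 = 11.55$ h at the
uninduced reference state, where the linear form would give 8.3 h.

## What the estimator estimates, and its validity conditions

$a/t$ and $b/t$ are **net isotopologue exchange rates**. They equal the
gross synthesis and breakdown fluxes only while two conditions hold:

1. **Negligible recycling.** Nam released by NAD+ breakdown (d3- and
   d0-Nam) must not be re-incorporated appreciably. `recyclingCheck()`
   computes the molar fractions of the three medium Nam isotopomers and
   passes when the combined non-precursor (d3+d0) fraction is at most 10%
   — a round, configurable codification of the reference run, where 6.4%
   at 3 h was accepted as negligible. No numeric cutoff is inherent to
   the assay, so the bound is explicit and adjustable.
2. **Tracer equivalence.** d4-Nam and d3-Nam must be used and degraded
   like unlabeled Nam. `equivalenceCheck()` is a descriptive
   tolerance-on-means check (default 15%, duplicate-level agreement), not
   a formal TOST; the assay's own evidence is descriptive too.

A third check, `linearityCheck()`, fits a through-origin line to a
d3-NAD+ time course and flags saturation (default $R^2 \ge 0.98$), the
symptom of labeling windows long enough for label re-degradation to bite.

Even with recycling negligible, the estimator systematically under-reads
the **gross** fluxes: freshly made d3-NAD+ is itself degraded during the
window, at a relative rate of roughly $k_B t/2$ (about 9% at 3 h for the
reference turnover). The medium d3-Nam measured at 3 h in the reference
run is direct evidence of this loss. The package therefore treats the net
exchange rates as the estimand — `estimateFluxes()` recovers them
exactly on noiseless data — and quantifies the gap to the gross fluxes
with `biasScan()`, which shows the underestimation deepening
monotonically with labeling time and steepening further when recycling is
enabled. Reading its output makes the case for the 2 µM / 3 h design: at
3 h the precursor still dominates the medium while the signal (276 pmol
of d3-NAD+ per $10^6$ cells) is far above the 0.1-0.4 pmol limits of
quantification.

## Quantification layer

`fitCalibration()` fits unweighted ordinary least squares per analyte
(`area = slope * pmol + intercept`); a 1/x weighting is available behind
an argument but off by default, since the printed curves span a modest
range where homoscedastic errors are a fair assumption. Curves with
$R^2 < 0.99$ are refused unless forced — "excellent linearity" is the
only fit-quality criterion the assay states, so the gate is explicit.
`quantifyPeak()` inverts the line, floors at zero, and **flags** rather
than censors: `below_loq` under the limit of quantification (default the
conservative 0.4 pmol when no per-analyte value is configured) and
`out_of_range` outside the standards' span. SRM transition settings are
provenance metadata only; they never enter the arithmetic.

## The kinetic simulator

`simulateLabeling()` integrates a five-pool ODE model (deSolve::lsoda,
rtol $10^{-8}$, atol $10^{-10}$), in absolute pmol internally and pmol
per $10^6$ cells at the interface:

* medium d4-, d3-, d0-Nam; cellular d0-, d3-NAD+;
* synthesis $j_S = V_{max} S/(K_{m,\mathrm{eff}}(C) + S)$ on the total
  accessible medium Nam $S$, apportioned across isotopomers by molar
  fraction (the d4 share scaled by an isotope-effect factor, default 1,
  per the tracer-equivalence evidence); d4-Nam consumption yields
  d3-NAD+;
* feedback $K_{m,\mathrm{eff}} = K_{m,0}(1 + C/K_i)$, a
  competitive-style linear inflation calibrated to the two published
  anchors for Nampt: $K_m$ = 1 µM at zero NAD+ rising to 25 µM at 500 µM
  NAD+, giving $K_i = 500/24 \approx 20.8$ µM. The cited inhibition has
  no published functional form; linear inflation is the simplest form
  through both anchors.
* lumped first-order breakdown $j_B = k_B C$ per isotopologue, releasing
  Nam of matching label into the medium (one $k_B$ for all consumers,
  matching the aggregate $R_B$ the assay measures);
* a `recycling` switch: off, released/carryover d3- and d0-Nam
  accumulate but are excluded from the substrate — the estimator's ideal
  reference condition.

The Nam moiety is conserved exactly across compartments (the ADP-ribose
half of breakdown leaves the balance), which the tests verify to
$10^{-6}$ relative on every run, together with the analytic solutions of
the decoupled limits ($k_B = 0$; recycling off, where
$\mathrm{d0\text{-}NAD^+}(t) = \mathrm{nad}_0 e^{-k_B t}$ regardless of
synthesis).

### Default parameters: the reference study conditions

The defaults of `kineticParams()` encode one reference labeling run,
HepG2-like cells under the standard design:

| parameter | default | origin |
|---|---|---|
| cells, medium | $4.04\times10^5$ cells, 0.95 mL | stated experimental conditions |
| d4-Nam | 2 µM | the assay design concentration |
| initial d0-NAD+ | 1437 pmol/$10^6$ cells (574.8 µM) | 3-h total (1455) minus net gain; volume below |
| cell volume | 2.5 pL | not printed for HepG2; chosen once so the NAD+ concentration (575 µM) sits inside the published 400-700 µM band |
| $K_{m,0}$, $K_i$ | 1 µM, 500/24 µM | the two feedback anchors |
| $V_{max}$, $k_B$ | 647.007 µM/h, 0.068460 /h | back-computed (Newton root-find on the noiseless model) so the 3-h run reproduces the reference exchange $a = 276$, $b = 258$ pmol/$10^6$ cells |
| d0-Nam carryover | 0.0026 µM | the measured 3-h medium d0-Nam (264) minus the 258 released by breakdown |
| noise CV | 0.05 | typical LC-MS peak-area repeatability |

Un-tuned consequences of that calibration agree with the independent
observations: the simulated 3-h medium composition is 0.6/5.6/93.8%
(d3/d0/d4) against the measured 1.0/5.4/93.6%; the model's steady state
sits at 597 µM NAD+ (band: 400-700) with a 10.1 h half-life (range:
3.9-11.5).

### Noise model and synthetic datasets

`generateDataset()` applies independent multiplicative log-normal noise
per observation with the configured CV, using the mean-preserving
parameterization ($\sigma^2_{\log} = \log(1+\mathrm{CV}^2)$, mean-log
$-\sigma^2_{\log}/2$), then pushes absolute amounts back through the
calibration curves to emit vendor-style peak-area tables, so synthetic
data exercise the entire pipeline. Fixed seeds give identical output.
What the generator does **not** emulate: chromatographic drift and
between-batch effects, correlated errors within an injection, isotopic
natural-abundance cross-talk between SRM channels (none is applied in
quantification either — the channels are treated as fully resolved, as
the assay does), cell growth during labeling, and intracellular Nam
compartmentation (transport is assumed fast; the assay measures medium
Nam only). Passing the recovery tests therefore demonstrates estimator
correctness under the stated error model, not robustness to structured
instrument artifacts.

A note on recovery precision: $R_S$ inherits the measurement CV directly
(it is one observation divided by time), but $R_B$ is the difference of
two large noisy d0-NAD+ readings (1437 and 1179 against a decrease of
258), so its per-dataset CV is ~38% at 5% measurement noise, and a mean
over 50 datasets still carries ~5% Monte Carlo error. Averaging
independent experiments — the study's own practice — is the remedy the
design offers; the package reports both rates' empirical CVs so users
can size replication accordingly.

### Induction phenomenology

`inductionScenario()` compares feedback steady states under clamped
medium Nam (routinely refreshed medium), solving
$V_{max}S/(K_{m,0}(1+C/K_i)+S) = k_B C$ in closed form. Scaling
$V_{max}$ 6-fold raises the model's $R_S$ only ~2.5-fold, with $R_B$
rising in exact step (steady state forces $R_S = R_B$) — the
fold-suppression the assay observed (6-fold activity, 2-fold rates). At
a true steady state the NAD+ fold equals the rate folds in this model;
the smaller observed NAD+ fold (1.6) is consistent with cells measured
before full relaxation and with consumers' saturation behavior the
lumped first-order breakdown does not resolve.

## Numerical and design choices

* Two-point estimation is the default (the protocol's design); the
  multi-timepoint through-origin slope (`fluxSlope()`) serves time-course
  data.
* A negative observed $b$ (d0-NAD+ apparently rising under noise) is
  clamped to zero with a warning and a validity flag — one noisy
  replicate must not halt a batch; a negative $a$ is an error, since
  label cannot vanish.
* Per-cell rates are the primary storage; µM-basis values are derived
  through the cell volume and carried alongside, never instead.
* The steady-state solver uses the cancellation-safe quadratic root, so
  weak-feedback limits ($K_i \to \infty$) stay accurate.
* Test and example problem sizes (3-9 h horizons, 50-dataset recovery
  studies) keep the full suite in a few seconds on one CPU.

## Limitations

The model lumps all NAD+ consumers into one first-order constant, ignores
the nicotinic-acid (Preiss-Handler) route, models no NMN/NR precursors,
and resolves no subcellular compartments — all deliberate matches to what
the assay itself measures (aggregate $R_B$, whole-cell concentrations,
salvage-only labeling). The printed per-cell-line panels and induced-cell
measurements are wet-lab observables; the package reproduces the assay's
arithmetic and its worked numbers, and provides property-level checks for
everything else.
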