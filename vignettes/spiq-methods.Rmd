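---
title: "Automated evaluation of direct-injection spICP-MS scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated evaluation of direct-injection spICP-MS scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiq)
```

## The measurement model

A single-particle ICP-MS acquisition is a sequence of intensities, one
per dwell interval $t_d$ (3 ms by default). Dissolved analyte produces a
continuous count rate; a nanoparticle that reaches the plasma is
vaporized and ionized within one (occasionally two) dwell intervals and
produces a discrete spike. The effective sample volume interrogated per
dwell is $\eta \, Q \, t_d$, where $Q$ is the sample flow rate and $\eta$
the transport efficiency — the fraction of nebulized particles that
actually reaches the plasma. With an ionic calibration slope $R$ (counts
per dwell per µg/L), these two facts give the whole quantification
chain:

* element mass of one event: $m = I_\mathrm{net} \, \eta Q t_d / R$;
* compound mass $m_c = m / f_m$ with $f_m$ the element mass fraction
  (Cu in CuO: $63.546/79.545 \approx 0.799$);
* spherical-equivalent diameter $d = (6 m_c / \pi \rho)^{1/3}$;
* number concentration $C_p = n_\mathrm{events} / (\eta V)$ over the
  analyzed volume $V$;
* ionic background concentration
  $C_\mathrm{ion} = (\bar{B} - a)/R$ from the trimmed background mean
  $\bar{B}$ and the calibration intercept $a$;
* total element content $= C_\mathrm{ion} + $ particulate content
  (exact by construction).

Direct injection replaces steady-state nebulization with a 300 µL loop
pushed at 500 µL/min, so the scan shows a transient plug: dead time, a
rise, a plateau of roughly loop volume / flow rate $= 36$ s, and a
washout tail. Evaluation is confined to a detected transient window.

## Particle/background discrimination

The discrimination procedure is deliberately simple and fully
deterministic:

1. the window is split into `n_pieces` (default 10) consecutive pieces
   whose lengths differ by at most one dwell (remainders go to the last
   pieces) — piecewise evaluation absorbs drift within a measurement;
2. per piece, all dwells start as background; for each of
   `n_iterations` (default 5) passes the mean and *sample* standard
   deviation of the retained dwells are computed, the limit is
   $\mathrm{mean} + k\sigma$ ($k \in \{3, 5\}$), and dwells strictly
   above the limit are removed;
3. the limit of the final pass is the piece's detection threshold;
   dwells above it are particle dwells, and maximal runs of particle
   dwells separated by at most `gap_tolerance` background dwells merge
   into one event.

Numerical conventions, chosen once and used consistently:

* $k\sigma$ is $k$ times the *absolute* sample SD added to the mean — a
  relative SD is dimensionless and could not be added to a count;
* points exactly at the limit remain background (strict `>` removal),
  which makes tie-breaking deterministic;
* the per-iteration limit sequence is non-increasing (trimming can only
  lower mean and SD), so the fixed 5-pass loop needs no convergence
  test; convergence earlier is harmless;
* a piece whose retained set falls below 2 dwells gets SD 0,
  threshold = mean, and a quality flag;
* the whole-window untrimmed mean is computed and reported for
  transparency but plays no role in trimming;
* all dwell indices are 1-based and windows/pieces are closed intervals
  `[start, end]`, the natural R convention;
* `gap_tolerance` defaults to 0 (only adjacent particle dwells merge);
  1 is appropriate when plume splitting across two 3 ms dwells matters.
  Both the merged event count and the raw above-threshold dwell count
  are reported, since either may be read as "particle number".

A known failure mode is a background at or below the electrical noise:
after trimming, the SD collapses and essentially every nonzero dwell is
called a particle. No correction is applied; the result carries a
`low_background` flag (default floor 0.1 counts/dwell).

## Calibration and transport efficiency

Ionic calibrations are ordinary least squares with a free intercept,
per matrix. The free intercept is deliberate: matrix blanks are real
(cell culture medium contributes dissolved copper of its own), and
clamping the intercept would push that blank into every sample. The
standards follow the 1, 2, 5, 10 µg/L design; a 0 µg/L blank is allowed
and useful.

Transport efficiency uses the particle-frequency method only: a
reference nanoparticle standard of certified diameter $d_\mathrm{ref}$,
density $\rho_\mathrm{ref}$ and mass concentration $C_\mathrm{mass}$
(NIST 8012 gold, diluted to tens of ng/L) is measured, and
$$\eta = \frac{\text{detected rate}}{(C_\mathrm{mass}/m_\mathrm{ref}) \cdot Q},
\qquad m_\mathrm{ref} = \tfrac{\pi}{6} d_\mathrm{ref}^3 \rho_\mathrm{ref}.$$
The default $d_\mathrm{ref}$ is the certified electron-microscopy mean
of 27.6 nm rather than the nominal 30 nm; the cube in $m_\mathrm{ref}$
makes this a ~30 % effect on $\eta$, and back-calculating published
water-matrix numbers (3580 detected events/min at 50 ng/L and
500 µL/min giving $\eta \approx 0.029$) is consistent with the certified
value. The nominal diameter remains one argument away. Mass-flux and
waste-collection efficiency methods are out of scope.

## Analyzed volume

"The actual volume used" is ambiguous between $Q \cdot t_\mathrm{window}$
and the loop volume. The package computes $Q \cdot t$ and caps it at the
loop volume by default (`cap_at_loop = TRUE`): with direct injection the
loop bounds the sample that can possibly pass the detector, and a
detected window slightly longer than the plug (rise and washout edges)
would otherwise dilute every concentration. For steady-flow
acquisitions, the cap is turned off.

## Transient window detection

No published rule exists for locating the plug, so the package defines
one: smooth the scan with a centered moving mean of width `min_run`
(partial windows at the edges keep it defined everywhere), take the
baseline as the median of the first and last 5 % of dwells and the
plateau as the median of the top decile of the smoothed series, and
return the longest contiguous run of at least `min_run` dwells whose
smoothed value exceeds baseline + `baseline_fraction` × (plateau −
baseline). A flat scan returns the full range. The defaults
(`baseline_fraction = 0.1`, `min_run = 50`) suit ionic-dominated
transients; when the plateau is carried mostly by particle spikes the
smoothed signal fluctuates strongly and a wider `min_run` (several
hundred dwells) is the right choice — the worked analyses in this
package use 500 for spike-dominated CuO scans. The rule is invariant
under positive rescaling of the intensities, and every run records the
parameters used.

## The simulator

The generator exists so that every stage can be validated against known
truth. Per dwell at envelope level $g(t) \in [0,1]$:

* background counts $\sim$ Poisson of
  $\lambda_b (1 + \text{drift}(t)) + R\, C_\mathrm{ion}\, g(t)$;
* particle arrivals $\sim$ Poisson of $C_p\, \eta\, Q\, t_d\, g(t)$;
* each arrival draws a diameter from a log-normal (median, geometric
  SD), and its ideal intensity — the exact inverse of the sizing
  formula — is Poisson-sampled (detector counting statistics) onto its
  dwell, optionally split over two adjacent dwells.

The envelope is a trapezoid with an exponential washout tail (time
constant fall/3) after a configurable dead time; the default
(2 s rise, 33 s plateau, 6 s fall after 5 s delay) integrates to 36
effective seconds, i.e. exactly one 300 µL loop at 500 µL/min, keeping
the loop-volume cap consistent with the planted concentration. A fixed
seed reproduces scans bit-identically.

Deliberate simplifications: no flicker (1/f) noise term beyond Poisson
counting statistics, no agglomeration or coincidence correction beyond
what Poisson arrivals naturally produce, no plasma/ionization physics,
no size-dependent transport. Passing recovery tests therefore shows the
evaluation chain is self-consistent at realistic count levels — not
that it is immune to real-matrix effects such as sensitivity drift
between calibration and sample, which the piecewise thresholding only
partially absorbs.

Dissolution experiments use shrinking-sphere kinetics on a finite
population: every diameter decreases linearly (nm/h), lost mass accrues
to the dissolved pool, and particles below a cutoff (default 10 nm)
dissolve entirely, so total element mass is conserved between pools
exactly. Media presets (water, BSA, hydrocarbonate buffer, lysosomal
fluid, Gamble's and enhanced Gamble's solutions, RPMI) bundle a
sensitivity factor, background level, starting dissolved concentration
and shrink rate that reproduce the qualitative matrix ranking — fastest
dissolution in the acidic lysosomal fluid, slowest in buffer, a high
copper blank in RPMI. They are illustrative defaults, not fitted
constants.

## Dissolution arithmetic

Digestion-based fractionation assumes the 1 mL sample splits into two
equal 500 µL halves after centrifugation, with dissolved ions
homogeneous across both at sampling: the ionic share of the total is
$2\,c_\mathrm{sup} / (c_\mathrm{sup} + c_\mathrm{pellet})$, clipped to
$[0, 1]$; the particulate share is its complement. Incomplete
sedimentation (density- and time-dependent) would bias the ionic share
upward; the estimator does not model it — the simulator is the place to
study that sensitivity. Fractions are computed per replicate, then
averaged.

Series summaries average the first and last `n_summary` (default 3)
timepoints, the "start of experiment" versus "after a week" comparison.
`fit_first_order_loss()` is a convenience single-rate summary — the
least-squares slope of log(observable) against time — and is not a
mechanistic model; shrinking-sphere decay of a polydisperse population
is not exponential, and the reported SE and $r^2$ say how far from
exponential a series is.

## Problem sizes and tolerances in the validation suite

The test suite validates each stage at sizes a desk run completes in
seconds: oracle-equivalence over 100 random 500–2000-dwell vectors
against an independently written naive transcription of the trimming
loop; null false-positive control over 50 seeds of 20,000 Poisson(10)
dwells (3σ calls ≤ 1 % of dwells; 5σ strictly fewer); and a
5000-event monodisperse 30 nm gold run at $\eta = 0.03$ for end-to-end
recovery (η and median size within 5 %, number concentration within
3·√N counting error). The 30 nm run keeps the per-dwell arrival rate
near 0.008 so that event pile-up (two arrivals merging into one
detected event) stays near 1 % — at the high count rates of real
direct-injection runs this coincidence loss is the dominant small bias
of frequency-based counting, and the 5σ margin is used there so that
background false positives (up to ~1 % of dwells at 3σ) do not swamp
the planted events. Scale invariance, mass conservation (ionic +
particulate constant to 10⁻⁹ relative in truth; total = ionic +
particulate to 10⁻¹² in every quantification) and kinetics recovery
(fitted loss rate within 2 combined SE of a reference fit on the truth
series; acidic preset strictly outpacing buffered) complete the suite.

## Known limitations

* Event counting is frequency-based; no dead-time or coincidence
  correction is applied, so number concentrations at high particle
  rates are biased low.
* Non-spherical particles are reported at their spherical-equivalent
  diameter.
* No drift correction across measurement days; the piecewise thresholds
  only absorb drift within one scan.
* The ionic background estimate inherits any particle contamination
  that survives trimming; at very high spike densities the trimmed
  means rise visibly.
* Isotopic interferences are the analyst's responsibility (the isotope
  is a label here).
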