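---
title: "Adaptive interference matrices for targeted 1H NMR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive interference matrices for targeted 1H NMR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquanmr)
```

## The quantification model

Targeted quantification in 1D ^1^H NMR uses one preselected *target signal*
per compound. The height $y_i$ observed at compound $i$'s target position is
not pure: it is the compound's own *reporter* contribution $x_i$
(proportional to concentration) plus interference from the tails of every
other compound's signals in the same region. With $k$ targeted compounds,
the per-spectrum model is a linear system

$$\bar{y}_n = \bar{\bar{m}} \, \bar{x}_n,$$

where column $j$ of the $k \times k$ interference matrix $\bar{\bar{m}}$
holds compound $j$'s calibration-spectrum heights, normalized so that the
reporter height is exactly 1 and sampled at all $k$ target positions
(`build_constant_matrix()`). The diagonal is therefore 1, all elements lie
in $[0, 1]$ for a well-designed library, and solving the system
(`solve_reporters()`, a direct dense solve) separates each target height
into its reporter part and its interference part. Concentrations follow as
$c_i = x_i \cdot \mathrm{rf}_i$ with a per-compound response factor
(micromolar per unit normalized reporter height), and the relative
interference $\Delta_i = (y_i - x_i)/y_i$ measures the fraction of the
target height that did not come from compound $i$.

A constant matrix is adequate when signal positions and line widths are
stable across spectra (drifts of about one 0.0002-ppm bin). Some compounds
violate this badly: in plasma collected with EDTA as the anticoagulant, the
two singlets of free EDTA (3.62 and 3.23 ppm) are pH-sensitive, drift by
up to about ten bins between spectra, vary in line width, and tower over
nearby metabolite signals. Using nominal-geometry interference elements for
such a compound mis-models its tails, and every metabolite under those
tails inherits the error.

The adaptive ("improved") mode fixes this per spectrum. For each compound
declared *variable*, a guided peak picker locates all of its signals
(`characterize_compound()`), measuring apex position, height, and full width
at half maximum. Its calibration spectrum is then re-synthesized as a sum of
Lorentzians,

$$I(\delta) = \sum_s h_s \frac{(w_s/2)^2}{(\delta - \delta_{0,s})^2 + (w_s/2)^2},$$

with the observed positions and widths but library-fixed *relative* heights
(so the reporter normalization stays well defined; observed heights enter
only through $\bar{y}_n$). The matrix $\bar{\bar{m}}_n$ is updated in two
places: the compound's **column** is re-sampled at the current target
positions, and the **row** of its re-optimized target position is re-sampled
for *all* compounds, because moving the target position changes which part
of every other compound's calibration spectrum is sampled. All other
elements — the constant portion — are copied from the constant matrix
unchanged. The pictorial division into a constant and a variable portion
leaves open whether only the column or also the row moves; updating both is
the self-consistent choice, since a column-only update would read $y$ at the
new position while modelling interference at the old one.

## Peak picking and width estimation

`pick_target_signal()` takes the discrete argmax over local maxima inside
the search window (strictly greater than the nearest non-equal neighbours;
plateaus resolve to the lowest bin; ties resolve by height, then proximity
to the nominal position, then lower ppm). A signal is *found* when its apex
exceeds 3 × noise, where the noise level is the SD of a signal-free region
after linear detrend (`estimate_noise()`, default region 10–11 ppm). A
three-point parabolic sub-bin apex is stored for inspection, but matrix
sampling deliberately stays on-grid: bin-level positions keep the MAD and
positional-deviation statistics in integer bins and make runs reproducible.

`estimate_fwhm()` scans outward from the apex to the two half-height
crossings. The crossing is interpolated on the *reciprocal intensity* scale:
for a Lorentzian, $1/I$ is linear in the squared distance from the centre,
so this recovers the width of an ideal on-grid Lorentzian to machine
precision, where linear interpolation carries a systematic bias of a few
tenths of a percent. That bias matters: a relative width error $\epsilon$
perturbs far tails by about $2\epsilon$, and for a metabolite whose target
receives interference comparable to its own height this propagates to a
concentration error of the same order. Exact on-bin half-height hits are
taken without interpolation, so symmetric linear (triangular) peaks with
integral half-widths are still measured exactly. If the intensity rises
substantially (by more than 10% of the apex, guarding against single noisy
bins) before crossing half height — an overlapped shoulder — that side is
abandoned and the other side's width is doubled, flagged asymmetric.

Line widths convert between Hz and ppm through the spectrometer frequency
(1.2 Hz = 0.002 ppm = 10 bins at 600 MHz on the 0.0002-ppm grid).

## The adaptation deadband

Even in a noiseless spectrum, the measured width of a signal in a crowded
region is contaminated by the tails of its neighbours (relative bias around
0.2% for the simulated EDTA panel). Re-synthesizing a calibration spectrum
from such a measurement when the geometry has not actually changed would
replace exact library values with slightly wrong ones. `adapt_matrix()`
therefore only re-derives a compound's elements when the observation
*deviates* from the library: any apex more than half a bin
(`pos_tol_ppm = 1e-4`) from its nominal position, or any width off by more
than 5% (`width_tol`). Below the deadband the constant elements are the
better-characterized model; above it the real drift dominates the
measurement bias by an order of magnitude. A variable compound whose
signals are not found at all falls back to its constant column and row, and
the spectrum is flagged.

Reading the target height at the detected apex (rather than the nominal
position) is the matching choice on the $\bar{y}_n$ side: when a target
jitters by a bin, the apex height equals the reporter contribution while
the nominal-bin height underestimates it. When no local maximum clears the
detection limit — including the case where a strong interferer's tail slope
swamps the target's own curvature — the height is read at the nominal
position, which is exactly where the matrix row models it.

## Quality indicators

Computed by `qc_report()` over a quantified dataset, per compound:

* **Occurrence** — fraction of spectra with the reporter above the
  detection limit ($x_i > 3 \times$ noise, strict). Conventional flags at
  5% (reportable) and 90% (reliable).
* **Positional deviation** — smallest whole-bin radius around the dataset
  median covering at least 95% of observed target positions. The quantile
  rule (smallest symmetric integer radius, lower median for even series) is
  chosen to be deterministic and conservative; one bin is the typical
  metabolite scale.
* **MAD profile** (`mad_positions()`) — per-spectrum |position − median| in
  bins; drifting signals such as free EDTA reach around ten.
* **Degree of interference** — $F_q$, the fraction of spectra where
  $\Delta_i$ exceeds $q$, reported at $q = 0.05$ and $0.50$ and split by
  interference source: the modelled interference
  $\sum_{j \ne i} m_{ij} x_j$ decomposes exactly into a metabolite part and
  a non-metabolite (EDTA-like) part, and
  $\Delta_{met} + \Delta_{nonmet} = \Delta$ holds to the solver residual.
  Spectra with undefined $\Delta$ (zero target height) leave the
  denominator and are counted in the report. Traffic light per source:
  red $F_{0.50} > 0.50$, yellow $F_{0.50} \le 0.50$ and $F_{0.05} > 0$,
  green $F_{0.05} = 0$.
* **Mode comparison** (`compare_means()`) — per-compound
  $(\mu_a - \mu_b)/\mu_b$ of mean concentrations between two runs, used to
  quantify what ignoring a drifting interferer costs.

Negative solutions are reported as-is with the below-detection flag rather
than clipped or re-solved under non-negativity constraints: preserving
linearity keeps the computation identical to the stated model, and negative
reporters are informative (they coincide with below-detection calls).
The solve aborts when the estimated condition number exceeds `1e8`
(configurable), naming the most strongly coupled compound pair — a silently
unstable solve is worse than failure.

## The simulator and what it does (not) emulate

`edta_plasma_preset()` encodes the study conditions the package is
validated under, on the standard grid (0.0002 ppm/bin, 600 MHz, axis −0.05
to 4.25 ppm):

* ten named toy metabolites with plausible plasma concentrations and
  response factors, single 1.5-Hz Lorentzian singlets, several placed
  0.02 ppm (100 bins) from the free-EDTA singlets so they sit in its tails
  (dimethylsulfone, acetylcarnitine, carnitine; ornithine additionally
  under a stable Mg–EDTA tail, histidine under a Ca–EDTA tail);
  `n_metabolites = 54` appends generic singlets over 0.9–2.2 ppm to
  reproduce production-scale dimensions;
* free EDTA: two high-intensity singlets (3.62, 3.23 ppm; relative heights
  1 / 0.85) with independent uniform integer drifts up to ±10 bins and
  line widths drawn uniformly from 1.0–2.2 Hz per spectrum — the drifting
  interferer;
* Ca–EDTA (3.13/2.55 ppm) and Mg–EDTA (2.69/3.21 ppm): intense but stable,
  modelled as ordinary constant non-metabolites;
* a fixed TSP internal-standard singlet at 0 ppm (1.1 Hz, the shim-quality
  line width);
* per-signal Gaussian jitter with SD 0.4 bins for constant compounds
  (95% of draws within ±1 bin, the typical metabolite scale), log-normal
  planted reporter heights (CV 0.3 for metabolites, 0.5 for free EDTA),
  and i.i.d. Gaussian bin noise (SD 0.005, giving metabolite SNR of
  roughly 100–600 and essentially 100% occurrence, the typical outcome);
* the 4.0–4.2 ppm region is kept signal-free and `noise_region =
  c(4.02, 4.18)` points the noise estimator at it.

Each spectrum is the sum of planted reporter heights times
reporter-normalized Lorentzian shapes evaluated with the drawn geometry, so
the planted $x$ is exactly the compound's contribution at its (shifted)
reporter position and noiseless recovery is testable to near machine
precision. Randomness comes from one RNG stream keyed by the seed with a
documented draw order (spectrum-major; per compound: height, per-signal
shift, per-signal width; then the noise vector), making datasets
bit-reproducible.

Deliberately *not* emulated: multiplet J-structure, correlated baselines
and macromolecule background, pH-to-shift physics (drift is drawn, not
modelled), phasing/binning artifacts, and protein-binding effects. Passing
tests therefore demonstrate the algebra, the adaptation logic, and the
statistics on Lorentzian mixtures with known truth — not robustness to
every artifact of real plasma spectra.

## Problem sizes and numerical tolerances

The validation suite uses 200-spectrum datasets for recovery and direction
checks and one 772-spectrum, 58-compound run to exercise production-scale
throughput (about ten seconds for the adaptive mode on one core; timing is
logged, never asserted). Key tolerances: solver residual
$\le 10^{-9} \cdot \max(1, \|y\|_\infty)$; noiseless end-to-end recovery
within $10^{-8}$ relative; adaptive-mode mean-concentration error within
0.5% under full drift; interference decomposition conserved to $10^{-12}$;
FWHM round trip within 5% noiseless and 15% at SNR 50.

## Known limitations

* One signal per metabolite: overlapped multiplets are not deconvolved, and
  compounds absent from the library contribute unmodelled interference.
* Reading target heights at the detected apex carries the classical
  interference-with-positional-deviation error: when an interferer's tail
  slope is comparable to a weak target's own curvature, the combined
  spectrum's apex can sit one bin off the preselected position while the
  matrix row stays at that position, costing up to about 0.1% in the
  recovered reporter. The positional-deviation indicator is exactly the
  tool that flags compounds exposed to this.
* The adaptation measures each variable signal independently; severely
  overlapping *variable* signals (closer than about one line width) would
  bias each other's measured geometry.
* Response factors are treated as given library constants; absolute
  calibration against the internal standard is upstream of this package.
* Spectra are assumed phased, baseline-corrected and binned on a uniform
  grid before they arrive.
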