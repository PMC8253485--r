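# aquanmr

Targeted metabolite quantification in binned 1D ¹H NMR spectra, with
per-spectrum adaptation of the interference model for signals that drift.

## The problem

Targeted NMR metabolomics quantifies each compound from **one preselected
signal**. In a crowded biofluid spectrum that signal's observed height
*y&#7522;* is the compound's own *reporter* contribution *x&#7522;*
(proportional to concentration) plus interference from the tails of every
other compound's signals. With *k* targeted compounds this is a linear
system per spectrum *n*:

```
ȳₙ = m̿ · x̄ₙ
```

where column *j* of the *k × k* interference matrix **m̿** holds compound
*j*'s calibration spectrum, normalized to unit reporter height and sampled
at all *k* target positions (diagonal = 1). Solving the system separates
reporter heights from interference; concentrations follow via per-compound
response factors, and Δ&#7522; = (y&#7522; − x&#7522;)/y&#7522; measures
the interference each target received.

A constant matrix works while signal positions and line widths are stable
(drift ≈ 1 bin of 0.0002 ppm). It fails for compounds like **free EDTA**
in plasma drawn with EDTA as the anticoagulant: two intense, pH-sensitive
singlets (δ 3.62, 3.23) drift up to ~10 bins and change width between
spectra, sitting on top of metabolite signals such as acetylcarnitine,
carnitine and dimethyl sulfone. This package implements the adaptive fix:
each drifting compound's signals are located per spectrum by guided peak
picking (apex, height, FWHM), its calibration spectrum is re-synthesized
from Lorentzian line shapes with the observed geometry, and the affected
column and row of the matrix are re-derived before solving:

```
ȳₙ = m̿ₙ · x̄ₙ
```

Quality indicators (occurrence above the 3×noise detection limit,
positional deviation in bins, degree of interference F_q split into
metabolite and non-metabolite sources) flag which compounds are reliable,
and a mode comparison quantifies what ignoring the drift would cost.
A simulator with exact ground truth generates EDTA-plasma-like datasets
for validation.

## Worked example

```r
library(aquanmr)

cfg <- edta_plasma_preset(n_spectra = 50, seed = 1)   # drifting free EDTA + toy panel
sim <- simulate_dataset(cfg)

rec_improved <- quantify_dataset(sim$spectra, sim$library, sim$targets,
                                 mode = "improved",
                                 noise_region = cfg$noise_region)
subset(rec_improved, spectrum_id == "sim0001" &
         compound_id %in% c("alanine", "acetylcarnitine", "carnitine", "free_edta"),
       c(compound_id, y, x, delta, delta_nonmet, conc_uM))
#>        compound_id          y          x        delta delta_nonmet   conc_uM
#> 1          alanine  0.8362727  0.8360073 0.0003173821 2.152800e-04 292.60257
#> 8  acetylcarnitine  1.4523397  1.1180365 0.2301824918 2.285113e-01  11.18037
#> 9        carnitine  1.3464169  0.7982037 0.4071644817 4.066127e-01  39.91019
#> 11       free_edta 77.1913448 77.1832061 0.0001054353 6.191676e-06        NA
```

In this spectrum 23% of acetylcarnitine's and 41% of carnitine's target
height came from interference — almost all of it from EDTA
(`delta_nonmet`) — and was removed before converting reporter heights to
micromolar concentrations (`conc_uM`; EDTA itself is modelled but never
interpreted quantitatively, hence `NA`).

What would ignoring the EDTA signals cost? Quantify with a metabolite-only
constant matrix and compare mean concentrations:

```r
met <- which(vapply(sim$library, `[[`, "", "compound_class") == "metabolite")
rec_const <- quantify_dataset(sim$spectra, sim$library[met], sim$targets[met, ],
                              mode = "constant", noise_region = cfg$noise_region)
cmp <- compare_means(rec_const, rec_improved)
head(cmp[order(-cmp$rel_deviation), ])
#>        compound_id    mean_a     mean_b rel_deviation
#> 5  dimethylsulfone  11.24408   8.343876    0.34758417
#> 3        carnitine  55.05023  41.422393    0.32899679
#> 1  acetylcarnitine  11.58865   8.769286    0.32150472
#> 8        histidine 111.10854  85.706349    0.29638630
#> 10       ornithine  76.95014  63.876942    0.20466216
#> 7          glycine 265.63551 256.024265    0.03754038
```

Every metabolite under an EDTA tail would be overestimated — by 20–35%
here — because the unmodelled tail height is attributed to the metabolite.
The QC report summarizes reliability per compound:

```r
qc <- qc_report(rec_improved)
qc[qc$compound_id %in% c("alanine", "acetylcarnitine", "free_edta"),
   c("compound_id", "occurrence", "positional_deviation_bins",
     "F0.05_nonmet", "F0.50_nonmet", "interference_nonmet")]
#>        compound_id occurrence positional_deviation_bins F0.05_nonmet F0.50_nonmet interference_nonmet
#> 1          alanine          1                         1            0         0.00               green
#> 8  acetylcarnitine          1                         1            1         0.04              yellow
#> 11       free_edta          1                        11            0         0.00               green
```

All compounds occur in 100% of spectra; metabolite positions stay within
±1 bin while free EDTA wanders ±11 bins — exactly the regime the adaptive
matrix is for.

A command-line front end wraps the same pipeline
(`simulate | quantify | qc | compare`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "aqua.R", package = "aquanmr"))')" \
  quantify --library lib.json --targets targets.tsv --spectra spectra/ \
  --mode improved --noise-region 4.02:4.18 --out results.csv
```

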