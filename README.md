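# dualmlc

Patient-specific QA tooling for VMAT delivered through a
stacked-and-staggered **dual-layer MLC** (29 proximal + 28 distal pairs
of 10 mm leaves at half-pitch offset, 5 mm effective resolution), for
medical physicists commissioning or auditing the leaf-tip model of their
treatment planning system.

The physics in one paragraph: rounded leaf ends transmit radiation
through the tip region, which planning systems absorb into the
**dosimetric leaf gap (DLG)** — the geometric gap `g` behaves as
`g + DLG`.  On a dual layer the tip transmission depends on **leaf
trailing**: with the second layer's tip a distance `t` behind the
defining tip, the edge behaves like a single rounded tip for `t ≳ 5` mm
but approaches a mono-block edge (lower, even negative DLG) as `t → 0`.
In a sweeping-gap test the corrected chamber ratio is linear in the gap,
`y = (g + DLG)/L`, so the DLG is minus the x-intercept of the
least-squares line.  A planning system with a fixed built-in DLG (0.1 mm
here, not user-editable) then shows a systematic mean dose difference
`DD = 100·(D_calc − D_meas)/D_max,meas` in QA; because leaf positions are
stored at 0.1 mm resolution, an effective DLG can still be *assigned* by
opening every bank by `(DLG_emp − 0.1)/2`, restricted to the
`0.1 + 0.2k` mm grid.  The package finds `DLG_emp` as the zero crossing
of mean DD versus DLG and verifies the result with the global gamma
index (2%/2 mm, 10% threshold).

What the package provides:

* DICOM RT Plan read/write for dual-layer leaf sequences (0.1 mm
  serialization rounding, layers identified by pair count) and a JSON
  fixture format;
* aperture decomposition into 5 mm strips with gap-width percentiles and
  trailing-class percentages;
* leaf-sequence editing: single-layer conversion with 5 mm tracking
  retraction, symmetric leaf opening, sweeping-gap (and trailing
  sweeping-gap) test sequences;
* sweeping-gap DLG extraction with transmission correction;
* dose-difference and global gamma verification (compiled, oracle-tested
  search) with pooled histograms;
* DLG tuning (grid evaluation, zero crossing, grid assignment);
* a synthetic plan generator plus a trailing-aware leaf-tip dose engine,
  so the whole pipeline runs end to end without machine access.

## Worked example

```r
library(dualmlc)

## 1. sweeping-gap test: simulate readings, correct, fit
m  <- TipModel()                       # synthetic tip model
rd <- simulateSweepReading(seq(2, 20, 2), t = NULL, m, "proximal")
fitDlg(rd$g, correctedRatio(rd, tLayer = 0.004))
#> DlgFitResult: DLG = 0.420 mm (slope 8.333e-03 /mm, intercept 3.500e-03,
#>   R^2 = 1.000000, n = 10)

## 2. aperture statistics of a synthetic prostate-class VMAT plan
p <- generateVmatPlan("small", nArcs = 3, nCpPerArc = 40, seed = 42)
planGapTrailingStats(p)
#> Gap width (mm): median 18.0 [p25 13.5, p75 23.2]  (unweighted)
#> Trailing classes (% of open edges):
#>   proximal defining:  15.0 (0<t<5)   27.2 (t>=5)
#>   distal defining:    21.9 (0<t<5)   26.6 (t>=5)
#>   complete overlap:    9.3 (t=0)

## 3. assign an empirical DLG to the 0.1 + 0.2k mm grid
assignDlg(0.97)
#> $assigned_dlg
#> [1] 0.9
#> $per_bank_opening
#> [1] 0.4
```

The slope of the fitted line is `1/L = 1/120` per mm, its intercept
`DLG/L`; the gap median near 18 mm and the five trailing-class
percentages summing to 100 describe how often each layer defines the
aperture edge and how far the other layer trails.  The last call shows
the assignment rule: an empirical DLG of 0.97 mm is realized as 0.9 mm
by opening each bank 0.4 mm.

`runStudy(studyConfig(), seed = 1)` chains the whole pipeline on
synthetic plans — statistics, single-layer conversion, baseline
verification, per-layer tuning, re-verification — and prints the
recovered per-layer DLGs, the pooled DD before/after tuning and the
gamma pass rates.  See the vignette (`vignettes/dlg-calibration.Rmd`)
for the model, its assumptions and all numerical choices.

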