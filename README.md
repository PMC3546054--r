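# shuttleQuant

Single-cell quantification of stress-induced transcription-factor
nucleocytoplasmic shuttling from fluorescence time-lapse microscopy.

## What it is for

Stress-responsive transcription factors such as yeast Crz1p, Msn2p and
Msn4p report signalling state through their subcellular localization:
under continuous stress a cell may show **no response**, repeated short
**nucleocytoplasmic oscillations** (bursts of 2–3 min), or **permanent
nuclear localization** after a stochastic lag. shuttleQuant is for
researchers analysing such experiments: it converts image stacks (or
precomputed per-cell trajectory tables) into per-cell and population
statistics, and ships a ground-truthed synthetic-data generator so the
whole chain can be validated without any experimental data.

## The method

Per cell and frame, with selection done in a Gaussian-smoothed frame:
the brightest in-region pixel plus in-region pixels within 3 px form the
**nucleus**; the 90 brightest remaining cell pixels form the **cytosol**.
The localization trajectory is

    l(t) = median(I_nucleus) / median(I_cytosol) - 1

so no accumulation sits near 0 and the value is invariant to global
intensity rescaling. Event detection applies a 5-frame centred moving
average, a strict threshold of 0.28, and run-length cleanup (runs
shorter than 5 frames ≈ 20 s are flipped, record-boundary runs exempt).
From the cleaned binary state track come per-cell metrics — time to
first nuclear localization (censored for non-responders), total nuclear
time in the observation window, event count, and the
no-response / only-oscillating / permanent classification — and
population outputs: instantaneous fraction-localized curves,
entry-time-ordered localization matrices, and Mann–Whitney U
comparisons (exact by enumeration up to 8 per group, otherwise
tie/continuity-corrected normal approximation).

## Worked example

```r
library(shuttleQuant)

scenario <- SimScenario(nCells = 80, seed = 11L)   # 60 min at 4 s/frame
x <- detectStates(simulatePopulation(scenario))    # simulate + binarize
metrics <- cellMetrics(x)
head(metrics, 3)
#>   cell_id responded first_localization_time total_nuclear_time n_events
#> 1  cell_1      TRUE                    1020                924        5
#> 2  cell_2      TRUE                     456                956        6
#> 3  cell_3      TRUE                    1108               2492        1
#>     classification
#> 1 only_oscillating
#> 2 only_oscillating
#> 3        permanent

summarizeCondition(metrics, x, label = "115 uW (synthetic)")
#> PopulationSummary '115 uW (synthetic)': 80 cells
#>   classes: no_response=9, only_oscillating=53, permanent=18
#>   median total nuclear time: 21.8 min
#>   median time to first localization: 4.9 min (9 of 80 censored)
```

`cell_3` entered the nucleus at 1108 s and stayed (one event, 2492 s
nuclear, classified permanent); cells 1–2 oscillate in short bursts.
The summary medians use responders only for the first-localization time
and report the censored count rather than imputing it. Comparing a
slower condition (median lag 32 min instead of 20):

```r
y <- detectStates(simulatePopulation(
  SimScenario(nCells = 80, lagMedian = 1920, seed = 12L)))
mannWhitney(cellMetrics(y)$total_nuclear_time,
            metrics$total_nuclear_time, alternative = "two.sided")
#> Mann-Whitney U test (normal_approx, two.sided)
#>   U = 2677 (n1 = 80, n2 = 80), p = 0.07394
```

Image-based entry points (`renderFrames()`, `extractTrajectories()`,
`expressionResponse()`), table IO (`readTrajectories()`,
`writeTrajectories()`), the one-call `runPipeline()` and a thin command
line (`inst/scripts/shuttlequant.R` with subcommands
`simulate | extract | analyze | stats | compare | run`) are documented in
the package help and the vignette
`vignettes/quantifying-nuclear-shuttling.Rmd`. A small synthetic example
table ships as `inst/extdata/synthetic_trajectories.tsv`.

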