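---
title: "Quantifying transcription-factor nucleocytoplasmic shuttling from time-lapse microscopy"
author: "shuttleQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-factor nucleocytoplasmic shuttling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuttleQuant)
```

## The measurement problem

Stress-responsive transcription factors such as yeast Crz1p, Msn2p and
Msn4p shuttle between cytoplasm and nucleus, and the *dynamics* of that
shuttling — a single permanent entry, repeated short bursts, or no response
at all — carry the signalling information. In a time-lapse fluorescence
experiment each immobilized cell is imaged continuously (one frame every
~4 s for 60 min or more), and the quantity of interest per cell and frame
is the degree of nuclear accumulation of a GFP-tagged factor.

shuttleQuant implements the full quantification chain:

1. **Image quantification** — nucleus/cytosol pixel selection and the
   localization trajectory;
2. **Event detection** — filtering, thresholding and run-length cleanup
   into a binary nuclear/cytoplasmic state track;
3. **Per-cell metrics and classification**;
4. **Population summaries** and nonparametric comparisons;
5. A **synthetic-data generator** that produces ground-truthed
   trajectories, rendered image stacks and reporter-expression traces, so
   that every stage can be validated end to end.

## The localization trajectory

For each cell region (segmentation is delegated: regions come from a
labelled mask and are constant over time, because cells are immobilized on
the cover glass), each frame is Gaussian-smoothed and, *in the smoothed
frame*:

* the brightest in-region pixel and all in-region pixels within a
  Euclidean radius of 3 px of it form the **nucleus** (29 pixels before
  clipping to the region) — in these cells the nucleus reliably contains
  the intensity maximum once any accumulation occurs;
* the 90 brightest remaining cell pixels form the **cytosol**. Using a
  fixed pixel count rather than "everything else" suppresses fluctuations
  caused by dark vacuoles and slightly erroneous cell contours.

The localization value at each time point is

$$\ell(t) = \frac{\mathrm{median}\, I_\mathrm{nucleus}(t)}
                 {\mathrm{median}\, I_\mathrm{cytosol}(t)} - 1,$$

so that no accumulation gives $\ell \approx 0$ and $\ell$ is invariant
under global intensity rescaling.

Two choices here were genuinely open and are worth recording:

* **Measure on original or smoothed intensities?** Selection happens on
  the smoothed frame, but the medians are taken on the *original*
  intensities by default (`measureOn = "original"`): smoothing is a
  selection substrate, and measuring on blurred values would bias the
  nuclear median toward the blur scale. The alternative is one switch
  away.
* **Tie-breaks.** The brightest-pixel tie and the tie at the k-th cytosol
  intensity are broken by row-major scan order — deterministic and
  documented, so selections are bit-reproducible.

The smoothing sd defaults to `sigma = 2` px (a nucleus-scale blur for
~60X/EM-CCD imaging of yeast); it is configurable and none of the
downstream logic depends on its exact value.

## From trajectory to events

Event detection is deliberately simple and transparent
(`detectStates()`):

1. a centred **moving average** of 5 frames (~20 s); at the record
   boundaries the window truncates to the frames that exist — no values
   are invented;
2. **thresholding** at 0.28, *strictly above*, so a value exactly at the
   threshold is cytoplasmic; raising the threshold can only remove
   nuclear frames;
3. **run cleanup**: nuclear runs shorter than 5 frames become
   cytoplasmic, then — on the updated signal — cytoplasmic runs shorter
   than 5 frames become nuclear. The order matches the listing order of
   the rule; runs touching either record boundary are exempt, because
   records routinely start or end mid-event and flipping a truncated run
   would fabricate state. The pass pair is iterated to a fixed point, so
   `cleanRuns()` is idempotent and the record interior never contains a
   run shorter than `minRun`.

For a clean step of amplitude at least twice the threshold, the centred
5-frame mean crosses the threshold within $\lceil 5/2 \rceil = 3$ frames
of the true onset; in practice the error is 0–1 frames (this bound is
checked exhaustively in the test suite).

## Per-cell metrics and classes

Within an observation window (default 60 min):

* **responded** — at least one nuclear run;
* **time to first nuclear localization** — time of the first frame of the
  first nuclear run; censored (`NA`) for non-responders;
* **total nuclear time** — nuclear frames × frame interval; an event
  straddling the window end counts as an event, but only its in-window
  frames contribute time;
* **classification** — `permanent` if the final maximal run is nuclear
  and lasts at least `permanenceTail` (default 600 s: "sustained to the
  record end" needs a quantitative cut, and 10 min is long compared with
  the 2–3 min bursts while short compared with the record); otherwise
  `only_oscillating` if any event exists, else `no_response`.

Population medians of the time to first localization are computed over
**responders only**, with the censored count reported alongside — at weak
stimuli only a minority of cells respond within the window and their
median alone can look deceptively fast, so the censored cells must stay
visible but are never imputed.

The population curve (`fractionLocalized()`) is the *instantaneous*
fraction of cells in the nuclear state: a cumulative reading would make
transient population peaks (typical for an oscillatory factor that
responds and withdraws) impossible. An optional 5-point display smoother
is emitted as a separate column and never feeds statistics.

## Mann–Whitney U comparisons

Metric distributions are compared with the Mann–Whitney U test
(`mannWhitney()`): rank-based, no distributional assumption — appropriate
since total-nuclear-time and first-localization distributions are strongly
non-Gaussian. With at most 8 observations per group and no ties the null
distribution of U is enumerated exactly (at most
$\binom{16}{8} = 12870$ arrangements, desk scale); otherwise the normal
approximation with tie correction and continuity correction is used. The
test suite verifies the approximation against enumeration
($|\Delta p| \le 0.02$ at $n_1 = n_2 = 8$) and both branches against
`stats::wilcox.test` as an independent reference.

## What the synthetic generator emulates

`simulatePopulation()` draws, per cell, one of three archetypes:

| archetype | model |
|---|---|
| `no_response` | baseline throughout |
| `only_oscillating` | renewal process: exponential inter-burst gaps (`burstRate`, default 0.2/min), burst lengths uniform on 120–180 s |
| `permanent` | cytoplasmic until a log-normal lag, nuclear to the end |

and emits $\ell(t)$ as `baselineLoc` (0) or `nuclearLoc` (0.8, i.e. a
nucleus-to-cytosol ratio of 1.8) per true state plus i.i.d. Gaussian noise
(`noiseSd`, default 0.05). Defaults mirror the blue-light stress setting:
4 s frames, 60 min records, populations of ~100 cells (experiments used
80–258), and an archetype mixture (0.2/0.5/0.3) resembling a responsive
wild-type population in which most cells respond and a subpopulation
localizes permanently.

Choices that the data constrain only loosely:

* **Lag distribution.** Published population curves show right-skewed,
  positive lag spreads but no distributional form; we use a log-normal
  parameterized by its median (so recovery experiments can set the median
  directly) with `lagSdlog = 0.5`, which gives an interquartile spread of
  roughly 0.7–1.4 × median, comparable to the spread of measured
  first-localization times.
* **Burst process.** Only the typical burst duration (2–3 min) is
  constrained; the renewal-process form (exponential gaps, uniform
  lengths) is a modelling choice. Near-zero gaps occasionally merge two
  bursts on the 4 s sampling grid; the stored ground truth keeps the
  merged run.
* All randomness flows from the scenario seed through `withr::with_seed`;
  identical `(scenario, seed)` pairs are bit-identical.

`renderFrames()` turns ground-truth states into image stacks: cells are
filled discs (radius 7 px, 149 pixels) with a centred disc nucleus
(radius 3 px, 29 pixels), so after nucleus removal 120 cytosolic
candidates always remain; the nucleus is multiplied by `nuclearGain`
(default 1.8) when localized. Optional shot noise draws each pixel from a
Poisson with the noise-free value as mean; at the default intensities
(cytosol 200 counts) the induced noise on the median-ratio localization
value is well below 0.05 sd, so round-trip checks at a nominal noise of
0.05 are conservative. The renderer makes no attempt to mimic vacuoles,
brightfield contrast or photobleaching — segmentation and illumination
artefacts are explicitly out of scope, so passing round-trip tests
validate the *quantification* chain, not segmentation robustness on real
images.

`simulateExpression()` emulates the slow transcriptional-reporter readout
(whole-cell, background-subtracted mean fluorescence sampled every 10 min
for 5 h after a 40 min stress pulse): induced cells rise monotonically in
expectation after a per-cell log-normal lag with saturating kinetics;
uninduced cells stay flat. For the reporter response both an absolute
background-subtracted difference and a trace re-zeroed to its first time
point are available (`expressionResponse(mode=)`); the absolute difference
is the default.

## Numerical and validation choices

* Times are stored in seconds; reports render minutes. Coordinates are
  1-based (row, column) matrix indices.
* Trajectory tables are UTF-8 TSV with a commented metadata header,
  written at full double precision (`%.17g`), so write/read cycles are
  bit-exact; spreadsheet import is read-only.
* Validation problem sizes: selection oracles on 1000 random regions;
  onset bound on 500 random steps; cleanup checked exhaustively over all
  $2^{1..14}$ binary strings; U-test agreement over 1000 random draws at
  $n_1 = n_2 = 8$; lag recovery on 200-cell permanent-only populations
  over 120 min records (so that even a 32 min median lag is essentially
  uncensored); a full render→extract→detect round trip on a 100-cell
  mixed stack of 900 frames. These sizes make every check reproducible on
  a laptop in minutes.

## Worked example

```{r example}
scenario <- SimScenario(nCells = 80, seed = 11L)
x <- detectStates(simulatePopulation(scenario))
metrics <- cellMetrics(x)
summarizeCondition(metrics, x, label = "115 uW (synthetic)")
```

The per-cell table feeds straight into comparisons:

```{r compare}
y <- detectStates(simulatePopulation(
  SimScenario(nCells = 80, lagMedian = 1920, seed = 12L)))
mannWhitney(cellMetrics(y)$total_nuclear_time,
            metrics$total_nuclear_time, alternative = "two.sided")
```

## Known limitations

* Cell segmentation and tracking are not provided; regions come in as
  labelled masks and are assumed constant (immobilized cells).
* Thresholding with run cleanup is the detection model; no HMM or
  changepoint alternative is offered.
* Censoring is reported, not modelled — no survival-analysis treatment of
  first-localization times.
* The renderer's disc geometry is a deliberate idealization; results on
  rendered stacks bound what the pipeline can do on clean data, not on
  images with segmentation errors, drift or bleaching.
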