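---
title: "Methods: wavelet QRS detection, delineation and beat classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet QRS detection, delineation and beat classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavecg)
```

This vignette describes the processing model implemented by `wavecg`, the
parameters that matter, the numerical conventions, and the design choices
made where the design was genuinely open. It is the companion to the
function reference; nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The signal model

A single-channel ECG sampled at rate $f_s$ (canonically 360 Hz, 11-bit,
about 1 mV R waves) is decomposed with a 10-level dyadic discrete wavelet
transform using the Daubechies db6 wavelet. The transform is realized as
the standard Mallat filter bank: at each level the running approximation is
convolved with the 12-tap analysis low-pass and high-pass filters and
downsampled by two, after symmetric (mirror) extension of the boundaries.
Level-$k$ detail coefficients represent the band roughly
$[f_s/2^{k+1}, f_s/2^k]$. At 360 Hz:

| component | band (Hz) | physiological content |
|-----------|-----------|----------------------|
| D1, D2    | 45–180    | EMG noise, most powerline interference |
| D3–D5     | 5.6–45    | QRS complex energy |
| D6–D10    | 0.18–5.6  | P and T waves, ST segment |
| A10       | < 0.18    | baseline wander, DC |

Three operations are exposed on a decomposition: `dwt_component()` (one
component back-projected to a full-length time-domain signal),
`dwt_reconstruct()` (sum of a chosen subset), and perfect reconstruction
(keeping everything), which the tests require to hold to a relative
$L_2$ error below $10^{-8}$; the double-precision filter bank leaves
orders of magnitude of headroom below that bound.

Denoising (`denoise_ecg()`) is defined as reconstruction without D1, D2
and A10. No coefficient thresholding is applied inside the kept bands:
component removal *is* the denoiser. Consequences worth knowing:

* baseline wander is only removed below $f_s/2^{11} \approx 0.18$ Hz;
  respiratory wander near 0.3 Hz survives largely intact (it does not
  disturb detection, which operates on D3–D5);
* at 360 Hz most 60 Hz powerline energy falls in D2 and is removed; at
  lower sampling rates it would not be.

## QRS detection

`detect_r_peaks()` chains four steps:

1. the *region signal* $D_3 + D_4 + D_5$;
2. thresholding $|region| > \theta$ with
   $\theta = 0.15 \cdot \max|region|$. The absolute value is used because
   wavelet detail sums are oscillatory and their sign depends on lead
   polarity; the threshold is *relative*, which makes detection exactly
   invariant to positive rescaling of the input (a tested property);
3. one search window of 160 ms centred on each supra-threshold run's
   absolute peak ("around the QRS area" is read as centring);
4. the R-peak is the index of the maximum denoised value inside each
   window (`polarity = "positive"`, the default, for upright-R leads;
   `"absolute"` for inverted leads), and peaks closer than the 200 ms
   refractory period are merged keeping the larger amplitude — physiology
   forbids a second ventricular depolarization inside that interval, and
   amplitude dominance is the standard disambiguation.

The threshold maximum is global over the record. For long nonstationary
recordings a per-segment variant would be preferable; it is deliberately
not the default because the global rule is the simplest reproducible
reading and the thresholding is relative.

### Tunable parameters

| parameter | default | unit | role |
|-----------|---------|------|------|
| `threshold_frac` | 0.15 | — | detection threshold relative to max |
| `window_ms` | 160 | ms | R search window per candidate run |
| `refractory_ms` | 200 | ms | minimum R-R separation |
| `q_search_ms` / `s_search_ms` | 83.3 / 138.9 | ms | Q/S trough windows (30/50 samples at 360 Hz) |
| `onoff_search_ms` | 55.6 | ms | QRS onset/offset windows (20 samples) |
| `t_range_ms` | 83.3–444.4 | ms | T-peak range right of R (30–160 samples) |
| `t_on_search_ms` / `t_off_search_ms` | 97.2 / 138.9 | ms | T onset/offset windows (35/50 samples) |

All delineation windows are stored in milliseconds and converted to samples
at the record's rate, so the canonical sample counts are recovered exactly
at 360 Hz while other rates scale consistently.

## Delineation conventions

All indices are 1-based (R convention) and windows are inclusive index
ranges. The rules, with their tie-breaks (fixed so results are
bit-reproducible):

* **Q**: minimum value in the window left of R; ties → closest to R.
* **S**: minimum value right of R; ties → closest to R. "Negative maximum"
  morphology is read as the most negative value, the standard Q/S trough.
* **QRS onset/offset**: index of minimum $|x_{i+1} - x_i|$ in the window
  left of Q (right of S); ties → farthest from the complex. This unifies
  the two natural readings ("pick $n$ samples beyond Q/S" and "minimum
  slope") into one testable rule.
* **T peak**: maximum signed value in the T range anchored at R (anchoring
  at R rather than S is a documented choice; the range is configurable);
  ties → earliest. An absolute-value option exists for inverted T waves.
* **T onset/offset**: minimum value in the windows flanking the T peak;
  ties → farthest from T.

Windows that would leave the record produce absent (`NA`) landmarks rather
than errors; downstream feature extraction drops such beats with a warning.

Two delineation subtleties deserve honesty. First, on a *smooth* waveform
the flattest-slope rule is nearly degenerate: the discrete first difference
almost vanishes both next to the Q/S trough (depending on sub-sample phase)
and anywhere the signal is isoelectric, so the argmin can move several
samples under tiny perturbations. On real ECGs the rule is anchored by
genuinely sloped P-tail and ST morphology. Second, on a perfectly flat
baseline the T onset/offset minima sit at the far window edges by the tie
rule. Both behaviours are exercised explicitly in the unit tests.

## Per-beat features

Eight features per beat: previous RR interval (the first beat receives the
record-mean RR so the vector stays complete), the denoised-signal
amplitudes at Q, R, S and T, the QRS duration
(`qrs_off − qrs_on`), the QT interval measured `qrs_on → t_off`
(the conventional QT; ending at the T peak instead is a configurable
alternative we did not take) and the ST interval `qrs_off → t_off`. The
single previous-RR feature keeps the descriptor at exactly eight
dimensions alongside the four amplitudes and three durations.
Normalization is z-scoring with training-set statistics only
(`normalize_features()` persists and re-applies them); constant columns
pass through unscaled with a warning.

## Classifiers

The MLP is implemented from its update equations: one sigmoid hidden layer
(default 10 units), a sigmoid output unit per class with one-hot targets,
squared-error loss, and per-sample delta-rule updates
$x_{ij} \leftarrow x_{ij} + \eta\,\delta_j a_i$ with
sigmoid-derivative $\delta$s. Bias units are included in both layers — the
bare weighted-sum formulation has none, but a bias-free sigmoid network
cannot shift its decision boundaries and is not a serious classifier.
Defaults: $\eta = 0.01$, 500 epochs with early stopping after 10
plateau epochs. Weight initialization and the per-epoch shuffle are drawn
from one seeded RNG stream, so training is exactly reproducible; the
analytic gradient is verified against central finite differences to
$10^{-5}$ in the tests.

The SVM is a maximum-margin kernel classifier solved by `e1071`'s SMO
implementation (one-vs-one multiclass), behind a thin wrapper fixing the
kernel vocabulary: `"quadratic"` (polynomial degree 2), `"polynomial"`
(degree 3) and `"rbf"` (default — all three are selectable since no single
kernel is canonical for this task). Inputs are assumed pre-normalized, so
the solver's internal scaling is disabled.

The train/test protocol for the synthetic experiments is a seeded
stratified 70/30 split; no protocol is canonical here, so it is stated
everywhere a number is reported.

## Evaluation metrics

`match_beats()` performs greedy nearest-neighbour one-to-one matching
within a tolerance (default 50 ms — strict and common in the wavelet-QRS
literature; the 150 ms AAMI convention is one argument away). Pairs are
ranked by absolute time difference with deterministic tie-breaks (earlier
reference, then earlier detection). Matched pairs are TP, unmatched
detections FP, unmatched references FN; TN is zero by convention because
beat detection has no defined negative event.

The ratios (in percent): Se $=$ TP/(TP+FN), +P $=$ TP/(TP+FP),
DER $=$ (FP+FN)/TP (which may exceed 100), accuracy
$=$ (TP+TN)/(TP+FP+TN+FN). Specificity is provided in two variants:
the `"ratio"` form TN/(TP+FP) exactly as tabulated in the detection
literature this chain follows (non-standard, hence a note on use), and the
conventional `"standard"` TN/(TN+FP). Report formatting offers both
round-half-up and truncation at two decimals, because published tables mix
the two.

Undefined ratios (zero denominators) are reported as `NA` rather than 0 or
100, with a message.

## The synthetic generator

`generate_ecg()` builds each beat as a sum of Gaussian bumps whose
amplitudes (mV), centres (ms relative to R) and widths are class-specific:

* **N** — narrow QRS (~80 ms morphological duration), with a P wave, a
  small atrial-repolarization (Ta) dip before Q and a gentle ST hump after
  S. The two micro-waves give the PQ and ST segments genuine slope
  zero-crossings, which is what pins QRS onset/offset on an otherwise
  smooth template (see the delineation caveat above);
* **LBBB / RBBB** — widened QRS (~150 ms) with class-specific R/S balance
  (RBBB carries the deeper S);
* **Paced** — a narrow (σ = 2.5 ms) stimulus spike on a broad pacing
  afterpotential 85 ms before a wide ventricular complex. The spike is
  mostly D1/D2 content and is largely removed by denoising, as a real
  pacing artifact would be.

Per-beat amplitude jitter (5 % s.d.), RR variability (3 bpm s.d. around 60
bpm), and three noise presets — `clean` (0/0/0), `moderate`
(0.15 mV baseline wander at 0.3 Hz, 0.05 mV powerline at 60 Hz, 0.02 mV
white) and `noisy` (0.30/0.10/0.05) — emulate the benchmark regime at
moderate and poor signal quality. Everything is driven by one seed and is
bit-reproducible.

Ground truth: R, Q, S and T truths are the analytic bump centres. QRS
onset/offset and T onset/offset truths are computed at generation time by
applying the boundary rules to the *denoised noiseless* template anchored
at the true R position — the morphological boundary of a smooth waveform
is not otherwise well defined, and the flattest-slope criterion is only
meaningful in the denoised domain where the chain applies it. Tests
against these boundary truths therefore verify anchoring and window
arithmetic, not an independent morphological notion of onset; the peak
landmarks provide the template-independent check.

What the generator does **not** emulate: ectopy and rhythm disturbances,
biphasic or inverted T waves, electrode motion artifacts, QRS morphology
drift within a class, or multi-lead projections. Passing the synthetic
suite shows the chain is implemented correctly under the stated regime; it
does not certify detection rates on clinical recordings.

## Numerical choices and degenerate inputs

* Convolutions run through an FFT padded to 2-3-5-smooth lengths (mixed
  radix FFTs degrade badly on prime lengths).
* Per-level coefficient counts follow
  $\lfloor (n + \mathrm{filterlen} - 1)/2 \rfloor$, the convention of
  even-phase downsampling of a full convolution; stored per-level lengths
  make the inverse exact for odd lengths.
* Symmetric extension handles windows larger than the signal by repeated
  reflection, so any depth is feasible for $n \ge 2$; an all-zero region
  signal yields zero candidate windows (with a message), an empty `keep`
  set reconstructs a zero signal (with a warning), and empty R-peak lists
  delineate to empty tables.
* Decomposition depth below 10 is accepted for denoising with a warning
  that the final approximation then spans a wider low band.
* Problem sizes in the shipped tests were chosen to keep the default run
  around half a minute: perfect reconstruction on signals up to 8192
  samples, 200 random fixtures for the detector invariants, a ~500-beat
  record for end-to-end detection, and 4 × 100 beats for classification.

## Known limitations

Single-lead only; no search-back or adaptive thresholding (deliberately —
fidelity to the described chain over maximal detection performance); the
flattest-slope onset rule is phase-sensitive on smooth signals; QT is not
rate-corrected; headline database-wide accuracy figures require the
original benchmark recordings and a specified train/test protocol, and are
therefore supported only as a user-supplied-data workflow
(`read_ecg_record()` on WFDB files → `detect_r_peaks()` →
`detection_report()`), not as package tests.
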