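---
title: "Methods: quality scoring of bone decalcification protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality scoring of bone decalcification protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decalQC)
```

# The problem

Bone must be decalcified — the hydroxyapatite mineral dissolved away —
before cryosectioning and imaging. The choice of decalcifier (strong
inorganic acid, weak organic acid, or a chelator such as EDTA) and the
immersion time control a trade-off: fast protocols risk macerating the
organic matrix, gentle ones take days. `decalQC` implements the
quantitative machinery for comparing protocols across three imaging
modalities (H&E histology, immunofluorescence, Raman microspectroscopy):
spectral preprocessing and unmixing, objective quality statistics, and the
aggregation of semi-quantitative observer scores into a single ranked
score per protocol. Protocols are identified by codes such as `E_24`
(25 % EDTA, 24 h) or `HF_8` (hydrochloric + formic acid, 8 h); the 20
valid decalcifier × duration combinations are listed by
`protocol_codes()`.

# The spectral model behind the synthetic generator

No public raw scans accompany the study design this package serves, so a
first-class synthetic generator defines the test conditions. It renders
Raman spectra as sums of Gaussian bands on a polynomial baseline with
additive i.i.d. Gaussian channel noise:

* **Calcified bone**: phosphate bands at 431, 583, 959 and 1072 cm⁻¹
  (the 959 cm⁻¹ ν₁ phosphate band dominating the spectrum), superimposed
  on the collagen signature.
* **Decalcified bone**: collagen only — proline/hydroxyproline at
  855/876/921 cm⁻¹, the broad amide III and amide I envelopes (rendered as
  single wide Gaussians at 1281.5 and 1663 cm⁻¹, the midpoints of their
  conventional ranges), CH₂ deformation at 1450 cm⁻¹ and the CH stretch
  region near 2935 cm⁻¹.
* **Bone marrow** adds cellular bands: nucleic acid at 780 cm⁻¹ and the
  sharp phenylalanine ring-breathing band at 1003 cm⁻¹.

Numerical defaults, chosen once: the axis is 400–3200 cm⁻¹ at 2 cm⁻¹
spacing (1401 channels, matching a dispersive instrument with its spectral
centre near 2000 cm⁻¹); sharp bands have FWHM 12 cm⁻¹ and the amide
envelopes 60 cm⁻¹, which visually reproduces the morphology of bone
spectra; amplitudes are arbitrary counts with the 959 cm⁻¹ band at 100 and
noise SD 4 by default, so only ratios (e.g. SNR) are meaningful. Cosmic
rays are single-channel positive excursions of 20–30× the noise SD,
injected per spectrum with a configurable probability at interior
channels. Image scans are convex mixtures of k endmember spectra with a
configurable fraction of pure pixels (the assumption N-FINDR needs), and
the generator returns the ground-truth endmembers, abundances and spike
positions for testing.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: Poisson shot noise and detector etaloning
(noise is purely additive Gaussian), spatial correlation between
neighbouring pixels, band-shape changes from chemical degradation (damage
only scales noise here), and paraffin or embedding signals. Observer score
tables are simulated as `round(2·(quality + ε))` clamped to {0, 1, 2} with
Gaussian observer noise ε — real rater behaviour (systematic leniency,
parameter-specific biases) is richer than this.

# Preprocessing chain

Compact bone: wavenumber calibration → cosmic-ray removal → per-pixel SNIP
baseline correction → per-pixel mean normalization → channelwise median
spectrum. Bone marrow: calibration → cosmic-ray removal → truncation to
400–1800 and 2800–3100 cm⁻¹ → per-pixel rubber-band correction, feeding
the unmixing step.

**Calibration.** The silicon band is located as the global maximum in
480–560 cm⁻¹ and refined by three-point parabolic interpolation — the
cheapest sub-grid method, accurate to a few hundredths of a cm⁻¹ for a
well-resolved band; the axis shift is `520 − observed`. A flat or
edge-peaked calibration window is an error.

**Cosmic-ray removal.** A single-channel spike produces two consecutive
first differences that are both extreme and opposite in sign. Channels
where both flanking differences exceed a modified z-score (median/MAD) of
8 with a sign change are repaired by linear interpolation of the
neighbouring channels. Requiring the sign change keeps steep band flanks
(same-signed consecutive differences) from being mistaken for spikes; the
detector is idempotent, and only interior channels can be flagged.

**SNIP.** At clipping pass `m = 1…400`, every interior channel
`i ∈ [m+1, n−m]` is clipped to `min(y[i], (y[i−m]+y[i+m])/2)`, a
simultaneous update from the previous pass. Edge channels keep their
values. This interior-only rule is deliberate: clamping the window indices
at the spectrum edges instead looks harmless but is catastrophically wrong
for sloped backgrounds — with a growing window the clamped edge value is
dragged toward the far end of the spectrum and the distortion cascades
inward until the whole baseline collapses to the global minimum (a linear
ramp rising 28 counts over the axis is flattened entirely). Under the
interior-only rule a linear ramp is preserved to machine precision while
narrow bands are still eroded from the baseline estimate. The baseline
never exceeds the input; a constant spectrum corrects to exactly zero.

**Rubber band.** The baseline is the lower convex hull of the
(wavenumber, intensity) points (Andrew's monotone chain), interpolated
linearly between hull vertices; the corrected spectrum is nonnegative and
touches zero at every vertex.

**Order of operations** follows the processing narrative the pipeline
models: calibration before despiking, and mean normalization before the
median spectrum.

# N-FINDR unmixing

Pixels are projected onto the leading k−1 principal components; N-FINDR
seeks the k pixels spanning the maximum-volume simplex there, since under
the linear mixing model with pure pixels present the vertices of the data
simplex are the endmembers. Implementation choices that make runs
reproducible: a seeded random initial set; replacement sweeps over
endmember slots and pixels in index order; a replacement accepted only on
a strict volume increase (ties therefore keep the incumbent set); at most
20 sweeps, stopping early when a full sweep makes no change. The volume
trace is returned and is non-decreasing by construction. A scan whose
pixel cloud has rank below k−1 (e.g. all pixels identical) is a degenerate
input and errors.

Abundances are per-pixel nonnegative least squares against the endmember
spectra without a sum-to-one constraint — robust to residual intensity
variation after baseline correction, at the cost of abundances that are
relative rather than fractional. False-colour images min–max scale one
abundance plane to [0, 1] on the row-major pixel grid; the endmember with
the strongest rubber-band-corrected 780 cm⁻¹ band is suggested as the
nuclei channel. k defaults to 2 for marrow scans and is otherwise the
user's choice.

# Quality statistics

**Four-step SNR.** (1) Noise: SD of the residuals of a polynomial fit
(default order 1 — the silent region is short and near-linear; the order
is exposed) over 1900–2300 cm⁻¹, where tissue has essentially no Raman
bands. (2) The 1300–1600 cm⁻¹ region around the C–H deformation band at
~1450 cm⁻¹ is smoothed with a Savitzky–Golay filter (window 11, order 3 —
gentle enough to attenuate a 12 cm⁻¹-FWHM band by only a few percent).
(3) The smoothed region is SNIP-corrected — smoothing feeds the SNIP
input — with the pass count capped at one less than the region length
(beyond half the region length a pass has no interior channels and is a
no-op), and the maximum corrected value is the signal. (4) SNR =
signal/noise. The statistic is exactly invariant under intensity scaling,
and a noiseless silent region (noise < 1e−12) is a degenerate-input error
rather than an infinite SNR. For image scans, the pixel with the highest
maximum intensity is summarized (`scan_snr()`), and SNR must be computed
before truncation removes the silent region.

**Phosphate detection.** Prominence of each phosphate band is the maximum
smoothed, SNIP-corrected intensity within ±15 cm⁻¹ of its centre. The
spectrum is calcified iff the 959 cm⁻¹ prominence exceeds 5× the
silent-region noise. The factor 5 turns the visual "bands present/absent"
call into a noise-relative test: on synthetic spectra the corrected noise
floor reaches ≈3× noise SD in a ±15 cm⁻¹ window while a 959 band at the
generator's default amplitude stands ≥10× above it, so the two classes are
cleanly separated whenever the band amplitude is at least ~7× the noise
SD.

**SII.** `100/(LP·DG)` per fluorescence channel, strictly decreasing in
both laser power and detector gain; summed over channels for a
per-protocol brightness proxy. It is a relative index only.

# Scoring scheme

Observers assign integer scores 0–2 per parameter (2 best; half points are
not permitted). Aggregation for one modality and protocol: mean over
observers within each (batch, parameter) cell → mean over batches per
parameter → sum over parameters → divide by 2 × (number of parameters
actually evaluated). Normalizing by the *attainable* maximum (rather than
the cohort maximum, which would force the best protocol to 1.0 by
definition) keeps scores comparable across modalities with different
parameter counts; parameters missing everywhere (e.g. marrow lost during
preparation) simply drop out of both the sum and the normalizer.

A (protocol, batch) cell is flagged for a third observer when two
observers' totals over their shared parameters differ by strictly more
than 1. Acquisition settings map to set-2 scores by cohort tertiles per
channel and parameter — highest laser power or gain scores 0, lowest
scores 2, consistent with the endpoint convention — summed, normalized
per batch by the attainable maximum and averaged over batches. SNR values
pool across the cohort per tissue and map to 0/1/2 by tertiles; adding a
constant to all SNRs leaves scores unchanged. Exact ties across a cohort
cannot be ranked and receive the middle score 1 with a warning.

A modality total is the mean of its set-1 and set-2 normalized scores; the
final protocol score is the mean over the modalities present, with the
*population* standard deviation across modalities as its error bar (the
spread of 2–3 modality values is descriptive, not an estimate of a larger
population's variance).

# Pipeline and reproducibility

`run_pipeline()` wires the stages over a JSON config (unknown keys are
rejected) and writes plain-text artifacts plus `manifest.json` with MD5
hashes of every file. All randomness derives from the config seed via
per-stage offsets, and numeric output is serialized at 17 significant
digits, so identical configs give byte-identical artifacts. The shipped
demo config compares a three-protocol cohort (E_24, T_12, HF_8 at latent
qualities 0.9/0.7/0.4 — a cohort of three exercises every tertile level)
with 8×8 marrow scans, 4×4 compact-bone scans, two batches and two
observers; these sizes keep a full run to a few seconds while every stage
still operates on non-trivial input.

# Known limitations

* The synthetic noise model is additive Gaussian; shot-noise-limited
  spectra will have wavenumber-dependent noise the SNR statistic's silent
  region cannot see.
* N-FINDR's single-pixel replacement ascent is not guaranteed to reach the
  global volume maximum on noisy data without pure pixels; on the
  generator's noise-free mixtures it provably does (verified against
  exhaustive search in the test suite).
* The LP/DG and SNR tertile mappings fix only the endpoints of the stated
  convention; other monotone three-level rules are defensible and would
  shift mid-cohort scores by at most one level.
* Scores are treated as exchangeable across observers; no inter-rater
  reliability statistics are computed.
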