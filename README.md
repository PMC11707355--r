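# decalQC

Quantitative quality control for **bone decalcification protocols** assessed
by multimodal imaging — label-free Raman microspectroscopy, H&E histology and
immunofluorescence.

Before hard tissue like mouse long bone can be cryosectioned and imaged, the
hydroxyapatite mineral must be removed (decalcified) with a strong acid, a
weak organic acid or a chelator such as EDTA. Decalcifying too aggressively
or too long damages the remaining collagen matrix and cells, which degrades
every downstream imaging modality. `decalQC` implements the analysis
machinery needed to compare decalcification protocols objectively:

- **Raman preprocessing** — wavenumber calibration against the silicon band
  at 520 cm⁻¹ (sub-channel peak location by parabolic interpolation),
  automated cosmic-ray removal (modified z-score of first spectral
  differences), SNIP baseline correction (400 growing-window clipping
  passes), mean normalization, per-image median spectra, truncation to the
  fingerprint (400–1800 cm⁻¹) and CH-stretch (2800–3100 cm⁻¹) regions and
  rubber-band (lower convex hull) baseline correction.
- **N-FINDR spectral unmixing** — endmember extraction by maximum simplex
  volume in the (k−1)-dimensional PCA projection, nonnegative least-squares
  abundance maps and false-colour images; the endmember rich in the
  780 cm⁻¹ nucleic-acid band visualizes cell nuclei in bone marrow.
- **A four-step SNR statistic** — noise as the standard deviation of the
  polynomial-detrended *silent region* (1900–2300 cm⁻¹, where tissue has no
  Raman bands); signal as the maximum of the Savitzky–Golay-smoothed,
  SNIP-corrected C–H deformation band region (1300–1600 cm⁻¹);
  SNR = signal/noise.
- **Phosphate-band detection** — the hydroxyapatite bands at 431, 583, 959
  and 1072 cm⁻¹ vanish on complete decalcification; a spectrum is classified
  *calcified* when the 959 cm⁻¹ prominence exceeds 5× the silent-region
  noise.
- **Signal intensity index** for fluorescence acquisition settings,
  `SII = 100 / (LP · DG)`: bright, well-preserved staining needs low laser
  power (LP) and detector gain (DG), so higher SII means better staining.
- **Score aggregation** — semi-quantitative 0–2 observer scores averaged per
  (batch, parameter) over observers, then over batches, summed over
  parameters and normalized by the attainable maximum; a third-observer flag
  when two observers' totals differ by more than 1; tertile mapping of
  acquisition settings and SNR values to 0/1/2 scores; per-modality totals
  (mean of qualitative set 1 and quantitative set 2) and the final
  cross-modality score with its between-modality standard deviation.
- **A seeded synthetic-data generator** reproducing the band structure of
  calcified/decalcified compact bone and bone marrow, polynomial baselines,
  Gaussian noise, cosmic-ray spikes, mixture scans with ground truth, and
  observer score tables with controllable disagreement — so the whole
  pipeline is testable end to end.

## Worked example

```r
library(decalQC)

## has the mineral gone?  (synthetic spectra, noise SD 5 counts)
calc <- make_bone_spectrum("calcified",   "compact_bone", noise_sd = 5, seed = 1)
dec  <- make_bone_spectrum("decalcified", "compact_bone", noise_sd = 5, seed = 1)
detect_phosphate_bands(calc)
#> <phosphate_report> calcified (959 cm^-1 prominence 94.1 vs threshold 26.5)
detect_phosphate_bands(dec)
#> <phosphate_report> decalcified (959 cm^-1 prominence 7.63 vs threshold 26.5)

## spectral quality of the decalcified section
compute_snr(dec)
#> <snr_report> SNR = 9.25 (signal 49.1 / noise 5.3)
#>   silent region 1900-2300 cm^-1 (poly order 1), signal region 1300-1600 cm^-1

## unmix a bone-marrow image scan and find the nuclei endmember
scan <- make_scan(c(8, 8), roi = "bone_marrow", protocol = "E_24",
                  k = 2, noise_sd = 2, seed = 7)
pre <- preprocess_marrow(scan)
em  <- nfindr(pre$scan, k = 2, seed = 1)
em
#> <endmember_set> k=2, pure pixels: 43, 22, simplex volume 157.6
suggest_nuclei_channel(em)
#> [1] 1

## aggregate observer scores: EDTA 24 h vs hydrochloric/formic acid 8 h
tab <- make_score_fixture(c("E_24", "HF_8"),
                          quality = c(E_24 = 0.9, HF_8 = 0.4),
                          disagreement_sd = 0.1, modality = "raman", seed = 11)
aggregate_qualitative(tab, "raman", "E_24")
#> <modality_score> raman / E_24: 0.938 (total 3.75 over 2 parameters)
aggregate_qualitative(tab, "raman", "HF_8")
#> <modality_score> raman / HF_8: 0.438 (total 1.75 over 2 parameters)

final_score(he = 0.95, fluorescence = 0.88, raman = 0.875, protocol = "E_24")
#> <final_score> E_24 0.902 +/- 0.034 over 3 modalities (HE, fluorescence, raman)
```

The prominence report says the 959 cm⁻¹ phosphate band stands 94 counts
above baseline in the calcified spectrum (far above the 5×-noise threshold
of 26.5) and is absent after decalcification. The modality scores are on a
0–1 scale where 1 means every observer gave every parameter the top score;
the final score averages the three imaging modalities, with the error bar
showing their spread.

An entire comparison — synthetic scans and score tables for a cohort of
protocols, preprocessing, unmixing, SNR/SII scoring and final ranking, with
a hashed artifact manifest — runs from one config:

```r
run_pipeline(system.file("extdata", "demo-config.json", package = "decalQC"),
             out_dir = "demo-out")
```

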