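# Quantitative quality statistics: the four-step SNR anchored in the
# spectroscopically silent region, phosphate-band detection of residual
# bone mineral, and the fluorescence signal-intensity index.

#' Four-step signal-to-noise ratio of a Raman spectrum
#'
#' 1. *Noise*: within the silent region (default 1900--2300 cm^-1, where
#'    biological tissue has essentially no Raman bands) a polynomial of
#'    order `poly_order` is fitted to the intensities and the standard
#'    deviation of the residuals is the noise value.
#' 2. *Signal focusing and smoothing*: the CH-deformation band near
#'    1450 cm^-1 is the primary signal band; the region
#'    `signal_range` (default 1300--1600 cm^-1) is smoothed with a
#'    Savitzky-Golay filter.
#' 3. *Signal baseline and value*: the smoothed region is baseline-corrected
#'    with SNIP (clipping passes capped at one less than the region length)
#'    and the maximum corrected value is the signal.
#' 4. *SNR* = signal / noise.
#'
#' @param spectrum A [raman_spectrum()] covering both ranges with at least
#'   8 channels in each.
#' @param silent_range,signal_range Closed wavenumber intervals (cm^-1).
#' @param poly_order Order of the silent-region baseline polynomial.
#' @param sg_window,sg_polyorder Savitzky-Golay filter length (odd) and
#'   polynomial order.
#' @param snip_iterations SNIP passes for the signal-region baseline.
#' @return An object of class `snr_report` with elements `noise`, `signal`,
#'   `snr`, `silent_range`, `signal_range`, `baseline_poly_order`.
#' @export
compute_snr <- function(spectrum, silent_range = c(1900, 2300),
                        signal_range = c(1300, 1600), poly_order = 1,
                        sg_window = 11, sg_polyorder = 3,
                        snip_iterations = 400) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  w <- spectrum$wavenumber
  y <- spectrum$intensity
  sil <- which(in_range(w, silent_range))
  sig <- which(in_range(w, signal_range))
  if (length(sil) < 8L || length(sig) < 8L)
    stop("silent and signal ranges must each cover at least 8 channels",
         call. = FALSE)
  # step 1: noise from polynomial-detrended silent region
  X <- outer(w[sil], 0:poly_order, `^`)
  noise <- stats::sd(stats::lm.fit(X, y[sil])$residuals)
  if (!is.finite(noise) || noise < 1e-12)
    stop("degenerate noise: silent region is noiseless", call. = FALSE)
  # step 2: Savitzky-Golay smoothing of the signal region
  if (sg_window %% 2 == 0) stop("sg_window must be odd", call. = FALSE)
  smoothed <- signal::sgolayfilt(y[sig], p = sg_polyorder, n = sg_window)
  # step 3: SNIP baseline on the smoothed region, maximum as signal
  iters <- min(as.integer(snip_iterations), length(sig) - 1L)
  corrected <- snip_baseline(smoothed, iterations = iters)$corrected
  signal_value <- max(corrected)
  snr_report(noise = noise, signal = signal_value,
             silent_range = silent_range, signal_range = signal_range,
             baseline_poly_order = poly_order)
}

#' SNR of the brightest pixel of a scan
#'
#' Applies [compute_snr()] to the pixel spectrum with the highest maximum
#' intensity -- the per-image SNR summary used for scoring.
#'
#' @param scan A [hyper_scan()] (not yet truncated: the silent region must
#'   still be present).
#' @param ... Passed to [compute_snr()].
#' @return An `snr_report` with extra element `pixel` (index used).
#' @export
scan_snr <- function(scan, ...) {
  stopifnot(inherits(scan, "hyper_scan"))
  px <- which.max(apply(scan$pixels, 1, max))
  rep <- compute_snr(scan_pixel(scan, px), ...)
  rep$pixel <- px
  rep
}

#' Detect hydroxyapatite phosphate bands
#'
#' Measures the prominence (maximum smoothed, SNIP-baseline-corrected
#' intensity within +/- `halfwidth` cm^-1) of the four phosphate bands of
#' bone mineral at 431, 583, 959 and 1072 cm^-1 and classifies the spectrum
#' as `calcified` when the dominant 959 cm^-1 band exceeds
#' `prominence_factor` times the silent-region noise, and `decalcified`
#' otherwise.  Vanishing phosphate bands indicate complete decalcification.
#'
#' @param spectrum A [raman_spectrum()] covering 400--1100 cm^-1 and the
#'   silent region (needed for the noise reference).
#' @param prominence_factor Noise multiples the 959 cm^-1 prominence must
#'   exceed to call the spectrum calcified.
#' @param bands Phosphate band centres (cm^-1).
#' @param halfwidth Search half-width per band (cm^-1).
#' @param ... Passed to [compute_snr()] for the noise estimate.
#' @return A list of class `phosphate_report` with `prominence` (named
#'   vector), `noise`, `threshold` and `classified`.
#' @export
detect_phosphate_bands <- function(spectrum, prominence_factor = 5,
                                   bands = c(431, 583, 959, 1072),
                                   halfwidth = 15, ...) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  w <- spectrum$wavenumber
  if (min(w) > min(bands) - halfwidth || max(w) < max(bands) + halfwidth)
    stop("axis does not cover the phosphate bands", call. = FALSE)
  noise <- compute_snr(spectrum, ...)$noise
  smoothed <- signal::sgolayfilt(spectrum$intensity, p = 3, n = 11)
  iters <- min(400L, length(w) - 1L)
  corrected <- snip_baseline(smoothed, iterations = iters)$corrected
  prominence <- vapply(bands, function(b) {
    max(corrected[in_range(w, c(b - halfwidth, b + halfwidth))])
  }, numeric(1))
  names(prominence) <- as.character(bands)
  threshold <- prominence_factor * noise
  structure(
    list(prominence = prominence, noise = noise, threshold = threshold,
         classified = if (prominence[["959"]] > threshold) "calcified"
                      else "decalcified"),
    class = "phosphate_report"
  )
}

#' @export
print.phosphate_report <- function(x, ...) {
  cat(sprintf("<phosphate_report> %s (959 cm^-1 prominence %.3g vs threshold %.3g)\n",
              x$classified, x$prominence[["959"]], x$threshold))
  invisible(x)
}

#' Signal intensity index of a fluorescence channel
#'
#' `SII = 100 / (LP * DG)`: acquisition settings needed for a well-exposed
#' image encode staining brightness -- bright, specific staining needs low
#' laser power (LP) and low detector gain (DG), so a higher SII means a
#' brighter stain at lower excitation.  The index is relative; it carries
#' no absolute radiometric meaning.
#'
#' @param laser_power Laser power (instrument %), > 0.  Vectorized.
#' @param detector_gain Detector gain, > 0.  Vectorized.
#' @return Numeric SII values.
#' @examples
#' signal_intensity_index(10, 10)  # 1
#' signal_intensity_index(2, 5)    # 10
#' @export
signal_intensity_index <- function(laser_power, detector_gain) {
  if (any(!is.finite(laser_power)) || any(laser_power <= 0) ||
      any(!is.finite(detector_gain)) || any(detector_gain <= 0))
    stop("laser_power and detector_gain must be positive", call. = FALSE)
  100 / (laser_power * detector_gain)
}

#' Sum of signal intensity indices over channels
#'
#' @param laser_power,detector_gain Per-channel acquisition settings
#'   (equal-length positive vectors, >= 1 channel).
#' @return The summed SII.
#' @export
sii_sum <- function(laser_power, detector_gain) {
  if (length(laser_power) < 1L)
    stop("need at least one channel", call. = FALSE)
  if (length(laser_power) != length(detector_gain))
    stop("laser_power and detector_gain must have equal length", call. = FALSE)
  sum(signal_intensity_index(laser_power, detector_gain))
}
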