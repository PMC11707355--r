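# Raman preprocessing chain: wavenumber calibration against the silicon
# band, automated cosmic-ray removal, SNIP and rubber-band baseline
# correction, mean normalization, median spectra, spectral truncation.

#' Estimate the wavenumber calibration shift from a silicon spectrum
#'
#' Locates the silicon Raman band (expected near 520 cm^-1) as the global
#' maximum in the 480--560 cm^-1 window, refines its position to sub-channel
#' precision by 3-point parabolic interpolation, and returns the additive
#' axis shift `reference - observed`.
#'
#' @param silicon A [raman_spectrum()] of the silicon calibration standard.
#' @param reference Reference band position (cm^-1); 520 for silicon.
#' @param window Search window (cm^-1).
#' @return A list of class `calibration_shift` with elements `delta` (cm^-1)
#'   and `observed_peak`.
#' @export
estimate_wavenumber_shift <- function(silicon, reference = 520,
                                      window = c(480, 560)) {
  stopifnot(inherits(silicon, "raman_spectrum"))
  sel <- which(in_range(silicon$wavenumber, window))
  if (length(sel) < 3L)
    stop("calibration window not covered by the axis", call. = FALSE)
  w <- silicon$wavenumber[sel]
  y <- silicon$intensity[sel]
  i <- which.max(y)
  if (i == 1L || i == length(y))
    stop("no interior peak found in the calibration window", call. = FALSE)
  if (sum(y == y[i]) > 1L)
    stop("peak in calibration window is not unique", call. = FALSE)
  # parabola through the three samples around the maximum
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  offset <- if (abs(denom) < 1e-300) 0 else
    0.5 * (w[i + 1] - w[i - 1]) / 2 * (y[i - 1] - y[i + 1]) / denom
  observed <- w[i] + offset
  structure(list(delta = reference - observed, observed_peak = observed),
            class = "calibration_shift")
}

#' Apply a wavenumber calibration shift
#'
#' Adds `delta` to the axis; intensities are untouched.
#'
#' @param x A [raman_spectrum()] or [hyper_scan()].
#' @param shift A `calibration_shift` from [estimate_wavenumber_shift()], or
#'   a single numeric delta (cm^-1).
#' @return The shifted object (same class as `x`).
#' @export
apply_shift <- function(x, shift) {
  delta <- if (inherits(shift, "calibration_shift")) shift$delta else as.numeric(shift)
  stopifnot(length(delta) == 1L, is.finite(delta))
  x$wavenumber <- x$wavenumber + delta
  validate_axis(x$wavenumber)
  x
}

# Whitaker-Hayes style spike detection on one intensity vector: modified
# z-score of the first spectral difference; a single-channel spike produces
# two large opposite-signed consecutive differences.
#' @noRd
find_spike_channels <- function(y, z_threshold) {
  n <- length(y)
  d <- diff(y)
  med <- stats::median(d)
  madv <- stats::median(abs(d - med))
  if (madv < 1e-300) return(integer(0))
  z <- 0.6745 * (d - med) / madv
  a <- z[seq_len(n - 2L)]        # difference into channel i
  b <- z[2:(n - 1L)]             # difference out of channel i
  which(abs(a) > z_threshold & abs(b) > z_threshold & sign(a) != sign(b)) + 1L
}

#' @noRd
repair_channels <- function(y, bad) {
  if (!length(bad)) return(y)
  good <- setdiff(seq_along(y), bad)
  y[bad] <- stats::approx(good, y[good], xout = bad, rule = 2)$y
  y
}

#' Remove cosmic-ray spikes
#'
#' Detects single-channel cosmic-ray events as pairs of large
#' opposite-signed consecutive first differences (modified z-score above
#' `z_threshold`) and repairs flagged channels by linear interpolation of
#' the flanking channels.  The operation is idempotent on repaired data.
#'
#' @param x A [raman_spectrum()] or [hyper_scan()].
#' @param z_threshold Modified z-score threshold (default 8).
#' @return The despiked object with attribute `repairs`: a data frame with
#'   columns `pixel` (1 for single spectra) and `channel`.
#' @export
remove_cosmic_rays <- function(x, z_threshold = 8) UseMethod("remove_cosmic_rays")

#' @export
remove_cosmic_rays.raman_spectrum <- function(x, z_threshold = 8) {
  bad <- find_spike_channels(x$intensity, z_threshold)
  x$intensity <- repair_channels(x$intensity, bad)
  attr(x, "repairs") <- data.frame(pixel = rep(1L, length(bad)), channel = bad)
  x
}

#' @export
remove_cosmic_rays.hyper_scan <- function(x, z_threshold = 8) {
  reps <- vector("list", nrow(x$pixels))
  for (i in seq_len(nrow(x$pixels))) {
    bad <- find_spike_channels(x$pixels[i, ], z_threshold)
    if (length(bad)) {
      x$pixels[i, ] <- repair_channels(x$pixels[i, ], bad)
      reps[[i]] <- data.frame(pixel = i, channel = bad)
    }
  }
  reps <- do.call(rbind, reps)
  attr(x, "repairs") <- if (is.null(reps))
    data.frame(pixel = integer(0), channel = integer(0)) else reps
  x
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive Non-linear Iterative Peak-clipping: at iteration
#' `m = 1..iterations` every interior point `i` in `[m + 1, n - m]` is
#' clipped to `min(y[i], (y[i-m] + y[i+m]) / 2)` (simultaneous update from
#' the previous pass); channels within `m` of either edge keep their
#' current value, so a sloped background is preserved exactly.  The window
#' grows with the iteration number, eroding narrow peaks from the baseline
#' estimate while smooth background survives.
#'
#' @param x A [raman_spectrum()] or numeric intensity vector.
#' @param iterations Number of clipping passes (window grows 1..iterations);
#'   must satisfy `1 <= iterations < length(x)`.
#' @return A list with `baseline` and `corrected` (input minus baseline),
#'   both the same type as the input.
#' @export
snip_baseline <- function(x, iterations = 400) {
  y <- if (inherits(x, "raman_spectrum")) x$intensity else as.numeric(x)
  n <- length(y)
  iterations <- as.integer(iterations)
  if (iterations < 1L || iterations >= n)
    stop("iterations must satisfy 1 <= iterations < spectrum length",
         call. = FALSE)
  b <- y
  for (m in seq_len(iterations)) {
    if (2L * m >= n) break  # no interior channel has a full window
    i <- (m + 1L):(n - m)
    b[i] <- pmin(b[i], (b[i - m] + b[i + m]) / 2)
  }
  corrected <- y - b
  if (inherits(x, "raman_spectrum")) {
    bl <- x; bl$intensity <- b
    co <- x; co$intensity <- corrected
    list(baseline = bl, corrected = co)
  } else {
    list(baseline = b, corrected = corrected)
  }
}

#' Mean normalization
#'
#' Divides a spectrum by its mean intensity, so the output mean is exactly 1.
#'
#' @param x A [raman_spectrum()] or numeric vector with nonzero mean.
#' @return Normalized object of the same type.
#' @export
mean_normalize <- function(x) {
  y <- if (inherits(x, "raman_spectrum")) x$intensity else as.numeric(x)
  m <- mean(y)
  if (!is.finite(m) || abs(m) < 1e-300)
    stop("cannot mean-normalize a zero-mean spectrum", call. = FALSE)
  if (inherits(x, "raman_spectrum")) {
    x$intensity <- y / m
    x
  } else y / m
}

#' Median spectrum of a scan
#'
#' Mean-normalizes every pixel spectrum, then takes the channelwise median
#' across pixels: a robust per-image summary spectrum.
#'
#' @param scan A [hyper_scan()] with at least one pixel.
#' @return A [raman_spectrum()].
#' @export
median_spectrum <- function(scan) {
  stopifnot(inherits(scan, "hyper_scan"))
  norm <- t(apply(scan$pixels, 1, mean_normalize))
  raman_spectrum(scan$wavenumber, apply(norm, 2, stats::median),
                 label = sprintf("median of %d px (%s)", nrow(norm), scan$roi))
}

#' Truncate a spectrum or scan to selected wavenumber ranges
#'
#' Keeps channels whose wavenumber falls inside any of the closed ranges.
#' The defaults retain the fingerprint (400--1800 cm^-1) and CH-stretch
#' (2800--3100 cm^-1) regions used for bone-marrow analysis.
#'
#' @param x A [raman_spectrum()] or [hyper_scan()].
#' @param ranges List of `c(lo, hi)` wavenumber intervals (cm^-1).
#' @return Truncated object of the same class.
#' @export
truncate_spectrum <- function(x, ranges = list(c(400, 1800), c(2800, 3100))) {
  keep <- Reduce(`|`, lapply(ranges, function(r) in_range(x$wavenumber, r)))
  if (!any(keep)) stop("truncation ranges select no channels", call. = FALSE)
  if (inherits(x, "raman_spectrum")) {
    raman_spectrum(x$wavenumber[keep], x$intensity[keep], x$label)
  } else if (inherits(x, "hyper_scan")) {
    hyper_scan(x$wavenumber[keep], x$pixels[, keep, drop = FALSE],
               x$n_rows, x$n_cols, roi = x$roi, protocol = x$protocol)
  } else stop("unsupported input", call. = FALSE)
}

#' Rubber-band baseline correction
#'
#' The baseline is the lower convex hull of the (wavenumber, intensity)
#' points, linearly interpolated between hull vertices; the corrected
#' spectrum is therefore nonnegative and touches zero at the hull vertices.
#'
#' @param x A [raman_spectrum()] or numeric vector (>= 3 channels).
#' @param wavenumber Axis, required when `x` is a bare numeric vector.
#' @return A list with `baseline` and `corrected`, same type as the input.
#' @export
rubberband_baseline <- function(x, wavenumber = NULL) {
  if (inherits(x, "raman_spectrum")) {
    w <- x$wavenumber; y <- x$intensity
  } else {
    y <- as.numeric(x)
    w <- if (is.null(wavenumber)) seq_along(y) else wavenumber
  }
  n <- length(y)
  if (n < 3L) stop("rubber-band correction needs at least 3 channels", call. = FALSE)
  # Andrew's monotone chain, lower hull only (w is strictly increasing)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      j <- hull[length(hull)]
      k <- hull[length(hull) - 1L]
      cross <- (w[j] - w[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (w[i] - w[k])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  b <- stats::approx(w[hull], y[hull], xout = w)$y
  corrected <- pmax(y - b, 0)  # clip float dust at hull vertices
  if (inherits(x, "raman_spectrum")) {
    bl <- x; bl$intensity <- b
    co <- x; co$intensity <- corrected
    list(baseline = bl, corrected = co)
  } else list(baseline = b, corrected = corrected)
}

#' Compact-bone preprocessing chain
#'
#' Wavenumber calibration -> cosmic-ray removal -> per-pixel SNIP baseline
#' correction -> per-pixel mean normalization -> channelwise median
#' spectrum.
#'
#' @param scan A compact-bone [hyper_scan()].
#' @param silicon Optional silicon [raman_spectrum()] for calibration; when
#'   `NULL` the axis is assumed calibrated.
#' @param snip_iterations SNIP clipping passes (default 400).
#' @param despike_z Cosmic-ray z-score threshold.
#' @return A list with `median` (the summary [raman_spectrum()]), `scan`
#'   (the processed scan) and `shift` (the applied `calibration_shift` or
#'   `NULL`).
#' @export
preprocess_compact <- function(scan, silicon = NULL, snip_iterations = 400,
                               despike_z = 8) {
  shift <- NULL
  if (!is.null(silicon)) {
    shift <- estimate_wavenumber_shift(silicon)
    scan <- apply_shift(scan, shift)
  }
  scan <- remove_cosmic_rays(scan, despike_z)
  for (i in seq_len(nrow(scan$pixels)))
    scan$pixels[i, ] <- snip_baseline(scan$pixels[i, ], snip_iterations)$corrected
  list(median = median_spectrum(scan), scan = scan, shift = shift)
}

#' Bone-marrow preprocessing chain
#'
#' Wavenumber calibration -> cosmic-ray removal -> truncation to the
#' fingerprint and CH-stretch regions -> per-pixel rubber-band baseline
#' correction.  The result feeds N-FINDR unmixing.
#'
#' @inheritParams preprocess_compact
#' @param ranges Truncation ranges passed to [truncate_spectrum()].
#' @return A list with `scan` (processed [hyper_scan()]) and `shift`.
#' @export
preprocess_marrow <- function(scan, silicon = NULL, despike_z = 8,
                              ranges = list(c(400, 1800), c(2800, 3100))) {
  shift <- NULL
  if (!is.null(silicon)) {
    shift <- estimate_wavenumber_shift(silicon)
    scan <- apply_shift(scan, shift)
  }
  scan <- remove_cosmic_rays(scan, despike_z)
  scan <- truncate_spectrum(scan, ranges)
  for (i in seq_len(nrow(scan$pixels)))
    scan$pixels[i, ] <- rubberband_baseline(scan$pixels[i, ],
                                            scan$wavenumber)$corrected
  list(scan = scan, shift = shift)
}
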