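# Core domain types: wavenumber axis, spectra, hyperspectral scans,
# decalcification protocol codes, observer score tables.

#' Default spectrometer wavenumber axis
#'
#' A 400--3200 cm^-1 axis sampled every 2 cm^-1 (1401 channels), matching a
#' dispersive Raman setup with the spectral centre near 2000 cm^-1.
#'
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @export
default_axis <- function() seq(400, 3200, by = 2)

#' @noRd
validate_axis <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 16L)
    stop("wavenumber axis must be numeric with at least 16 channels", call. = FALSE)
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumber axis must be finite", call. = FALSE)
  if (any(wavenumber <= 0))
    stop("wavenumber axis values must be positive", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  invisible(wavenumber)
}

#' Construct a single Raman spectrum
#'
#' The central carrier of the pipeline: a shared wavenumber axis plus one
#' intensity vector (arbitrary counts; values may be negative after baseline
#' subtraction).
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, length >= 16, all positive.
#' @param intensity Numeric vector of intensities, same length as the axis,
#'   finite.
#' @param label Free-text label carried through processing steps.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity`, `label`.
#' @examples
#' s <- raman_spectrum(default_axis(), rnorm(1401, 100, 1), "example")
#' print(s)
#' @export
raman_spectrum <- function(wavenumber, intensity, label = "") {
  validate_axis(wavenumber)
  if (length(intensity) != length(wavenumber))
    stop("intensity length must match axis length", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = as.numeric(intensity),
         label = as.character(label)[1]),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s\n  %d channels, %.0f-%.0f cm^-1, intensity [%.3g, %.3g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$intensity, type = "l",
                 xlab = expression(paste("Wavenumber (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", main = x$label, ...)
  invisible(x)
}

#' Construct a hyperspectral Raman scan
#'
#' A square (or rectangular) image scan: one spectrum per pixel on a shared
#' wavenumber axis.  Pixels are stored row-major with the origin at the
#' top-left, so pixel index `(r - 1) * n_cols + c` holds row `r`, column `c`.
#'
#' @param wavenumber Shared axis (see [raman_spectrum()]).
#' @param pixels Numeric matrix, one row per pixel (row-major order), one
#'   column per channel.
#' @param n_rows,n_cols Grid shape; `n_rows * n_cols` must equal `nrow(pixels)`.
#' @param roi Region of interest: `"compact_bone"` or `"bone_marrow"`.
#' @param protocol Decalcification protocol code, e.g. `"E_24"`
#'   (see [protocol_codes()]), or `NA` for unassigned scans.
#' @return An object of class `hyper_scan`.
#' @export
hyper_scan <- function(wavenumber, pixels, n_rows, n_cols,
                       roi = c("compact_bone", "bone_marrow"),
                       protocol = NA_character_) {
  roi <- match.arg(roi)
  validate_axis(wavenumber)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixel intensities must be finite numeric values", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L || nrow(pixels) == 0L)
    stop("scan must contain at least one pixel", call. = FALSE)
  if (n_rows * n_cols != nrow(pixels))
    stop("grid shape does not match the number of pixel spectra", call. = FALSE)
  if (ncol(pixels) != length(wavenumber))
    stop("every pixel spectrum must match the axis length", call. = FALSE)
  if (!is.na(protocol)) protocol <- parse_protocol(protocol)$code
  structure(
    list(wavenumber = as.numeric(wavenumber),
         pixels = unname(pixels),
         n_rows = n_rows, n_cols = n_cols,
         roi = roi, protocol = protocol),
    class = "hyper_scan"
  )
}

#' @export
print.hyper_scan <- function(x, ...) {
  cat(sprintf("<hyper_scan> %dx%d pixels, %d channels, roi=%s, protocol=%s\n",
              x$n_rows, x$n_cols, length(x$wavenumber), x$roi,
              ifelse(is.na(x$protocol), "(none)", x$protocol)))
  invisible(x)
}

#' Extract one pixel of a scan as a spectrum
#'
#' @param scan A `hyper_scan`.
#' @param pixel Row-major pixel index (1-based).
#' @return A `raman_spectrum`.
#' @export
scan_pixel <- function(scan, pixel) {
  stopifnot(inherits(scan, "hyper_scan"))
  pixel <- as.integer(pixel)
  if (pixel < 1L || pixel > nrow(scan$pixels)) stop("pixel index out of range", call. = FALSE)
  r <- (pixel - 1L) %/% scan$n_cols + 1L
  c <- (pixel - 1L) %% scan$n_cols + 1L
  raman_spectrum(scan$wavenumber, scan$pixels[pixel, ],
                 label = sprintf("px_%d_%d", r, c))
}

# ---------------------------------------------------------------------------
# Protocol codes: decalcifier x duration pairs used in the study design.

#' Table of valid decalcification protocol codes
#'
#' The study design crosses six decalcifier formulations with
#' agent-appropriate immersion times: strong inorganic acids (3% and 5%
#' nitric acid `N3`/`N5`, hydrochloric + formic acid `HF`) for 2/6/8 h,
#' weaker organic acids (5% trichloroacetic acid `T` for 12/24/48/72 h, 8%
#' formic acid `F` for 6/12/24 h) and the chelator 25% EDTA (`E`) for
#' 12/24/48/72 h -- 20 protocol codes in total.
#'
#' @return A data frame with columns `decalcifier`, `duration_h`, `code`.
#' @examples
#' protocol_codes()$code
#' @export
protocol_codes <- function() {
  spec <- list(N3 = c(2, 6, 8), N5 = c(2, 6, 8), HF = c(2, 6, 8),
               T = c(12, 24, 48, 72), F = c(6, 12, 24),
               E = c(12, 24, 48, 72))
  out <- do.call(rbind, lapply(names(spec), function(d) {
    data.frame(decalcifier = d, duration_h = as.integer(spec[[d]]),
               stringsAsFactors = FALSE)
  }))
  out$code <- paste0(out$decalcifier, "_", out$duration_h)
  out
}

#' Parse and validate a protocol code string
#'
#' @param code Character string such as `"E_24"` or `"HF_8"`.
#' @return A list with elements `decalcifier`, `duration_h`, `code`.
#' @examples
#' parse_protocol("E_24")
#' @export
parse_protocol <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code))
    stop("protocol code must be a single string", call. = FALSE)
  tab <- protocol_codes()
  hit <- match(code, tab$code)
  if (is.na(hit))
    stop(sprintf("unknown protocol code '%s' (valid: %s)", code,
                 paste(tab$code, collapse = ", ")), call. = FALSE)
  list(decalcifier = tab$decalcifier[hit],
       duration_h = tab$duration_h[hit],
       code = tab$code[hit])
}

# ---------------------------------------------------------------------------
# Observer score tables.

#' Construct and validate an observer score table
#'
#' A sparse table of semi-quantitative scores keyed by
#' (modality, protocol, batch, observer, parameter).  Scores are integers in
#' {0, 1, 2} (2 = highest quality); combinations that were not evaluated are
#' simply absent.
#'
#' @param records Data frame with columns `modality`, `protocol`, `batch`,
#'   `observer`, `parameter`, `score`.
#' @return A validated data frame of class `score_table`.
#' @export
score_table <- function(records) {
  required <- c("modality", "protocol", "batch", "observer", "parameter", "score")
  if (!all(required %in% names(records)))
    stop("score table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[required]
  if (!all(records$modality %in% c("HE", "fluorescence", "raman")))
    stop("modality must be one of HE, fluorescence, raman", call. = FALSE)
  for (p in unique(records$protocol)) parse_protocol(p)
  records$batch <- as.integer(records$batch)
  if (any(is.na(records$batch)) || any(records$batch < 1L))
    stop("batch must be an integer >= 1", call. = FALSE)
  sc <- records$score
  if (!is.numeric(sc) || anyNA(sc) || any(sc != as.integer(sc)) ||
      any(!(sc %in% c(0, 1, 2))))
    stop("scores must be integers in {0, 1, 2}", call. = FALSE)
  records$score <- as.integer(sc)
  key <- do.call(paste, c(records[c("modality", "protocol", "batch",
                                    "observer", "parameter")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (modality, protocol, batch, observer, parameter) key",
         call. = FALSE)
  rownames(records) <- NULL
  class(records) <- c("score_table", "data.frame")
  records
}

# ---------------------------------------------------------------------------
# SNR report container.

#' @noRd
snr_report <- function(noise, signal, silent_range, signal_range,
                       baseline_poly_order) {
  structure(
    list(noise = noise, signal = signal, snr = signal / noise,
         silent_range = silent_range, signal_range = signal_range,
         baseline_poly_order = baseline_poly_order),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf(paste0("<snr_report> SNR = %.3g (signal %.3g / noise %.3g)\n",
                     "  silent region %g-%g cm^-1 (poly order %d), ",
                     "signal region %g-%g cm^-1\n"),
              x$snr, x$signal, x$noise,
              x$silent_range[1], x$silent_range[2], x$baseline_poly_order,
              x$signal_range[1], x$signal_range[2]))
  invisible(x)
}
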