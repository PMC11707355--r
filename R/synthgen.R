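# Synthetic-data generator: seeded Raman spectra, image scans, observer
# score tables and fluorescence acquisition tables with the statistical
# structure the downstream analysis assumes.

# Gaussian/Lorentzian band profile evaluated on an axis
#' @noRd
render_band <- function(wavenumber, center, fwhm, amplitude,
                        shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  if (shape == "gaussian") {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    amplitude * exp(-0.5 * ((wavenumber - center) / s)^2)
  } else {
    g <- fwhm / 2
    amplitude * g^2 / ((wavenumber - center)^2 + g^2)
  }
}

# Band tables.  Centres follow the bone Raman literature: the phosphate
# nu1/nu2/nu4 modes of hydroxyapatite plus the carbonate-overlapped band at
# 1072 cm^-1; collagen proline/hydroxyproline, the broad amide III and
# amide I envelopes (rendered as single wide Gaussians at the midpoint of
# the envelope), CH2 deformation at 1450 cm^-1 and the CH-stretch region
# near 2935 cm^-1.  Marrow cells add the nucleic-acid band at 780 cm^-1 and
# the sharp phenylalanine ring-breathing band at 1003 cm^-1.  Amplitudes are
# arbitrary units chosen so that 959 cm^-1 dominates calcified spectra.
#' @noRd
band_table <- function(which) {
  switch(which,
    phosphate = data.frame(
      center = c(431, 583, 959, 1072),
      fwhm = c(12, 12, 12, 12),
      amplitude = c(30, 25, 100, 30)),
    collagen = data.frame(
      center = c(855, 876, 921, 1281.5, 1450, 1663, 2935),
      fwhm = c(12, 12, 12, 60, 12, 60, 80),
      amplitude = c(40, 35, 40, 30, 50, 45, 60)),
    marrow = data.frame(
      center = c(780, 1003),
      fwhm = c(12, 8),
      amplitude = c(25, 35)),
    stop("unknown band table", call. = FALSE))
}

#' @noRd
bands_for <- function(state, tissue) {
  b <- band_table("collagen")
  if (tissue == "bone_marrow") b <- rbind(b, band_table("marrow"))
  if (state == "calcified") b <- rbind(band_table("phosphate"), b)
  b$shape <- "gaussian"
  b[order(b$center), ]
}

#' Generate a synthetic bone Raman spectrum
#'
#' Emulates the band structure of mouse bone cryosections: calcified bone is
#' dominated by the hydroxyapatite phosphate band at 959 cm^-1 (with further
#' phosphate bands at 431, 583 and 1072 cm^-1); after complete
#' decalcification those bands vanish and the collagen matrix signature
#' remains (855/876/921 cm^-1 proline/hydroxyproline, broad amide III and
#' amide I envelopes, CH2 deformation at 1450 cm^-1).  Bone-marrow spectra
#' additionally carry cellular bands: nucleic acid at 780 cm^-1 and
#' phenylalanine at 1003 cm^-1.  A polynomial baseline, i.i.d. Gaussian
#' channel noise and optional single-channel cosmic-ray spikes are added.
#'
#' @param state `"calcified"` or `"decalcified"`.
#' @param tissue `"compact_bone"` or `"bone_marrow"`.
#' @param band_overrides Named list mapping a band centre (as character,
#'   e.g. `"780"`) to a replacement amplitude; amplitude 0 removes the band.
#' @param noise_sd Standard deviation of additive Gaussian noise (counts).
#' @param baseline_coeffs Polynomial baseline coefficients in ascending
#'   order, evaluated on (wavenumber - 400).
#' @param cosmic_ray_rate Probability that the spectrum carries one
#'   single-channel spike of >= 20 x `noise_sd`.
#' @param axis Wavenumber axis; default [default_axis()].
#' @param seed Integer seed; identical seeds give identical spectra.
#' @return A [raman_spectrum()] with attributes `clean` (noise- and
#'   baseline-free band signal), `baseline`, and `spike_channel` (NA if no
#'   spike was injected).
#' @examples
#' s <- make_bone_spectrum("calcified", "compact_bone", seed = 1)
#' @export
make_bone_spectrum <- function(state = c("calcified", "decalcified"),
                               tissue = c("compact_bone", "bone_marrow"),
                               band_overrides = list(),
                               noise_sd = 4,
                               baseline_coeffs = c(60, -0.01),
                               cosmic_ray_rate = 0,
                               axis = default_axis(),
                               seed = NULL) {
  state <- match.arg(state)
  tissue <- match.arg(tissue)
  validate_axis(axis)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  bands <- bands_for(state, tissue)
  for (ctr in names(band_overrides)) {
    i <- which(abs(bands$center - as.numeric(ctr)) < 1e-9)
    if (length(i) != 1L)
      stop("band_overrides refers to unknown band centre ", ctr, call. = FALSE)
    bands$amplitude[i] <- band_overrides[[ctr]]
  }
  clean <- rowSums(vapply(seq_len(nrow(bands)), function(i) {
    render_band(axis, bands$center[i], bands$fwhm[i], bands$amplitude[i],
                bands$shape[i])
  }, numeric(length(axis))))
  baseline <- drop(outer(axis - 400, seq_along(baseline_coeffs) - 1, `^`) %*%
                     baseline_coeffs)
  with_seed(seed, {
    y <- clean + baseline + stats::rnorm(length(axis), 0, noise_sd)
    spike_channel <- NA_integer_
    if (cosmic_ray_rate > 0 && stats::runif(1) < cosmic_ray_rate) {
      spike_channel <- sample(2:(length(axis) - 1L), 1L)
      y[spike_channel] <- y[spike_channel] +
        (20 + stats::runif(1, 0, 10)) * max(noise_sd, 1)
    }
    out <- raman_spectrum(axis, y, label = paste(state, tissue, sep = "/"))
    attr(out, "clean") <- clean
    attr(out, "baseline") <- baseline
    attr(out, "spike_channel") <- spike_channel
    out
  })
}

#' Generate a synthetic silicon calibration spectrum
#'
#' A single narrow band near the silicon reference line at 520 cm^-1, used
#' to exercise wavenumber calibration.  `true_peak` sets where the band
#' actually sits, so the expected calibration shift is
#' `520 - true_peak`.
#'
#' @param true_peak Band centre (cm^-1).
#' @param fwhm Band width (cm^-1).
#' @param amplitude Band height (counts).
#' @param noise_sd Additive Gaussian noise SD.
#' @param axis Wavenumber axis.
#' @param seed Integer seed.
#' @return A [raman_spectrum()].
#' @export
make_silicon_spectrum <- function(true_peak = 520, fwhm = 12, amplitude = 1000,
                                  noise_sd = 0, axis = default_axis(),
                                  seed = NULL) {
  validate_axis(axis)
  clean <- render_band(axis, true_peak, fwhm, amplitude)
  with_seed(seed, {
    raman_spectrum(axis, clean + stats::rnorm(length(axis), 0, noise_sd),
                   label = "silicon")
  })
}

#' Generate a synthetic hyperspectral scan with known ground truth
#'
#' Pixels are convex mixtures of `k` endmember spectra plus i.i.d. Gaussian
#' noise, with a configurable fraction of pure pixels (the assumption
#' N-FINDR relies on), optional disk-shaped "nuclei" layouts for
#' false-colour-image tests, and optional cosmic-ray spikes.
#'
#' For `roi = "bone_marrow"` the default endmembers are a nuclei-rich cell
#' spectrum (strong 780 cm^-1 nucleic-acid band) and a cytoplasm/matrix
#' spectrum; for `roi = "compact_bone"` they are collagen-matrix spectra
#' with per-endmember amplitude scaling.
#'
#' @param grid_shape Integer vector `c(n_rows, n_cols)`, each >= 2.
#' @param roi `"bone_marrow"` or `"compact_bone"`.
#' @param protocol Protocol code attached to the scan.
#' @param k Number of endmembers (>= 1).
#' @param pure_fraction Fraction of pixels forced pure (per endmember at
#'   least one); must be > 0 when `k >= 2`.
#' @param noise_sd Additive Gaussian channel noise SD.
#' @param cosmic_ray_rate Per-pixel probability of one single-channel spike
#'   of >= 20 x `noise_sd`.
#' @param layout `"random"` (Dirichlet-style mixtures) or `"disks"`
#'   (endmember 1 concentrated in disk-shaped regions, mimicking nuclei).
#' @param state Decalcification state of the underlying tissue spectra.
#' @param axis Wavenumber axis.
#' @param seed Integer seed.
#' @return A [hyper_scan()] with attribute `truth`: a list with
#'   `endmembers` (k x channels matrix), `abundances` (pixels x k, rows sum
#'   to 1), `pure_pixels` (list of pixel indices per endmember), `spikes`
#'   (data frame pixel/channel), and for `layout = "disks"` a logical
#'   `nucleus_mask` of length `n_pixels`.
#' @export
make_scan <- function(grid_shape = c(8, 8),
                      roi = c("bone_marrow", "compact_bone"),
                      protocol = "E_24", k = 2, pure_fraction = 0.2,
                      noise_sd = 2, cosmic_ray_rate = 0,
                      layout = c("random", "disks"),
                      state = "decalcified",
                      axis = default_axis(), seed = NULL) {
  roi <- match.arg(roi)
  layout <- match.arg(layout)
  n_rows <- as.integer(grid_shape[1]); n_cols <- as.integer(grid_shape[2])
  if (n_rows < 2L || n_cols < 2L) stop("grid must be at least 2x2", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k >= 2L && pure_fraction <= 0)
    stop("pure_fraction must be > 0 when k >= 2 (N-FINDR needs pure pixels)",
         call. = FALSE)
  n_pix <- n_rows * n_cols

  # endmember library (noise-free)
  em <- if (roi == "bone_marrow") {
    nuc <- make_bone_spectrum(state, "bone_marrow",
                              band_overrides = list("780" = 60, "1003" = 45),
                              noise_sd = 0, baseline_coeffs = 0, axis = axis)
    cyt <- make_bone_spectrum(state, "compact_bone", noise_sd = 0,
                              baseline_coeffs = 0, axis = axis)
    base <- rbind(nuc$intensity, cyt$intensity)
    if (k > 2) {
      extra <- t(vapply(seq_len(k - 2L), function(i) {
        make_bone_spectrum(state, "bone_marrow",
                           band_overrides = list("1003" = 20 + 25 * i,
                                                 "780" = 5),
                           noise_sd = 0, baseline_coeffs = 0,
                           axis = axis)$intensity * (1 + 0.4 * i)
      }, numeric(length(axis))))
      base <- rbind(base, extra)
    }
    base[seq_len(k), , drop = FALSE]
  } else {
    t(vapply(seq_len(k), function(i) {
      make_bone_spectrum(state, "compact_bone", noise_sd = 0,
                         baseline_coeffs = 0, axis = axis)$intensity *
        (0.6 + 0.5 * i)
    }, numeric(length(axis))))
  }

  with_seed(seed, {
    nucleus_mask <- NULL
    if (layout == "disks") {
      if (k < 2L) stop("disk layout needs k >= 2", call. = FALSE)
      rr <- rep(seq_len(n_rows), each = n_cols)
      cc <- rep(seq_len(n_cols), times = n_rows)
      n_disks <- max(1L, round(n_rows * n_cols / 24))
      ctr_r <- stats::runif(n_disks, 1.5, n_rows - 0.5)
      ctr_c <- stats::runif(n_disks, 1.5, n_cols - 0.5)
      radius <- stats::runif(n_disks, 1.2, 2.2)
      nucleus_mask <- rep(FALSE, n_pix)
      for (d in seq_len(n_disks))
        nucleus_mask <- nucleus_mask |
          ((rr - ctr_r[d])^2 + (cc - ctr_c[d])^2 <= radius[d]^2)
      ab <- matrix(0, n_pix, k)
      ab[, 1] <- ifelse(nucleus_mask, 0.95, 0.05)
      ab[, 2] <- 1 - ab[, 1]
      pure <- lapply(seq_len(k), function(j) integer(0))
    } else if (k == 1L) {
      ab <- matrix(1, n_pix, 1)
      pure <- list(seq_len(n_pix))
    } else {
      ab <- matrix(stats::runif(n_pix * k), n_pix, k)
      ab <- ab / rowSums(ab)
      n_pure <- max(k, round(pure_fraction * n_pix))
      pure_idx <- sample(n_pix, n_pure)
      assign_em <- c(seq_len(k), sample(k, n_pure - k, replace = TRUE))
      for (i in seq_along(pure_idx)) {
        ab[pure_idx[i], ] <- 0
        ab[pure_idx[i], assign_em[i]] <- 1
      }
      pure <- lapply(seq_len(k), function(j) pure_idx[assign_em == j])
    }
    pixels <- ab %*% em +
      matrix(stats::rnorm(n_pix * length(axis), 0, noise_sd), n_pix)
    spikes <- data.frame(pixel = integer(0), channel = integer(0))
    if (cosmic_ray_rate > 0) {
      hit <- which(stats::runif(n_pix) < cosmic_ray_rate)
      if (length(hit)) {
        ch <- sample(2:(length(axis) - 1L), length(hit), replace = TRUE)
        amp <- (20 + stats::runif(length(hit), 0, 10)) * max(noise_sd, 1)
        for (i in seq_along(hit))
          pixels[hit[i], ch[i]] <- pixels[hit[i], ch[i]] + amp[i]
        spikes <- data.frame(pixel = hit, channel = ch)
      }
    }
    scan <- hyper_scan(axis, pixels, n_rows, n_cols, roi = roi,
                       protocol = protocol)
    attr(scan, "truth") <- list(endmembers = em, abundances = ab,
                                pure_pixels = pure, spikes = spikes,
                                nucleus_mask = nucleus_mask,
                                noise_sd = noise_sd)
    scan
  })
}

#' Generate a synthetic observer score table
#'
#' Each protocol carries a latent quality in [0, 1]; observers see the
#' latent quality perturbed by Gaussian noise and report
#' `round(2 * (quality + noise))` clamped to {0, 1, 2}, emulating
#' independent semi-quantitative raters.
#'
#' @param protocols Character vector of protocol codes.
#' @param quality Named numeric vector of latent qualities in [0, 1] (one
#'   per protocol), or a single value recycled.
#' @param n_batches,n_observers Design size; `n_observers >= 2`.
#' @param disagreement_sd Observer noise SD on the latent [0, 1] scale.
#' @param modality `"HE"`, `"fluorescence"` or `"raman"`.
#' @param parameters Character vector of scored parameters; defaults to the
#'   modality's standard parameter set (2 for Raman bone marrow, 5 for H&E,
#'   6 for fluorescence).
#' @param seed Integer seed.
#' @return A [score_table()].
#' @export
make_score_fixture <- function(protocols, quality = 0.8, n_batches = 2,
                               n_observers = 2, disagreement_sd = 0.1,
                               modality = c("raman", "HE", "fluorescence"),
                               parameters = NULL, seed = NULL) {
  modality <- match.arg(modality)
  if (length(protocols) < 1L) stop("need at least one protocol", call. = FALSE)
  if (n_observers < 2L) stop("need at least two observers", call. = FALSE)
  for (p in protocols) parse_protocol(p)
  if (is.null(parameters))
    parameters <- switch(modality,
      raman = c("resolved_structures", "spectral_quality"),
      HE = c("cement_line", "osteocytes", "marrow_nuclei",
             "marrow_distribution", "cytoplasm"),
      fluorescence = c("nuclei", "cytoskeleton", "osteoclasts",
                       "preosteoblasts", "marrow_nuclei", "marrow_cytoskeleton"))
  if (length(quality) == 1L && is.null(names(quality)))
    quality <- stats::setNames(rep(quality, length(protocols)), protocols)
  if (!all(protocols %in% names(quality)))
    stop("quality must name every protocol", call. = FALSE)
  if (any(quality < 0 | quality > 1))
    stop("latent quality must lie in [0, 1]", call. = FALSE)

  grid <- expand.grid(parameter = parameters,
                      observer = paste0("obs", seq_len(n_observers)),
                      batch = seq_len(n_batches),
                      protocol = protocols,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    latent <- quality[grid$protocol] +
      stats::rnorm(nrow(grid), 0, disagreement_sd)
    grid$score <- as.integer(clamp(round(2 * latent), 0, 2))
    grid$modality <- modality
    score_table(grid)
  })
}

#' Generate synthetic fluorescence acquisition settings
#'
#' Brighter staining (higher latent quality) needs less excitation: laser
#' power and detector gain decrease with quality, with multiplicative
#' log-normal batch scatter.  Ranges emulate confocal practice: laser power
#' 2--20 (instrument %), detector gain 500--1000.
#'
#' @param protocols Character vector of protocol codes.
#' @param quality Named latent quality in [0, 1] per protocol (or single
#'   value recycled).
#' @param n_batches Number of batches.
#' @param channels Imaged channels.
#' @param scatter_cv Coefficient of variation of batch-to-batch scatter.
#' @param seed Integer seed.
#' @return Data frame `protocol,batch,channel,laser_power,detector_gain`.
#' @export
make_acquisition_fixture <- function(protocols, quality = 0.8, n_batches = 2,
                                     channels = c("osteoclast", "preosteoblast",
                                                  "actin", "nuclei"),
                                     scatter_cv = 0.05, seed = NULL) {
  for (p in protocols) parse_protocol(p)
  if (length(quality) == 1L && is.null(names(quality)))
    quality <- stats::setNames(rep(quality, length(protocols)), protocols)
  grid <- expand.grid(channel = channels, batch = seq_len(n_batches),
                      protocol = protocols, stringsAsFactors = FALSE)
  with_seed(seed, {
    q <- quality[grid$protocol]
    scatter <- function(n) exp(stats::rnorm(n, 0, scatter_cv))
    grid$laser_power <- (2 + (1 - q) * 18) * scatter(nrow(grid))
    grid$detector_gain <- (500 + (1 - q) * 500) * scatter(nrow(grid))
    grid[c("protocol", "batch", "channel", "laser_power", "detector_gain")]
  })
}
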