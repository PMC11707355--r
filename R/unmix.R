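# N-FINDR endmember extraction, NNLS abundance estimation and false-colour
# image rendering for bone-marrow scans.

# simplex volume of pixel set `idx` in the (k-1)-dimensional PC scores Y
#' @noRd
simplex_volume_coords <- function(Y, idx) {
  k <- length(idx)
  M <- rbind(rep(1, k), t(Y[idx, , drop = FALSE]))
  abs(det(M)) / factorial(k - 1L)
}

#' Simplex volume spanned by a set of pixels
#'
#' Projects the scan onto its leading `length(idx) - 1` principal
#' components and returns the volume of the simplex whose vertices are the
#' chosen pixels -- the quantity N-FINDR maximizes.
#'
#' @param scan A [hyper_scan()].
#' @param idx Pixel indices (vertices), length >= 2.
#' @return Nonnegative volume (arbitrary units).
#' @export
simplex_volume <- function(scan, idx) {
  stopifnot(inherits(scan, "hyper_scan"), length(idx) >= 2L)
  Y <- stats::prcomp(scan$pixels, center = TRUE,
                     rank. = length(idx) - 1L)$x
  simplex_volume_coords(Y, idx)
}

#' N-FINDR endmember extraction
#'
#' Finds the `k` pixels whose spectra span the maximum-volume simplex in
#' the (k-1)-dimensional principal-component projection of the scan.
#' Starting from a seeded random pixel set, single-pixel replacement sweeps
#' (pixels in index order, endmember slots in index order; replacements
#' accepted only on a strict volume increase, which breaks ties toward the
#' incumbent, lower-index configuration) are iterated until no replacement
#' improves the volume or `max_sweeps` is reached.  The simplex volume is
#' non-decreasing across sweeps and at least that of the random start.
#'
#' @param scan A preprocessed (baseline-corrected) [hyper_scan()].
#' @param k Number of endmembers, `2 <= k <=` number of pixels.
#' @param seed Integer seed for the random initial pixel set.
#' @param max_sweeps Maximum replacement sweeps.
#' @return A list of class `endmember_set` with `k`, `pure_pixel_indices`,
#'   `spectra` (k x channels, rows of the scan at those indices), `volume`,
#'   and `volume_trace` (volume after initialization and after every sweep).
#' @export
nfindr <- function(scan, k = 2, seed = 1, max_sweeps = 20) {
  stopifnot(inherits(scan, "hyper_scan"))
  k <- as.integer(k)
  n_pix <- nrow(scan$pixels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n_pix) stop("k must not exceed the number of pixels", call. = FALSE)
  pc <- stats::prcomp(scan$pixels, center = TRUE, rank. = k - 1L)
  sdev <- pc$sdev
  if (sdev[1] < 1e-10 || length(sdev) < k - 1L ||
      sdev[k - 1L] < 1e-10 * sdev[1])
    stop("degenerate scan: pixel cloud has rank below k - 1", call. = FALSE)
  Y <- pc$x[, seq_len(k - 1L), drop = FALSE]

  idx <- with_seed(seed, sample(n_pix, k))
  vol <- simplex_volume_coords(Y, idx)
  trace <- vol
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (slot in seq_len(k)) {
      cand <- idx
      for (p in seq_len(n_pix)) {
        if (p %in% idx) next
        cand[slot] <- p
        v <- simplex_volume_coords(Y, cand)
        if (v > vol * (1 + 1e-12) && v > vol) {
          idx[slot] <- p
          vol <- v
          improved <- TRUE
        }
        cand[slot] <- idx[slot]
      }
    }
    trace <- c(trace, vol)
    if (!improved) break
  }
  structure(
    list(k = k, pure_pixel_indices = idx,
         spectra = scan$pixels[idx, , drop = FALSE],
         wavenumber = scan$wavenumber,
         volume = vol, volume_trace = trace),
    class = "endmember_set"
  )
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> k=%d, pure pixels: %s, simplex volume %.4g\n",
              x$k, paste(x$pure_pixel_indices, collapse = ", "), x$volume))
  invisible(x)
}

#' Nonnegative least-squares abundance estimation
#'
#' Fits every pixel spectrum as a nonnegative linear combination of the
#' endmember spectra (no sum-to-one constraint, so the coefficients are
#' robust to residual intensity variation).
#'
#' @param scan A [hyper_scan()].
#' @param endmembers An `endmember_set` from [nfindr()], or a k x channels
#'   numeric matrix of endmember spectra.
#' @return A pixels x k matrix of class `abundance_map` with attributes
#'   `grid_shape` and `residual_norm` (per-pixel NNLS residual norms).
#' @export
estimate_abundances <- function(scan, endmembers) {
  stopifnot(inherits(scan, "hyper_scan"))
  E <- if (inherits(endmembers, "endmember_set")) endmembers$spectra
       else as.matrix(endmembers)
  if (ncol(E) != length(scan$wavenumber))
    stop("endmember spectra do not match the scan axis", call. = FALSE)
  k <- nrow(E)
  if (qr(t(E))$rank < k)
    stop("endmember spectra are linearly dependent", call. = FALSE)
  A <- t(E)  # channels x k design matrix
  n_pix <- nrow(scan$pixels)
  ab <- matrix(0, n_pix, k)
  resid <- numeric(n_pix)
  for (i in seq_len(n_pix)) {
    fit <- pracma::lsqnonneg(A, scan$pixels[i, ])
    ab[i, ] <- fit$x
    resid[i] <- sqrt(fit$resid.norm)
  }
  structure(ab, class = c("abundance_map", "matrix"),
            grid_shape = c(scan$n_rows, scan$n_cols),
            residual_norm = resid)
}

#' Render a false-colour abundance image
#'
#' Min-max scales the abundance plane of one endmember to [0, 1] and
#' reshapes it to the scan grid (row-major, origin top-left).  A constant
#' plane cannot be scaled and returns zeros with attribute
#' `constant_plane = TRUE` plus a warning.
#'
#' @param abundances An `abundance_map` from [estimate_abundances()].
#' @param channel Endmember index to render (1..k).
#' @return An `n_rows` x `n_cols` numeric matrix with values in [0, 1].
#' @export
false_color_image <- function(abundances, channel) {
  stopifnot(inherits(abundances, "abundance_map"))
  channel <- as.integer(channel)
  if (channel < 1L || channel > ncol(abundances))
    stop("channel index out of range", call. = FALSE)
  shape <- attr(abundances, "grid_shape")
  v <- abundances[, channel]
  rng <- range(v)
  constant <- diff(rng) < 1e-300
  if (constant) {
    warning("constant abundance plane; returning zeros")
    v <- rep(0, length(v))
  } else {
    v <- (v - rng[1]) / diff(rng)
  }
  img <- matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  attr(img, "constant_plane") <- constant
  img
}

#' Suggest the nuclei endmember channel
#'
#' The endmember richest in nucleic-acid signal -- the strongest
#' baseline-corrected band near 780 cm^-1 -- is the natural channel for
#' visualizing cellular nuclei in false-colour Raman images.
#'
#' @param endmembers An `endmember_set` (or matrix with attribute-free rows,
#'   in which case `wavenumber` must be supplied).
#' @param wavenumber Axis matching the endmember spectra columns.
#' @param band Nucleic-acid band centre (cm^-1).
#' @param halfwidth Search half-width around the band (cm^-1).
#' @return Integer index of the suggested nuclei endmember.
#' @export
suggest_nuclei_channel <- function(endmembers, wavenumber = NULL,
                                   band = 780, halfwidth = 10) {
  if (inherits(endmembers, "endmember_set")) {
    E <- endmembers$spectra
    w <- endmembers$wavenumber
  } else {
    E <- as.matrix(endmembers)
    w <- wavenumber
    if (is.null(w)) stop("wavenumber axis required", call. = FALSE)
  }
  sel <- in_range(w, c(band - halfwidth, band + halfwidth))
  if (!any(sel)) stop("axis does not cover the nucleic-acid band", call. = FALSE)
  heights <- apply(E, 1, function(y) {
    max(rubberband_baseline(y, w)$corrected[sel])
  })
  which.max(heights)
}
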