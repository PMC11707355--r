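# Preprocessing chain: calibration, despiking, SNIP, normalization,
# median spectrum, truncation, rubber-band baseline.

test_that("wavenumber shift matches its definition at on-grid peaks", {
  ax <- default_axis()
  s520 <- make_silicon_spectrum(520, axis = ax)
  expect_equal(estimate_wavenumber_shift(s520)$delta, 0, tolerance = 1e-9)
  s522 <- make_silicon_spectrum(522, axis = ax)
  expect_equal(estimate_wavenumber_shift(s522)$delta, -2, tolerance = 1e-9)
})

test_that("parabolic interpolation recovers sub-channel peak positions", {
  # noiseless gaussian centred off-grid at 517.3 -> delta 520 - 517.3 = +2.7
  s <- make_silicon_spectrum(517.3, fwhm = 12, axis = default_axis())
  expect_equal(estimate_wavenumber_shift(s)$delta, 2.7, tolerance = 0.05)
  flat <- raman_spectrum(default_axis(), rep(1, 1401))
  expect_error(estimate_wavenumber_shift(flat), "unique|peak")
})

test_that("apply_shift translates the axis and round-trips", {
  s <- make_silicon_spectrum(520)
  expect_identical(apply_shift(s, 0), s)
  back <- apply_shift(apply_shift(s, -2), 2)
  expect_equal(back$wavenumber, s$wavenumber)
  expect_identical(back$intensity, s$intensity)
  expect_true(all(diff(apply_shift(s, 5)$wavenumber) > 0))
})

test_that("despiking repairs injected spikes and leaves clean spectra alone", {
  ax <- default_axis()
  set.seed(41)
  clean <- 100 + gauss_band(ax, 1450, 12, 50) + rnorm(length(ax), 0, 1)
  spiked <- clean
  spiked[700] <- spiked[700] + 50  # 50x noise sd
  out <- remove_cosmic_rays(raman_spectrum(ax, spiked))
  expect_true(700 %in% attr(out, "repairs")$channel)
  expect_lt(abs(out$intensity[700] - clean[700]), 3)
  # spike-free input is untouched
  s0 <- raman_spectrum(ax, clean)
  out0 <- remove_cosmic_rays(s0)
  expect_identical(out0$intensity, clean)
  expect_equal(nrow(attr(out0, "repairs")), 0L)
})

test_that("despiking is idempotent", {
  scan <- make_scan(c(6, 6), cosmic_ray_rate = 0.3, noise_sd = 2, seed = 11)
  once <- remove_cosmic_rays(scan)
  twice <- remove_cosmic_rays(once)
  expect_identical(twice$pixels, once$pixels)
  expect_equal(nrow(attr(twice, "repairs")), 0L)
})

test_that("despiking recovers nearly all spikes with few false repairs", {
  recall <- numeric(10); false_rate <- numeric(10)
  for (s in 1:10) {
    scan <- make_scan(c(8, 8), cosmic_ray_rate = 0.25, noise_sd = 2, seed = s)
    tru <- attr(scan, "truth")$spikes
    reps <- attr(remove_cosmic_rays(scan), "repairs")
    key_t <- paste(tru$pixel, tru$channel)
    key_r <- paste(reps$pixel, reps$channel)
    recall[s] <- mean(key_t %in% key_r)
    n_clean <- length(scan$pixels) - nrow(tru)
    false_rate[s] <- sum(!(key_r %in% key_t)) / n_clean
  }
  expect_gte(mean(recall), 0.95)
  expect_lte(max(false_rate), 0.01)
})

test_that("SNIP clips constants to zero and never exceeds the input", {
  const <- rep(7.5, 500)
  out <- snip_baseline(const, 400)
  expect_identical(out$baseline, const)
  expect_identical(out$corrected, rep(0, 500))
  zero <- snip_baseline(rep(0, 500), 400)
  expect_identical(zero$corrected, rep(0, 500))
  set.seed(5)
  y <- cumsum(rnorm(600)) + 50
  out <- snip_baseline(y, 300)
  expect_true(all(out$baseline <= y + 1e-12))
  expect_error(snip_baseline(rep(1, 100), 100), "iterations")
  expect_error(snip_baseline(rep(1, 100), 0), "iterations")
})

test_that("SNIP matches the literal per-iteration loop oracle", {
  set.seed(17)
  for (rep in 1:5) {
    y <- 100 + 0.05 * (1:451) + gauss_band(1:451, 200, 20, 80) +
      rnorm(451, 0, 2)
    expect_equal(snip_baseline(y, 400)$baseline, snip_oracle(y, 400),
                 tolerance = 1e-12)
  }
})

test_that("SNIP isolates a narrow peak from a linear ramp", {
  ax <- default_axis()
  peak <- gauss_band(ax, 1450, 12, 100)
  y <- 50 + 0.02 * (ax - 400) + peak
  corrected <- snip_baseline(y, 400)$corrected
  interior <- ax > 420 & ax < 3180
  expect_lt(max(abs(corrected - peak)[interior]), 5)  # < 5% of amplitude
})

test_that("mean normalization fixes the mean at one", {
  expect_equal(mean_normalize(rep(5, 100)), rep(1, 100))
  set.seed(3)
  y <- runif(200, 10, 20)
  expect_equal(mean(mean_normalize(y)), 1, tolerance = 1e-12)
  expect_identical(mean_normalize(mean_normalize(y)), mean_normalize(y))
  expect_error(mean_normalize(c(-1, 1, rep(0, 30))), "zero-mean")
})

test_that("median spectrum agrees with a sort-based oracle", {
  scan <- make_scan(c(5, 5), k = 2, noise_sd = 3, seed = 13)
  med <- median_spectrum(scan)
  norm <- t(apply(scan$pixels, 1, function(r) r / mean(r)))
  oracle <- apply(norm, 2, function(col) {
    s <- sort(col)
    (s[13])  # middle of 25
  })
  expect_equal(med$intensity, oracle)
  one <- hyper_scan(scan$wavenumber, scan$pixels[rep(1, 4), ], 2, 2)
  expect_equal(median_spectrum(one)$intensity,
               scan$pixels[1, ] / mean(scan$pixels[1, ]))
})

test_that("truncation keeps exactly the channels inside the ranges", {
  s <- make_bone_spectrum("decalcified", "compact_bone", noise_sd = 0)
  tr <- truncate_spectrum(s)
  expect_length(tr$wavenumber, 701 + 151)  # default 2 cm^-1 grid
  expect_true(all((tr$wavenumber >= 400 & tr$wavenumber <= 1800) |
                  (tr$wavenumber >= 2800 & tr$wavenumber <= 3100)))
  full <- truncate_spectrum(s, list(c(0, 4000)))
  expect_identical(full$intensity, s$intensity)
  expect_error(truncate_spectrum(s, list(c(10, 20))), "no channels")
})

test_that("rubber-band baseline is the lower convex hull", {
  ax <- seq(400, 1000, by = 2)
  # convex curve: hull touches every sampled point -> corrected == 0
  par <- raman_spectrum(ax, (ax - 700)^2 / 100)
  expect_equal(rubberband_baseline(par)$corrected$intensity,
               rep(0, length(ax)), tolerance = 1e-9)
  # single band on a flat zero baseline: correction is almost the identity
  band <- gauss_band(ax, 700, 30, 100)
  rb <- rubberband_baseline(raman_spectrum(ax, band))
  expect_lt(max(abs(rb$corrected$intensity - band)), 1e-6)
  # random spectra: corrected >= 0 with at least two exact zeros
  set.seed(23)
  for (i in 1:5) {
    y <- cumsum(rnorm(100)) + 30
    out <- rubberband_baseline(y)
    expect_true(all(out$corrected >= 0))
    expect_gte(sum(out$corrected == 0), 2)
    expect_true(all(out$baseline <= y + 1e-9))
  }
})

test_that("compact-bone chain is deterministic and marrow chain truncates", {
  scan <- make_scan(c(4, 4), roi = "compact_bone", k = 1, noise_sd = 2,
                    cosmic_ray_rate = 0.2, seed = 19)
  silicon <- make_silicon_spectrum(521.2)
  a <- preprocess_compact(scan, silicon)
  b <- preprocess_compact(scan, silicon)
  expect_identical(a$median$intensity, b$median$intensity)
  expect_equal(a$shift$delta, -1.2, tolerance = 0.05)
  marrow <- make_scan(c(4, 4), roi = "bone_marrow", k = 2, noise_sd = 2,
                      seed = 20)
  pre <- preprocess_marrow(marrow, make_silicon_spectrum(520))
  expect_length(pre$scan$wavenumber, 701 + 151)
  expect_true(all(pre$scan$pixels >= 0))
})
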